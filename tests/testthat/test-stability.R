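test_that("ARI handles worked examples and degenerate partitions", {
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_identical(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)
  expect_identical(adjusted_rand_index(rep(1, 5), c(1, 1, 2, 2, 3)), 0)
  expect_identical(adjusted_rand_index(1:5, 1:5), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("AMI handles worked examples, label invariance, and degeneracies", {
  expect_identical(adjusted_mutual_information(c(1, 1, 2, 2),
                                               c(1, 1, 2, 2)), 1)
  a <- c(1, 1, 2, 2, 3, 3)
  relab <- c(7, 7, 5, 5, 9, 9)
  expect_equal(adjusted_mutual_information(a, relab), 1, tolerance = 1e-12)
  expect_identical(adjusted_mutual_information(rep(1, 4), rep(1, 4)), 1)
  expect_identical(adjusted_mutual_information(rep(1, 4), c(1, 2, 1, 2)), 0)

  # exhaustive permutation oracle at n = 4: E[MI] over all 4! relabelings
  b <- c(1, 2, 1, 2)
  a4 <- c(1, 1, 2, 2)
  mi <- function(u, v) {
    ct <- table(u, v); n <- length(u)
    pu <- rowSums(ct) / n; pv <- colSums(ct) / n
    s <- 0
    for (i in seq_along(pu)) for (j in seq_along(pv)) {
      if (ct[i, j] > 0)
        s <- s + ct[i, j] / n * log((ct[i, j] / n) / (pu[i] * pv[j]))
    }
    s
  }
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                 c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                 c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                 c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  emi <- mean(apply(perms, 1, function(p) mi(a4, b[p])))
  h <- log(2)  # both entropies
  expected <- unname((mi(a4, b) - emi) / ((h + h) / 2 - emi))
  expect_lt(abs(adjusted_mutual_information(a4, b) - expected), 1e-12)
})

test_that("ARI and AMI match brute-force oracles on random partitions", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    a <- sample.int(sample(2:4, 1), n, replace = TRUE)
    b <- sample.int(sample(2:4, 1), n, replace = TRUE)
    if (length(unique(a)) < 2) a[1:2] <- c(1, 2)
    if (length(unique(b)) < 2) b[1:2] <- c(1, 2)
    expect_lt(abs(adjusted_rand_index(a, b) - brute_ari(a, b)), 1e-12)
    expect_lt(abs(adjusted_mutual_information(a, b) - brute_ami(a, b)),
              1e-12)
    # symmetry
    expect_lt(abs(adjusted_rand_index(a, b) - adjusted_rand_index(b, a)),
              1e-12)
    expect_lt(abs(adjusted_mutual_information(a, b) -
                    adjusted_mutual_information(b, a)), 1e-12)
  }
})

test_that("ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:50) {
    a <- sample.int(4, 30, replace = TRUE)
    b <- sample.int(3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI is centered at zero under random relabeling", {
  set.seed(12)
  a <- sample.int(4, 100, replace = TRUE)
  b <- sample.int(3, 100, replace = TRUE)
  vals <- replicate(10000, adjusted_rand_index(a, b[sample.int(100)]))
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("stability search separates stable from unstable data", {
  b <- blob_square(25, sep = 8, seed = 13)
  tab <- stability_search(b$x, list(c(2, 2)), c(20, 40), n_repeats = 5,
                          seed = 14)
  expect_s3_class(tab, "stability_table")
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$ari_mean >= 0.95))
  expect_true(all(tab$ami_mean >= 0.95))

  # unstructured data: runs partition the same noise realization, so their
  # agreement is well below the structured case but not chance-level zero
  # (the chance correction zeroes only independent partitions)
  set.seed(15)
  noise <- matrix(rnorm(500 * 20), 500, 20)
  ntab <- stability_search(noise, list(c(2, 2)), 30, n_repeats = 5,
                           seed = 16)
  expect_lt(ntab$ari_mean, 0.5)
  expect_lt(ntab$ari_mean, min(tab$ari_mean) - 0.3)
})

test_that("n_repeats = 2 yields exactly one pair per cell", {
  b <- blob_square(10, seed = 17)
  tab <- stability_search(b$x, list(c(2, 2)), 10, n_repeats = 2, seed = 1)
  expect_identical(nrow(tab), 1L)
  expect_true(is.finite(tab$ari_mean))
  expect_true(is.na(tab$ari_se))  # sd of one pair is undefined
})

test_that("select_config maximizes stability with parsimony tie-breaks", {
  one <- tibble::tibble(dx = 2, dy = 2, dims = "2x2", epochs = 100,
                        ari_mean = 0.8, ari_se = 0.01, ami_mean = 0.8,
                        ami_se = 0.01, n_repeats = 5L)
  expect_identical(select_config(one)$epochs, 100)

  tie <- dplyr::bind_rows(one, dplyr::mutate(one, epochs = 260),
                          dplyr::mutate(one, epochs = 200))
  tie$ari_mean <- c(0.7, 0.9, 0.9); tie$ami_mean <- c(0.7, 0.9, 0.9)
  expect_identical(select_config(tie)$epochs, 200)

  dom <- dplyr::bind_rows(
    dplyr::mutate(one, dx = 3, dy = 3, dims = "3x3", epochs = 200,
                  ari_mean = 0.85, ami_mean = 0.85),
    dplyr::mutate(one, epochs = 200, ari_mean = 0.95, ami_mean = 0.95),
    dplyr::mutate(one, epochs = 40, ari_mean = 0.6, ami_mean = 0.6))
  sel <- select_config(dom)
  expect_identical(sel$dims, c(2, 2))
  expect_identical(sel$epochs, 200)

  bad <- dplyr::mutate(one, ari_mean = NaN, ami_mean = NaN)
  expect_error(select_config(bad), "NaN")
  expect_error(select_config(one[0, ]), "empty")
})

test_that("two-step tuning screens grids then sweeps epochs", {
  b <- blob_square(20, sep = 8, seed = 18)
  tn <- tune_som(b$x, list(c(2, 2), c(3, 3), c(4, 4)), c(20, 40),
                 n_repeats = 4, screen_epochs = 20, n_keep = 2, seed = 19)
  expect_identical(nrow(tn$step1), 3L)
  expect_identical(length(unique(tn$step2$dims)), 2L)
  expect_identical(tn$selected$dims, c(2, 2))  # true structure is 2x2
})
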