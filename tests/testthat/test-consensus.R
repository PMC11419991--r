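test_that("ensembles have the right shape and agree on separable data", {
  b <- blob_square(15, sep = 8, seed = 20)
  ens <- run_ensemble(b$x, c(2, 2), 20, n_runs = 5, seed = 21)
  expect_identical(dim(ens$labels), c(5L, 60L))
  prs <- combn(5, 2)
  aris <- apply(prs, 2, function(ij)
    adjusted_rand_index(ens$labels[ij[1], ], ens$labels[ij[2], ]))
  expect_true(all(aris >= 0.95))
  expect_error(run_ensemble(b$x, c(2, 2), 10, n_runs = 1), "n_runs")
})

test_that("forcing one seed reproduces identical ensemble rows", {
  b <- blob_square(10, seed = 22)
  l1 <- som_assign(som_fit(b$x, c(2, 2), 15, seed = 5), b$x)$label
  l2 <- som_assign(som_fit(b$x, c(2, 2), 15, seed = 5), b$x)$label
  expect_identical(l1, l2)
})

test_that("consensus matrix counts co-assignments exactly", {
  l <- rbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 2, 2))  # identical up to relabel
  m <- build_consensus_matrix(l)
  expect_true(all(m %in% c(0, 1)))
  expect_identical(m, brute_consensus(l))

  l2 <- rbind(c(1, 2), c(1, 1))
  expect_identical(build_consensus_matrix(l2)[1, 2], 0.5)

  set.seed(23)
  l3 <- matrix(sample.int(3, 5 * 18, replace = TRUE), 5, 18)
  m3 <- build_consensus_matrix(l3)
  expect_equal(m3, brute_consensus(l3), tolerance = 1e-12)
  expect_identical(m3, t(m3))
  expect_true(all(diag(m3) == 1))
})

test_that("consensus partition recovers blocks and matches brute-force linkage", {
  blocks <- rep(1:3, times = c(4, 3, 5))
  m <- outer(blocks, blocks, "==") * 1
  expect_identical(adjusted_rand_index(consensus_partition(m, 3), blocks), 1)
  expect_identical(consensus_partition(m, 1), rep(1L, 12))
  expect_error(consensus_partition(m, 13), "between 1")

  set.seed(24)
  for (i in 1:5) {
    mm <- matrix(runif(100), 10, 10)
    mm <- (mm + t(mm)) / 2
    diag(mm) <- 1
    for (k in 2:4) {
      ours <- consensus_partition(mm, k)
      brute <- brute_average_linkage(1 - mm, k)
      expect_identical(adjusted_rand_index(ours, brute), 1)
    }
  }
})

test_that("representative-run selection is an exhaustive argmax with low tie-break", {
  l <- rbind(c(1, 1, 2, 2), c(1, 2, 1, 2), c(2, 2, 1, 1))
  final <- c(1, 1, 2, 2)
  expect_identical(as.integer(select_representative_run(l, final)), 1L)

  same <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_identical(as.integer(select_representative_run(same, final)), 1L)

  set.seed(25)
  l4 <- matrix(sample.int(4, 6 * 40, replace = TRUE), 6, 40)
  fin <- sample.int(4, 40, replace = TRUE)
  pick <- select_representative_run(l4, fin)
  scores <- sapply(1:6, function(r)
    (adjusted_rand_index(l4[r, ], fin) +
       adjusted_mutual_information(l4[r, ], fin)) / 2)
  expect_identical(as.integer(pick), which.max(scores))
})

test_that("consensus partition is invariant to per-run relabeling", {
  b <- blob_square(12, sep = 6, seed = 26)
  ens <- run_ensemble(b$x, c(2, 2), 15, n_runs = 6, seed = 27)
  final <- consensus_partition(build_consensus_matrix(ens), 4)
  set.seed(28)
  shuffled <- ens$labels
  for (r in seq_len(nrow(shuffled))) {
    perm <- sample.int(4)
    shuffled[r, ] <- perm[shuffled[r, ]]
  }
  final2 <- consensus_partition(build_consensus_matrix(shuffled), 4)
  expect_identical(adjusted_rand_index(final, final2), 1)
})

test_that("archetype summaries reproduce planted templates and effects", {
  cfg <- synth_config(n_subjects = 8, n_runs = 1, n_nodes = 12,
                      noise_sd = 0, seed = 30)
  tpl <- generate_templates(cfg)
  ds <- simulate_dataset(cfg, tpl)
  asg <- ds$truth$assignments
  class(asg) <- c("som_assignment", class(asg))
  attr(asg, "dims") <- cfg$grid_dims
  summ <- suppressWarnings(summarize_archetypes(ds$connectomes, asg))
  for (nm in names(summ$means)) {
    if (is.null(summ$means[[nm]])) next
    expect_equal(summ$means[[nm]], tpl$templates[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_identical(sum(summ$sizes$n), 8L)

  # X-margin difference recovers the planted anterior block effect
  cfg2 <- synth_config(n_subjects = 120, n_runs = 1, n_nodes = 15,
                       noise_sd = 0.2, block_effect = 0.4, seed = 31)
  ds2 <- simulate_dataset(cfg2)
  asg2 <- ds2$truth$assignments
  class(asg2) <- c("som_assignment", class(asg2))
  attr(asg2, "dims") <- cfg2$grid_dims
  s2 <- summarize_archetypes(ds2$connectomes, asg2)
  ant <- which(default_partition(15) == "anterior")
  dm <- s2$margins$x$diff
  ant_vals <- dm[ant, ant][upper.tri(dm[ant, ant])]
  se <- 0.2 / sqrt(60)  # edge noise / sqrt(obs per margin), per-edge scale
  expect_lt(abs(mean(ant_vals) - 0.4), 3 * se)
  off <- dm
  off[ant, ant] <- NA
  expect_lt(max(abs(off[upper.tri(off)]), na.rm = TRUE), 0.3)
})

test_that("summaries warn on empty archetypes and single members are exact", {
  cfg <- synth_config(n_subjects = 2, n_runs = 1, n_nodes = 10,
                      noise_sd = 0.1, seed = 32)
  ds <- simulate_dataset(cfg)
  asg <- ds$truth$assignments
  class(asg) <- c("som_assignment", class(asg))
  attr(asg, "dims") <- cfg$grid_dims
  expect_warning(summ <- summarize_archetypes(ds$connectomes, asg), "empty")
  occupied <- sprintf("x%d_y%d", asg$x[1], asg$y[1])
  if (asg$cell[1] != asg$cell[2]) {
    expect_equal(summ$means[[occupied]],
                 ds$connectomes$matrices[, , 1], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("full consensus clustering recovers planted archetypes", {
  st <- tiny_study(seed = 33, n_subjects = 40, n_runs = 2, n_nodes = 20)
  red <- suppressWarnings(reduce_dataset(st$connectomes, n_sim = 100,
                                         seed = 34))
  cons <- consensus_cluster(red, c(2, 2), 50, n_runs = 20, seed = 35)
  expect_gte(adjusted_rand_index(cons$final_labels,
                                 st$truth$assignments$cell), 0.9)
  expect_identical(dim(cons$consensus_matrix),
                   c(nrow(red$scores), nrow(red$scores)))
  expect_true(all(cons$per_run$ari >= -1 & cons$per_run$ari <= 1))
  expect_s3_class(tidy(cons), "tbl_df")
  expect_identical(glance(cons)$n_clusters, 4L)
})

test_that("consensus is at least as stable as individual runs", {
  wins <- 0
  for (rep in 1:20) {
    st <- tiny_study(seed = 100 + rep, n_subjects = 20, n_runs = 2,
                     n_nodes = 16, noise_sd = 0.35)
    red <- suppressWarnings(reduce_dataset(st$connectomes,
                                           n_components = 2))
    ens <- run_ensemble(red, c(2, 2), 15, n_runs = 8, seed = 200 + rep)
    final <- consensus_partition(build_consensus_matrix(ens), 4)
    to_final <- mean(sapply(1:8, function(r)
      adjusted_rand_index(ens$labels[r, ], final)))
    prs <- combn(8, 2)
    between <- mean(apply(prs, 2, function(ij)
      adjusted_rand_index(ens$labels[ij[1], ], ens$labels[ij[2], ])))
    if (to_final >= between - 1e-12) wins <- wins + 1
  }
  expect_gte(wins, 18)
})
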