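test_that("Box-Cox rescaling pins the range and finds the right lambda", {
  set.seed(50)
  x <- rexp(200) + 0.5
  tr <- boxcox_rescale(x)
  expect_equal(min(tr$scores), 1)
  expect_equal(max(tr$scores), 100)

  # lambda forced to 1: affine transform, so rescaling raw x is identical
  tr1 <- boxcox_rescale(x, lambda = 1)
  expect_equal(tr1$scores, 1 + 99 * (x - min(x)) / (max(x) - min(x)),
               tolerance = 1e-12)

  # log-normal data: MLE lambda near 0
  set.seed(51)
  xl <- exp(rnorm(5000))
  expect_lt(abs(boxcox_rescale(xl)$lambda), 0.1)

  expect_error(boxcox_rescale(rep(3, 10)), "distinct")
  expect_error(boxcox_rescale(c(1, NA, 2, 3)), "missing")
})

test_that("Box-Cox profile-likelihood lambda agrees with MASS::boxcox", {
  skip_if_not_installed("MASS")
  set.seed(52)
  x <- rgamma(400, shape = 2)
  ours <- boxcox_rescale(x)$lambda
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 1 / 400), plotit = FALSE)
  theirs <- bc$x[which.max(bc$y)]
  expect_equal(ours, theirs, tolerance = 0.01)
})

test_that("Box-Cox transforms invert to the shifted raw scores", {
  set.seed(53)
  x <- rnorm(100)  # min < 0 forces a shift
  tr <- boxcox_rescale(x)
  back <- boxcox_inverse(tr$y, tr$lambda, tr$shift)
  expect_equal(back, x, tolerance = 1e-8)
})

test_that("behavior preprocessing drops incomplete rows and records transforms", {
  beh <- tibble::tibble(subject_id = 1:10,
                        a = c(NA, rexp(9)), b = rnorm(10))
  expect_message(pre <- preprocess_behaviors(beh), "dropping 1")
  expect_identical(nrow(pre$scores), 9L)
  expect_true(all(pre$scores$a >= 1 - 1e-9 & pre$scores$a <= 100 + 1e-9))
  expect_identical(pre$transforms$behavior, c("a", "b"))
})

test_that("two-way ANOVA matches an explicit sums-of-squares oracle", {
  # balanced 2x2 with cell values (1,2),(1,2),(1,2),(5,6)
  s <- c(1, 2, 1, 2, 1, 2, 5, 6)
  x <- c(1, 1, 2, 2, 1, 1, 2, 2)
  y <- c(1, 1, 1, 1, 2, 2, 2, 2)
  res <- anova_grid(s, x, y)

  cellm <- tapply(s, list(x, y), mean)
  rowm <- tapply(s, x, mean); colm <- tapply(s, y, mean); gm <- mean(s)
  ss_x <- 4 * sum((rowm - gm)^2)
  ss_y <- 4 * sum((colm - gm)^2)
  ss_int <- 2 * sum((cellm - outer(rowm, colm, "+") + gm)^2)
  ss_err <- sum((s - cellm[cbind(x, y)])^2)
  f_int <- (ss_int / 1) / (ss_err / 4)
  expect_equal(res$statistic[res$term == "X:Y"], f_int, tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "X"], (ss_x / 1) / (ss_err / 4),
               tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "Y"], (ss_y / 1) / (ss_err / 4),
               tolerance = 1e-10)
})

test_that("ANOVA degenerate inputs behave as documented", {
  res <- anova_grid(rep(2, 12), rep(1:2, 6), rep(1:2, each = 6))
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p.value == 1))

  expect_warning(
    res1 <- anova_grid(rnorm(12), rep(1, 12), rep(1:2, 6)),
    "single level")
  expect_true(is.na(res1$p.value[res1$term == "X"]))
  expect_false(is.na(res1$p.value[res1$term == "Y"]))
})

test_that("planted main effects drive the right ANOVA term", {
  set.seed(54)
  x <- rep(1:2, each = 100); y <- rep(rep(1:2, each = 50), 2)
  s <- 2 * (x == 2) + rnorm(200, sd = 0.5)
  res <- anova_grid(s, x, y)
  expect_lt(res$p.value[res$term == "X"], 1e-12)
  expect_gt(res$p.value[res$term == "Y"], 0.01)
  expect_gt(res$p.value[res$term == "X:Y"], 0.01)
})

test_that("the mixed model matches ANOVA with one run per subject", {
  set.seed(55)
  x <- rep(1:2, each = 60); y <- rep(rep(1:2, each = 30), 2)
  s <- 1.2 * (x == 2) + 0.8 * xor(x == 2, y == 2) + rnorm(120)
  an <- anova_grid(s, x, y)
  lm_ <- lme_grid(s, x, y, subject = seq_along(s))
  expect_true(all(lm_$converged))
  # same significance ordering across terms
  expect_identical(order(an$p.value), order(lm_$p.value))
  expect_equal(lm_$p.value, an$p.value, tolerance = 0.3)
})

test_that("the mixed model guards type-I error under replicated runs", {
  # pseudo-replication: each subject's cell is fixed, its runs replicate a
  # subject-constant null score; the naive ANOVA treats the replicated rows
  # as independent and inflates, the random intercept does not
  set.seed(56)
  n_sub <- 40; n_runs <- 4
  hits_lme <- hits_anova <- 0
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    xs <- sample(1:2, n_sub, replace = TRUE)
    ys <- sample(1:2, n_sub, replace = TRUE)
    subj <- rep(1:n_sub, each = n_runs)
    x <- rep(xs, each = n_runs); y <- rep(ys, each = n_runs)
    s <- rep(rnorm(n_sub), each = n_runs) +
      rnorm(n_sub * n_runs, sd = 0.1)
    pa <- anova_grid(s, x, y)$p.value[1]
    pl <- lme_grid(s, x, y, subj)$p.value[1]
    if (!is.na(pa) && pa < 0.05) hits_anova <- hits_anova + 1
    if (!is.na(pl) && pl < 0.05) hits_lme <- hits_lme + 1
  }
  expect_lte(hits_lme / n_rep, 1.5 * 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(hits_anova / n_rep, hits_lme / n_rep)
  expect_gt(hits_anova / n_rep, 0.15)
})

test_that("degenerate mixed-model fits are flagged", {
  res <- lme_grid(rep(1, 40), rep(1:2, 20), rep(1:2, each = 20),
                  rep(1:10, 4))
  expect_true(all(!res$converged))
})

test_that("post-hoc comparisons respect the one-coordinate restriction", {
  set.seed(57)
  x <- rep(1:2, each = 100); y <- rep(rep(1:2, each = 50), 2)
  s <- rnorm(200)
  ph <- posthoc_pairwise(s, x, y)
  expect_identical(nrow(ph), 4L)
  expect_true(all((ph$x1 != ph$x2) + (ph$y1 != ph$y2) == 1))
  expect_true(all(ph$p_fdr >= ph$p.value - 1e-15))
  expect_true(all(ph$p_bonf >= ph$p_fdr - 1e-15))
  expect_gt(min(ph$p_fdr), 0.05)  # identical distributions

  ph_all <- posthoc_pairwise(s, x, y, restriction = "all-pairs")
  expect_identical(nrow(ph_all), 6L)

  # planted XOR: all four restricted comparisons significant, alternating sign
  s2 <- 2 * xor(x == 2, y == 2) + rnorm(200, sd = 0.4)
  ph2 <- posthoc_pairwise(s2, x, y)
  expect_true(all(ph2$p_bonf < 1e-6))
  expect_identical(sum(ph2$mean_diff > 0), 2L)
  expect_identical(sum(ph2$mean_diff < 0), 2L)
})

test_that("p-value corrections match hand-computed values", {
  expect_identical(correct_pvalues(0.03, "BH"), 0.03)
  expect_identical(correct_pvalues(0.3, "bonferroni"), 0.3)
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4), tolerance = 1e-15)
  expect_identical(correct_pvalues(c(0.3, 0.2, 0.5, 0.9), "bonferroni"),
                   c(1, 0.8, 1, 1))
  expect_error(correct_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(58)
  for (i in 1:20) {
    p <- runif(sample(3:10, 1))
    bh <- correct_pvalues(p, "BH"); bf <- correct_pvalues(p, "bonferroni")
    expect_true(all(bh >= p - 1e-15))
    expect_true(all(bf >= bh - 1e-15))
    ord <- order(p)
    expect_true(all(diff(bh[ord]) >= -1e-15))
  }
})

test_that("the association battery recovers planted coding and degeneracy", {
  cfg <- synth_config(n_subjects = 200, n_runs = 1, n_nodes = 15,
                      noise_sd = 0.2, run_consistency = 1, seed = 60)
  st <- simulate_study(cfg)
  asg <- st$truth$assignments
  class(asg) <- c("som_assignment", class(asg))
  attr(asg, "dims") <- cfg$grid_dims

  assoc <- associate_behaviors(st$behavior, asg, mode = "runs")
  terms <- assoc$terms
  expect_lt(terms$p.value[terms$behavior == "beh_x" & terms$term == "X"],
            0.001)
  expect_lt(terms$p.value[terms$behavior == "beh_y" & terms$term == "Y"],
            0.001)
  expect_lt(terms$p.value[terms$behavior == "beh_xor" &
                            terms$term == "X:Y"], 0.001)

  summ <- summarize_archetypes(st$connectomes, asg)
  deg <- degeneracy_report(assoc, summ)
  cls <- deg$classification
  expect_identical(cls$coding[cls$behavior == "beh_x"], "X-coded")
  expect_identical(cls$coding[cls$behavior == "beh_y"], "Y-coded")
  expect_identical(cls$coding[cls$behavior == "beh_xor"],
                   "interaction-coded")
  expect_identical(cls$coding[cls$behavior == "beh_null"], "uncoded")

  pairs <- deg$degenerate_pairs
  expect_identical(nrow(pairs), 1L)
  expect_identical(sort(c(paste0(pairs$x1, pairs$y1),
                          paste0(pairs$x2, pairs$y2))), c("12", "21"))
  expect_gte(pairs$distance, pairs$median_distance)
})

test_that("degeneracy without summaries skips the distance criterion", {
  set.seed(61)
  x <- rep(1:2, each = 100); y <- rep(rep(1:2, each = 50), 2)
  beh <- tibble::tibble(subject_id = 1:200,
                        b = 1.5 * xor(x == 2, y == 2) + rnorm(200, 0.3))
  asg <- tibble::tibble(subject_id = 1:200, run_id = 1L, x = x, y = y)
  assoc <- associate_behaviors(beh, asg)
  deg <- degeneracy_report(assoc, summaries = NULL)
  expect_false(deg$distance_available)
  expect_identical(nrow(deg$degenerate_pairs), 1L)
  expect_true(is.na(deg$degenerate_pairs$distance))
})
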