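#' Histogram of unique cluster assignments per subject
#'
#' Counts, for each subject, how many distinct cluster labels its runs
#' received, and summarizes the distribution. Subjects with no labeled runs
#' are excluded with a warning.
#'
#' @param assignment Tibble with `subject_id` and `label` columns (e.g. a
#'   `som_assignment`).
#' @return List with `per_subject` (tibble: subject_id, n_unique),
#'   `histogram` (tibble: n_unique, count), and `mean`.
#' @export
unique_cluster_histogram <- function(assignment) {
  stopifnot(all(c("subject_id", "label") %in% names(assignment)))
  ok <- !is.na(assignment$label)
  if (any(!ok)) {
    warning(sum(!ok), " unlabeled run(s) dropped")
    assignment <- assignment[ok, ]
  }
  per <- dplyr::summarise(dplyr::group_by(assignment, .data$subject_id),
                          n_unique = dplyr::n_distinct(.data$label),
                          .groups = "drop")
  hist <- dplyr::count(per, .data$n_unique, name = "count")
  list(per_subject = per, histogram = hist, mean = mean(per$n_unique))
}

#' Monte Carlo null for within-subject assignment consistency
#'
#' Simulates studies in which every run of every subject receives an i.i.d.
#' label, and returns the distribution over simulations of the mean
#' unique-clusters-per-subject. With uniform labels the analytic mean is
#' `k * (1 - (1 - 1/k)^R)`.
#'
#' @param n_subjects,n_runs Study shape.
#' @param k Number of clusters.
#' @param n_sims Number of simulated studies (>= 100).
#' @param seed RNG seed.
#' @param probs Optional label probabilities (length `k`); uniform by
#'   default. Empirical cluster frequencies can be supplied when the observed
#'   clusters are unbalanced.
#' @return Object of class `assignment_null`: `means` (per-sim mean unique
#'   counts), `mean`, `sd`, and the parameters.
#' @export
random_assignment_null <- function(n_subjects, n_runs, k, n_sims = 1000L,
                                   seed = 1L, probs = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (n_sims < 100) stop("n_sims must be >= 100")
  if (!is.null(probs) && length(probs) != k)
    stop("probs must have length k")
  set.seed(seed)
  means <- numeric(n_sims)
  chunk <- max(1L, min(n_sims, as.integer(ceiling(2e6 / (n_subjects * n_runs)))))
  done <- 0L
  while (done < n_sims) {
    b <- min(chunk, n_sims - done)
    rows <- n_subjects * b
    m <- matrix(sample.int(k, rows * n_runs, replace = TRUE, prob = probs),
                rows, n_runs)
    dup <- matrix(FALSE, rows, n_runs)
    if (n_runs > 1) {
      for (j in 2:n_runs) {
        for (l in 1:(j - 1)) dup[, j] <- dup[, j] | (m[, j] == m[, l])
      }
    }
    counts <- n_runs - rowSums(dup)
    means[done + seq_len(b)] <-
      colMeans(matrix(counts, n_subjects, b))
    done <- done + b
  }
  structure(list(means = means, mean = mean(means), sd = sd(means),
                 n_subjects = as.integer(n_subjects),
                 n_runs = as.integer(n_runs), k = as.integer(k),
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 probs = probs),
            class = "assignment_null")
}

#' Test observed assignment consistency against the random null
#'
#' One-sided empirical p-value: the fraction of null simulations whose mean
#' unique-clusters-per-subject is less than or equal to the observed mean.
#' Small p means subjects' runs are assigned more consistently than random.
#'
#' @param assignment Observed assignment tibble (`subject_id`, `label`), or
#'   the output of [unique_cluster_histogram()].
#' @param null An `assignment_null` from [random_assignment_null()]. Its
#'   `n_subjects`/`n_runs` must match the observed structure.
#' @return Object of class `consistency_report`: observed histogram and mean,
#'   null mean and sd, `p` (reported as `1 / n_sims` with `p_label`
#'   `"< 1/n_sims"` when no null value is as small), `n_sims`, `seed`.
#' @export
consistency_test <- function(assignment, null) {
  stopifnot(inherits(null, "assignment_null"))
  obs <- if (!is.data.frame(assignment) && is.list(assignment) &&
             !is.null(assignment[["per_subject"]]))
    assignment else unique_cluster_histogram(assignment)
  if (nrow(obs$per_subject) != null$n_subjects)
    stop("observed n_subjects (", nrow(obs$per_subject),
         ") does not match the null (", null$n_subjects, ")")
  if (max(obs$per_subject$n_unique) > min(null$n_runs, null$k))
    stop("observed unique counts exceed min(n_runs, k) of the null")
  n_le <- sum(null$means <= obs$mean)
  p <- n_le / null$n_sims
  structure(list(observed_mean = obs$mean, histogram = obs$histogram,
                 null_mean = null$mean, null_sd = null$sd,
                 p = if (n_le == 0) 1 / null$n_sims else p,
                 p_label = if (n_le == 0)
                   sprintf("< 1/%d", null$n_sims) else sprintf("%g", p),
                 n_sims = null$n_sims, seed = null$seed),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report> observed mean unique clusters ",
      format(x$observed_mean, digits = 4), " vs null ",
      format(x$null_mean, digits = 4), " (sd ",
      format(x$null_sd, digits = 3), "), p ", x$p_label, "\n", sep = "")
  invisible(x)
}
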