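partition_args <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 observations")
  list(a = as.integer(factor(a)), b = as.integer(factor(b)))
}

# partitions equal up to relabeling: contingency has one nonzero per row & col
partitions_identical <- function(a, b) {
  ct <- table(a, b)
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' `ARI = (sum_ij C(n_ij, 2) - E) / (M - E)` with
#' `E = sum_i C(a_i, 2) * sum_j C(b_j, 2) / C(n, 2)` and
#' `M = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2`, from the contingency table
#' of the two labelings. Invariant to label permutation. Degenerate cases
#' where the chance correction is undefined (e.g. both partitions a single
#' cluster) return 1 when the partitions are identical and 0 otherwise.
#'
#' @param a,b Label vectors of equal length (any types coercible to factors).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  p <- partition_args(a, b)
  n <- length(p$a)
  ct <- table(p$a, p$b)
  sum_ij <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  cn2 <- choose(n, 2)
  # integer-scaled form of (sum_ij - E)/(M - E): exact for rational results
  num <- 2 * (sum_ij * cn2 - sa * sb)
  den <- (sa + sb) * cn2 - 2 * sa * sb
  if (den == 0)
    return(as.numeric(partitions_identical(p$a, p$b)))
  num / den
}

# expected mutual information under the permutation (hypergeometric) model
expected_mi <- function(ai, bj, n) {
  emi <- 0
  lfn <- lfactorial(n)
  for (a in ai) {
    for (b in bj) {
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lfactorial(a) + lfactorial(b) +
        lfactorial(n - a) + lfactorial(n - b) - lfn -
        lfactorial(nij) - lfactorial(a - nij) - lfactorial(b - nij) -
        lfactorial(n - a - b + nij)
      emi <- emi + sum(nij / n * log(n * nij / (a * b)) * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two partitions, corrected by its expectation
#' under the permutation model (hypergeometric marginals) and normalized by
#' the arithmetic mean of the two entropies:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`. Natural logarithms.
#' Degenerate conventions follow [adjusted_rand_index()]: identical
#' single-cluster partitions give 1; a single-cluster vs a multi-cluster
#' partition gives 0.
#'
#' @inheritParams adjusted_rand_index
#' @return AMI (1 for identical partitions with >= 2 clusters).
#' @export
adjusted_mutual_information <- function(a, b) {
  p <- partition_args(a, b)
  n <- length(p$a)
  ct <- table(p$a, p$b)
  ai <- rowSums(ct); bj <- colSums(ct)
  pi_ <- ai / n; pj <- bj / n
  ha <- -sum(pi_ * log(pi_))
  hb <- -sum(pj * log(pj))
  pij <- ct / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  emi <- expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12)
    return(as.numeric(partitions_identical(p$a, p$b)))
  (mi - emi) / denom
}

#' Clustering-stability grid search over SOM dimensions and epochs
#'
#' For every combination of grid dimensions and epoch count, trains
#' `n_repeats` SOMs from distinct seeds, assigns the data, and records the
#' mean and standard error of ARI and AMI over all `C(n_repeats, 2)` pairs of
#' runs. Higher values mean the configuration clusters the data more
#' reproducibly.
#'
#' @param features Observations x features matrix or [reduce_dataset()]
#'   output.
#' @param dims_list List of `c(Dx, Dy)` grids.
#' @param epochs_list Integer vector of epoch counts.
#' @param n_repeats Repeats per cell (>= 2).
#' @param seed Base seed; repeat seeds are derived from it.
#' @return Tibble of class `stability_table` with columns `dx`, `dy`, `dims`,
#'   `epochs`, `ari_mean`, `ari_se`, `ami_mean`, `ami_se`, `n_repeats`.
#' @export
stability_search <- function(features, dims_list, epochs_list,
                             n_repeats = 20L, seed = 1L) {
  if (length(dims_list) == 0 || length(epochs_list) == 0)
    stop("dims_list and epochs_list must be non-empty")
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  x <- as_feature_matrix(features)
  if (is.numeric(dims_list) && !is.list(dims_list))
    dims_list <- list(dims_list)

  cells <- tidyr::expand_grid(d = seq_along(dims_list), epochs = epochs_list)
  rows <- purrr::pmap(cells, function(d, epochs) {
    dims <- dims_list[[d]]
    seeds <- derive_seeds(seed + 7919L * d + epochs, n_repeats)
    labels <- lapply(seeds, function(s)
      som_assign(som_fit(x, dims, epochs, seed = s), x)$label)
    prs <- combn(n_repeats, 2)
    ari <- apply(prs, 2, function(ij)
      adjusted_rand_index(labels[[ij[1]]], labels[[ij[2]]]))
    ami <- apply(prs, 2, function(ij)
      adjusted_mutual_information(labels[[ij[1]]], labels[[ij[2]]]))
    tibble::tibble(
      dx = dims[1], dy = dims[2],
      dims = sprintf("%dx%d", dims[1], dims[2]), epochs = epochs,
      ari_mean = mean(ari), ari_se = sd(ari) / sqrt(length(ari)),
      ami_mean = mean(ami), ami_se = sd(ami) / sqrt(length(ami)),
      n_repeats = as.integer(n_repeats))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_table", class(out))
  out
}

#' Select the most stable SOM configuration
#'
#' Default rule: maximize `mean(ari_mean, ami_mean)`; ties are broken toward
#' fewer epochs, then toward the smaller grid (parsimony guards against
#' overfitting long trainings or large grids that only look stable).
#'
#' @param table A `stability_table` from [stability_search()].
#' @param rule `"mean"` (mean of ARI and AMI), `"ari"`, or `"ami"`.
#' @return List with `dims` (`c(Dx, Dy)`), `epochs`, and `score`.
#' @export
select_config <- function(table, rule = c("mean", "ari", "ami")) {
  rule <- match.arg(rule)
  if (nrow(table) == 0) stop("empty stability table")
  score <- switch(rule,
                  mean = (table$ari_mean + table$ami_mean) / 2,
                  ari = table$ari_mean, ami = table$ami_mean)
  if (all(is.na(score))) stop("all stability scores are NaN")
  ord <- order(-score, table$epochs, table$dx * table$dy, table$dx)
  best <- table[ord[1], ]
  list(dims = c(best$dx, best$dy), epochs = best$epochs,
       score = score[ord[1]])
}

#' Two-step SOM fine-tuning
#'
#' Step 1 screens all candidate grid dimensions at a fixed epoch count
#' (`screen_epochs`, 100 by default) and keeps the `n_keep` most stable grids.
#' Step 2 sweeps the full epoch range for the surviving grids. The selected
#' configuration is the step-2 argmax under [select_config()].
#'
#' @inheritParams stability_search
#' @param screen_epochs Epoch count used in the screening step.
#' @param n_keep Number of grids surviving to step 2.
#' @param rule Selection rule passed to [select_config()].
#' @return List with `step1` and `step2` stability tables and `selected`.
#' @export
tune_som <- function(features, dims_list, epochs_list, n_repeats = 20L,
                     screen_epochs = 100L, n_keep = 2L, seed = 1L,
                     rule = "mean") {
  step1 <- stability_search(features, dims_list, screen_epochs,
                            n_repeats = n_repeats, seed = seed)
  score1 <- (step1$ari_mean + step1$ami_mean) / 2
  keep <- order(-score1, step1$dx * step1$dy)[seq_len(min(n_keep, nrow(step1)))]
  survivors <- dims_list[keep]
  step2 <- stability_search(features, survivors, epochs_list,
                            n_repeats = n_repeats, seed = seed + 1L)
  list(step1 = step1, step2 = step2,
       selected = select_config(step2, rule = rule))
}
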