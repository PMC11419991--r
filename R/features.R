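#' Connectome set container
#'
#' Stacks per-(subject, run) symmetric connectivity matrices (Fisher-z units)
#' with their labels. Matrices must be square, finite, and symmetric within
#' 1e-10.
#'
#' @param matrices N x N x n_obs array, or a list of N x N matrices.
#' @param subject_id,run_id Vectors of length n_obs.
#' @param node_labels Optional node names (length N).
#' @param network Optional node-to-network assignment (length N), used to
#'   reorder archetype summaries.
#' @return Object of class `connectome_set`.
#' @export
connectome_set <- function(matrices, subject_id, run_id,
                           node_labels = NULL, network = NULL) {
  if (is.list(matrices))
    matrices <- array(unlist(matrices),
                      dim = c(nrow(matrices[[1]]), ncol(matrices[[1]]),
                              length(matrices)))
  stopifnot(length(dim(matrices)) == 3)
  n <- dim(matrices)[1]
  if (dim(matrices)[2] != n) stop("matrices must be square")
  n_obs <- dim(matrices)[3]
  if (length(subject_id) != n_obs || length(run_id) != n_obs)
    stop("subject_id and run_id must have one entry per matrix")
  if (!all(is.finite(matrices))) stop("matrices must be finite")
  for (i in seq_len(n_obs)) {
    m <- matrices[, , i]
    if (max(abs(m - t(m))) > 1e-10)
      stop("matrix ", i, " is not symmetric within 1e-10")
  }
  if (!is.null(network) && length(network) != n)
    stop("network must have one entry per node")
  structure(list(matrices = matrices, subject_id = subject_id,
                 run_id = run_id,
                 node_labels = node_labels %||% paste0("n", seq_len(n)),
                 network = network),
            class = "connectome_set")
}

#' @export
print.connectome_set <- function(x, ...) {
  cat("<connectome_set> ", dim(x$matrices)[3], " observations, ",
      dim(x$matrices)[1], " x ", dim(x$matrices)[1], " nodes, ",
      length(unique(x$subject_id)), " subjects\n", sep = "")
  invisible(x)
}

#' Fisher z transform of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform used for functional
#' connectivity. Values with `|r| >= 1` are a domain error unless `clip = TRUE`,
#' in which case they are clipped to `+/-(1 - 1e-7)` first (degenerate inputs
#' can produce exact +/-1 correlations).
#'
#' @param r Correlations in (-1, 1).
#' @param clip Clip out-of-domain values instead of erroring.
#' @return Fisher-z values.
#' @seealso [fisher_z_inverse()]
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(!is.finite(r))) stop("r must be finite")
  if (any(abs(r) >= 1)) {
    if (!clip) stop("|r| >= 1; enable clip = TRUE to clip to +/-(1 - 1e-7)")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z values.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Vectorize the lower triangle of a symmetric matrix
#'
#' Extracts the strictly-lower-triangular entries in R's native column-major
#' order (column 1 rows 2..N, column 2 rows 3..N, ...), the documented order
#' used throughout the package. For an N x N matrix the result has length
#' `N * (N - 1) / 2`.
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of off-diagonal values.
#' @seealso [devectorize_lower_triangle()]
#' @export
vectorize_lower_triangle <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  m[lower.tri(m)]
}

#' @rdname vectorize_lower_triangle
#' @param v Vector of length `N * (N - 1) / 2`.
#' @return `devectorize_lower_triangle()`: the symmetric N x N matrix with
#'   zero diagonal whose lower triangle is `v`.
#' @export
devectorize_lower_triangle <- function(v) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8)
    stop("length of v is not a triangular number")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

# obs x edges matrix from a connectome_set
vectorize_set <- function(cs) {
  stopifnot(inherits(cs, "connectome_set"))
  n_obs <- dim(cs$matrices)[3]
  lw <- lower.tri(cs$matrices[, , 1])
  t(vapply(seq_len(n_obs), function(i) cs$matrices[, , i][lw],
           numeric(sum(lw))))
}

# eigenvalues of the feature correlation matrix, via the n x n Gram matrix
# when p > n (the nonzero spectra coincide); returns min(n - 1, p) values
corr_eigenvalues <- function(x) {
  n <- nrow(x); p <- ncol(x)
  z <- scale(x)
  r <- min(n - 1L, p)
  ev <- if (p <= n) {
    eigen(crossprod(z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(tcrossprod(z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  }
  pmax(ev[seq_len(r)], 0)
}

#' Null eigenvalue quantiles for Horn's parallel analysis
#'
#' Simulates `n_sim` standard-normal datasets of the given shape, computes the
#' eigenvalues of each dataset's feature correlation matrix, and returns the
#' per-rank `percentile` quantile. The null depends only on the data shape, so
#' one table can be reused across same-shape datasets.
#'
#' @param n_obs,n_features Shape of the data.
#' @param n_sim Number of Monte Carlo datasets (>= 100).
#' @param percentile Null quantile in (0, 100); 95 by default.
#' @param seed RNG seed for the null simulation.
#' @return Numeric vector of per-rank null quantiles (length
#'   `min(n_obs - 1, n_features)`), with the simulation parameters as
#'   attributes.
#' @export
pa_null_quantiles <- function(n_obs, n_features, n_sim = 10000L,
                              percentile = 95, seed = 1L) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  r <- min(n_obs - 1L, n_features)
  set.seed(seed)
  sims <- matrix(0, n_sim, r)
  for (s in seq_len(n_sim)) {
    z <- matrix(rnorm(n_obs * n_features), n_obs, n_features)
    sims[s, ] <- corr_eigenvalues(z)
  }
  q <- apply(sims, 2, quantile, probs = percentile / 100, names = FALSE)
  attributes(q) <- list(n_obs = n_obs, n_features = n_features,
                        n_sim = n_sim, percentile = percentile, seed = seed)
  q
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed correlation-matrix eigenvalues rank by rank against
#' the `percentile` quantile of eigenvalues from `n_sim` standard-normal
#' datasets of identical shape. The number of retained components is the
#' length of the leading prefix of ranks whose observed eigenvalue exceeds its
#' null quantile (counting stops at the first failure, so the retained set is
#' always a prefix).
#'
#' @param data Observations x features matrix.
#' @param n_sim Number of Monte Carlo null datasets (>= 100).
#' @param percentile Null quantile in (0, 100).
#' @param seed Seed for the null simulation (only the null draws consume
#'   randomness).
#' @param null_quantiles Optional precomputed [pa_null_quantiles()] table for
#'   this shape (checked), e.g. to share one null across same-shape datasets.
#' @return Integer number of components to retain, with attributes
#'   `observed_eigenvalues` and `null_quantiles`.
#' @export
parallel_analysis <- function(data, n_sim = 1000L, percentile = 95,
                              seed = 1L, null_quantiles = NULL) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (p >= n)
    warning("more features than observations: correlation matrix is rank deficient")
  if (is.null(null_quantiles)) {
    null_quantiles <- pa_null_quantiles(n, p, n_sim, percentile, seed)
  } else {
    if (attr(null_quantiles, "n_obs") != n ||
        attr(null_quantiles, "n_features") != p)
      stop("null_quantiles were computed for a different data shape")
  }
  obs <- corr_eigenvalues(data)
  r <- min(length(obs), length(null_quantiles))
  exceeds <- obs[seq_len(r)] > null_quantiles[seq_len(r)]
  n_retain <- if (!exceeds[1]) 0L else {
    fail <- which(!exceeds)
    if (length(fail)) fail[1] - 1L else r
  }
  structure(as.integer(n_retain),
            observed_eigenvalues = obs, null_quantiles = null_quantiles)
}

#' Reduce a connectome set to z-scored principal-component scores
#'
#' Vectorizes each connectome's lower triangle, drops constant edge columns
#' (with a warning), runs PCA on the centered data (no per-feature scaling:
#' edges share the Fisher-z scale), retains the number of components chosen by
#' parallel analysis (or `n_components` if given), and z-scores the retained
#' scores per component.
#'
#' @param cs A [connectome_set()], or an observations x features matrix.
#' @param n_sim,percentile,seed Parallel-analysis parameters; see
#'   [parallel_analysis()].
#' @param n_components Optional fixed number of components, bypassing
#'   parallel analysis.
#' @param null_quantiles Optional precomputed null table for this shape.
#' @return Object of class `reduced_features`: `scores` (obs x k, z-scored),
#'   `loadings`, `eigenvalues` (all PCA variances, non-increasing),
#'   `n_components`, `subject_id`, `run_id`, and the retention record.
#' @export
reduce_dataset <- function(cs, n_sim = 1000L, percentile = 95, seed = 1L,
                           n_components = NULL, null_quantiles = NULL) {
  if (inherits(cs, "connectome_set")) {
    x <- vectorize_set(cs)
    subject_id <- cs$subject_id; run_id <- cs$run_id
  } else {
    x <- as.matrix(cs)
    subject_id <- seq_len(nrow(x)); run_id <- rep(1L, nrow(x))
  }
  if (nrow(x) < 2) stop("need at least 2 observations")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0 || max(apply(x, 2, sd)) == 0)
    stop("no variance in the data: PCA undefined")

  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pca$sdev^2
  if (max(eig) < 1e-300) stop("no variance in the data: PCA undefined")

  if (is.null(n_components)) {
    n_components <- as.integer(parallel_analysis(
      x, n_sim = n_sim, percentile = percentile, seed = seed,
      null_quantiles = null_quantiles))
    if (n_components < 1) {
      warning("parallel analysis retained 0 components; keeping 1")
      n_components <- 1L
    }
  }
  n_components <- min(n_components, sum(pca$sdev > 1e-12))
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  scores <- scale(scores)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL

  structure(list(scores = scores,
                 loadings = pca$rotation[, seq_len(n_components), drop = FALSE],
                 eigenvalues = eig, n_components = n_components,
                 subject_id = subject_id, run_id = run_id,
                 pa = list(n_sim = n_sim, percentile = percentile,
                           seed = seed)),
            class = "reduced_features")
}

#' @export
print.reduced_features <- function(x, ...) {
  cat("<reduced_features> ", nrow(x$scores), " observations, ",
      x$n_components, " retained component(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
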