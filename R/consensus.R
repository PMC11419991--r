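#' Run an ensemble of independently seeded SOM clusterings
#'
#' Trains `n_runs` SOMs with distinct seeds at a fixed configuration and
#' stores every run's labels and grid coordinates.
#'
#' @param features Observations x features matrix or [reduce_dataset()]
#'   output.
#' @param dims,epochs SOM configuration (typically from [select_config()]).
#' @param n_runs Ensemble size (>= 2).
#' @param seed Base seed; run seeds are derived from it.
#' @return List of class `som_ensemble`: `labels` (n_runs x n_obs integer
#'   matrix), `x`, `y` (same shape, grid coordinates), `dims`, `epochs`,
#'   `seeds`.
#' @export
run_ensemble <- function(features, dims, epochs, n_runs = 100L, seed = 1L) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  x <- as_feature_matrix(features)
  seeds <- derive_seeds(seed, n_runs)
  labels <- matrix(0L, n_runs, nrow(x))
  cx <- matrix(0L, n_runs, nrow(x))
  cy <- matrix(0L, n_runs, nrow(x))
  for (r in seq_len(n_runs)) {
    asg <- tryCatch(
      som_assign(som_fit(x, dims, epochs, seed = seeds[r]), x),
      error = function(e) stop("ensemble run ", r, " failed: ",
                               conditionMessage(e)))
    labels[r, ] <- asg$label
    cx[r, ] <- asg$x
    cy[r, ] <- asg$y
  }
  structure(list(labels = labels, x = cx, y = cy, dims = dims,
                 epochs = epochs, seeds = seeds),
            class = "som_ensemble")
}

#' Consensus (co-assignment) matrix of a clustering ensemble
#'
#' `M[i, j]` is the fraction of runs in which observations i and j share a
#' cluster label: the probability of co-assignment. Invariant to per-run
#' label permutations; symmetric with unit diagonal.
#'
#' @param labels n_runs x n_obs label matrix (or a `som_ensemble`).
#' @return n_obs x n_obs matrix with entries in `[0, 1]`.
#' @export
build_consensus_matrix <- function(labels) {
  if (inherits(labels, "som_ensemble")) labels <- labels$labels
  labels <- as.matrix(labels)
  if (nrow(labels) < 2) stop("need at least 2 runs")
  n <- ncol(labels)
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(labels))) {
    l <- labels[r, ]
    m <- m + outer(l, l, "==")
  }
  m / nrow(labels)
}

#' Cut the consensus matrix into a final partition
#'
#' Hierarchical clustering with average linkage on the dissimilarity
#' `D = 1 - M`, cut to exactly `k` groups. If the cut produces fewer than `k`
#' distinct clusters (possible only under pathological ties) a warning is
#' issued.
#'
#' @param m Consensus matrix from [build_consensus_matrix()].
#' @param k Number of clusters (1 to n_obs).
#' @return Integer vector of final labels.
#' @export
consensus_partition <- function(m, k) {
  n <- nrow(m)
  if (k < 1 || k > n) stop("k must be between 1 and the number of observations")
  hc <- hclust(stats::as.dist(1 - m), method = "average")
  labels <- cutree(hc, k = k)
  if (length(unique(labels)) < k)
    warning("consensus cut produced fewer than k distinct clusters")
  as.integer(labels)
}

#' Select the ensemble run most similar to the consensus partition
#'
#' The representative run maximizes `mean(ARI, AMI)` against the consensus
#' labels (ties to the lowest run index). Its grid coordinates become the
#' archetype coordinates used downstream — this resolves the SOM
#' label-alignment problem, since grid axes are exchangeable across runs.
#'
#' @param labels n_runs x n_obs label matrix (or a `som_ensemble`).
#' @param final_labels Consensus partition.
#' @return Integer run index, with per-run scores in the `scores` attribute
#'   (tibble: run, ari, ami).
#' @export
select_representative_run <- function(labels, final_labels) {
  if (inherits(labels, "som_ensemble")) labels <- labels$labels
  scores <- purrr::map_dfr(seq_len(nrow(labels)), function(r)
    tibble::tibble(
      run = r,
      ari = adjusted_rand_index(labels[r, ], final_labels),
      ami = adjusted_mutual_information(labels[r, ], final_labels)))
  best <- which.max((scores$ari + scores$ami) / 2)
  structure(as.integer(best), scores = scores)
}

#' Consensus clustering of reduced connectome features
#'
#' The full consensus procedure: run an ensemble of independently seeded SOMs
#' at the chosen configuration, build the co-assignment consensus matrix, cut
#' it by average-linkage hierarchical clustering into `Dx * Dy` clusters, and
#' pick the representative run whose labels (and grid coordinates) best match
#' the consensus.
#'
#' @inheritParams run_ensemble
#' @return Object of class `consensus_result`: `consensus_matrix`,
#'   `final_labels`, `representative_run`, `assignment` (tibble with the
#'   representative run's label/x/y per observation, relabeled so `label` is
#'   the representative run's neuron index), `per_run` (tibble of per-run
#'   ARI/AMI vs the consensus), `ensemble`, `dims`, `epochs`.
#' @export
consensus_cluster <- function(features, dims, epochs, n_runs = 100L,
                              seed = 1L) {
  ens <- run_ensemble(features, dims, epochs, n_runs = n_runs, seed = seed)
  m <- build_consensus_matrix(ens)
  final <- consensus_partition(m, prod(dims))
  rep_run <- select_representative_run(ens, final)
  subject_id <- if (inherits(features, "reduced_features"))
    features$subject_id else seq_len(ncol(ens$labels))
  run_id <- if (inherits(features, "reduced_features"))
    features$run_id else rep(1L, ncol(ens$labels))
  assignment <- tibble::tibble(
    subject_id = subject_id, run_id = run_id,
    label = ens$labels[rep_run, ],
    x = ens$x[rep_run, ], y = ens$y[rep_run, ])
  attr(assignment, "dims") <- dims
  class(assignment) <- c("som_assignment", class(assignment))
  structure(list(consensus_matrix = m, final_labels = final,
                 representative_run = as.integer(rep_run),
                 assignment = assignment,
                 per_run = attr(rep_run, "scores"),
                 ensemble = ens, dims = dims, epochs = epochs,
                 seed = as.integer(seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", length(x$final_labels), " observations, ",
      length(unique(x$final_labels)), " clusters (", x$dims[1], " x ",
      x$dims[2], " grid), representative run ", x$representative_run,
      "\n", sep = "")
  invisible(x)
}

#' Archetype connectivity summaries
#'
#' Computes the mean connectome per archetype (grid cell), the difference
#' matrix for every archetype pair, the per-axis margin means and differences
#' (e.g. all X = 1 observations vs all X = 2, as used to characterize what
#' each grid axis encodes), and cluster sizes. When the connectome set has a
#' node-to-network map, rows/columns are reordered by network.
#'
#' @param cs A [connectome_set()].
#' @param assignment A `som_assignment` tibble (e.g.
#'   `consensus_cluster()$assignment`, or planted truth assignments) with one
#'   row per observation of `cs`.
#' @return Object of class `archetype_summary`: `means` (named list of mean
#'   matrices, `NULL` for empty archetypes), `sizes` (tibble: cell, x, y, n),
#'   `pair_diffs` (named list `"x1_y1-x2_y1"` etc.), `margins` (list with
#'   per-axis level means and last-minus-first differences), `node_order`.
#' @export
summarize_archetypes <- function(cs, assignment) {
  stopifnot(inherits(cs, "connectome_set"))
  n_obs <- dim(cs$matrices)[3]
  if (nrow(assignment) != n_obs)
    stop("assignment must label every observation")
  dims <- attr(assignment, "dims")
  if (is.null(dims)) dims <- c(max(assignment$x), max(assignment$y))

  node_order <- if (!is.null(cs$network)) order(cs$network) else
    seq_len(dim(cs$matrices)[1])

  grid <- tidyr::expand_grid(y = seq_len(dims[2]), x = seq_len(dims[1]))
  grid$cell <- cell_index(grid$x, grid$y, dims[1])
  cell_name <- sprintf("x%d_y%d", grid$x, grid$y)

  mean_over <- function(idx) {
    if (length(idx) == 0) return(NULL)
    apply(cs$matrices[, , idx, drop = FALSE], c(1, 2), mean)[node_order,
                                                             node_order]
  }
  obs_cell <- cell_index(assignment$x, assignment$y, dims[1])
  means <- lapply(grid$cell, function(cl) mean_over(which(obs_cell == cl)))
  names(means) <- cell_name
  sizes <- tibble::tibble(cell = grid$cell, x = grid$x, y = grid$y,
                          n = vapply(grid$cell,
                                     function(cl) sum(obs_cell == cl), 0L))
  if (any(sizes$n == 0))
    warning("empty archetype(s): ",
            paste(cell_name[sizes$n == 0], collapse = ", "),
            "; mean reported as missing")

  pairs <- combn(seq_len(nrow(grid)), 2)
  pair_diffs <- apply(pairs, 2, function(ij) {
    a <- means[[ij[1]]]; b <- means[[ij[2]]]
    if (is.null(a) || is.null(b)) return(NULL)
    a - b
  }, simplify = FALSE)
  names(pair_diffs) <- apply(pairs, 2, function(ij)
    paste(cell_name[ij[1]], cell_name[ij[2]], sep = "-"))

  margin <- function(axis) {
    vals <- assignment[[axis]]
    levs <- seq_len(if (axis == "x") dims[1] else dims[2])
    lm <- lapply(levs, function(l) mean_over(which(vals == l)))
    names(lm) <- paste0(axis, levs)
    diff <- if (length(levs) > 1 && !is.null(lm[[length(levs)]]) &&
                !is.null(lm[[1]])) lm[[length(levs)]] - lm[[1]] else NULL
    list(levels = lm, diff = diff)
  }
  structure(list(means = means, sizes = sizes, pair_diffs = pair_diffs,
                 margins = list(x = margin("x"), y = margin("y")),
                 node_order = node_order, dims = dims),
            class = "archetype_summary")
}

#' @export
print.archetype_summary <- function(x, ...) {
  cat("<archetype_summary> ", x$dims[1], " x ", x$dims[2], " grid; sizes: ",
      paste(sprintf("%s=%d", names(x$means), x$sizes$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
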