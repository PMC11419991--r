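#' Configuration for the synthetic connectome study
#'
#' Bundles the parameters of the synthetic multi-run connectome generator. The
#' generator emulates a resting-state study in which each subject contributes
#' several runs, each run's connectome is one of `Dx * Dy` archetypal profiles
#' arranged on a 2D grid, and the two grid axes modulate the within-block
#' connectivity of an "anterior" and a "posterior" node block respectively.
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: 200 subjects with 4 runs each over 90 nodes, a 2x2
#' archetype grid, a 0.5 z-unit block effect over 0.3 z-units of edge noise,
#' and 0.8 within-subject run consistency.
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Runs per subject.
#' @param n_nodes Number of nodes (parcels); at least 8.
#' @param grid_dims Integer vector `c(Dx, Dy)` of the archetype grid.
#' @param block_effect Fisher-z units added to within-block connectivity per
#'   grid level (X modulates the anterior block, Y the posterior block).
#' @param noise_sd Standard deviation of i.i.d. Gaussian edge noise (z units).
#' @param run_consistency Probability `rho` that a run inherits its subject's
#'   modal archetype; otherwise the run's archetype is redrawn uniformly over
#'   the whole grid (so a redraw can still land on the modal cell).
#' @param baseline Baseline off-diagonal connectivity (z units) shared by all
#'   templates.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 200L, n_runs = 4L, n_nodes = 90L,
                         grid_dims = c(2L, 2L), block_effect = 0.5,
                         noise_sd = 0.3, run_consistency = 0.8,
                         baseline = 0.25, seed = 1L) {
  stopifnot(n_subjects >= 1, n_runs >= 1)
  if (n_nodes < 8) stop("n_nodes must be >= 8")
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 2 || any(grid_dims < 1))
    stop("grid_dims must be two integers >= 1")
  if (run_consistency < 0 || run_consistency > 1)
    stop("run_consistency must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         n_nodes = as.integer(n_nodes), grid_dims = grid_dims,
         block_effect = block_effect, noise_sd = noise_sd,
         run_consistency = run_consistency, baseline = baseline,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' Default anterior/posterior node partition
#'
#' The first `ceiling(N/3)` nodes form the "anterior" block, the next
#' `ceiling(N/3)` the "posterior" block, and the remainder is "background".
#'
#' @param n_nodes Number of nodes.
#' @return Character vector of block labels, one per node.
#' @export
default_partition <- function(n_nodes) {
  b <- ceiling(n_nodes / 3)
  blocks <- rep("background", n_nodes)
  blocks[seq_len(b)] <- "anterior"
  blocks[seq_len(min(2 * b, n_nodes))[-seq_len(b)]] <- "posterior"
  blocks
}

# cell index convention shared with the SOM grid: idx = (y-1)*Dx + x
cell_index <- function(x, y, dx) (y - 1L) * dx + x
cell_coords <- function(idx, dx) {
  list(x = 1L + (idx - 1L) %% dx, y = 1L + (idx - 1L) %/% dx)
}

#' Generate archetype template connectomes on a 2D grid
#'
#' Builds one symmetric, zero-diagonal template matrix per grid cell. All
#' templates share a constant baseline on off-diagonal edges; the X grid level
#' adds `(x - 1) * block_effect` to edges within the anterior block and the Y
#' level adds `(y - 1) * block_effect` to edges within the posterior block.
#'
#' @param cfg A [synth_config()].
#' @param partition Node-to-block assignment: either a character vector of
#'   length `n_nodes` with values `"anterior"`, `"posterior"` (and anything
#'   else as background), or a data frame with columns `node` (index) and
#'   `block`. Defaults to [default_partition()].
#' @return A list of class `archetype_templates`: `templates` (named list of
#'   N x N matrices, cell order `x` fastest), `grid` (tibble of cell, x, y),
#'   `partition`, and the generating config.
#' @export
generate_templates <- function(cfg, partition = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_nodes
  if (is.null(partition)) partition <- default_partition(n)
  if (is.data.frame(partition)) {
    if (!all(c("node", "block") %in% names(partition)))
      stop("partition data frame needs columns 'node' and 'block'")
    if (any(partition$node < 1 | partition$node > n |
            partition$node != round(partition$node)))
      stop("partition references unknown nodes")
    p <- rep("background", n)
    p[partition$node] <- partition$block
    partition <- p
  }
  if (length(partition) != n)
    stop("partition must cover all ", n, " nodes")

  dx <- cfg$grid_dims[1]; dy <- cfg$grid_dims[2]
  ant <- which(partition == "anterior")
  post <- which(partition == "posterior")
  base <- matrix(cfg$baseline, n, n)
  diag(base) <- 0

  grid <- tidyr::expand_grid(y = seq_len(dy), x = seq_len(dx))
  grid <- dplyr::arrange(grid, .data$y, .data$x)
  grid$cell <- cell_index(grid$x, grid$y, dx)

  templates <- purrr::pmap(grid, function(y, x, cell) {
    m <- base
    if (length(ant) > 1)
      m[ant, ant] <- m[ant, ant] + (x - 1) * cfg$block_effect
    if (length(post) > 1)
      m[post, post] <- m[post, post] + (y - 1) * cfg$block_effect
    diag(m) <- 0
    m
  })
  names(templates) <- sprintf("x%d_y%d", grid$x, grid$y)

  structure(list(templates = templates, grid = grid,
                 partition = partition, config = cfg),
            class = "archetype_templates")
}

#' Simulate a multi-run connectome dataset with planted archetypes
#'
#' Each subject receives a modal archetype drawn uniformly over the grid. Each
#' run keeps the modal archetype with probability `run_consistency` and is
#' otherwise redrawn uniformly over all grid cells. The observed connectome is
#' the run's template plus symmetric Gaussian edge noise.
#'
#' @param cfg A [synth_config()].
#' @param templates Output of [generate_templates()]; built from `cfg` if
#'   missing.
#' @return A list with elements `connectomes` (a [connectome_set()]) and
#'   `truth` (class `ground_truth`: per-observation assignments, per-subject
#'   modal archetypes, the grid, and the generating config).
#' @export
simulate_dataset <- function(cfg, templates = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(templates)) templates <- generate_templates(cfg)
  stopifnot(inherits(templates, "archetype_templates"))

  dx <- cfg$grid_dims[1]; dy <- cfg$grid_dims[2]
  k <- dx * dy
  n <- cfg$n_nodes
  n_obs <- cfg$n_subjects * cfg$n_runs

  set.seed(cfg$seed)
  modal <- sample.int(k, cfg$n_subjects, replace = TRUE)
  keep <- matrix(runif(n_obs) < cfg$run_consistency,
                 cfg$n_subjects, cfg$n_runs)
  redraw <- matrix(sample.int(k, n_obs, replace = TRUE),
                   cfg$n_subjects, cfg$n_runs)
  cells <- matrix(ifelse(keep, rep(modal, cfg$n_runs), redraw),
                  cfg$n_subjects, cfg$n_runs)

  subject_id <- rep(seq_len(cfg$n_subjects), times = cfg$n_runs)
  run_id <- rep(seq_len(cfg$n_runs), each = cfg$n_subjects)
  obs_cell <- as.vector(cells)

  e <- n * (n - 1) / 2
  mats <- array(0, dim = c(n, n, n_obs))
  lowr <- lower.tri(matrix(0, n, n))
  for (i in seq_len(n_obs)) {
    m <- templates$templates[[obs_cell[i]]]
    if (cfg$noise_sd > 0) {
      noise <- devectorize_lower_triangle(rnorm(e, sd = cfg$noise_sd))
      m <- m + noise
    }
    mats[, , i] <- m
  }

  cs <- connectome_set(mats, subject_id = subject_id, run_id = run_id)
  xy <- cell_coords(obs_cell, dx)
  mxy <- cell_coords(modal, dx)
  truth <- structure(list(
    assignments = tibble::tibble(subject_id = subject_id, run_id = run_id,
                                 cell = obs_cell, x = xy$x, y = xy$y),
    subject_modal = tibble::tibble(subject_id = seq_len(cfg$n_subjects),
                                   cell = modal, x = mxy$x, y = mxy$y),
    grid = templates$grid, config = cfg),
    class = "ground_truth")
  list(connectomes = cs, truth = truth)
}

coding_levels <- c("X-coded", "Y-coded", "interaction-coded", "null")

#' Simulate behavioral scores with a known coding map
#'
#' Generates one score per subject and behavior from the subject's modal
#' archetype: `score = d * sigma * g(x, y) + Normal(0, sigma)`, where `g` is an
#' indicator that depends on the behavior's coding. X-coded behaviors are high
#' when the modal X coordinate is at its last level, Y-coded when Y is at its
#' last level, and interaction-coded behaviors follow the XOR pattern (high iff
#' exactly one of X, Y is at its last level) — the degenerate pattern in which
#' two connectionally different archetypes share the same elevated outcome.
#' Null behaviors are pure noise.
#'
#' @param truth A `ground_truth` object from [simulate_dataset()].
#' @param coding Named character vector mapping behavior names to one of
#'   `"X-coded"`, `"Y-coded"`, `"interaction-coded"`, `"null"`. Defaults to one
#'   behavior of each kind.
#' @param effect_size Standardized effect size `d`.
#' @param noise_sd Score noise standard deviation `sigma`.
#' @param seed RNG seed.
#' @return List with `scores` (tibble: subject_id plus one column per
#'   behavior) and `coding_map` (tibble: behavior, coding).
#' @export
simulate_behavior <- function(truth, coding = NULL, effect_size = 0.8,
                              noise_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(coding))
    coding <- c(beh_x = "X-coded", beh_y = "Y-coded",
                beh_xor = "interaction-coded", beh_null = "null")
  if (!all(coding %in% coding_levels))
    stop("unknown coding label(s): ",
         paste(setdiff(coding, coding_levels), collapse = ", "))
  dx <- truth$config$grid_dims[1]; dy <- truth$config$grid_dims[2]
  if (any(coding == "interaction-coded") && (dx < 2 || dy < 2))
    stop("interaction-coded behaviors require a grid of at least 2 x 2")

  modal <- truth$subject_modal
  hx <- modal$x == dx
  hy <- modal$y == dy
  set.seed(seed)
  scores <- tibble::tibble(subject_id = modal$subject_id)
  for (b in names(coding)) {
    g <- switch(coding[[b]],
      "X-coded" = as.numeric(hx),
      "Y-coded" = as.numeric(hy),
      "interaction-coded" = as.numeric(xor(hx, hy)),
      "null" = 0)
    # effect scaled by the noise sd so effect_size is a standardized d;
    # at noise_sd = 0 the raw pattern is kept (amplitude effect_size)
    scale_ <- if (noise_sd > 0) noise_sd else 1
    scores[[b]] <- effect_size * scale_ * g +
      rnorm(nrow(modal), sd = noise_sd)
  }
  list(scores = scores,
       coding_map = tibble::tibble(behavior = names(coding),
                                   coding = unname(coding)))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: templates, connectomes, ground truth, and behaviors.
#'
#' @inheritParams simulate_dataset
#' @inheritParams simulate_behavior
#' @param partition Optional node partition for [generate_templates()].
#' @return List with `connectomes`, `truth` (with `coding_map` attached),
#'   `behavior` (scores tibble), and `templates`.
#' @export
simulate_study <- function(cfg, partition = NULL, coding = NULL,
                           effect_size = 0.8, noise_sd = 1) {
  tpl <- generate_templates(cfg, partition)
  ds <- simulate_dataset(cfg, tpl)
  beh <- simulate_behavior(ds$truth, coding, effect_size, noise_sd,
                           seed = cfg$seed + 1L)
  ds$truth$coding_map <- beh$coding_map
  list(connectomes = ds$connectomes, truth = ds$truth,
       behavior = beh$scores, templates = tpl)
}
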