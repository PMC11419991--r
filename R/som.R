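#' Initialize a self-organizing map
#'
#' Creates a `Dx * Dy` rectangular grid of neurons with weight vectors in the
#' feature space. `"sample"` initialization (default) draws weight vectors from
#' the data rows without replacement (with replacement, warned, if there are
#' more neurons than observations); `"linear"` places the grid regularly along
#' the top two principal axes of the data.
#'
#' Neuron index j maps to grid coordinate `x = 1 + (j - 1) %% Dx`,
#' `y = 1 + (j - 1) %/% Dx` (x varies fastest).
#'
#' @param dims Integer vector `c(Dx, Dy)`.
#' @param data Observations x features matrix (or [reduce_dataset()] output).
#' @param seed RNG seed (sample initialization).
#' @param method `"sample"` or `"linear"`.
#' @return Object of class `som_model`.
#' @export
som_init <- function(dims, data, seed = 1L, method = c("sample", "linear")) {
  method <- match.arg(method)
  data <- as_feature_matrix(data)
  if (nrow(data) == 0) stop("data must be non-empty")
  dims <- as.integer(dims)
  stopifnot(length(dims) == 2, all(dims >= 1))
  m <- dims[1] * dims[2]
  idx <- seq_len(m)
  gx <- 1L + (idx - 1L) %% dims[1]
  gy <- 1L + (idx - 1L) %/% dims[1]

  if (method == "sample") {
    set.seed(seed)
    if (m > nrow(data)) {
      warning("more neurons than observations: sampling with replacement")
      rows <- sample.int(nrow(data), m, replace = TRUE)
    } else {
      rows <- sample.int(nrow(data), m)
    }
    w <- data[rows, , drop = FALSE]
  } else {
    ctr <- colMeans(data)
    sv <- svd(sweep(data, 2, ctr), nu = 0, nv = 2)
    span <- function(d, n) if (n == 1) 0 else seq(-1, 1, length.out = n)
    lx <- span(1, dims[1])[gx] * sv$d[1] / sqrt(max(1, nrow(data) - 1))
    ly <- if (ncol(sv$v) >= 2 && dims[2] > 1)
      span(2, dims[2])[gy] * sv$d[2] / sqrt(max(1, nrow(data) - 1)) else 0
    w <- matrix(ctr, m, ncol(data), byrow = TRUE) +
      outer(lx, sv$v[, 1]) +
      (if (ncol(sv$v) >= 2) outer(ly, sv$v[, 2]) else 0)
  }
  dimnames(w) <- NULL
  structure(list(dims = dims, weights = w, gx = gx, gy = gy,
                 epochs_trained = 0L, qe = numeric(0),
                 seed = as.integer(seed), init = method),
            class = "som_model")
}

as_feature_matrix <- function(data) {
  if (inherits(data, "reduced_features")) data <- data$scores
  as.matrix(data)
}

#' Best matching unit for one input vector
#'
#' Returns the index of the neuron whose weight vector is closest to `x` in
#' Euclidean distance; ties are broken toward the lowest index.
#'
#' @param model A `som_model`.
#' @param x Feature vector matching the weight dimension.
#' @return Integer neuron index.
#' @export
find_bmu <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(x) != ncol(model$weights))
    stop("x has length ", length(x), ", expected ", ncol(model$weights))
  d2 <- rowSums(sweep(model$weights, 2, x)^2)
  which.min(d2)
}

#' Train a self-organizing map
#'
#' Online (per-observation) training: each epoch presents every observation in
#' a freshly seeded shuffled order; the best matching unit and its grid
#' neighbors move toward the input, `w <- w + alpha(t) * h * (x - w)`, with a
#' Gaussian neighborhood `h = exp(-d_grid^2 / (2 sigma(t)^2))` over Euclidean
#' grid distance. `alpha` and `sigma` decay linearly across epochs; defaults
#' are `alpha` 0.5 to 0.01 and `sigma` `max(Dx, Dy)/2` to 0.5. The mean BMU
#' distance per epoch (quantization error) is recorded in `$qe`.
#'
#' @param model A `som_model` from [som_init()].
#' @param data Observations x features matrix (or [reduce_dataset()] output).
#' @param epochs Number of full passes over the data (>= 1).
#' @param alpha Length-2 vector: initial and final learning rate.
#' @param sigma Length-2 vector: initial and final neighborhood radius;
#'   default `c(max(dims)/2, 0.5)`.
#' @param seed Seed for the presentation-order shuffles.
#' @return The trained `som_model`.
#' @export
som_train <- function(model, data, epochs, alpha = c(0.5, 0.01),
                      sigma = NULL, seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  data <- as_feature_matrix(data)
  if (epochs < 1) stop("epochs must be >= 1")
  if (ncol(data) != ncol(model$weights))
    stop("data feature dimension does not match model weights")
  if (is.null(sigma)) sigma <- c(max(model$dims) / 2, 0.5)
  epochs <- as.integer(epochs)

  set.seed(seed)
  ord <- t(vapply(seq_len(epochs), function(e) sample.int(nrow(data)),
                  integer(nrow(data))))
  if (epochs == 1) ord <- matrix(ord, nrow = 1)

  out <- som_train_cpp(model$weights, data, ord, model$gx, model$gy,
                       alpha[1], alpha[2], sigma[1], sigma[2])
  model$weights <- out$weights
  model$qe <- c(model$qe, out$qe)
  model$epochs_trained <- model$epochs_trained + epochs
  model
}

#' Assign observations to SOM clusters and grid coordinates
#'
#' Each observation is labeled with its best matching unit; the label's grid
#' coordinate follows the fixed index map `x = 1 + (label - 1) %% Dx`,
#' `y = 1 + (label - 1) %/% Dx`. Neurons may be empty.
#'
#' @param model A trained `som_model`.
#' @param data Observations x features matrix (or [reduce_dataset()] output;
#'   subject/run labels are carried through when present).
#' @param subject_id,run_id Optional per-observation labels.
#' @return Tibble with columns `subject_id`, `run_id`, `label`, `x`, `y`
#'   (class `som_assignment`; grid dims in the `dims` attribute).
#' @export
som_assign <- function(model, data, subject_id = NULL, run_id = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (inherits(data, "reduced_features")) {
    subject_id <- subject_id %||% data$subject_id
    run_id <- run_id %||% data$run_id
  }
  x <- as_feature_matrix(data)
  n <- nrow(x)
  # n x m squared distances; max.col with "first" ties == lowest index
  d2 <- outer(rowSums(x^2), rep(1, nrow(model$weights))) -
    2 * x %*% t(model$weights) +
    outer(rep(1, n), rowSums(model$weights^2))
  label <- max.col(-d2, ties.method = "first")
  out <- tibble::tibble(
    subject_id = subject_id %||% seq_len(n),
    run_id = run_id %||% rep(1L, n),
    label = as.integer(label),
    x = 1L + (label - 1L) %% model$dims[1],
    y = 1L + (label - 1L) %/% model$dims[1])
  attr(out, "dims") <- model$dims
  class(out) <- c("som_assignment", class(out))
  out
}

#' Fit a SOM in one call
#'
#' [som_init()] followed by [som_train()], sharing one seed.
#'
#' @inheritParams som_train
#' @inheritParams som_init
#' @return A trained `som_model`.
#' @export
som_fit <- function(data, dims, epochs, seed = 1L,
                    alpha = c(0.5, 0.01), sigma = NULL,
                    init = c("sample", "linear")) {
  model <- som_init(dims, data, seed = seed, method = match.arg(init))
  som_train(model, data, epochs, alpha = alpha, sigma = sigma, seed = seed)
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$dims[1], " x ", x$dims[2], " grid, ",
      ncol(x$weights), " features, ", x$epochs_trained,
      " epoch(s) trained\n", sep = "")
  invisible(x)
}
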