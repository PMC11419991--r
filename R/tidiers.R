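#' Tidy a SOM model
#'
#' One row per neuron with its grid coordinates and weight vector columns.
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.som_model <- function(x, ...) {
  m <- x  # avoid masking the grid column named `x`
  w <- tibble::as_tibble(m$weights, .name_repair = ~ paste0("w", seq_along(.)))
  dplyr::bind_cols(
    tibble::tibble(neuron = seq_len(nrow(m$weights)), x = m$gx, y = m$gy), w)
}

#' @rdname tidy.som_model
#' @return `glance()`: a one-row tibble with dims, feature count, epochs,
#'   and final quantization error.
#' @export
glance.som_model <- function(x, ...) {
  tibble::tibble(dx = x$dims[1], dy = x$dims[2],
                 n_features = ncol(x$weights),
                 epochs_trained = x$epochs_trained,
                 quantization_error = if (length(x$qe)) x$qe[length(x$qe)]
                 else NA_real_)
}

#' Tidy reduced connectome features
#'
#' One row per observation with subject/run labels and retained component
#' scores.
#'
#' @param x A `reduced_features` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reduced_features <- function(x, ...) {
  s <- tibble::as_tibble(x$scores,
                         .name_repair = ~ paste0("PC", seq_along(.)))
  dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id,
                                  run_id = x$run_id), s)
}

#' @rdname tidy.reduced_features
#' @export
glance.reduced_features <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(n_components = x$n_components,
                 prop_variance = sum(x$eigenvalues[seq_len(x$n_components)]) /
                   tot,
                 n_observations = nrow(x$scores))
}

#' Tidy a consensus clustering result
#'
#' One row per observation: final consensus label plus the representative
#' run's label and grid coordinates.
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.consensus_result <- function(x, ...) {
  res <- x  # avoid masking the coordinate column named `x`
  dplyr::mutate(res$assignment, final_label = res$final_labels,
                .after = "run_id")
}

#' @rdname tidy.consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(n_clusters = length(unique(x$final_labels)),
                 dx = x$dims[1], dy = x$dims[2], epochs = x$epochs,
                 n_runs = nrow(x$ensemble$labels),
                 representative_run = x$representative_run,
                 mean_run_ari = mean(x$per_run$ari),
                 mean_run_ami = mean(x$per_run$ami))
}

#' Tidy an association table
#'
#' @param x An `association_table`.
#' @param ... Unused.
#' @return The per-behavior, per-term test tibble.
#' @export
tidy.association_table <- function(x, ...) x$terms

#' @rdname tidy.association_table
#' @export
glance.association_table <- function(x, ...) {
  tibble::tibble(n_behaviors = length(unique(x$terms$behavior)),
                 mode = x$mode, alpha = x$alpha,
                 n_bonferroni = sum(x$terms$tier == "bonferroni",
                                    na.rm = TRUE),
                 n_fdr = sum(x$terms$tier %in% c("fdr", "bonferroni"),
                             na.rm = TRUE))
}
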