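#' Plot a stability table
#'
#' Mean ARI and AMI (with standard-error ribbons) against epochs, one colour
#' per grid dimension.
#'
#' @param object A `stability_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, ari_lo = .data$ari_mean - .data$ari_se,
                  ari_hi = .data$ari_mean + .data$ari_se,
                  ami_lo = .data$ami_mean - .data$ami_se,
                  ami_hi = .data$ami_mean + .data$ami_se),
    cols = c("ari_mean", "ami_mean"),
    names_to = "metric", values_to = "value")
  long$metric <- toupper(sub("_mean", "", long$metric))
  long$lo <- ifelse(long$metric == "ARI", long$ari_lo, long$ami_lo)
  long$hi <- ifelse(long$metric == "ARI", long$ari_hi, long$ami_hi)
  ggplot2::ggplot(long, ggplot2::aes(.data$epochs, .data$value,
                                     colour = .data$dims,
                                     fill = .data$dims)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "epochs", y = "mean pairwise agreement",
                  colour = "grid", fill = "grid") +
    ggplot2::theme_minimal()
}

#' Plot a consensus matrix
#'
#' Heatmap of co-assignment probabilities with observations ordered by their
#' final consensus label; crisp blocks indicate a stable partition.
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- order(object$final_labels)
  m <- object$consensus_matrix[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(nrow(m)))
  df$consensus <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-assignment") +
    ggplot2::theme_minimal()
}

#' Plot archetype mean connectomes
#'
#' One heatmap per grid cell (nodes ordered by network when available).
#'
#' @param object An `archetype_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.archetype_summary <- function(object, ...) {
  dfs <- purrr::imap(object$means, function(m, nm) {
    if (is.null(m)) return(NULL)
    d <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(nrow(m)))
    d$z <- as.vector(m)
    d$archetype <- nm
    d
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~archetype) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean z") +
    ggplot2::theme_minimal()
}

#' Association tier map
#'
#' Behaviors x terms heatmap of -log10 ANOVA p-values with the significance
#' tier marked: point for p < 0.001 uncorrected, circle for FDR, triangle for
#' Bonferroni.
#'
#' @param association An `association_table`.
#' @return A ggplot.
#' @export
plot_association_tiers <- function(association) {
  stopifnot(inherits(association, "association_table"))
  d <- association$terms
  d$neglogp <- -log10(pmax(d$p.value, 1e-300))
  d$term <- factor(d$term, levels = c("X", "Y", "X:Y"))
  sig <- d[!is.na(d$tier) & d$tier != "ns", ]
  ggplot2::ggplot(d, ggplot2::aes(.data$term, .data$behavior,
                                  fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "lemonchiffon", high = "firebrick") +
    ggplot2::geom_point(data = sig,
                        ggplot2::aes(shape = .data$tier), size = 2,
                        inherit.aes = TRUE, fill = NA, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(uncorrected = 16, fdr = 1,
                                           bonferroni = 17)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p",
                  shape = "survives") +
    ggplot2::theme_minimal()
}

#' Plot an assignment-consistency report
#'
#' Observed unique-clusters-per-subject histogram with the observed mean
#' (dashed) and the null mean (dotted).
#'
#' @param object A `consistency_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consistency_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$n_unique, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$null_mean,
                        linetype = "dotted") +
    ggplot2::labs(x = "unique clusters per subject", y = "subjects") +
    ggplot2::theme_minimal()
}
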