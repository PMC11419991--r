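#' Box-Cox transform and 1-100 rescale of a behavioral score
#'
#' If the minimum is non-positive the scores are first shifted so the minimum
#' becomes 1. The Box-Cox exponent `lambda` is then chosen by maximizing the
#' profile log-likelihood (`y = (x^lambda - 1)/lambda`, or `log x` at
#' `lambda = 0`), and the transformed values are min-max rescaled to
#' `[1, 100]` via `1 + 99 * (y - min)/(max - min)`.
#'
#' @param x Raw scores (at least 3 distinct values; missing values are not
#'   allowed here — drop them upstream).
#' @param lambda Optional fixed exponent, bypassing the likelihood search.
#' @return List of class `boxcox_transform`: `scores` (in `[1, 100]`),
#'   `lambda`, `shift`, `y` (transformed values before rescaling), `y_range`.
#' @seealso [boxcox_inverse()]
#' @export
boxcox_rescale <- function(x, lambda = NULL) {
  if (any(is.na(x))) stop("x must not contain missing values")
  if (length(unique(x)) < 3) stop("need at least 3 distinct values")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  if (is.null(lambda)) {
    n <- length(xs)
    slog <- sum(log(xs))
    profile_ll <- function(l) {
      y <- if (abs(l) < 1e-9) log(xs) else (xs^l - 1) / l
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slog
    }
    lambda <- optimize(profile_ll, c(-5, 5), maximum = TRUE,
                       tol = 1e-6)$maximum
  }
  y <- if (abs(lambda) < 1e-9) log(xs) else (xs^lambda - 1) / lambda
  rng <- range(y)
  structure(list(scores = 1 + 99 * (y - rng[1]) / (rng[2] - rng[1]),
                 lambda = lambda, shift = shift, y = y, y_range = rng),
            class = "boxcox_transform")
}

#' @rdname boxcox_rescale
#' @param y Transformed (pre-rescale) values.
#' @param shift Shift that was applied before the transform.
#' @return `boxcox_inverse()`: the raw scores.
#' @export
boxcox_inverse <- function(y, lambda, shift = 0) {
  x <- if (abs(lambda) < 1e-9) exp(y) else (lambda * y + 1)^(1 / lambda)
  x - shift
}

#' Preprocess a behavior table
#'
#' Drops rows with any missing score (logged), then applies
#' [boxcox_rescale()] to every behavior column.
#'
#' @param behavior Tibble with `subject_id` plus one column per behavior.
#' @return List: `scores` (tibble, all behaviors in `[1, 100]`) and
#'   `transforms` (tibble: behavior, lambda, shift).
#' @export
preprocess_behaviors <- function(behavior) {
  stopifnot("subject_id" %in% names(behavior))
  ok <- complete.cases(behavior)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " row(s) with missing scores")
    behavior <- behavior[ok, ]
  }
  cols <- setdiff(names(behavior), "subject_id")
  out <- behavior["subject_id"]
  rec <- purrr::map_dfr(cols, function(b) {
    tr <- boxcox_rescale(behavior[[b]])
    out[[b]] <<- tr$scores
    tibble::tibble(behavior = b, lambda = tr$lambda, shift = tr$shift)
  })
  list(scores = out, transforms = rec)
}

term_map <- c(fx = "X", fy = "Y", `fx:fy` = "X:Y")

#' Two-way ANOVA of a behavior on SOM grid coordinates
#'
#' Fits `score ~ X * Y` with the grid coordinates as categorical factors and
#' returns F tests for the X and Y main effects and the X:Y interaction.
#' Unbalanced designs use Type-II sums of squares by default (Type III via
#' `type = 3`). A single-level factor drops the corresponding terms (reported
#' as missing with a warning); constant scores return `F = 0, p = 1`.
#'
#' @param scores Numeric score per observation.
#' @param x,y Grid coordinates per observation (coerced to factors).
#' @param type Sums-of-squares type: 2 (default) or 3.
#' @return Tibble: `term` (`"X"`, `"Y"`, `"X:Y"`), `df`, `statistic`
#'   (F), `p.value`.
#' @export
anova_grid <- function(scores, x, y, type = 2) {
  stopifnot(length(scores) == length(x), length(x) == length(y))
  fx <- factor(x); fy <- factor(y)
  terms_all <- c("X", "Y", "X:Y")
  if (nlevels(fx) < 2 || nlevels(fy) < 2) {
    warning("factor with a single level: affected terms reported as missing")
    one <- if (nlevels(fx) >= 2) fx else if (nlevels(fy) >= 2) fy else NULL
    out <- tibble::tibble(term = terms_all, df = NA_real_,
                          statistic = NA_real_, p.value = NA_real_)
    if (!is.null(one)) {
      keep <- if (nlevels(fx) >= 2) "X" else "Y"
      a <- anova(lm(scores ~ one))
      out$df[out$term == keep] <- a$Df[1]
      out$statistic[out$term == keep] <- a$`F value`[1]
      out$p.value[out$term == keep] <- a$`Pr(>F)`[1]
    }
    return(out)
  }
  if (var(scores) == 0)
    return(tibble::tibble(term = terms_all, df = NA_real_, statistic = 0,
                          p.value = 1))
  full_cells <- all(table(fx, fy) > 0)
  if (!full_cells)
    warning("empty grid cell(s): interaction term dropped")
  fit <- if (full_cells) lm(scores ~ fx * fy) else lm(scores ~ fx + fy)
  a <- if (type == 3) {
    car::Anova(lm(scores ~ fx * fy,
                  contrasts = list(fx = "contr.sum", fy = "contr.sum")),
               type = 3)
  } else car::Anova(fit, type = 2)
  rows <- rownames(a)
  out <- tibble::tibble(
    term = unname(term_map[rows[rows %in% names(term_map)]]),
    df = a$Df[rows %in% names(term_map)],
    statistic = a$`F value`[rows %in% names(term_map)],
    p.value = a$`Pr(>F)`[rows %in% names(term_map)])
  missing <- setdiff(terms_all, out$term)
  if (length(missing))
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = missing, df = NA_real_, statistic = NA_real_,
      p.value = NA_real_))
  out[match(terms_all, out$term), ]
}

#' Mixed-effects grid association with a subject random intercept
#'
#' Fits `score ~ X * Y + (1 | subject)` by REML and returns Type-II Wald
#' chi-square tests per fixed-effect term. This is the statistically guarded
#' twin of [anova_grid()] when runs are replicated within subject: the random
#' intercept absorbs subject-level score correlation that a naive ANOVA on
#' replicated rows ignores.
#'
#' @inheritParams anova_grid
#' @param subject Subject identifier per observation.
#' @return Tibble: `term`, `df`, `statistic` (Wald chi-square), `p.value`,
#'   `converged`.
#' @export
lme_grid <- function(scores, x, y, subject) {
  stopifnot(length(scores) == length(x), length(x) == length(subject))
  fx <- factor(x); fy <- factor(y)
  terms_all <- c("X", "Y", "X:Y")
  bad <- tibble::tibble(term = terms_all, df = NA_real_,
                        statistic = NA_real_, p.value = NA_real_,
                        converged = FALSE)
  if (var(scores) == 0) return(bad)
  if (nlevels(fx) < 2 || nlevels(fy) < 2) return(bad)
  # allow the one-observation-per-subject limit: the random-intercept
  # variance collapses to zero and the fit reduces to the fixed-effects model
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(scores ~ fx * fy + (1 | subject), REML = TRUE,
                 control = ctrl))),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(a)) return(bad)
  rows <- rownames(a)
  out <- tibble::tibble(
    term = unname(term_map[rows[rows %in% names(term_map)]]),
    df = a$Df[rows %in% names(term_map)],
    statistic = a$Chisq[rows %in% names(term_map)],
    p.value = a$`Pr(>Chisq)`[rows %in% names(term_map)],
    converged = TRUE)
  out[match(terms_all, out$term), ]
}

#' Restricted post-hoc comparisons between grid cells
#'
#' Welch two-sample t-tests between archetype (grid-cell) score
#' distributions. The default restriction keeps only pairs that differ in
#' exactly one grid coordinate (on a 2x2 grid: 4 of the 6 pairs; the
#' cross-diagonal pairs enter only through the interaction term and the
#' degeneracy report). Raw p-values are corrected within the behavior's
#' comparison family by both Benjamini-Hochberg FDR and Bonferroni.
#'
#' @inheritParams anova_grid
#' @param restriction `"one-coordinate"` (default) or `"all-pairs"`.
#' @param min_cell Minimum observations per cell; smaller cells skip their
#'   pairs (logged via message).
#' @return Tibble with one row per comparison: `x1, y1, x2, y2`,
#'   `mean_diff`, `statistic`, `df`, `p.value`, `p_fdr`, `p_bonf`, `n1`,
#'   `n2`.
#' @export
posthoc_pairwise <- function(scores, x, y,
                             restriction = c("one-coordinate", "all-pairs"),
                             min_cell = 2L) {
  restriction <- match.arg(restriction)
  cells <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(scores = scores, x = x, y = y),
                    .data$x, .data$y),
    n = dplyr::n(), .groups = "drop")
  if (nrow(cells) < 2) stop("need at least 2 non-empty cells")
  prs <- combn(nrow(cells), 2)
  rows <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    c1 <- cells[i1, ]; c2 <- cells[i2, ]
    ndiff <- (c1$x != c2$x) + (c1$y != c2$y)
    if (restriction == "one-coordinate" && ndiff != 1) return(NULL)
    if (c1$n < min_cell || c2$n < min_cell) {
      message("skipping pair (", c1$x, ",", c1$y, ")-(", c2$x, ",", c2$y,
              "): cell below ", min_cell, " observations")
      return(NULL)
    }
    s1 <- scores[x == c1$x & y == c1$y]
    s2 <- scores[x == c2$x & y == c2$y]
    tt <- t.test(s1, s2)
    tibble::tibble(x1 = c1$x, y1 = c1$y, x2 = c2$x, y2 = c2$y,
                   mean_diff = mean(s1) - mean(s2),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value,
                   n1 = c1$n, n2 = c2$n)
  })
  if (nrow(rows) == 0) return(rows)
  rows$p_fdr <- correct_pvalues(rows$p.value, "BH")
  rows$p_bonf <- correct_pvalues(rows$p.value, "bonferroni")
  rows
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni (`min(1, m * p)`) adjustment.
#'
#' @param p P-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values (monotone in the input).
#' @export
correct_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Grid-coordinate association battery over a behavior table
#'
#' For every behavior, runs the two-way ANOVA ([anova_grid()]) and the
#' mixed-model twin ([lme_grid()]) of the score on the archetype grid
#' coordinates, plus restricted post-hoc comparisons. Battery-wide FDR and
#' Bonferroni corrections are applied across all behavior-by-term ANOVA
#' p-values, and each test is tiered: `"bonferroni"` if it survives
#' Bonferroni, else `"fdr"` if it survives FDR (both at `alpha`), else
#' `"uncorrected"` if `p < 0.001`, else `"ns"` — the nested thresholds of the
#' standard tier map.
#'
#' @param behavior Tibble: `subject_id` plus behavior columns (typically
#'   [preprocess_behaviors()] output).
#' @param assignment `som_assignment` tibble (observation-level labels with
#'   `subject_id`, `run_id`, `x`, `y`).
#' @param mode `"runs"` replicates each subject's score across its runs (one
#'   row per connectome); `"subjects"` uses one row per subject at the
#'   subject's modal cell.
#' @param type Sums-of-squares type for the ANOVA arm.
#' @param restriction Post-hoc restriction; see [posthoc_pairwise()].
#' @param alpha Significance level for the FDR/Bonferroni tiers.
#' @return Object of class `association_table`: `terms` (tibble: behavior,
#'   term, ANOVA df/F/p, LME chi-square/p/convergence, battery-wide `p_fdr`
#'   and `p_bonf`, `tier`), `posthoc` (tibble with behavior column), `data`
#'   (the analysis rows), `mode`, `alpha`.
#' @export
associate_behaviors <- function(behavior, assignment,
                                mode = c("runs", "subjects"), type = 2,
                                restriction = "one-coordinate",
                                alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot("subject_id" %in% names(behavior))
  beh_cols <- setdiff(names(behavior), "subject_id")
  obs <- if (mode == "runs") {
    dplyr::inner_join(assignment, behavior, by = "subject_id")
  } else {
    modal <- dplyr::count(assignment, .data$subject_id, .data$x, .data$y)
    modal <- dplyr::arrange(modal, .data$subject_id,
                            dplyr::desc(.data$n), .data$y, .data$x)
    modal <- dplyr::distinct(modal, .data$subject_id, .keep_all = TRUE)
    dplyr::inner_join(modal[, c("subject_id", "x", "y")], behavior,
                      by = "subject_id")
  }

  terms <- purrr::map_dfr(beh_cols, function(b) {
    an <- anova_grid(obs[[b]], obs$x, obs$y, type = type)
    lm_ <- lme_grid(obs[[b]], obs$x, obs$y,
                    if (mode == "runs") obs$subject_id else
                      seq_len(nrow(obs)))
    tibble::tibble(behavior = b, term = an$term, df = an$df,
                   statistic = an$statistic, p.value = an$p.value,
                   chisq = lm_$statistic, p_lme = lm_$p.value,
                   lme_converged = lm_$converged)
  })
  ok <- !is.na(terms$p.value)
  terms$p_fdr <- NA_real_; terms$p_bonf <- NA_real_
  terms$p_fdr[ok] <- correct_pvalues(terms$p.value[ok], "BH")
  terms$p_bonf[ok] <- correct_pvalues(terms$p.value[ok], "bonferroni")
  terms$tier <- dplyr::case_when(
    is.na(terms$p.value) ~ NA_character_,
    terms$p_bonf < alpha ~ "bonferroni",
    terms$p_fdr < alpha ~ "fdr",
    terms$p.value < 0.001 ~ "uncorrected",
    TRUE ~ "ns")

  posthoc <- purrr::map_dfr(beh_cols, function(b)
    dplyr::mutate(
      posthoc_pairwise(obs[[b]], obs$x, obs$y, restriction = restriction),
      behavior = b, .before = 1))

  structure(list(terms = terms, posthoc = posthoc, data = obs,
                 mode = mode, alpha = alpha),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("<association_table> ", length(unique(x$terms$behavior)),
      " behavior(s), mode '", x$mode, "'\n", sep = "")
  print(x$terms)
  invisible(x)
}

tier_rank <- c(ns = 0, uncorrected = 1, fdr = 2, bonferroni = 3)

#' Degenerate brain-behavior coding report
#'
#' Classifies each behavior by its most significant surviving term (X-coded,
#' Y-coded, interaction-coded, or uncoded at the chosen tier). For
#' interaction-coded behaviors it then searches for degenerate pairs: two
#' archetypes whose behavioral cell means are statistically indistinguishable
#' (Welch p >= `alpha_equal`, uncorrected) while their mean-connectome
#' Euclidean distance is at least the median of all pairwise archetype
#' distances — structurally different profiles producing the same behavioral
#' outcome. `side = "high"` (default) reports pairs sharing an elevated
#' outcome (both cell means above the behavior's grand mean), matching the
#' canonical readout in which two distant archetypes both show high scores;
#' `"low"` and `"both"` cover the mirrored and unrestricted definitions.
#'
#' @param association An `association_table` from [associate_behaviors()].
#' @param summaries An `archetype_summary` from [summarize_archetypes()];
#'   when missing the connectivity-distance criterion is skipped and flagged.
#' @param tier Minimum significance tier a term must reach to count as
#'   surviving: `"bonferroni"`, `"fdr"`, or `"uncorrected"`.
#' @param alpha_equal Threshold above which two cell means count as equal.
#' @param side `"high"`, `"low"`, or `"both"`.
#' @return Object of class `degeneracy_report`: `classification` (tibble:
#'   behavior, coding, best term p), `degenerate_pairs` (tibble: behavior,
#'   cells, equality p, connectome distance, median distance),
#'   `distance_available`.
#' @export
degeneracy_report <- function(association, summaries = NULL,
                              tier = c("fdr", "bonferroni", "uncorrected"),
                              alpha_equal = 0.05,
                              side = c("high", "low", "both")) {
  stopifnot(inherits(association, "association_table"))
  tier <- match.arg(tier)
  side <- match.arg(side)
  need <- tier_rank[tier]
  obs <- association$data

  coding_of <- c(X = "X-coded", Y = "Y-coded", `X:Y` = "interaction-coded")
  classification <- dplyr::group_modify(
    dplyr::group_by(association$terms, .data$behavior), function(d, g) {
      surv <- d[!is.na(d$tier) & tier_rank[d$tier] >= need, ]
      if (nrow(surv) == 0)
        return(tibble::tibble(coding = "uncoded", term = NA_character_,
                              p.value = NA_real_))
      best <- surv[which.min(surv$p.value), ]
      tibble::tibble(coding = unname(coding_of[best$term]),
                     term = best$term, p.value = best$p.value)
    })
  classification <- dplyr::ungroup(classification)

  dist_ok <- !is.null(summaries) &&
    all(!vapply(summaries$means, is.null, TRUE))
  if (!dist_ok && !is.null(summaries))
    warning("archetype summaries incomplete: connectivity criterion skipped")
  med_dist <- NA_real_
  dist_tbl <- NULL
  if (dist_ok) {
    cells <- summaries$sizes
    prs <- combn(nrow(cells), 2)
    dist_tbl <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
      i1 <- prs[1, j]; i2 <- prs[2, j]
      d <- sqrt(sum((summaries$means[[i1]] - summaries$means[[i2]])^2))
      tibble::tibble(x1 = cells$x[i1], y1 = cells$y[i1],
                     x2 = cells$x[i2], y2 = cells$y[i2], distance = d)
    })
    med_dist <- stats::median(dist_tbl$distance)
  }

  inter <- classification$behavior[classification$coding ==
                                     "interaction-coded"]
  pairs <- purrr::map_dfr(inter, function(b) {
    cm <- dplyr::summarise(dplyr::group_by(obs, .data$x, .data$y),
                           m = mean(.data[[b]]), n = dplyr::n(),
                           .groups = "drop")
    grand <- mean(obs[[b]])
    prs <- combn(nrow(cm), 2)
    purrr::map_dfr(seq_len(ncol(prs)), function(j) {
      c1 <- cm[prs[1, j], ]; c2 <- cm[prs[2, j], ]
      if (side == "high" && !(c1$m > grand && c2$m > grand)) return(NULL)
      if (side == "low" && !(c1$m < grand && c2$m < grand)) return(NULL)
      s1 <- obs[[b]][obs$x == c1$x & obs$y == c1$y]
      s2 <- obs[[b]][obs$x == c2$x & obs$y == c2$y]
      if (length(s1) < 2 || length(s2) < 2) return(NULL)
      p_eq <- t.test(s1, s2)$p.value
      if (p_eq < alpha_equal) return(NULL)
      d <- if (dist_ok) {
        hit <- dist_tbl$distance[
          (dist_tbl$x1 == c1$x & dist_tbl$y1 == c1$y &
             dist_tbl$x2 == c2$x & dist_tbl$y2 == c2$y) |
            (dist_tbl$x1 == c2$x & dist_tbl$y1 == c2$y &
               dist_tbl$x2 == c1$x & dist_tbl$y2 == c1$y)]
        hit[1]
      } else NA_real_
      if (dist_ok && d < med_dist) return(NULL)
      tibble::tibble(behavior = b, x1 = c1$x, y1 = c1$y, x2 = c2$x,
                     y2 = c2$y, p_equal = p_eq, distance = d,
                     median_distance = med_dist)
    })
  })

  structure(list(classification = classification,
                 degenerate_pairs = pairs,
                 distance_available = dist_ok,
                 tier = tier, side = side, alpha_equal = alpha_equal),
            class = "degeneracy_report")
}

#' @export
print.degeneracy_report <- function(x, ...) {
  cat("<degeneracy_report> tier '", x$tier, "', side '", x$side, "'\n",
      sep = "")
  print(x$classification)
  if (nrow(x$degenerate_pairs)) {
    cat("degenerate pairs:\n")
    print(x$degenerate_pairs)
  } else cat("no degenerate pairs\n")
  invisible(x)
}
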