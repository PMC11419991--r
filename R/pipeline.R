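#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' reference procedure: dimension screening over square grids 2x2 to 10x10 at
#' 100 epochs, an epoch sweep 40 to 260 in steps of 20 for the surviving
#' grids, consensus over 100 runs, parallel analysis at the 95th percentile.
#' Tuning repeat counts and the parallel-analysis simulation count are kept
#' configurable; full-fidelity values (200 repeats, 10,000 simulations) are
#' practical on a compute server, the defaults here suit desk-scale work.
#'
#' @param dims Grid dimensions used when `tune = FALSE`.
#' @param epochs Training epochs used when `tune = FALSE`.
#' @param tune If `TRUE`, run the two-step stability search first.
#' @param dims_list,epochs_list,n_repeats,screen_epochs,n_keep
#'   Stability-search settings (see [tune_som()]).
#' @param n_consensus_runs Ensemble size for consensus clustering.
#' @param pa_n_sim,pa_percentile Parallel-analysis settings.
#' @param n_components Optional fixed component count, bypassing parallel
#'   analysis.
#' @param preprocess Apply [preprocess_behaviors()] (Box-Cox + 1-100 rescale)
#'   to the behavior table.
#' @param mode,ss_type,restriction,alpha Association-battery settings (see
#'   [associate_behaviors()]).
#' @param tier,side Degeneracy-report settings (see [degeneracy_report()]).
#' @param null_sims Simulations for the assignment-consistency null.
#' @param seed Global seed; every stage consumes a sub-seed derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dims = c(2, 2), epochs = 200, tune = FALSE,
                            dims_list = lapply(2:10, function(d) c(d, d)),
                            epochs_list = seq(40, 260, by = 20),
                            n_repeats = 20, screen_epochs = 100,
                            n_keep = 2,
                            n_consensus_runs = 100, pa_n_sim = 1000,
                            pa_percentile = 95, n_components = NULL,
                            preprocess = TRUE,
                            mode = "runs", ss_type = 2,
                            restriction = "one-coordinate", alpha = 0.05,
                            tier = "fdr", side = "high",
                            null_sims = 1000, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the archetype-discovery pipeline end to end
#'
#' Stages: behavioral preprocessing, connectome reduction (vectorization, PCA,
#' parallel analysis), optional stability tuning, consensus SOM clustering,
#' the within-subject assignment-consistency null, the grid-coordinate
#' association battery, and the degeneracy report. Every stage draws its seed
#' from the global seed, so a fixed configuration reproduces the report
#' byte-identically. If a stage fails, the report is returned (and written)
#' up to the failing stage with the diagnostic recorded under `$error`.
#'
#' @param connectomes A [connectome_set()], or a directory path readable by
#'   [read_connectomes()].
#' @param behavior Behavior tibble (`subject_id` + score columns), or a CSV
#'   path.
#' @param config A [pipeline_config()].
#' @param out Optional path: the JSON run report is written here.
#' @return List of class `pipeline_report`; stage results under `$stages`,
#'   the JSON-ready summary under `$report`.
#' @export
run_pipeline <- function(connectomes, behavior, config = pipeline_config(),
                         out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(connectomes)) connectomes <- read_connectomes(connectomes)
  if (is.character(behavior))
    behavior <- tibble::as_tibble(read.csv(behavior))
  seeds <- derive_seeds(config$seed, 5)
  cfg_hash <- digest::digest(unclass(config))

  stages <- list()
  report <- list(config = unclass(config), config_hash = cfg_hash,
                 n_observations = dim(connectomes$matrices)[3],
                 n_subjects = length(unique(connectomes$subject_id)),
                 n_nodes = dim(connectomes$matrices)[1],
                 seeds = as.list(setNames(seeds,
                   c("features", "tune", "consensus", "null", "assoc"))))
  fail <- function(stage, e) {
    report$error <<- list(stage = stage, message = conditionMessage(e))
  }

  # behavioral preprocessing
  beh <- tryCatch({
    if (isTRUE(config$preprocess)) {
      pre <- preprocess_behaviors(behavior)
      stages$preprocess <- pre
      report$behavior_transforms <- pre$transforms
      pre$scores
    } else behavior
  }, error = function(e) { fail("preprocess", e); NULL })

  # reduction
  if (is.null(report$error)) {
    red <- tryCatch(
      reduce_dataset(connectomes, n_sim = config$pa_n_sim,
                     percentile = config$pa_percentile,
                     seed = seeds[1], n_components = config$n_components),
      error = function(e) { fail("reduce", e); NULL })
    if (!is.null(red)) {
      stages$features <- red
      report$n_components <- red$n_components
      report$top_eigenvalues <- head(red$eigenvalues, 10)
    }
  }

  # stability tuning
  dims <- config$dims; epochs <- config$epochs
  if (is.null(report$error) && isTRUE(config$tune)) {
    tn <- tryCatch(
      tune_som(stages$features, config$dims_list, config$epochs_list,
               n_repeats = config$n_repeats,
               screen_epochs = config$screen_epochs,
               n_keep = config$n_keep, seed = seeds[2]),
      error = function(e) { fail("tune", e); NULL })
    if (!is.null(tn)) {
      stages$tuning <- tn
      dims <- tn$selected$dims; epochs <- tn$selected$epochs
      report$selected <- list(dims = dims, epochs = epochs,
                              score = tn$selected$score)
    }
  }

  # consensus clustering
  if (is.null(report$error)) {
    cons <- tryCatch(
      consensus_cluster(stages$features, dims, epochs,
                        n_runs = config$n_consensus_runs, seed = seeds[3]),
      error = function(e) { fail("consensus", e); NULL })
    if (!is.null(cons)) {
      stages$consensus <- cons
      stages$summaries <- summarize_archetypes(connectomes, cons$assignment)
      report$archetype_sizes <- stages$summaries$sizes
      report$representative_run <- cons$representative_run
      report$mean_run_consensus_ari <- mean(cons$per_run$ari)
    }
  }

  # assignment-consistency null
  if (is.null(report$error)) {
    nullrep <- tryCatch({
      asg <- stages$consensus$assignment
      n_runs <- max(table(asg$subject_id))
      null <- random_assignment_null(
        length(unique(asg$subject_id)), n_runs, prod(dims),
        n_sims = config$null_sims, seed = seeds[4])
      consistency_test(asg, null)
    }, error = function(e) { fail("null", e); NULL })
    if (!is.null(nullrep)) {
      stages$consistency <- nullrep
      report$consistency <- list(observed_mean = nullrep$observed_mean,
                                 null_mean = nullrep$null_mean,
                                 null_sd = nullrep$null_sd,
                                 p = nullrep$p, p_label = nullrep$p_label)
    }
  }

  # association battery + degeneracy
  if (is.null(report$error)) {
    assoc <- tryCatch(
      associate_behaviors(beh, stages$consensus$assignment,
                          mode = config$mode, type = config$ss_type,
                          restriction = config$restriction,
                          alpha = config$alpha),
      error = function(e) { fail("assoc", e); NULL })
    if (!is.null(assoc)) {
      stages$association <- assoc
      report$association <- assoc$terms
      deg <- tryCatch(
        degeneracy_report(assoc, stages$summaries, tier = config$tier,
                          side = config$side),
        error = function(e) { fail("degeneracy", e); NULL })
      if (!is.null(deg)) {
        stages$degeneracy <- deg
        report$classification <- deg$classification
        report$degenerate_pairs <- deg$degenerate_pairs
      }
    }
  }

  res <- structure(list(report = report, stages = stages),
                   class = "pipeline_report")
  if (!is.null(out)) write_report(res, out)
  res
}

#' Write a pipeline report as JSON
#'
#' The JSON serialization is deterministic: identical configuration and seed
#' produce byte-identical files.
#'
#' @param x A `pipeline_report`.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "pipeline_report"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("<pipeline_report>\n")
  if (!is.null(r$error)) {
    cat("  FAILED at stage '", r$error$stage, "': ", r$error$message,
        "\n", sep = "")
  }
  if (!is.null(r$n_components))
    cat("  components retained:", r$n_components, "\n")
  if (!is.null(r$archetype_sizes)) {
    cat("  archetype sizes:",
        paste(sprintf("(%d,%d)=%d", r$archetype_sizes$x,
                      r$archetype_sizes$y, r$archetype_sizes$n),
              collapse = " "), "\n")
  }
  if (!is.null(r$consistency))
    cat("  consistency: observed ",
        format(r$consistency$observed_mean, digits = 4), " vs null ",
        format(r$consistency$null_mean, digits = 4), ", p ",
        r$consistency$p_label, "\n", sep = "")
  if (!is.null(r$classification)) {
    cat("  behavior coding:",
        paste(r$classification$behavior, r$classification$coding,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run a pipeline described by a YAML configuration file
#'
#' The file must contain `connectomes` (directory) and `behavior` (CSV) paths
#' plus any [pipeline_config()] fields; relative paths resolve against the
#' file's directory.
#'
#' @param path YAML configuration file.
#' @param out Optional JSON report path.
#' @return A `pipeline_report`.
#' @export
run_pipeline_file <- function(path, out = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base, p)
  stopifnot(!is.null(y$connectomes), !is.null(y$behavior))
  cfg_fields <- intersect(names(y), names(formals(pipeline_config)))
  cfg <- do.call(pipeline_config, y[cfg_fields])
  if (!is.null(y$dims)) cfg$dims <- unlist(y$dims)
  run_pipeline(resolve(y$connectomes), resolve(y$behavior), cfg, out = out)
}
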