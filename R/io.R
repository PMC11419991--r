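#' Write / read a connectome set as delimited matrices
#'
#' One tab-separated N x N matrix per observation, named
#' `sub<subject>_run<run>.tsv`. An optional `nodes.tsv` carries node labels
#' and the node-to-network map.
#'
#' @param cs A [connectome_set()].
#' @param dir Output directory (created if missing).
#' @return `write_connectomes()`: the directory, invisibly.
#' @export
write_connectomes <- function(cs, dir) {
  stopifnot(inherits(cs, "connectome_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(cs$matrices)[3])) {
    f <- file.path(dir, sprintf("sub%s_run%s.tsv", cs$subject_id[i],
                                cs$run_id[i]))
    utils::write.table(cs$matrices[, , i], f, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  nodes <- data.frame(node = cs$node_labels,
                      network = cs$network %||% NA)
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_connectomes
#' @return `read_connectomes()`: a [connectome_set()].
#' @export
read_connectomes <- function(dir) {
  files <- sort(list.files(dir, pattern = "^sub.*_run.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no connectome files in ", dir)
  meta <- regmatches(basename(files),
                     regexec("^sub(.+)_run(.+)\\.tsv$", basename(files)))
  subject_id <- vapply(meta, `[`, "", 2)
  run_id <- vapply(meta, `[`, "", 3)
  suppressWarnings({
    si <- as.integer(subject_id); ri <- as.integer(run_id)
  })
  if (!any(is.na(si))) subject_id <- si
  if (!any(is.na(ri))) run_id <- ri
  mats <- lapply(files, function(f)
    as.matrix(utils::read.table(f, sep = "\t")))
  nodes_f <- file.path(dir, "nodes.tsv")
  node_labels <- network <- NULL
  if (file.exists(nodes_f)) {
    nodes <- utils::read.table(nodes_f, sep = "\t", header = TRUE)
    node_labels <- as.character(nodes$node)
    if (!all(is.na(nodes$network))) network <- nodes$network
  }
  cs <- connectome_set(mats, subject_id, run_id, node_labels, network)
  # stable observation order: subject then run
  ord <- order(cs$subject_id, cs$run_id)
  connectome_set(cs$matrices[, , ord, drop = FALSE], cs$subject_id[ord],
                 cs$run_id[ord], node_labels, network)
}

#' Write / read the ground truth of a synthetic study
#'
#' @param truth A `ground_truth` object.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(assignments = truth$assignments,
              subject_modal = truth$subject_modal,
              grid = truth$grid,
              coding_map = truth$coding_map,
              config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  truth <- list(assignments = tibble::as_tibble(x$assignments),
                subject_modal = tibble::as_tibble(x$subject_modal),
                grid = tibble::as_tibble(x$grid),
                config = do.call(synth_config, cfg[names(cfg) != ""]))
  if (!is.null(x$coding_map))
    truth$coding_map <- tibble::as_tibble(x$coding_map)
  structure(truth, class = "ground_truth")
}

#' Write a complete synthetic study to disk
#'
#' Writes the connectome directory, the behavior CSV, the ground-truth JSON,
#' and the generating configuration as YAML. This is the file layout the
#' pipeline reads back.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_connectomes(study$connectomes, file.path(dir, "connectomes"))
  write.csv(study$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  write_ground_truth(study$truth, file.path(dir, "ground_truth.json"))
  yaml::write_yaml(unclass(study$truth$config),
                   file.path(dir, "synth_config.yaml"))
  invisible(dir)
}

#' @rdname write_study
#' @return `read_study()`: list with `connectomes`, `behavior`, `truth`.
#' @export
read_study <- function(dir) {
  list(connectomes = read_connectomes(file.path(dir, "connectomes")),
       behavior = tibble::as_tibble(read.csv(file.path(dir, "behavior.csv"))),
       truth = read_ground_truth(file.path(dir, "ground_truth.json")))
}
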