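# Plain-text I/O. Node order is always taken from the atlas node table,
# never from file row order.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "netsweep_io_error")
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Load an atlas node table from TSV
#'
#' Expected columns: `node_id`, `name`, `hemisphere`, `lobe`, `is_cortical`
#' and optionally `scale`.
#'
#' @param path TSV file path.
#' @return A validated atlas tibble.
#' @export
load_node_table <- function(path) {
  validate_atlas(.read_tsv(path))
}

#' @rdname load_node_table
#' @param atlas Atlas tibble to write.
#' @export
save_node_table <- function(atlas, path) {
  readr::write_tsv(validate_atlas(atlas), path)
  invisible(path)
}

#' Load per-subject streamline counts from TSV
#'
#' The file holds the directed count matrix in long format with columns
#' `from`, `to`, `count` (0-based node ids; absent pairs are zero), plus the
#' seed totals in a companion column set: rows with `to == -1` carry
#' `count = seeded[from]`. [save_counts()] writes this layout.
#'
#' @param path TSV path.
#' @param atlas Atlas node table fixing the dimension and node order.
#' @param subject_id Subject id; defaults to the file name.
#' @return A [streamline_counts()] object.
#' @export
load_counts <- function(path, atlas, subject_id = NULL) {
  atlas <- validate_atlas(atlas)
  n <- nrow(atlas)
  df <- .read_tsv(path, col_types = readr::cols(
    from = readr::col_integer(), to = readr::col_integer(),
    count = readr::col_double()))
  if (!all(c("from", "to", "count") %in% names(df))) {
    abort("counts file must have columns from, to, count",
          class = "netsweep_schema_error")
  }
  bad <- !is.finite(df$count)
  if (any(bad)) {
    abort(sprintf("non-numeric count at row %d", which(bad)[1]),
          class = "netsweep_parse_error")
  }
  seed_rows <- df$to == -1L
  body <- df[!seed_rows, ]
  if (any(body$from < 0 | body$from >= n | body$to < 0 | body$to >= n)) {
    abort(sprintf("counts file node ids out of range for %d-node atlas", n),
          class = "netsweep_schema_error")
  }
  max_id <- max(c(body$from, body$to, df$from[seed_rows]))
  if (sum(seed_rows) != n) {
    abort(sprintf(
      "counts file has seed totals for %d ROIs but node table has %d",
      sum(seed_rows), n), class = "netsweep_schema_error")
  }
  counts <- matrix(0, n, n)
  counts[cbind(body$from + 1L, body$to + 1L)] <- body$count
  seeded <- numeric(n)
  seeded[df$from[seed_rows] + 1L] <- df$count[seed_rows]
  if (is.null(subject_id)) {
    subject_id <- sub("\\.tsv$", "", basename(path))
  }
  streamline_counts(subject_id, counts, seeded, scale = atlas$scale)
}

#' @rdname load_counts
#' @param sc `streamline_counts` object to write.
#' @export
save_counts <- function(sc, path) {
  nz <- which(sc$counts != 0, arr.ind = TRUE)
  body <- tibble::tibble(from = nz[, 1] - 1L, to = nz[, 2] - 1L,
                         count = sc$counts[nz])
  seeds <- tibble::tibble(from = seq_along(sc$seeded) - 1L, to = -1L,
                          count = sc$seeded)
  readr::write_tsv(dplyr::arrange(dplyr::bind_rows(body, seeds),
                                  .data$from, .data$to), path)
  invisible(path)
}

#' Save / load a connectivity matrix as header-less TSV
#'
#' The file is N rows of N tab-separated floats (both triangles stored).
#'
#' @param m `connectivity_matrix`.
#' @param path TSV path.
#' @export
save_matrix <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname save_matrix
#' @param atlas Atlas fixing the expected dimension.
#' @param subject_id Subject id for the loaded matrix.
#' @export
load_matrix <- function(path, atlas, subject_id = "subject") {
  atlas <- validate_atlas(atlas)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(x) <- NULL
  if (nrow(x) != nrow(atlas) || ncol(x) != nrow(atlas)) {
    abort(sprintf("matrix is %dx%d but node table has %d nodes",
                  nrow(x), ncol(x), nrow(atlas)),
          class = "netsweep_schema_error")
  }
  connectivity_matrix(x, subject_id = subject_id)
}

#' Load a clinical covariate table from CSV
#'
#' Expected columns: `subject_id`, `group` (`patient`/`control`), `age`,
#' `handedness` (Edinburgh laterality index, -100..100), `bmi_scan`,
#' `bmi_lowest`; extra covariates are kept.
#'
#' @param path CSV path.
#' @return A tibble, one row per subject.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "netsweep_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "group", "age", "handedness")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("clinical table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "netsweep_schema_error")
  }
  if (!all(df$group %in% c("patient", "control"))) {
    abort("group labels must be 'patient' or 'control'",
          class = "netsweep_schema_error")
  }
  if (anyDuplicated(df$subject_id) > 0) {
    abort("duplicate subject_id in clinical table",
          class = "netsweep_schema_error")
  }
  df
}

#' Load per-subject ROI volumes from TSV
#'
#' Long format with columns `subject_id`, `node_id`, `volume` (mm^3).
#'
#' @param path TSV path.
#' @param atlas Atlas fixing the node set.
#' @return A tibble with one row per subject x node.
#' @export
load_volumes <- function(path, atlas) {
  atlas <- validate_atlas(atlas)
  df <- .read_tsv(path)
  req <- c("subject_id", "node_id", "volume")
  if (!all(req %in% names(df))) {
    abort("volume table must have columns subject_id, node_id, volume",
          class = "netsweep_schema_error")
  }
  if (!all(df$node_id %in% atlas$node_id)) {
    abort("volume table contains node ids absent from the node table",
          class = "netsweep_schema_error")
  }
  if (any(df$volume < 0)) {
    abort("volumes must be nonnegative", class = "netsweep_schema_error")
  }
  df
}

#' Export a network to GraphML
#'
#' Accepts either a weighted `connectivity_matrix` (weighted graph export) or
#' a `binary_network` from [threshold_to_density()].
#'
#' @param x Network to export.
#' @param path Output path.
#' @param atlas Optional atlas; node names are attached when supplied.
#' @export
export_graphml <- function(x, path, atlas = NULL) {
  if (inherits(x, "binary_network")) {
    g <- igraph::graph_from_adjacency_matrix(x$adjacency, mode = "undirected")
  } else {
    g <- igraph::graph_from_adjacency_matrix(unclass(x), mode = "undirected",
                                             weighted = TRUE)
  }
  if (!is.null(atlas)) {
    atlas <- validate_atlas(atlas)
    igraph::V(g)$name <- atlas$name
    igraph::V(g)$lobe <- atlas$lobe
    igraph::V(g)$hemisphere <- atlas$hemisphere
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
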