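# Streamline counts -> symmetric weighted connectivity matrices, and
# covariate residualization of edge weights or derived metrics.

#' Construct and validate a streamline-count object
#'
#' Holds the directed tract-sampling result for one subject: `counts[i, j]` is
#' the number of streamlines seeded in ROI `i` that reached ROI `j`, `seeded[i]`
#' the number of streamlines sampled from ROI `i`, and `scale[i]` an optional
#' per-ROI multiplier applied to the conditional probabilities.
#'
#' @param subject_id Subject identifier.
#' @param counts N x N nonnegative integer matrix with zero diagonal.
#' @param seeded Length-N vector of positive streamline totals per seed ROI.
#' @param scale Length-N vector of positive per-ROI scale factors (default 1).
#' @return A `streamline_counts` object.
#' @export
streamline_counts <- function(subject_id, counts, seeded, scale = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) {
    abort("counts must be square", class = "netsweep_schema_error")
  }
  if (is.null(scale)) scale <- rep(1, n)
  if (length(seeded) != n || length(scale) != n) {
    abort("seeded and scale must have one entry per ROI",
          class = "netsweep_schema_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers", class = "netsweep_schema_error")
  }
  if (any(diag(counts) != 0)) {
    abort("counts diagonal must be zero", class = "netsweep_schema_error")
  }
  if (any(seeded <= 0)) {
    bad <- which(seeded <= 0)[1]
    abort(sprintf("degenerate seed count for ROI %d (seeded = %s)",
                  bad - 1L, format(seeded[bad])),
          class = "netsweep_degenerate_seed_error")
  }
  if (any(counts > matrix(seeded, n, n))) {
    idx <- which(counts > matrix(seeded, n, n), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "counts[%d, %d] exceeds streamlines seeded in ROI %d",
      idx[1] - 1L, idx[2] - 1L, idx[1] - 1L),
      class = "netsweep_inconsistent_counts_error")
  }
  if (any(scale <= 0)) {
    abort("scale factors must be positive", class = "netsweep_schema_error")
  }
  structure(
    list(subject_id = as.character(subject_id), counts = counts,
         seeded = as.numeric(seeded), scale = as.numeric(scale)),
    class = "streamline_counts"
  )
}

#' @export
print.streamline_counts <- function(x, ...) {
  cat(sprintf("<streamline_counts> subject %s: %d ROIs, %s streamlines total\n",
              x$subject_id, nrow(x$counts), format(sum(x$counts))))
  invisible(x)
}

#' Scaled conditional-probability connectivity matrix
#'
#' Converts directed streamline counts into the undirected weighted
#' connectivity matrix used throughout the pipeline. The directed connection
#' probability from ROI i to ROI j is the scaled conditional probability
#' `d_ij = (counts[i, j] / seeded[i]) * scale[i]`; the two directed estimates
#' are then averaged, `P_ij = (d_ij + d_ji) / 2`, giving an exactly symmetric,
#' zero-diagonal matrix.
#'
#' @param sc A [streamline_counts()] object.
#' @return A `connectivity_matrix`: a symmetric numeric matrix with attribute
#'   `subject_id`.
#' @examples
#' counts <- matrix(0L, 3, 3)
#' counts[1, 2] <- 50L; counts[2, 1] <- 30L
#' sc <- streamline_counts("s1", counts, seeded = rep(5000, 3))
#' compute_probability_matrix(sc)[1, 2]  # (50/5000 + 30/5000) / 2 = 0.008
#' @export
compute_probability_matrix <- function(sc) {
  if (!inherits(sc, "streamline_counts")) {
    sc <- streamline_counts(sc$subject_id, sc$counts, sc$seeded, sc$scale)
  }
  d <- (sc$counts / sc$seeded) * sc$scale # rows scaled: seeded[i], scale[i]
  p <- (d + t(d)) / 2
  diag(p) <- 0
  connectivity_matrix(p, subject_id = sc$subject_id)
}

#' Tag a symmetric weight matrix as a connectivity matrix
#'
#' @param values Symmetric nonnegative matrix with zero diagonal.
#' @param subject_id Subject identifier stored as an attribute.
#' @param tol Symmetry tolerance for user-supplied matrices.
#' @return The matrix with class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, subject_id = "subject", tol = 1e-10) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("connectivity matrix must be square", class = "netsweep_schema_error")
  }
  if (max(abs(values - t(values))) > tol) {
    abort("connectivity matrix must be symmetric",
          class = "netsweep_schema_error")
  }
  values <- (values + t(values)) / 2 # make symmetry exact
  if (any(values < 0)) {
    abort("connectivity weights must be nonnegative",
          class = "netsweep_schema_error")
  }
  diag(values) <- 0
  structure(values, subject_id = as.character(subject_id),
            class = c("connectivity_matrix", class(values)))
}

#' Remove age and handedness effects by linear regression
#'
#' Regresses each feature (edge weight, nodal metric, or curve value) on the
#' supplied covariates across subjects by ordinary least squares and returns
#' the residuals with each feature's grand mean added back, so values stay on
#' their original scale. Rank-deficient designs drop the redundant column with
#' a warning.
#'
#' @param data Subjects x features numeric matrix (or data frame).
#' @param covariates Data frame with one row per subject; columns named in
#'   `cols` are used as regressors (default `age` and `handedness`).
#' @param cols Covariate column names.
#' @param floor_zero Clamp negative residualized values to 0 (use for edge
#'   weights, which are nonnegative by construction).
#' @return A matrix of the same dimension as `data`.
#' @export
residualize <- function(data, covariates, cols = c("age", "handedness"),
                        floor_zero = FALSE) {
  x <- as.matrix(data)
  if (nrow(x) < 3) {
    abort("residualization needs at least 3 subjects",
          class = "netsweep_insufficient_data_error")
  }
  missing <- setdiff(cols, names(covariates))
  if (length(missing) > 0) {
    abort(paste0("covariate column(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "netsweep_schema_error")
  }
  cov <- as.matrix(covariates[, cols, drop = FALSE])
  if (nrow(cov) != nrow(x)) {
    abort("covariates must have one row per subject",
          class = "netsweep_schema_error")
  }
  if (anyNA(cov)) {
    abort("covariate columns must be complete", class = "netsweep_schema_error")
  }
  design <- cbind(`(Intercept)` = 1, cov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warn(paste0("collinear covariates; dropping: ",
                paste(dropped, collapse = ", ")))
    design <- design[, keep, drop = FALSE]
    qrd <- qr(design)
  }
  if (nrow(x) < ncol(design) + 1) {
    abort("fewer subjects than covariates + 1",
          class = "netsweep_insufficient_data_error")
  }
  res <- qr.resid(qrd, x)
  out <- sweep(res, 2, colMeans(x), `+`)
  if (floor_zero) out[out < 0] <- 0
  dimnames(out) <- dimnames(x)
  out
}

#' Residualize edge weights across a cohort of connectivity matrices
#'
#' Vectorizes the upper triangle of each subject's matrix, applies
#' [residualize()] per edge, floors negative weights at zero, and rebuilds the
#' symmetric matrices.
#'
#' @param matrices List of `connectivity_matrix` objects (one per subject, all
#'   the same dimension).
#' @param covariates Clinical table aligned with `matrices`.
#' @param cols Covariate columns, as in [residualize()].
#' @return A list of adjusted `connectivity_matrix` objects.
#' @export
residualize_edges <- function(matrices, covariates,
                              cols = c("age", "handedness")) {
  n <- nrow(matrices[[1]])
  ut <- upper.tri(matrices[[1]])
  flat <- do.call(rbind, lapply(matrices, function(m) as.matrix(m)[ut]))
  adj <- residualize(flat, covariates, cols = cols, floor_zero = TRUE)
  purrr::map2(seq_along(matrices), matrices, function(i, m) {
    out <- matrix(0, n, n)
    out[ut] <- adj[i, ]
    out <- out + t(out)
    connectivity_matrix(out, subject_id = attr(m, "subject_id"))
  })
}
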