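#' Construct a beta-value matrix
#'
#' A `BetaMatrix` bundles a probes-by-samples matrix of methylation beta
#' values (the fraction of methylated signal at each CpG probe, in
#' \[0, 1\]) with an optional matrix of per-measurement detection p-values
#' of identical shape. Probe and sample identifiers live in the dimnames
#' and must be unique.
#'
#' @param beta numeric matrix, probes in rows and samples in columns, with
#'   row and column names; all values in \[0, 1\] (NA allowed).
#' @param detection_p optional numeric matrix of detection p-values with
#'   the same dimensions and dimnames as `beta`, values in \[0, 1\].
#' @return An object of class `BetaMatrix`.
#' @export
BetaMatrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must have probe row names and sample column names")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "))
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta values outside [0, 1] at probe ",
         rownames(beta)[bad[1, 1]], ", sample ", colnames(beta)[bad[1, 2]])
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta)))
      stop("`detection_p` must be a matrix with the same shape as `beta`")
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("`detection_p` dimnames must match `beta`")
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values must lie in [0, 1]")
  }
  structure(list(beta = beta, detection_p = detection_p), class = "BetaMatrix")
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' Probe identifiers of a BetaMatrix
#' @param x a `BetaMatrix`.
#' @return Character vector of probe ids (row order).
#' @export
probe_ids <- function(x) rownames(x$beta)

#' Sample identifiers of a BetaMatrix
#' @param x a `BetaMatrix`.
#' @return Character vector of sample ids (column order).
#' @export
sample_ids <- function(x) colnames(x$beta)

#' @export
`[.BetaMatrix` <- function(x, i, j, ...) {
  b <- x$beta[i, j, drop = FALSE]
  d <- if (is.null(x$detection_p)) NULL else x$detection_p[i, j, drop = FALSE]
  BetaMatrix(b, d)
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  invisible(x)
}

#' Read a beta-value matrix from a tab-separated file
#'
#' The file must have a header line of sample ids and one row per probe,
#' keyed by probe id in the first column. An optional parallel file of
#' detection p-values in the same layout may be supplied.
#'
#' @param path path to the tab-separated beta-value file.
#' @param detection_path optional path to a detection p-value file with
#'   identical probe/sample layout.
#' @return A [BetaMatrix].
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  b <- .read_matrix_tsv(path, what = "beta value")
  d <- if (is.null(detection_path)) NULL
       else .read_matrix_tsv(detection_path, what = "detection p-value")
  BetaMatrix(b, d)
}

.read_matrix_tsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed ", what, " file (need id column + samples): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe id in ", path, ": ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r))))
    stop("non-numeric ", what, " in ", path, " at row for probe ", ids[bad[1]])
  }
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(what, " outside [0, 1] in ", path, " at row for probe ", ids[bad[1, 1]])
  m
}

#' Write a beta-value matrix (and its detection p-values) to TSV files
#'
#' Inverse of [read_beta_matrix()]; round-trips losslessly at full double
#' precision.
#'
#' @param x a [BetaMatrix].
#' @param path output path for the beta values.
#' @param detection_path optional output path for the detection p-values;
#'   required when `x` carries them and you want them preserved.
#' @return `x`, invisibly.
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL) {
  stopifnot(inherits(x, "BetaMatrix"))
  .write_matrix_tsv(x$beta, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p)) stop("no detection p-values to write")
    .write_matrix_tsv(x$detection_p, detection_path)
  }
  invisible(x)
}

.write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Remove probes that fail the detection p-value rule
#'
#' Probes whose signal cannot be distinguished from background are
#' unreliable; the conventional rule removes CpG sites with a detection
#' p-value above `alpha` (default 0.05). Two scopes are offered:
#' `"probe"` (default) drops a probe entirely if it fails in any sample,
#' keeping the matrix rectangular; `"mask"` sets only the failing
#' measurements to NA.
#'
#' @param x a [BetaMatrix] carrying detection p-values.
#' @param alpha detection p-value threshold; measurements with
#'   detection p > `alpha` fail.
#' @param mode `"probe"` to drop failing probes, `"mask"` to NA failing
#'   cells.
#' @return A [BetaMatrix]; in `"probe"` mode the attribute
#'   `"removed_probes"` lists the probe ids that were dropped.
#' @export
filter_by_detection <- function(x, alpha = 0.05, mode = c("probe", "mask")) {
  stopifnot(inherits(x, "BetaMatrix"))
  mode <- match.arg(mode)
  if (is.null(x$detection_p)) stop("`x` has no detection p-values")
  fail <- !is.na(x$detection_p) & x$detection_p > alpha
  if (mode == "mask") {
    b <- x$beta
    b[fail] <- NA
    return(BetaMatrix(b, x$detection_p))
  }
  keep <- rowSums(fail) == 0
  removed <- rownames(x$beta)[!keep]
  if (!any(keep)) warning("all probes removed by detection filtering")
  out <- x[keep, ]
  attr(out, "removed_probes") <- removed
  out
}
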