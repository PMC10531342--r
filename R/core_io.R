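#' Read a cytometry marker matrix
#'
#' Reads an FCS 3.0/3.1 file or a delimited text file (comma or tab,
#' header row) into a [MarkerMatrix-class].  For FCS input, markers are
#' identified by the $PnS stain name with $PnN as fallback, and non-marker
#' channels (time, event length, barcodes, bead distance) are excluded
#' unless explicitly requested through \code{markerSubset}.  Rows containing
#' non-finite values are dropped and counted in the \code{nDropped} slot.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"fcs"} or
#'   \code{"delimited"}.
#' @param markerSubset optional character vector of channels to keep, in the
#'   requested order.
#' @param labelColumn optional name of a column holding population labels
#'   (delimited input only).
#' @param batchColumn optional name of a column holding batch ids
#'   (delimited input only).
#' @return a [MarkerMatrix-class] with \code{transformed = FALSE}
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("CD45,B220", "1.0,2.0", "3.0,4.0"), tf)
#' m <- readMarkerMatrix(tf)
#' dim(m)
#' @export
readMarkerMatrix <- function(path, format = c("auto", "delimited", "fcs"),
                             markerSubset = NULL, labelColumn = NULL,
                             batchColumn = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  }
  if (format == "fcs") {
    parsed <- readFCSFile(path)
    df <- as.data.frame(parsed$data)
    names(df) <- parsed$channels
    keep <- if (is.null(markerSubset)) {
      parsed$channels[!isNonMarkerChannel(parsed$channels)]
    } else {
      missing <- setdiff(markerSubset, parsed$channels)
      if (length(missing)) stopf("channels not in file: %s", paste(missing, collapse = ", "))
      markerSubset
    }
    return(buildMarkerMatrix(df[keep], labels = NULL, batches = NULL))
  }

  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stopf("empty file: %s", path)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("no data rows in %s", path)
  if (anyDuplicated(names(df))) {
    stopf("duplicate marker names in header: %s",
          paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  labels <- NULL
  if (!is.null(labelColumn)) {
    if (!labelColumn %in% names(df)) stopf("label column '%s' not found", labelColumn)
    labels <- as.character(df[[labelColumn]])
    df[[labelColumn]] <- NULL
  }
  batches <- NULL
  if (!is.null(batchColumn)) {
    if (!batchColumn %in% names(df)) stopf("batch column '%s' not found", batchColumn)
    batches <- as.character(df[[batchColumn]])
    df[[batchColumn]] <- NULL
  }
  if (!is.null(markerSubset)) {
    missing <- setdiff(markerSubset, names(df))
    if (length(missing)) stopf("columns not in file: %s", paste(missing, collapse = ", "))
    df <- df[markerSubset]
  }
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad)) {
    stopf("non-numeric marker column(s): %s (use labelColumn/batchColumn for annotations)",
          paste(names(df)[bad], collapse = ", "))
  }
  buildMarkerMatrix(df, labels, batches)
}

buildMarkerMatrix <- function(df, labels, batches) {
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (ncol(m) == 0L) stopf("no marker columns selected")
  ok <- rowSums(!is.finite(m)) == 0L
  nDropped <- sum(!ok)
  if (nDropped > 0L) {
    message(sprintf("dropped %d row(s) with non-finite values", nDropped))
    m <- m[ok, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[ok]
    if (!is.null(batches)) batches <- batches[ok]
  }
  if (nrow(m) == 0L) stopf("no complete rows remain after filtering")
  markerMatrix(m, cellLabels = labels, batchIds = batches,
               transformed = FALSE, nDropped = nDropped)
}

isNonMarkerChannel <- function(ch) {
  grepl("^(time|event[_ ]?length|beaddist|bead[_ ]?dist|barcode|center|offset|width|residual)$",
        ch, ignore.case = TRUE)
}

#' Write a marker matrix as delimited text
#'
#' Values are written in full-precision decimal representation (17
#' significant digits) so that a read/write round trip is lossless well
#' beyond 12 significant digits.  A label column is appended when labels are
#' present.
#'
#' @param m a [MarkerMatrix-class]
#' @param path output file
#' @param sep field separator ("," or "\\t")
#' @param labelColumn name of the label column when labels are present
#' @return \code{path}, invisibly
#' @export
writeMarkerMatrix <- function(m, path, sep = ",", labelColumn = "population") {
  stopifnot(is(m, "MarkerMatrix"))
  v <- m@values
  cols <- lapply(seq_len(ncol(v)), function(j) sprintf("%.17g", v[, j]))
  header <- colnames(v)
  if (length(m@cellLabels)) {
    cols <- c(cols, list(m@cellLabels))
    header <- c(header, labelColumn)
  }
  lines <- do.call(paste, c(cols, sep = sep))
  writeLines(c(paste(header, collapse = sep), lines), path)
  invisible(path)
}

#' ArcSinh-transform a marker matrix
#'
#' Applies the standard cytometry variance-stabilizing transform
#' \code{asinh(x / cofactor)} elementwise.  Mass-cytometry intensities may
#' be negative after randomization; asinh handles them naturally.  Applying
#' the transform twice is refused.
#'
#' @param m a raw-space [MarkerMatrix-class]
#' @param cofactor positive scaling constant (default 5, the mass-cytometry
#'   convention)
#' @return the transformed [MarkerMatrix-class] (\code{transformed = TRUE})
#' @examples
#' m <- markerMatrix(matrix(c(0, 5), 2, 1, dimnames = list(NULL, "CD45")))
#' intensityValues(arcsinhTransform(m))  # 0 and asinh(1) = log(1 + sqrt(2))
#' @export
arcsinhTransform <- function(m, cofactor = 5) {
  stopifnot(is(m, "MarkerMatrix"))
  if (length(cofactor) != 1L || !is.finite(cofactor) || cofactor <= 0) {
    stopf("cofactor must be a positive number")
  }
  if (m@transformed) stopf("matrix is already arcsinh-transformed")
  out <- m
  out@values <- asinh(m@values / cofactor)
  out@transformed <- TRUE
  validObject(out)
  out
}
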