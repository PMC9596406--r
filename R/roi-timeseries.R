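#' Construct a regional BOLD time-series container
#'
#' Builds a \linkS4class{ROITimeSeries} from a frames x regions matrix. The
#' matrix orientation follows the analysis convention (one row per
#' acquisition frame, one column per region); internally the object stores
#' regions as SummarizedExperiment rows.
#'
#' @param values numeric frames x regions matrix; column names are used as
#'   region labels when `regionLabels` is missing.
#' @param tr repetition time in seconds (> 0).
#' @param regionLabels character vector of unique region names.
#' @param provenance named character vector of free-text tags
#'   (e.g. subject, tod, task, phase).
#' @return A \linkS4class{ROITimeSeries}.
#' @examples
#' x <- ROITimeSeries(matrix(rnorm(40), 20, 2), tr = 1.8,
#'                    regionLabels = c("A", "B"))
#' nFrames(x)
#' @export
ROITimeSeries <- function(values, tr = 1.8, regionLabels = colnames(values),
                          provenance = character()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  assertScalarNumeric(tr, "tr", lo = .Machine$double.xmin)
  if (is.null(regionLabels))
    regionLabels <- sprintf("ROI%03d", seq_len(ncol(values)))
  regionLabels <- as.character(regionLabels)
  if (length(regionLabels) != ncol(values))
    stop("number of region labels must equal the number of regions",
         call. = FALSE)
  a <- t(values)
  dimnames(a) <- list(regionLabels,
                      sprintf("frame%04d", seq_len(ncol(a))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bold = a),
    metadata = list(tr = tr, provenance = provenance))
  new("ROITimeSeries", se)
}

#' BOLD values as a frames x regions matrix
#'
#' @param x a \linkS4class{ROITimeSeries}.
#' @return numeric matrix, frames in rows, regions in columns.
#' @export
#' @aliases boldValues,ROITimeSeries-method
setMethod("boldValues", "ROITimeSeries", function(x) {
  t(SummarizedExperiment::assay(x, "bold"))
})

#' Repetition time (TR) in seconds
#' @param x a \linkS4class{ROITimeSeries}.
#' @return numeric scalar.
#' @export
#' @aliases repetitionTime,ROITimeSeries-method
setMethod("repetitionTime", "ROITimeSeries", function(x)
  S4Vectors::metadata(x)$tr)

#' Region labels
#' @param x a \linkS4class{ROITimeSeries} or \linkS4class{SurrogateSpec}.
#' @return character vector of region names.
#' @export
#' @aliases regionLabels,ROITimeSeries-method
setMethod("regionLabels", "ROITimeSeries", function(x) rownames(x))

#' @rdname regionLabels
#' @export
#' @aliases regionLabels,SurrogateSpec-method
setMethod("regionLabels", "SurrogateSpec", function(x) x@regionLabels)

#' Provenance tags
#' @param x a \linkS4class{ROITimeSeries} or \linkS4class{DCCMatrix}.
#' @return named character vector.
#' @export
#' @aliases provenance,ROITimeSeries-method
setMethod("provenance", "ROITimeSeries", function(x) {
  p <- S4Vectors::metadata(x)$provenance
  if (is.null(p)) character() else p
})

#' Number of acquisition frames
#' @param x a \linkS4class{ROITimeSeries}.
#' @return integer.
#' @export
#' @aliases nFrames,ROITimeSeries-method
setMethod("nFrames", "ROITimeSeries", function(x) ncol(x))

#' Number of regions
#' @param x a \linkS4class{ROITimeSeries}.
#' @return integer.
#' @export
#' @aliases nRegions,ROITimeSeries-method
setMethod("nRegions", "ROITimeSeries", function(x) nrow(x))

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: %d frames x %d regions, TR = %g s\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$tr))
  p <- S4Vectors::metadata(object)$provenance
  if (length(p))
    cat("provenance:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
})

#' Read / write a regional time-series matrix as TSV
#'
#' The on-disk format is a plain TSV with a header row of region labels and
#' one row per frame. `writeROIMatrix` formats values at 12 significant
#' digits, so a write/read round trip reproduces the matrix to better than
#' 1e-9 absolute.
#'
#' @param path file path.
#' @param tr repetition time attached on read (the TSV does not carry it).
#' @param provenance tags attached on read.
#' @return `readROIMatrix` returns a \linkS4class{ROITimeSeries};
#'   `writeROIMatrix` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeROIMatrix(ROITimeSeries(matrix(1:6 / 7, 3, 2), 1.8, c("A", "B")), f)
#' readROIMatrix(f)
#' @export
readROIMatrix <- function(path, tr = 1.8, provenance = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  labels <- colnames(dt)
  if (anyDuplicated(labels))
    stop("duplicate region labels in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, nrow(dt), ncol(dt))
  for (j in seq_along(dt)) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(is.na(v) & !is.na(dt[[j]]))
    if (length(bad) || anyNA(dt[[j]]))
      stop(sprintf(
        "non-numeric or missing cell at row %d, column '%s'",
        if (length(bad)) bad[1] else which(is.na(dt[[j]]))[1], labels[j]),
        call. = FALSE)
    m[, j] <- v
  }
  ROITimeSeries(m, tr = tr, regionLabels = labels, provenance = provenance)
}

#' @rdname readROIMatrix
#' @param x a \linkS4class{ROITimeSeries}.
#' @export
writeROIMatrix <- function(x, path) {
  stopifnot(is(x, "ROITimeSeries"))
  m <- boldValues(x)
  txt <- apply(m, 1L, function(r) paste(formatNum(r), collapse = "\t"))
  writeLines(c(paste(regionLabels(x), collapse = "\t"), txt), path)
  invisible(path)
}
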