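#' Accessors for DartSet and AdmixtureFit
#'
#' `bandCalls()` returns the call matrix in the analysis orientation
#' (genotypes in rows, markers in columns; `NA` = missing).
#' `intensityMatrix()` returns the paired hybridization-level matrix in the
#' same orientation, or `NULL` if none was supplied. `genotypeIds()` and
#' `markerIds()` return the identifier vectors. `admixQ()` / `admixP()` /
#' `lnPD()` extract the posterior summaries of an [AdmixtureFit-class].
#'
#' @param x a [DartSet-class] (or, for `bandCalls`, a plain
#'   genotypes-by-markers matrix, returned as-is after validation) or an
#'   [AdmixtureFit-class].
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bandCalls", function(x) standardGeneric("bandCalls"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("admixQ", function(x) standardGeneric("admixQ"))
#' @rdname accessors
#' @export
setGeneric("admixP", function(x) standardGeneric("admixP"))
#' @rdname accessors
#' @export
setGeneric("lnPD", function(x) standardGeneric("lnPD"))

#' @rdname accessors
#' @export
setMethod("bandCalls", "DartSet", function(x) t(assay(x, "calls")))

#' @rdname accessors
#' @export
setMethod("bandCalls", "matrix", function(x) {
  bad <- !(x %in% c(0, 1) | is.na(x))
  if (any(bad)) stop("call matrix must contain only 0, 1 or NA")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("m", seq_len(ncol(x)))
  storage.mode(x) <- "integer"
  x
})

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "DartSet", function(x) {
  if (!"intensity" %in% assayNames(x)) return(NULL)
  t(assay(x, "intensity"))
})

#' @rdname accessors
#' @export
setMethod("genotypeIds", "DartSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("markerIds", "DartSet", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("admixQ", "AdmixtureFit", function(x) x@Q)

#' @rdname accessors
#' @export
setMethod("admixP", "AdmixtureFit", function(x) x@P)

#' @rdname accessors
#' @export
setMethod("lnPD", "AdmixtureFit", function(x) x@lnPD)

#' Per-marker missing rates
#'
#' @param x a [DartSet-class]
#' @return named numeric vector, fraction of missing calls per marker.
#' @export
missingRates <- function(x) {
  stopifnot(is(x, "DartSet"))
  setNames(rowData(x)$missingRate, rownames(x))
}
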