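#' DartSet: a container for dominant marker calls
#'
#' `DartSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' ternary dominant-marker call matrix (band present = 1, absent = 0,
#' missing = `NA`) together with an optional hybridization-intensity assay of
#' the same shape. Following Bioconductor convention markers are rows and
#' genotypes are columns; the analysis-facing accessor [bandCalls()] returns
#' the transposed genotypes-by-markers orientation used by every statistical
#' function in the package.
#'
#' Per-marker missing rates are computed at construction and stored in
#' `rowData(x)$missingRate`; markers whose missing fraction exceeds the cap
#' (default 0.28) are flagged in `rowData(x)$flaggedMissing` and reported
#' with a warning.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("DartSet", contains = "SummarizedExperiment")

setValidity("DartSet", function(object) {
  msg <- character()
  if (!"calls" %in% assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cl <- assay(object, "calls")
    bad <- !(cl %in% c(0L, 1L) | is.na(cl))
    if (any(bad))
      msg <- c(msg, "calls must be 0, 1 or NA (missing)")
  }
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "marker ids must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "genotype ids must be present and unique")
  if ("intensity" %in% assayNames(object)) {
    it <- assay(object, "intensity")
    cl <- assay(object, "calls")
    if (any(!is.finite(it[!is.na(cl)])))
      msg <- c(msg, "intensity must be finite wherever the call is non-missing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DartSet from a genotypes-by-markers call matrix
#'
#' @param calls integer/numeric matrix, genotypes in rows, markers in
#'   columns; values 0 (band absent), 1 (band present) or `NA` (missing).
#'   Row and column names are required and must be unique.
#' @param intensity optional numeric matrix of hybridization levels with the
#'   same shape and dimnames as `calls`.
#' @param origin optional character/factor of genotype origins (length
#'   `nrow(calls)`), stored in `colData`.
#' @param missingCap per-marker missing-fraction cap; markers above it are
#'   flagged with a warning (and dropped if `dropOverCap = TRUE`).
#' @param dropOverCap drop flagged markers instead of only flagging them.
#' @return a validated [DartSet-class] object.
#' @examples
#' calls <- matrix(c(1, 0, NA, 1, 0, 0), nrow = 3,
#'                 dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
#' DartSet(calls)
#' @export
DartSet <- function(calls, intensity = NULL, origin = NULL,
                    missingCap = 0.28, dropOverCap = FALSE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must carry genotype rownames and marker colnames")
  mode(calls) <- "integer"
  assays <- list(calls = t(calls))
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    if (!identical(dim(intensity), dim(calls)))
      stop("intensity must match the shape of calls")
    if (!is.null(rownames(intensity)) &&
        !identical(rownames(intensity), rownames(calls)))
      stop("intensity genotype ids disagree with calls")
    dimnames(intensity) <- dimnames(calls)
    assays$intensity <- t(intensity)
  }
  cd <- DataFrame(row.names = rownames(calls))
  if (!is.null(origin)) {
    if (length(origin) != nrow(calls))
      stop("origin must have one entry per genotype")
    cd$origin <- as.character(origin)
  }
  miss <- colMeans(is.na(calls))
  rd <- DataFrame(missingRate = miss,
                  flaggedMissing = miss > missingCap,
                  row.names = colnames(calls))
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
  x <- new("DartSet", se)
  metadata(x)$missingCap <- missingCap
  nflag <- sum(rd$flaggedMissing)
  if (nflag > 0) {
    warning(sprintf("%d marker(s) exceed the missing-fraction cap of %g: %s",
                    nflag, missingCap,
                    paste(head(rownames(rd)[rd$flaggedMissing], 5),
                          collapse = ", ")))
    if (dropOverCap) x <- x[!rd$flaggedMissing, ]
  }
  validObject(x)
  x
}

#' AdmixtureFit: posterior summaries of the Bayesian admixture model
#'
#' Holds the posterior-mean admixture proportions `Q` (genotypes x K), the
#' posterior-mean cluster band frequencies `P` (K x markers), the per-sweep
#' observed-data log-likelihood trace and the `lnPD` model-comparison
#' estimate (mean minus half variance of the trace), plus the MCMC settings.
#'
#' @slot K integer, number of clusters.
#' @slot Q numeric matrix, genotypes x K, rows sum to one.
#' @slot P numeric matrix, K x markers, entries in (0, 1).
#' @slot lnPD numeric, estimated log probability of the data.
#' @slot logLik numeric vector, per-sweep log-likelihood after burn-in.
#' @slot settings list of sampler settings (burnIn, reps, alpha, prior, seed).
#' @export
setClass("AdmixtureFit",
         representation(K = "integer", Q = "matrix", P = "matrix",
                        lnPD = "numeric", logLik = "numeric",
                        settings = "list"))

setValidity("AdmixtureFit", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K) msg <- c(msg, "Q must have K columns")
  if (nrow(object@P) != object@K) msg <- c(msg, "P must have K rows")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "Q rows must sum to 1")
  if (any(object@P <= 0 | object@P >= 1))
    msg <- c(msg, "P entries must lie in (0, 1)")
  if (!is.finite(object@lnPD)) msg <- c(msg, "lnPD must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn DartSet-class compact display
#' @param object a `DartSet`
#' @export
setMethod("show", "DartSet", function(object) {
  cat("DartSet:", ncol(object), "genotypes x", nrow(object), "markers\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  mr <- rowData(object)$missingRate
  cat(sprintf("  per-marker missing rate: %.3f-%.3f (%d flagged > cap %.2f)\n",
              min(mr), max(mr), sum(rowData(object)$flaggedMissing),
              metadata(object)$missingCap %||% NA_real_))
})

#' @describeIn AdmixtureFit-class compact display
#' @param object an `AdmixtureFit`
#' @export
setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf("AdmixtureFit: K = %d, %d genotypes x %d markers\n",
              object@K, nrow(object@Q), ncol(object@P)))
  cat(sprintf("  lnP(D) = %.2f  (burn-in %d, %d retained sweeps)\n",
              object@lnPD, object@settings$burnIn, object@settings$reps))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
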