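#' Jaccard similarity between genotype band profiles
#'
#' For every genotype pair, markers where either call is missing are
#' excluded; with `n11`, `n10`, `n01` the counts of the remaining
#' present/present, present/absent and absent/present states,
#' `s = n11 / (n11 + n10 + n01)`. Joint absences (`n00`) count in neither
#' numerator nor denominator. Pairs whose denominator is zero (identical
#' all-absent observed profiles) are an error by default; with
#' `zeroDenominator = "one"` such pairs are treated as identical
#' (`s = 1`), the coherent empty-profile limit.
#'
#' @param x a [DartSet-class] or genotypes-by-markers call matrix.
#' @param zeroDenominator `"error"` (default) or `"one"`.
#' @return list of class `SimilarityMatrix`: `s` (symmetric, unit
#'   diagonal), `nEffective` (markers used per pair, i.e. non-missing in
#'   both).
#' @export
jaccardSimilarity <- function(x, zeroDenominator = c("error", "one")) {
  zeroDenominator <- match.arg(zeroDenominator)
  X <- bandCalls(x)
  P <- (!is.na(X)) * (X == 1); P[is.na(P)] <- 0   # present indicator
  A <- (!is.na(X)) * (X == 0); A[is.na(A)] <- 0   # absent indicator
  n11 <- P %*% t(P)
  n10 <- P %*% t(A)
  n01 <- A %*% t(P)
  nEff <- (P + A) %*% t(P + A)
  den <- n11 + n10 + n01
  if (any(den[upper.tri(den)] == 0)) {
    if (zeroDenominator == "error") {
      idx <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("Jaccard similarity undefined for pair '%s'/'%s'",
                          " (no marker with a band present in either)"),
                   rownames(X)[idx[1]], rownames(X)[idx[2]]))
    }
    den[den == 0] <- 1
    n11[n11 == 0 & n10 + n01 == 0] <- 1   # identical empty profiles: s = 1
  }
  s <- n11 / den
  diag(s) <- 1
  dimnames(s) <- dimnames(nEff) <- list(rownames(X), rownames(X))
  structure(list(s = s, nEffective = nEff), class = "SimilarityMatrix")
}

#' Similarity-to-distance transform
#'
#' `d = 1 - s` elementwise, the transform applied before AMOVA, PCoA and
#' neighbour-joining. An involution: applying it twice returns the input.
#'
#' @param s a `SimilarityMatrix` (from [jaccardSimilarity()]) or a plain
#'   symmetric similarity matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceTransform <- function(s) {
  if (inherits(s, "SimilarityMatrix")) s <- s$s
  d <- 1 - as.matrix(s)
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double-centre `-d^2/2`, eigendecompose, and
#' scale eigenvectors by the square root of each positive eigenvalue
#' (computed via [stats::cmdscale()]). Negative eigenvalues are reported
#' but never used for coordinates; no Cailliez/Lingoes correction is
#' applied. Per-axis explained variance is relative to the sum of the
#' positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param tol eigenvalues below `tol` are treated as non-positive.
#' @return list of class `PcoaResult`: `coordinates` (n x nPositive,
#'   column-centred), `eigenvalues` (all, descending), `proportion`
#'   (per positive axis), `nPositive`.
#' @export
pcoa <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("d must be a symmetric square matrix")
  if (max(abs(diag(d))) > 1e-8) stop("d must have a zero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- which(ev > tol)
  if (length(pos) == 0) stop("degenerate input: no positive eigenvalues")
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  coords <- sweep(coords, 2, colMeans(coords))  # enforce exact centring
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion = ev[pos] / sum(ev[pos]),
                 nPositive = length(pos)),
            class = "PcoaResult")
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining via [ape::nj()], consistent on additive
#' metrics. Negative branch lengths (possible on non-additive input) are
#' clamped to zero with a message unless `clampNegative = FALSE`.
#'
#' @param d symmetric distance matrix (n >= 2) with ids.
#' @param clampNegative clamp negative branch lengths to 0.
#' @return an [ape::phylo] tree whose leaf set equals the input ids.
#' @export
njTree <- function(d, clampNegative = TRUE) {
  d <- as.matrix(d)
  if (any(is.na(d))) stop("NaN/NA distances are not allowed")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  if (clampNegative && any(tr$edge.length < 0)) {
    message(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
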