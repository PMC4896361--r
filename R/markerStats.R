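#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2)` for a vector of allele frequencies. For a
#' dominant biallelic locus the vector is `(p, 1 - p)` with `p` the band
#' present frequency, giving a maximum of 0.5 at `p = 0.5`.
#'
#' @param p numeric vector of allele frequencies: non-negative, summing to
#'   one within 1e-9.
#' @return the PIC value.
#' @examples
#' pic(c(0.25, 0.75))   # 0.375
#' pic(1)               # monomorphic: 0
#' @export
pic <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must be non-negative and sum to 1")
  1 - sum(p^2)
}

#' Per-marker informativeness and quality summaries
#'
#' For each marker: present frequency `p` over non-missing calls, dominant
#' PIC `1 - p^2 - (1-p)^2`, missing count, and (when intensities are
#' available) the quality parameter `Q`: the between-cluster variance of
#' the hybridization level (clusters = present vs absent calls) divided by
#' the total variance, using population (1/n) variances so the ratio is
#' the exact one-way ANOVA R-squared. `Q` is `NA` when no intensity is
#' supplied, a call cluster is empty, or the total intensity variance is
#' zero. All-missing markers are excluded with a warning.
#'
#' PIC is applied directly to the band-present frequency of the dominant
#' score; no dominant-to-allelic correction (such as a sqrt-based allele
#' frequency estimate) is attempted.
#'
#' @param x a [DartSet-class] (the intensity assay is used if present) or a
#'   genotypes-by-markers call matrix.
#' @param intensity optional genotypes-by-markers intensity matrix,
#'   overriding the assay.
#' @return a `data.frame` (one row per retained marker) with columns
#'   `markerId`, `presentFreq`, `pic`, `qQuality`, `nMissing`, `nCalls`;
#'   the PIC histogram (bins `[0,0.1)`, `[0.1,0.2)`, `[0.2,0.3)`,
#'   `[0.3,0.5]`) is attached as `attr(, "picHistogram")`.
#' @export
markerSummaries <- function(x, intensity = NULL) {
  X <- bandCalls(x)
  if (is.null(intensity) && is(x, "DartSet")) intensity <- intensityMatrix(x)
  nPresent <- colSums(X == 1, na.rm = TRUE)
  nAbsent <- colSums(X == 0, na.rm = TRUE)
  nMissing <- colSums(is.na(X))
  nCalls <- nPresent + nAbsent
  drop <- nCalls < 2
  if (any(drop))
    warning(sum(drop), " marker(s) with fewer than 2 non-missing calls ",
            "excluded: ", paste(head(colnames(X)[drop], 5), collapse = ", "))
  keep <- which(!drop)
  p <- nPresent[keep] / nCalls[keep]
  picv <- 1 - p^2 - (1 - p)^2
  qv <- rep(NA_real_, length(keep))
  if (!is.null(intensity)) {
    for (j in seq_along(keep)) {
      col <- keep[j]
      obs <- !is.na(X[, col])
      y <- intensity[obs, col]
      g <- X[obs, col]
      n1 <- sum(g == 1); n0 <- sum(g == 0); n <- n1 + n0
      if (n1 == 0 || n0 == 0) next          # empty cluster: Q undefined
      tot <- mean((y - mean(y))^2)          # population variance
      if (tot <= 0) next                    # zero variance: Q undefined
      m1 <- mean(y[g == 1]); m0 <- mean(y[g == 0]); m <- mean(y)
      between <- (n1 * (m1 - m)^2 + n0 * (m0 - m)^2) / n
      qv[j] <- between / tot
    }
  }
  out <- data.frame(markerId = colnames(X)[keep], presentFreq = p,
                    pic = picv, qQuality = qv, nMissing = nMissing[keep],
                    nCalls = nCalls[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  breaks <- c(0, 0.1, 0.2, 0.3, 0.5)
  h <- table(cut(out$pic, breaks = breaks, right = FALSE,
                 include.lowest = TRUE,
                 labels = c("0.0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.5")))
  attr(out, "picHistogram") <- as.data.frame(h,
                                             responseName = "nMarkers",
                                             stringsAsFactors = FALSE)
  out
}
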