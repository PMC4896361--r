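normalisePops <- function(pops, ids) {
  if (is.factor(pops)) pops <- setNames(as.integer(pops), names(pops))
  if (!is.null(names(pops)) && !is.null(ids)) {
    if (!all(ids %in% names(pops)))
      stop("population assignment is missing some genotype ids")
    pops <- pops[ids]
  }
  pops <- as.integer(factor(pops))
  if (any(table(pops) == 0)) stop("every population label must be non-empty")
  pops
}

amovaComponents <- function(d2, pops) {
  n <- nrow(d2)
  G <- length(unique(pops))
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssWithin <- 0
  sizes <- tabulate(pops)
  for (g in seq_len(G)) {
    idx <- which(pops == g)
    if (length(idx) > 1)
      ssWithin <- ssWithin + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) /
        length(idx)
  }
  ssAmong <- ssTotal - ssWithin
  dfAmong <- G - 1
  dfWithin <- n - G
  msAmong <- ssAmong / dfAmong
  msWithin <- ssWithin / dfWithin
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  Vb <- msWithin
  Va <- (msAmong - msWithin) / n0
  list(ssAmong = ssAmong, ssWithin = ssWithin, ssTotal = ssTotal,
       dfAmong = dfAmong, dfWithin = dfWithin, Va = Va, Vb = Vb, n0 = n0)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Single-level AMOVA on a genotype distance matrix (typically the Jaccard
#' distance `d = 1 - s`). Sums of squares follow the Excoffier squared
#' distance formulation: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_among` the
#' difference; `Vb = MS_within`, `Va = (MS_among - MS_within)/n0` with
#' `n0 = (n - sum n_g^2 / n)/(G - 1)`. The among-population p-value is the
#' proportion of label permutations whose `Va` reaches the observed one,
#' with the `(b + 1)/(m + 1)` correction.
#'
#' @param d symmetric distance matrix with genotype ids.
#' @param pops population assignment: named integer/factor vector (matched
#'   to `rownames(d)` by name when named).
#' @param nPerm number of label permutations (warns below 99).
#' @param seed optional seed for the permutations.
#' @return list of class `AmovaResult`: `dfAmong`, `dfWithin`, `Va`, `Vb`,
#'   `percentAmong`, `percentWithin`, `totalVariance`, `phiST`
#'   (`Va/(Va+Vb)`, raw), `pAmong`, plus the sums of squares.
#' @export
amova <- function(d, pops, nPerm = 999L, seed = NULL) {
  d <- as.matrix(d)
  pops <- normalisePops(pops, rownames(d))
  G <- length(unique(pops))
  if (G < 2) stop("need at least 2 populations")
  sizes <- tabulate(pops)
  if (any(sizes < 2))
    warning("population(s) of size < 2: within-population degrees of ",
            "freedom are degenerate for them")
  if (nPerm < 99) warning("nPerm < 99 gives a coarse permutation p-value")
  d2 <- d^2
  obs <- amovaComponents(d2, pops)
  if (!is.null(seed)) set.seed(seed)
  b <- 0L
  for (r in seq_len(nPerm)) {
    Vap <- amovaComponents(d2, sample(pops))$Va
    if (Vap >= obs$Va - 1e-12) b <- b + 1L
  }
  total <- obs$Va + obs$Vb
  structure(list(dfAmong = obs$dfAmong, dfWithin = obs$dfWithin,
                 ssAmong = obs$ssAmong, ssWithin = obs$ssWithin,
                 ssTotal = obs$ssTotal, Va = obs$Va, Vb = obs$Vb,
                 totalVariance = total,
                 percentAmong = 100 * obs$Va / total,
                 percentWithin = 100 * obs$Vb / total,
                 phiST = obs$Va / total,
                 pAmong = (b + 1) / (nPerm + 1), nPerm = nPerm),
            class = "AmovaResult")
}

#' @export
print.AmovaResult <- function(x, ...) {
  cat("AMOVA\n")
  cat(sprintf("  Among populations:  df = %d, Va = %.4g (%.2f%%)\n",
              x$dfAmong, x$Va, x$percentAmong))
  cat(sprintf("  Within populations: df = %d, Vb = %.4g (%.2f%%)\n",
              x$dfWithin, x$Vb, x$percentWithin))
  cat(sprintf("  Phi-ST = %.4f, permutation p = %.4g (%d permutations)\n",
              x$phiST, x$pAmong, x$nPerm))
  invisible(x)
}

#' Pairwise Phi-st between populations
#'
#' For each population pair, AMOVA is run on the union of the two
#' populations and `Phi_st = Va/(Va + Vb)` reported. Zero implies complete
#' panmixia; one implies all variation lies between the populations.
#' Negative raw values are clamped to 0 for reporting (the raw values are
#' returned in `attr(, "raw")`). Per-pair permutation p-values use the
#' `(b + 1)/(m + 1)` estimator.
#'
#' @inheritParams amova
#' @return list of class `PhiStMatrix`: `phiST` (clamped, zero diagonal),
#'   `p` (permutation p-values); raw values as an attribute of `phiST`.
#' @export
pairwisePhiSt <- function(d, pops, nPerm = 999L, seed = NULL) {
  d <- as.matrix(d)
  pops <- normalisePops(pops, rownames(d))
  G <- length(unique(pops))
  if (G < 2) stop("need at least 2 populations")
  phi <- raw <- p <- matrix(NA_real_, G, G,
                            dimnames = list(paste0("Pop", 1:G),
                                            paste0("Pop", 1:G)))
  diag(phi) <- diag(raw) <- 0
  if (!is.null(seed)) set.seed(seed)
  for (a in seq_len(G - 1))
    for (bb in (a + 1):G) {
      idx <- which(pops %in% c(a, bb))
      res <- amova(d[idx, idx], pops[idx], nPerm = nPerm)
      raw[a, bb] <- raw[bb, a] <- res$phiST
      phi[a, bb] <- phi[bb, a] <- max(0, res$phiST)
      p[a, bb] <- p[bb, a] <- res$pAmong
    }
  attr(phi, "raw") <- raw
  structure(list(phiST = phi, p = p), class = "PhiStMatrix")
}

shannonH <- function(X) {
  # X: genotypes x markers for one population; per-locus binary entropy
  p <- colMeans(X, na.rm = TRUE)
  Nl <- colSums(!is.na(X))
  keep <- Nl > 0
  p <- p[keep]; Nl <- Nl[keep]
  ent <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log(q))
  h <- ent(p) + ent(1 - p)
  list(H = sum(h), p = p, Nl = Nl)
}

#' Shannon diversity per population with Bowman and bootstrap variances
#'
#' Per population, `H'` is the sum over loci of the binary entropy of the
#' within-population band frequency (non-missing calls only; `0 log 0 = 0`).
#' The Bowman (Hutcheson large-sample) variance is
#' `sum_l ([p (ln p)^2 + q (ln q)^2] - [p ln p + q ln q]^2)/N_l +
#' 1/(2 N_l^2)`; the bootstrap variance is the variance of `H'` over
#' `nBoot` resamples of genotypes within the population.
#'
#' @param x a [DartSet-class] or call matrix.
#' @param pops population assignment (named vector, matched by id).
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed optional seed for the bootstrap.
#' @return data.frame, one row per population: `population`, `size`, `H`,
#'   `varBowman`, `sdBowman`, `varBootstrap`, `sdBootstrap`.
#' @export
shannonDiversity <- function(x, pops, nBoot = 10000L, seed = NULL) {
  X <- bandCalls(x)
  pops <- normalisePops(pops, rownames(X))
  if (!is.null(seed)) set.seed(seed)
  G <- length(unique(pops))
  out <- vector("list", G)
  for (g in seq_len(G)) {
    Xg <- X[pops == g, , drop = FALSE]
    ng <- nrow(Xg)
    hh <- shannonH(Xg)
    lp <- function(q) ifelse(q <= 0 | q >= 1, 0, log(q))
    p <- hh$p; q <- 1 - hh$p; Nl <- hh$Nl
    vB <- sum((p * lp(p)^2 + q * lp(q)^2 -
                 (p * lp(p) + q * lp(q))^2) / Nl + 1 / (2 * Nl^2))
    vBoot <- NA_real_
    if (ng >= 2 && nBoot > 0) {
      hb <- numeric(nBoot)
      for (r in seq_len(nBoot))
        hb[r] <- shannonH(Xg[sample(ng, ng, replace = TRUE), ,
                             drop = FALSE])$H
      vBoot <- var(hb)
    }
    out[[g]] <- data.frame(population = g, size = ng, H = hh$H,
                           varBowman = vB, sdBowman = sqrt(vB),
                           varBootstrap = vBoot,
                           sdBootstrap = sqrt(vBoot))
  }
  do.call(rbind, out)
}

#' Hutcheson t-test between two Shannon diversity values
#'
#' `t = (H1 - H2)/sqrt(V1 + V2)` with Hutcheson degrees of freedom
#' `(V1 + V2)^2 / (V1^2/N1 + V2^2/N2)`; two-sided p from the t
#' distribution. `method` chooses which variance column of the
#' [shannonDiversity()] rows to use.
#'
#' @param row1,row2 single rows of a [shannonDiversity()] table (or lists
#'   with `H`, the chosen variance, and `size`).
#' @param method `"bootstrap"` or `"bowman"`.
#' @return list: `t`, `df`, `p`.
#' @export
shannonTTest <- function(row1, row2, method = c("bootstrap", "bowman")) {
  method <- match.arg(method)
  vcol <- if (method == "bootstrap") "varBootstrap" else "varBowman"
  V1 <- row1[[vcol]]; V2 <- row2[[vcol]]
  if (!isTRUE(V1 > 0) || !isTRUE(V2 > 0))
    stop("both variances must be positive for the t-test")
  tt <- (row1$H - row2$H) / sqrt(V1 + V2)
  df <- (V1 + V2)^2 / (V1^2 / row1$size + V2^2 / row2$size)
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}
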