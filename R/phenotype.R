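#' Descriptive trait summaries with correlation counts
#'
#' Per trait: mean, median, SD, coefficient of variation (SD/mean) with a
#' flag for CV > 0.5, and the number of other traits with a significant
#' Pearson correlation at `alpha` (pairwise-complete observations; p from
#' the exact t transform of r with the pairwise n). Zero-variance traits
#' get `NA` correlation counts with a warning.
#'
#' @param traits genotypes x traits numeric matrix.
#' @param alpha significance level for the correlation count.
#' @return data.frame: `trait`, `mean`, `median`, `sd`, `cv`, `cvHigh`,
#'   `nCorrelated`; the full correlation and p matrices are attached as
#'   attributes `r` and `pR`.
#' @export
traitSummaries <- function(traits, alpha = 0.05) {
  traits <- as.matrix(traits)
  nt <- ncol(traits)
  nObs <- colSums(!is.na(traits))
  if (any(nObs < 3))
    stop("trait(s) with fewer than 3 non-missing values: ",
         paste(colnames(traits)[nObs < 3], collapse = ", "))
  mns <- colMeans(traits, na.rm = TRUE)
  sds <- apply(traits, 2, sd, na.rm = TRUE)
  zeroVar <- sds == 0
  if (any(zeroVar))
    warning("zero-variance trait(s) excluded from correlation counts: ",
            paste(colnames(traits)[zeroVar], collapse = ", "))
  r <- suppressWarnings(cor(traits, use = "pairwise.complete.obs"))
  pR <- matrix(NA_real_, nt, nt, dimnames = dimnames(r))
  for (a in seq_len(nt))
    for (b in seq_len(nt)) {
      if (a == b || zeroVar[a] || zeroVar[b]) next
      nab <- sum(!is.na(traits[, a]) & !is.na(traits[, b]))
      if (nab < 3) next
      rr <- min(max(r[a, b], -1), 1)
      if (abs(rr) >= 1) { pR[a, b] <- 0; next }
      tstat <- rr * sqrt((nab - 2) / (1 - rr^2))
      pR[a, b] <- 2 * pt(-abs(tstat), nab - 2)
    }
  nCorr <- vapply(seq_len(nt), function(a) {
    if (zeroVar[a]) return(NA_integer_)
    sum(pR[a, ] <= alpha, na.rm = TRUE)
  }, integer(1))
  out <- data.frame(trait = colnames(traits), mean = mns,
                    median = apply(traits, 2, median, na.rm = TRUE),
                    sd = sds, cv = sds / mns, cvHigh = abs(sds / mns) > 0.5,
                    nCorrelated = nCorr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "r") <- r
  attr(out, "pR") <- pR
  out
}

#' Varimax-rotated principal component analysis of traits
#'
#' PCA of the trait correlation matrix (traits standardised implicitly).
#' Components with eigenvalue strictly greater than 1 are retained
#' (Kaiser rule), their loadings (`eigenvector * sqrt(eigenvalue)`) are
#' varimax-rotated with Kaiser row normalization — closed-form planar
#' rotations swept over column pairs until the criterion change drops
#' below `tol` — and each trait is assigned to the component with the
#' largest absolute rotated loading. With fewer than 2 components
#' retained the rotation is the identity.
#'
#' @param traits genotypes x traits matrix (>= 2 traits with variance).
#' @param maxIter,tol varimax sweep limit and criterion tolerance;
#'   non-convergence returns the current rotation with a warning.
#' @return list of class `RotatedPca`: `eigenvalues` (all), `nRetained`,
#'   `loadings` (unrotated, traits x retained), `rotatedLoadings`,
#'   `rotation` (orthonormal), `explained` and `cumulative` variance
#'   proportions per rotated component, `assignment` (trait ->
#'   component index).
#' @export
rotatedPca <- function(traits, maxIter = 100L, tol = 1e-6) {
  traits <- as.matrix(traits)
  sds <- apply(traits, 2, sd, na.rm = TRUE)
  if (sum(sds > 0, na.rm = TRUE) < 2)
    stop("need at least 2 traits with variance")
  R <- cor(traits, use = "pairwise.complete.obs")
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  nt <- ncol(traits)
  retain <- which(ev > 1)
  if (length(retain) == 0) {
    warning("no eigenvalue exceeds 1; no components retained")
    return(structure(list(eigenvalues = ev, nRetained = 0L,
                          loadings = matrix(0, nt, 0),
                          rotatedLoadings = matrix(0, nt, 0),
                          rotation = matrix(0, 0, 0),
                          explained = numeric(0), cumulative = numeric(0),
                          assignment = rep(NA_integer_, nt)),
                     class = "RotatedPca"))
  }
  m <- length(retain)
  load <- eg$vectors[, retain, drop = FALSE] %*% diag(sqrt(ev[retain]), m)
  dimnames(load) <- list(colnames(traits), paste0("PC", seq_len(m)))
  if (m >= 2) {
    vm <- kaiserVarimax(load, tol = tol, maxIter = maxIter)
    rot <- vm$loadings
    rotation <- vm$rotmat
  } else {
    rot <- load
    rotation <- diag(1)
  }
  dimnames(rot) <- dimnames(load)
  expl <- colSums(rot^2) / nt
  assign <- apply(abs(rot), 1, which.max)
  structure(list(eigenvalues = ev, nRetained = m, loadings = load,
                 rotatedLoadings = rot, rotation = rotation,
                 explained = expl, cumulative = cumsum(expl),
                 assignment = setNames(as.integer(assign),
                                       colnames(traits))),
            class = "RotatedPca")
}

# Kaiser's varimax: row-normalise the loadings, then sweep closed-form
# planar rotations over column pairs until the criterion stops improving.
kaiserVarimax <- function(L, tol = 1e-8, maxIter = 100L) {
  p <- nrow(L); m <- ncol(L)
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  Z <- L / h
  R <- diag(m)
  crit <- function(z) sum(z^4) - sum(colSums(z^2)^2) / p
  prev <- crit(Z)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    for (a in seq_len(m - 1))
      for (b in (a + 1):m) {
        x <- Z[, a]; y <- Z[, b]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        num <- 2 * (sum(u * v) - A * B / p)
        den <- sum(u^2 - v^2) - (A^2 - B^2) / p
        if (num == 0 && den == 0) next
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-13) next
        cs <- cos(phi); sn <- sin(phi)
        Z[, a] <- x * cs + y * sn
        Z[, b] <- -x * sn + y * cs
        ra <- R[, a]
        R[, a] <- ra * cs + R[, b] * sn
        R[, b] <- -ra * sn + R[, b] * cs
      }
    cur <- crit(Z)
    if (cur - prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  if (!converged)
    warning("varimax rotation did not converge in ", maxIter,
            " sweeps; returning the current rotation")
  out <- Z * h
  dimnames(out) <- dimnames(L)
  list(loadings = out, rotmat = R)
}

#' Agglomerative clustering of genotypes on trait profiles
#'
#' Traits are standardised per column; genotype-pair similarity is the
#' Pearson correlation between standardised trait vectors; clustering is
#' UPGMA (unweighted average linkage) on `d = 1 - r`. Groups are read off
#' by cutting the dendrogram at each similarity level (cut height
#' `1 - level`), so groups at a higher similarity level always refine
#' groups at a lower one. Genotypes with fewer than 3 non-missing traits
#' are excluded with a message.
#'
#' @param traits genotypes x traits numeric matrix (>= 2 genotypes).
#' @param cutLevels similarity levels to cut at (default `c(0.75, 0.9)`).
#' @return list of class `GenotypeGrouping`: `dendrogram` (an `hclust`),
#'   `similarity` matrix, and `groups` — a named list (one element per cut
#'   level) of integer membership vectors.
#' @export
genotypeClusters <- function(traits, cutLevels = c(0.75, 0.9)) {
  traits <- as.matrix(traits)
  if (nrow(traits) < 2) stop("need at least 2 genotypes")
  ok <- rowSums(!is.na(traits)) >= 3
  if (any(!ok))
    message("excluding ", sum(!ok), " genotype(s) with fewer than 3 ",
            "non-missing traits")
  traits <- traits[ok, , drop = FALSE]
  Z <- scale(traits)
  r <- suppressWarnings(cor(t(Z), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  groups <- lapply(cutLevels, function(lv)
    cutree(hc, h = 1 - lv))
  names(groups) <- paste0("sim", cutLevels)
  structure(list(dendrogram = hc, similarity = r, groups = groups),
            class = "GenotypeGrouping")
}
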