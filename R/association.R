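#' Marker-based relative kinship
#'
#' `S_ij` is the identity-by-state proportion over mutually non-missing
#' markers; relative kinship adjusts it by the average off-diagonal
#' similarity between random individuals:
#' `K_r(i, j) = max(0, (S_ij - Sbar)/(1 - Sbar))`, diagonal set to 1.
#'
#' @param x a [DartSet-class] or call matrix.
#' @return symmetric kinship matrix with unit diagonal, entries in [0, 1].
#' @export
kinship <- function(x) {
  X <- bandCalls(x)
  P <- (!is.na(X)) * (X == 1); P[is.na(P)] <- 0
  A <- (!is.na(X)) * (X == 0); A[is.na(A)] <- 0
  same <- P %*% t(P) + A %*% t(A)
  nEff <- (P + A) %*% t(P + A)
  if (any(nEff[upper.tri(nEff)] == 0))
    stop("some genotype pairs share no non-missing marker")
  S <- same / nEff
  sBar <- mean(S[upper.tri(S)])
  if (sBar >= 1) stop("all genotypes are identical in state; kinship undefined")
  Kr <- (S - sBar) / (1 - sBar)
  Kr[Kr < 0] <- 0
  diag(Kr) <- 1
  dimnames(Kr) <- list(rownames(X), rownames(X))
  Kr
}

# REML profile log-likelihood machinery (EMMA-style). Kr is eigendecomposed
# once; for the variance ratio lambda = sigma_g^2 / sigma_e^2 the rotated
# model has independent errors with weights w_i = lambda d_i + 1.
remlFit <- function(y, X, U, dvals) {
  n <- length(y)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p <- qr(Xs)$rank
  profile <- function(logLambda) {
    w <- exp(logLambda) * dvals + 1
    sw <- 1 / sqrt(w)
    fit <- lm.fit(Xs * sw, ys * sw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    xtvx <- crossprod(Xs * sw)
    xtx <- crossprod(Xs)
    -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(w)) +
              determinant(xtvx, logarithm = TRUE)$modulus -
              determinant(xtx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(profile, interval = c(-12, 12), maximum = TRUE)
  lambda <- exp(opt$maximum)
  # boundary handling: treat extreme optima as the pure-OLS / pure-genetic
  # limits rather than interior estimates
  if (opt$maximum <= -11.9) lambda <- 0
  w <- lambda * dvals + 1
  sw <- 1 / sqrt(w)
  fit <- lm.fit(Xs * sw, ys * sw)
  rss <- sum(fit$residuals^2)
  s2e <- rss / (n - p)
  list(lambda = lambda, sigma2e = s2e, sigma2g = lambda * s2e,
       reml = as.numeric(profile(log(max(lambda, 1e-12)))),
       ys = ys, Xs = Xs, sw = sw, p = p)
}

#' Mixed-linear-model trait-marker association scan (Q + K)
#'
#' Per trait, the null model is `y = X beta + u + e` with fixed effects
#' `X = [1, Q_(1..K-1)]` (the last admixture column is dropped to avoid
#' collinearity with the intercept), `u ~ N(0, sigma_g^2 K_r)` and
#' `e ~ N(0, sigma_e^2 I)`. Variance components are estimated once per
#' trait by REML through a single spectral decomposition of `K_r`
#' (the P3D approximation) and reused for every marker; each marker enters
#' as a 0/1 fixed covariate (missing calls mean-imputed per marker, for the
#' association design only) and is tested with a GLS F-test. `markerR2` is
#' the incremental explained proportion `(RSS0 - RSS1)/TSS` on the
#' whitened scale. Monomorphic markers (after alignment) are skipped.
#'
#' @param traits genotypes x traits numeric matrix (missing allowed; each
#'   trait needs >= 3 non-missing values).
#' @param markers a [DartSet-class] or call matrix.
#' @param Q admixture proportion matrix (n x K) or `NULL` for no structure
#'   covariates.
#' @param Kr kinship matrix from [kinship()]; `NULL` means the identity
#'   (no polygenic term), in which case the scan reduces exactly to OLS.
#' @return data.frame, one row per trait x tested marker: `trait`,
#'   `marker`, `F`, `p`, `errorDf`, `markerR2`, `geneticVariance`,
#'   `residualVariance`, `neg2lnLik`.
#' @export
mlmScan <- function(traits, markers, Q = NULL, Kr = NULL) {
  X <- bandCalls(markers)
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) rownames(traits) <- rownames(X)
  ids <- intersect(rownames(X), rownames(traits))
  if (length(ids) < 4) stop("too few genotypes shared by traits and markers")
  X <- X[ids, , drop = FALSE]
  traits <- traits[ids, , drop = FALSE]
  n <- length(ids)
  if (is.null(Kr)) {
    Kr <- diag(n); dimnames(Kr) <- list(ids, ids)
  } else Kr <- as.matrix(Kr)[ids, ids]
  covar <- NULL
  if (!is.null(Q)) {
    Q <- as.matrix(Q)[ids, , drop = FALSE]
    if (ncol(Q) > 1) covar <- Q[, -ncol(Q), drop = FALSE]
  }
  eg <- eigen(Kr, symmetric = TRUE)
  if (any(eg$values < -1e-8))
    warning("kinship not positive semi-definite; negative eigenvalues ",
            "clipped at 0")
  dvals <- pmax(eg$values, 0)
  U <- eg$vectors
  out <- list()
  for (tr in colnames(traits) %||% seq_len(ncol(traits))) {
    y <- traits[, tr]
    obs <- which(!is.na(y))
    if (length(obs) < 3)
      stop("trait '", tr, "' has fewer than 3 non-missing values")
    if (length(obs) < n) {
      egs <- eigen(Kr[obs, obs], symmetric = TRUE)
      Us <- egs$vectors; ds <- pmax(egs$values, 0)
    } else { Us <- U; ds <- dvals }
    X0 <- cbind(`(Intercept)` = rep(1, length(obs)),
                if (!is.null(covar)) covar[obs, , drop = FALSE])
    null <- remlFit(y[obs], X0, Us, ds)
    sw <- null$sw
    y0 <- null$ys * sw
    X0s <- null$Xs * sw
    fit0 <- lm.fit(X0s, y0)
    rss0 <- sum(fit0$residuals^2)
    one <- crossprod(Us, rep(1, length(obs))) * sw
    mu <- lm.fit(one, y0)
    tss <- sum(mu$residuals^2)
    neg2ll <- -2 * null$reml
    for (m in colnames(X)) {
      g <- X[obs, m]
      gm <- mean(g, na.rm = TRUE)
      if (is.nan(gm) || all(g == g[!is.na(g)][1], na.rm = TRUE)) next
      g[is.na(g)] <- gm
      gs <- crossprod(Us, g) * sw
      X1s <- cbind(X0s, marker = gs)
      fit1 <- lm.fit(X1s, y0)
      r1 <- fit1$rank
      if (r1 <= ncol(X0s)) next                     # collinear marker
      rss1 <- sum(fit1$residuals^2)
      df2 <- length(obs) - r1
      Fm <- ((rss0 - rss1) / 1) / (rss1 / df2)
      out[[length(out) + 1]] <- data.frame(
        trait = tr, marker = m, F = Fm, p = pf(Fm, 1, df2, lower.tail = FALSE),
        errorDf = df2, markerR2 = (rss0 - rss1) / tss,
        geneticVariance = null$sigma2g, residualVariance = null$sigma2e,
        neg2lnLik = neg2ll, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Permutation-corrected fixed-effects association scan (GLM / SA)
#'
#' Fixed-effects model `y ~ intercept + covariates + marker` by least
#' squares with a marker F-test. The experiment-wise adjusted p-value per
#' marker is the proportion of permutations (trait values permuted across
#' genotypes, covariates fixed) in which the max-over-markers F reaches the
#' marker's observed F, with the `(b + 1)/(m + 1)` correction. The `"glm"`
#' variant uses continuous admixture columns as covariates; the `"sa"`
#' (structured association) variant uses hard population membership as a
#' categorical covariate.
#'
#' @inheritParams mlmScan
#' @param covariates a Q matrix (`"glm"`) or a population assignment
#'   vector/factor (`"sa"`); `NULL` for an intercept-only model.
#' @param nPerm number of permutations (warns below 100).
#' @param seed optional permutation seed.
#' @return data.frame per trait x marker: `trait`, `marker`, `F`, `pRaw`,
#'   `pAdj`.
#' @export
glmPermScan <- function(traits, markers, covariates = NULL, nPerm = 1000L,
                        seed = NULL) {
  X <- bandCalls(markers)
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) rownames(traits) <- rownames(X)
  ids <- intersect(rownames(X), rownames(traits))
  n <- length(ids)
  if (n < 2) stop("need at least 2 genotypes for permutation")
  if (nPerm < 100) warning("nPerm < 100 gives a coarse adjusted p-value")
  X <- X[ids, , drop = FALSE]
  traits <- traits[ids, , drop = FALSE]
  C <- cbind(rep(1, n))
  if (!is.null(covariates)) {
    if (is.matrix(covariates)) {
      Qm <- covariates[ids, , drop = FALSE]
      if (ncol(Qm) > 1) C <- cbind(C, Qm[, -ncol(Qm), drop = FALSE])
    } else {
      pops <- normalisePops(covariates, ids)
      f <- factor(pops)
      if (nlevels(f) > 1)
        C <- cbind(C, stats::model.matrix(~f)[, -1, drop = FALSE])
    }
  }
  qrc <- qr(C)
  pC <- qrc$rank
  # residualise markers on the covariates once (mean-impute missing calls)
  M <- apply(X, 2, function(g) {
    gm <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- if (is.nan(gm)) 0 else gm
    g
  })
  keep <- apply(M, 2, function(g) var(g) > 0)
  M <- M[, keep, drop = FALSE]
  Mres <- qr.resid(qrc, M)
  mss <- colSums(Mres^2)
  ok <- mss > 1e-12
  Mres <- Mres[, ok, drop = FALSE]; mss <- mss[ok]
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tr in colnames(traits) %||% seq_len(ncol(traits))) {
    y <- traits[, tr]
    if (any(is.na(y)))
      stop("permutation scan requires complete trait values (trait '",
           tr, "')")
    fstats <- function(yv) {
      yres <- qr.resid(qrc, yv)
      rss0 <- sum(yres^2)
      bnum <- drop(crossprod(Mres, yres))
      ssm <- bnum^2 / mss
      rss1 <- rss0 - ssm
      df2 <- n - pC - 1
      (ssm / 1) / (rss1 / df2)
    }
    Fobs <- fstats(y)
    exceed <- rep(0L, length(Fobs))
    for (r in seq_len(nPerm)) {
      Fmax <- max(fstats(y[sample(n)]))
      exceed <- exceed + (Fmax >= Fobs - 1e-12)
    }
    df2 <- n - pC - 1
    out[[length(out) + 1]] <- data.frame(
      trait = tr, marker = colnames(Mres),
      F = Fobs, pRaw = pf(Fobs, 1, df2, lower.tail = FALSE),
      pAdj = (exceed + 1) / (nPerm + 1),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rank MLM associations and confirm them against permutation scans
#'
#' Markers with MLM `p <= alpha1` are ranked by p per trait; a marker is
#' `confirmed` when its permutation-adjusted p in the GLM or SA scan is
#' also `<= alpha1`. Per-trait marker counts at both `alpha1` and `alpha2`
#' thresholds are attached as `attr(, "counts")`.
#'
#' @param mlm result of [mlmScan()].
#' @param glm result of [glmPermScan()] with Q covariates (or `NULL`).
#' @param sa result of [glmPermScan()] with population covariates (or
#'   `NULL`).
#' @param alpha1 primary significance threshold (0.05).
#' @param alpha2 stricter threshold for the counts table (0.01).
#' @return data.frame of ranked significant associations with a
#'   `confirmed` flag.
#' @export
rankAndConfirm <- function(mlm, glm = NULL, sa = NULL,
                           alpha1 = 0.05, alpha2 = 0.01) {
  sig <- mlm[mlm$p <= alpha1, , drop = FALSE]
  lookup <- function(scan, trait, marker) {
    if (is.null(scan)) return(NA_real_)
    hit <- scan$pAdj[scan$trait == trait & scan$marker == marker]
    if (length(hit)) hit[1] else NA_real_
  }
  if (nrow(sig)) {
    sig <- sig[order(sig$trait, sig$p), , drop = FALSE]
    sig$rank <- stats::ave(sig$p, sig$trait, FUN = seq_along)
    sig$pGlmPerm <- mapply(lookup, trait = sig$trait, marker = sig$marker,
                           MoreArgs = list(scan = glm))
    sig$pSaPerm <- mapply(lookup, trait = sig$trait, marker = sig$marker,
                          MoreArgs = list(scan = sa))
    sig$confirmed <- (!is.na(sig$pGlmPerm) & sig$pGlmPerm <= alpha1) |
      (!is.na(sig$pSaPerm) & sig$pSaPerm <= alpha1)
  } else {
    sig$rank <- numeric(0); sig$pGlmPerm <- numeric(0)
    sig$pSaPerm <- numeric(0); sig$confirmed <- logical(0)
  }
  counts <- do.call(rbind, lapply(unique(mlm$trait), function(tr) {
    pm <- mlm$p[mlm$trait == tr]
    data.frame(trait = tr, nAlpha1 = sum(pm <= alpha1),
               nAlpha2 = sum(pm <= alpha2), stringsAsFactors = FALSE)
  }))
  rownames(sig) <- NULL
  attr(sig, "counts") <- counts
  sig
}
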