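#' Fit the Bayesian admixture model to dominant band states
#'
#' Band calls are modelled as haploid Bernoulli observations:
#' `X_il | z_il ~ Bernoulli(p[z_il, l])`, `z_il | q_i ~ Categorical(q_i)`,
#' `q_i ~ Dirichlet(alpha 1_K)`, and `p_kl ~ Beta(lambda, lambda)` under the
#' independent-frequency prior. The `"correlated"` prior centres each locus
#' prior on the observed overall band frequency with drift parameter
#' `driftF`: `p_kl ~ Beta(pbar_l (1-F)/F, (1-pbar_l)(1-F)/F)`. A Gibbs
#' sweep updates `z`, `p` and `q` in closed form; missing cells are skipped
#' in every likelihood term. The model-comparison estimate `lnPD` is the
#' mean of the per-sweep observed-data log-likelihood minus half its
#' variance (the estimator the Evanno delta-K method expects). Posterior
#' means are taken after burn-in with within-chain label switching handled
#' by greedy alignment of each sweep's Q columns to the running mean.
#'
#' @param x a [DartSet-class] or genotypes-by-markers call matrix.
#' @param K number of clusters (1 <= K <= n genotypes).
#' @param burnIn burn-in sweeps (default 50000, the full-scale setting).
#' @param reps retained sweeps after burn-in (default 100000).
#' @param alpha Dirichlet concentration for `q`; default `1/K`.
#' @param lambda symmetric Beta prior parameter (independent prior).
#' @param freqPrior `"independent"` (default) or `"correlated"`.
#' @param driftF drift parameter of the correlated prior, in (0, 1).
#' @param alignLabels align sweeps to the running posterior mean before
#'   averaging; disable to study the raw label-symmetric posterior.
#' @param seed optional integer seed (applied via `set.seed`).
#' @return an [AdmixtureFit-class].
#' @export
fitAdmixture <- function(x, K, burnIn = 50000L, reps = 100000L,
                         alpha = NULL, lambda = 1,
                         freqPrior = c("independent", "correlated"),
                         driftF = 0.1, alignLabels = TRUE, seed = NULL) {
  freqPrior <- match.arg(freqPrior)
  X <- bandCalls(x)
  n <- nrow(X); L <- ncol(X)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K = ", K, " exceeds the number of genotypes (", n, ")")
  if (is.null(alpha)) alpha <- 1 / K
  if (freqPrior == "independent") {
    aPrior <- rep(lambda, L); bPrior <- rep(lambda, L)
  } else {
    stopifnot(driftF > 0, driftF < 1)
    pbar <- colMeans(X, na.rm = TRUE)
    pbar[is.nan(pbar)] <- 0.5
    pbar <- pmin(pmax(pbar, 0.01), 0.99)
    aPrior <- pbar * (1 - driftF) / driftF
    bPrior <- (1 - pbar) * (1 - driftF) / driftF
  }
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_admixture_cpp(X, K, as.integer(burnIn), as.integer(reps),
                             alpha, aPrior, bPrior, alignLabels)
  ll <- res$logLik
  lnpd <- mean(ll) - var(ll) / 2
  if (length(ll) < 2 || !is.finite(var(ll))) lnpd <- mean(ll)
  if (!is.finite(lnpd))
    stop("non-finite lnP(D); log-likelihood range: ",
         paste(range(ll), collapse = " .. "))
  Q <- res$Q / rowSums(res$Q)
  P <- pmin(pmax(res$P, 1e-12), 1 - 1e-12)
  dimnames(Q) <- list(rownames(X), paste0("K", seq_len(K)))
  dimnames(P) <- list(paste0("K", seq_len(K)), colnames(X))
  new("AdmixtureFit", K = K, Q = Q, P = P, lnPD = lnpd, logLik = ll,
      settings = list(burnIn = as.integer(burnIn), reps = as.integer(reps),
                      alpha = alpha, lambda = lambda, freqPrior = freqPrior,
                      driftF = driftF, seed = seed))
}

#' Evanno delta-K model selection table
#'
#' From replicate fits across a contiguous K range: per K the mean and SD
#' of `lnPD` across replicates, the successive differences
#' `L'(K) = L(K) - L(K-1)` and `L''(K) = L'(K+1) - L'(K)` of the means, and
#' `deltaK = |L''(K)| / S[L(K)]`. `deltaK` is defined only for interior K
#' with at least two replicates and positive SD; the best K is the argmax
#' over the defined values.
#'
#' @param fits either a list of [AdmixtureFit-class] objects (replicates
#'   over a K range) or a data.frame with columns `K` and `lnPD` (one row
#'   per replicate run).
#' @return data.frame with columns `K`, `nReps`, `meanL`, `sdL`, `L1`,
#'   `L2`, `deltaK`; the selected K is in `attr(, "bestK")`.
#' @export
deltaK <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits))
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(K = f@K, lnPD = f@lnPD)))
  stopifnot(all(c("K", "lnPD") %in% names(fits)))
  ks <- sort(unique(fits$K))
  if (length(ks) >= 2 && any(diff(ks) != 1))
    stop("K range must be contiguous")
  meanL <- tapply(fits$lnPD, factor(fits$K, levels = ks), mean)
  sdL <- tapply(fits$lnPD, factor(fits$K, levels = ks), sd)
  nReps <- tapply(fits$lnPD, factor(fits$K, levels = ks), length)
  nk <- length(ks)
  L1 <- c(NA, diff(as.numeric(meanL)))           # L'(K) = L(K) - L(K-1)
  L2 <- rep(NA_real_, nk)                        # L''(K) = L'(K+1) - L'(K)
  if (nk >= 3) L2[2:(nk - 1)] <- L1[3:nk] - L1[2:(nk - 1)]
  dk <- abs(L2) / sdL
  undef <- is.na(dk) | nReps < 2 | !(sdL > 0)
  if (any(!is.na(L2) & (nReps < 2 | !(sdL > 0))))
    warning("deltaK undefined where replicate SD is 0 or replicates < 2; ",
            "excluded from the argmax")
  dk[undef] <- NA_real_
  out <- data.frame(K = ks, nReps = as.integer(nReps), meanL = as.numeric(meanL),
                    sdL = as.numeric(sdL), L1 = as.numeric(L1),
                    L2 = as.numeric(L2), deltaK = as.numeric(dk),
                    row.names = NULL)
  attr(out, "bestK") <- if (all(is.na(out$deltaK))) NA_integer_ else
    out$K[which.max(out$deltaK)]
  out
}

#' Best K from a delta-K table
#' @param dk result of [deltaK()].
#' @return the K maximising deltaK (NA if undefined everywhere).
#' @export
bestK <- function(dk) attr(dk, "bestK")

#' Allele-frequency divergence between clusters
#'
#' Net distance between cluster band-frequency vectors:
#' `delta_ab = mean_l (p_al - p_bl)^2` (identical to the half-sum over the
#' two band states of the squared frequency differences).
#'
#' @param fit an [AdmixtureFit-class].
#' @return symmetric K x K matrix with zero diagonal; feed to [njTree()]
#'   for the population tree.
#' @export
clusterDivergence <- function(fit) {
  P <- admixP(fit)
  K <- nrow(P)
  d <- matrix(0, K, K, dimnames = list(rownames(P), rownames(P)))
  for (a in seq_len(K))
    for (b in seq_len(K))
      d[a, b] <- mean((P[a, ] - P[b, ])^2)
  d
}

#' Hard population assignment from admixture proportions
#'
#' Assigns each genotype to the cluster with the largest posterior-mean
#' admixture proportion; exact ties go to the lowest cluster index (with a
#' message).
#'
#' @param fit an [AdmixtureFit-class], or a Q matrix.
#' @return named integer vector of population labels in `1..K`.
#' @export
hardAssignment <- function(fit) {
  Q <- if (is(fit, "AdmixtureFit")) admixQ(fit) else as.matrix(fit)
  lab <- max.col(Q, ties.method = "first")
  nTies <- sum(apply(Q, 1, function(r) sum(r == max(r)) > 1))
  if (nTies > 0)
    message(nTies, " tie(s) in admixture proportions resolved to the ",
            "lowest cluster index")
  setNames(as.integer(lab), rownames(Q))
}

#' Align cluster labels of a fitted Q matrix to a reference
#'
#' Greedy column matching on squared distance; used to compare replicate
#' runs or a fit against simulation truth.
#'
#' @param Q fitted Q matrix (n x K).
#' @param ref reference Q matrix (n x K).
#' @return `Q` with columns permuted to best match `ref`.
#' @export
alignClusters <- function(Q, ref) {
  K <- ncol(Q)
  stopifnot(ncol(ref) == K, nrow(ref) == nrow(Q))
  cost <- matrix(0, K, K)
  for (a in seq_len(K))
    for (b in seq_len(K))
      cost[a, b] <- sum((Q[, a] - ref[, b])^2)
  perm <- integer(K)
  used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    cost2 <- cost
    cost2[which(perm > 0), ] <- Inf
    cost2[, used] <- Inf
    idx <- which(cost2 == min(cost2), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    used[idx[2]] <- TRUE
  }
  out <- Q
  out[, perm] <- Q
  colnames(out) <- colnames(ref)
  out
}
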