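#' Configuration for the synthetic dominant-marker generator
#'
#' Defaults emulate the study design the package targets: 111 genotypes,
#' 191 polymorphic dominant loci with per-marker missing fractions drawn
#' from [0, 0.28], 10 latent subpopulations under Balding-Nichols
#' divergence, Dirichlet admixture, and 38 phenotypes built from marker
#' effects plus a population effect plus noise.
#'
#' @param nGenotypes number of genotypes (individuals).
#' @param nMarkers number of biallelic dominant loci.
#' @param kTrue number of latent clusters.
#' @param fstDivergence Balding-Nichols drift F per cluster, in (0, 1];
#'   `F = 0` collapses every cluster to the ancestral frequency (allowed,
#'   with a warning at simulation time: structure is then undetectable).
#' @param admixtureAlpha Dirichlet concentration of the admixture
#'   proportions; small values give near-unadmixed individuals.
#' @param missingRateRange length-2 range of per-marker missing rates.
#' @param nTraits number of simulated traits.
#' @param nCausalPerTrait causal markers per trait.
#' @param nTraitBlocks number of correlated trait blocks; traits within a
#'   block share their causal marker set.
#' @param effectSizeSd SD of causal marker effects.
#' @param traitNoiseSd SD of the residual trait noise.
#' @param populationEffectSd SD of the per-cluster trait effect applied to
#'   the admixture proportions.
#' @param intensityMeans length-2 vector `c(muAbsent, muPresent)` of
#'   hybridization-level means.
#' @param intensitySd hybridization-level SD (0.25 by default, giving a
#'   high-quality regime with marker quality Q around 0.8).
#' @param seed integer; fully determines the simulated data.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenotypes = 111L, nMarkers = 191L, kTrue = 10L,
                             fstDivergence = 0.2, admixtureAlpha = 0.2,
                             missingRateRange = c(0, 0.28), nTraits = 38L,
                             nCausalPerTrait = 3L, nTraitBlocks = 9L,
                             effectSizeSd = 0.5, traitNoiseSd = 1,
                             populationEffectSd = 0.5,
                             intensityMeans = c(0, 1), intensitySd = 0.25,
                             seed = 1L) {
  cfg <- list(nGenotypes = as.integer(nGenotypes),
              nMarkers = as.integer(nMarkers), kTrue = as.integer(kTrue),
              fstDivergence = fstDivergence,
              admixtureAlpha = admixtureAlpha,
              missingRateRange = as.numeric(missingRateRange),
              nTraits = as.integer(nTraits),
              nCausalPerTrait = as.integer(nCausalPerTrait),
              nTraitBlocks = as.integer(nTraitBlocks),
              effectSizeSd = effectSizeSd, traitNoiseSd = traitNoiseSd,
              populationEffectSd = populationEffectSd,
              intensityMeans = as.numeric(intensityMeans),
              intensitySd = intensitySd, seed = as.integer(seed))
  stopifnot(cfg$nGenotypes >= 2, cfg$nMarkers >= 1, cfg$kTrue >= 1,
            cfg$fstDivergence >= 0, cfg$fstDivergence <= 1,
            cfg$admixtureAlpha > 0,
            length(cfg$missingRateRange) == 2,
            all(cfg$missingRateRange >= 0), all(cfg$missingRateRange <= 1),
            cfg$missingRateRange[1] <= cfg$missingRateRange[2],
            cfg$nTraits >= 1, cfg$nCausalPerTrait >= 0,
            cfg$traitNoiseSd >= 0, cfg$intensitySd > 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a structured dominant-marker dataset
#'
#' Generative model: ancestral band frequency `p_l ~ U(0.1, 0.9)`; cluster
#' frequency `p_kl ~ Beta(p_l (1-F)/F, (1-p_l)(1-F)/F)` (Balding-Nichols);
#' admixture `q_i ~ Dirichlet(alpha 1_K)`; call
#' `X_il ~ Bernoulli(sum_k q_ik p_kl)`. Missing calls are injected
#' completely at random per marker, at a rate drawn uniformly from
#' `missingRateRange`. Intensities are `N(muPresent, sd)` where the band is
#' present and `N(muAbsent, sd)` where absent (missing calls keep an
#' intensity draw from the underlying state).
#'
#' @param config a [simulationConfig()].
#' @return list with `markers` (a [DartSet-class] carrying calls and
#'   intensities) and `truth` (list: `Q` true admixture proportions, `P`
#'   true cluster band frequencies, `pAncestral`, `labels` = argmax of `Q`,
#'   plus the per-marker missing rates used).
#' @export
simulateMarkers <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nGenotypes; L <- config$nMarkers; K <- config$kTrue
  F <- config$fstDivergence
  pAnc <- runif(L, 0.1, 0.9)
  if (F <= 0) {
    warning("fstDivergence = 0: clusters collapse to the ancestral ",
            "frequencies; population structure is undetectable")
    P <- matrix(rep(pAnc, each = K), K, L)
  } else if (F >= 1) {
    # full-drift limit: each cluster fixed for presence or absence
    P <- matrix(rbinom(K * L, 1, rep(pAnc, each = K)), K, L)
    P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  } else {
    a <- pAnc * (1 - F) / F
    b <- (1 - pAnc) * (1 - F) / F
    P <- matrix(rbeta(K * L, rep(a, each = K), rep(b, each = K)), K, L)
  }
  Q <- matrix(rgamma(n * K, config$admixtureAlpha, 1), n, K)
  zero <- rowSums(Q) == 0        # tiny-alpha gamma draws can underflow
  if (any(zero))
    Q[zero, ] <- t(stats::rmultinom(sum(zero), 1, rep(1, K)))
  Q <- Q / rowSums(Q)
  prob <- Q %*% P                     # n x L band-presence probabilities
  calls <- matrix(rbinom(n * L, 1, prob), n, L)
  mu <- config$intensityMeans
  intensity <- matrix(rnorm(n * L, mu[1] + (mu[2] - mu[1]) * calls,
                            config$intensitySd), n, L)
  missRate <- runif(L, config$missingRateRange[1], config$missingRateRange[2])
  missMask <- matrix(runif(n * L), n, L) <= rep(missRate, each = n)
  calls[missMask] <- NA_integer_
  gid <- sprintf("G%03d", seq_len(n))
  mid <- sprintf("M%03d", seq_len(L))
  dimnames(calls) <- dimnames(intensity) <- list(gid, mid)
  dimnames(Q) <- list(gid, paste0("K", seq_len(K)))
  dimnames(P) <- list(paste0("K", seq_len(K)), mid)
  markers <- suppressWarnings(
    DartSet(calls, intensity = intensity,
            missingCap = max(config$missingRateRange[2], 0.28)))
  labels <- setNames(max.col(Q, ties.method = "first"), gid)
  list(markers = markers,
       truth = list(Q = Q, P = P, pAncestral = pAnc, labels = labels,
                    missRate = setNames(missRate, mid)))
}

#' Simulate marker-linked quantitative traits
#'
#' Phenotype model: `y_it = mu_t + sum_m beta_mt X_im + gamma_t' q_i +
#' eps_it`, with `eps ~ N(0, traitNoiseSd^2)`. Traits are organised into
#' `nTraitBlocks` blocks; traits in a block share the same causal marker
#' set (with independently drawn effect sizes), which induces correlated
#' trait families. Missing calls at causal loci are mean-imputed for trait
#' construction only. Causal markers that end up monomorphic over observed
#' calls are re-drawn (with a message).
#'
#' @param sim result of [simulateMarkers()] (list with `markers`, `truth`),
#'   or a [DartSet-class] if `truth` is passed separately.
#' @param config the [simulationConfig()] used for the markers.
#' @param truth optional truth list when `sim` is a `DartSet`.
#' @return list with `traits` (genotypes x traits numeric matrix) and
#'   `causal` (list per trait: named vector of marker effects).
#' @export
simulateTraits <- function(sim, config = simulationConfig(), truth = NULL) {
  if (is(sim, "DartSet")) {
    markers <- sim
    stopifnot(!is.null(truth))
  } else {
    markers <- sim$markers
    truth <- sim$truth
  }
  set.seed(config$seed + 1000003L)
  X <- bandCalls(markers)
  n <- nrow(X); L <- ncol(X); K <- ncol(truth$Q)
  # mean-impute missing calls (trait construction only)
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0.5
  Ximp <- X
  for (j in seq_len(L)) Ximp[is.na(X[, j]), j] <- cm[j]
  poly <- which(apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1
  }))
  if (length(poly) < config$nCausalPerTrait)
    stop("not enough polymorphic markers for the requested causal count")
  nb <- max(1L, min(config$nTraitBlocks, config$nTraits))
  block <- rep(seq_len(nb), length.out = config$nTraits)
  blockCausal <- lapply(seq_len(nb), function(b)
    sample(poly, config$nCausalPerTrait))
  traits <- matrix(0, n, config$nTraits,
                   dimnames = list(rownames(X),
                                   sprintf("T%02d", seq_len(config$nTraits))))
  causal <- vector("list", config$nTraits)
  names(causal) <- colnames(traits)
  for (t in seq_len(config$nTraits)) {
    idx <- blockCausal[[block[t]]]
    beta <- rnorm(length(idx), 0, config$effectSizeSd)
    gamma <- rnorm(K, 0, config$populationEffectSd)
    y <- drop(Ximp[, idx, drop = FALSE] %*% beta) +
      drop(truth$Q %*% gamma) +
      rnorm(n, 0, config$traitNoiseSd)
    traits[, t] <- y
    causal[[t]] <- setNames(beta, colnames(X)[idx])
  }
  list(traits = traits, causal = causal)
}
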