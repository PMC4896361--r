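test_that("kinship is the centred IBS similarity with hand-checked values", {
  x <- makeDart(c("1100", "1100", "0011", "1001"))
  Kr <- kinship(x)
  # IBS proportions by hand
  S <- matrix(1, 4, 4)
  S[1, 2] <- S[2, 1] <- 1
  S[1, 3] <- S[3, 1] <- 0
  S[2, 3] <- S[3, 2] <- 0
  S[1, 4] <- S[4, 1] <- 0.5
  S[2, 4] <- S[4, 2] <- 0.5
  S[3, 4] <- S[4, 3] <- 0.5
  sBar <- mean(S[upper.tri(S)])
  expect_equal(Kr[1, 2], 1)                                 # identical pair
  expect_equal(Kr[1, 4], max(0, (0.5 - sBar) / (1 - sBar)), tolerance = 1e-12)
  expect_equal(Kr[1, 3], 0)                                 # below average
  expect_equal(diag(Kr), setNames(rep(1, 4), paste0("g", 1:4)))
  expect_equal(Kr, t(Kr))

  same <- makeDart(c("1100", "1100", "1100"))
  expect_error(kinship(same), "identical")
})

test_that("a pair exactly at the mean similarity centres to zero kinship", {
  set.seed(71)
  sim <- simulateMarkers(simulationConfig(nGenotypes = 30, nMarkers = 80,
                                          kTrue = 2, seed = 71))
  Kr <- kinship(sim$markers)
  expect_true(all(Kr >= 0 & Kr <= 1 + 1e-12))
  expect_true(any(Kr[upper.tri(Kr)] == 0))    # truncation engages
})

test_that("the MLM with identity kinship and no structure is exactly OLS", {
  cfg <- simulationConfig(nGenotypes = 50, nMarkers = 30, kTrue = 2,
                          nTraits = 2, missingRateRange = c(0, 0.1),
                          seed = 81)
  sim <- simulateMarkers(cfg)
  tr <- simulateTraits(sim, cfg)
  mlm <- mlmScan(tr$traits, sim$markers, Q = NULL, Kr = NULL)
  X <- bandCalls(sim$markers)
  for (i in sample(nrow(mlm), 8)) {
    g <- X[, mlm$marker[i]]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    a <- anova(lm(tr$traits[, mlm$trait[i]] ~ g))
    expect_equal(mlm$F[i], a$`F value`[1], tolerance = 1e-8)
    expect_equal(mlm$p[i], a$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(mlm$errorDf[i], a$Df[2])
  }
})

test_that("marker R2 is affine invariant and near 1 for a perfect signal", {
  cfg <- simulationConfig(nGenotypes = 40, nMarkers = 25, kTrue = 2,
                          nTraits = 1, nCausalPerTrait = 1,
                          effectSizeSd = 10, traitNoiseSd = 1e-8,
                          populationEffectSd = 0,
                          missingRateRange = c(0, 0), seed = 82)
  sim <- simulateMarkers(cfg)
  tr <- simulateTraits(sim, cfg)
  m1 <- mlmScan(tr$traits, sim$markers, Q = NULL, Kr = NULL)
  m2 <- mlmScan(tr$traits * 3.7 + 11, sim$markers, Q = NULL, Kr = NULL)
  expect_equal(m1$markerR2, m2$markerR2, tolerance = 1e-9)
  top <- which.max(m1$F)
  expect_equal(m1$marker[top], names(tr$causal$T01))
  expect_gt(m1$markerR2[top], 0.99)
  expect_true(all(m1$markerR2 >= 0 & m1$markerR2 <= 1))
})

test_that("the mixed model controls type-I error under a structured null", {
  cfg <- simulationConfig(nGenotypes = 90, nMarkers = 150, kTrue = 3,
                          fstDivergence = 0.3, admixtureAlpha = 0.1,
                          missingRateRange = c(0, 0.1), seed = 101)
  sim <- simulateMarkers(cfg)
  Kr <- kinship(sim$markers)
  set.seed(42)
  nT <- 15
  Y <- vapply(seq_len(nT), function(t)
    drop(sim$truth$Q %*% rnorm(3)) + rnorm(90), numeric(90))
  dimnames(Y) <- list(genotypeIds(sim$markers), sprintf("T%02d", 1:nT))
  mlm <- mlmScan(Y, sim$markers, Q = sim$truth$Q, Kr = Kr)
  m <- nrow(mlm)
  expect_gte(m, 2000)
  emp <- mean(mlm$p <= 0.05)
  hw <- 2.576 * sqrt(0.05 * 0.95 / m)       # binomial 99% bounds
  expect_gt(emp, 0.05 - hw)
  expect_lt(emp, 0.05 + hw)
})

test_that("with zero genetic variance the MLM collapses to the fixed model", {
  # pure-noise trait on unstructured markers: REML drives sigma_g to the
  # boundary and the scan must equal the plain covariate regression
  set.seed(83)
  m <- randomCalls(45, 20)
  Kr <- kinship(m)
  y <- matrix(rnorm(45), dimnames = list(rownames(m), "T1"))
  mlm <- suppressWarnings(mlmScan(y, m, Q = NULL, Kr = Kr))
  if (unique(mlm$geneticVariance) == 0) {
    ols <- mlmScan(y, m, Q = NULL, Kr = NULL)
    expect_equal(mlm$F, ols$F, tolerance = 1e-8)
  } else succeed("REML found positive genetic variance on this draw")
})

test_that("permutation-adjusted p dominates raw p and flags true signals", {
  cfg <- simulationConfig(nGenotypes = 60, nMarkers = 40, kTrue = 2,
                          nTraits = 2, nCausalPerTrait = 1,
                          effectSizeSd = 8, traitNoiseSd = 0.5,
                          populationEffectSd = 0.2,
                          missingRateRange = c(0, 0), seed = 91)
  sim <- simulateMarkers(cfg)
  tr <- simulateTraits(sim, cfg)
  gp <- glmPermScan(tr$traits, sim$markers, covariates = sim$truth$Q,
                    nPerm = 400, seed = 6)
  expect_true(all(gp$pAdj >= gp$pRaw - 1e-12))
  for (t in c("T01", "T02")) {
    causal <- names(tr$causal[[t]])
    expect_lte(gp$pAdj[gp$trait == t & gp$marker == causal], 0.05)
  }
  # SA variant: hard labels as categorical covariate
  sa <- glmPermScan(tr$traits, sim$markers, covariates = sim$truth$labels,
                    nPerm = 200, seed = 7)
  expect_true(all(sa$pAdj >= sa$pRaw - 1e-12))

  # null trait: adjusted p-values pile near 1
  y0 <- matrix(rnorm(60), dimnames = list(genotypeIds(sim$markers), "N1"))
  g0 <- glmPermScan(y0, sim$markers, covariates = sim$truth$Q,
                    nPerm = 200, seed = 8)
  expect_gt(median(g0$pAdj), 0.5)
})

test_that("rank-and-confirm applies the two-stage significance rule", {
  mlm <- data.frame(trait = c("T1", "T1", "T1", "T2"),
                    marker = c("m1", "m2", "m3", "m1"),
                    F = c(9, 5, 1, 2), p = c(0.003, 0.04, 0.6, 0.2),
                    errorDf = 40, markerR2 = 0.1, geneticVariance = 1,
                    residualVariance = 1, neg2lnLik = 100)
  glm <- data.frame(trait = "T1", marker = c("m1", "m2"),
                    F = c(9, 5), pRaw = c(0.01, 0.05), pAdj = c(0.02, 0.3))
  sa <- data.frame(trait = "T1", marker = c("m1", "m2"),
                   F = c(9, 5), pRaw = c(0.01, 0.05), pAdj = c(0.9, 0.04))
  out <- rankAndConfirm(mlm, glm, sa)
  expect_equal(out$marker, c("m1", "m2"))          # T1 ranked by p, T2 absent
  expect_equal(out$rank, c(1, 2))
  expect_true(out$confirmed[1])                    # via GLM
  expect_true(out$confirmed[2])                    # via SA
  counts <- attr(out, "counts")
  expect_equal(counts$nAlpha1[counts$trait == "T1"], 2)
  expect_equal(counts$nAlpha2[counts$trait == "T1"], 1)
  expect_equal(counts$nAlpha1[counts$trait == "T2"], 0)

  # marker significant in MLM only stays listed but unconfirmed
  out2 <- rankAndConfirm(mlm, NULL, NULL)
  expect_equal(nrow(out2), 2)
  expect_false(any(out2$confirmed))

  # no significant markers: empty table
  out3 <- rankAndConfirm(transform(mlm, p = 0.9), glm, sa)
  expect_equal(nrow(out3), 0)
})

test_that("association power is non-decreasing in effect size", {
  set.seed(95)
  m <- randomCalls(60, 30)
  g <- m[, 5]
  power <- vapply(c(0, 0.4, 1.2), function(beta) {
    hits <- vapply(1:30, function(r) {
      y <- matrix(beta * g + rnorm(60), dimnames = list(rownames(m), "T"))
      mlm <- mlmScan(y, m, Q = NULL, Kr = NULL)
      mlm$p[mlm$marker == "m5"] <= 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(power) >= -0.05))
  expect_gt(power[3], power[1])
})
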