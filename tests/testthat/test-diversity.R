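test_that("AMOVA components equal the brute-force sums-of-squares oracle", {
  # 6-genotype toy instance, two populations of 3
  x <- makeDart(c("110010", "100110", "111000",
                  "001101", "011001", "000111"))
  d <- distanceTransform(jaccardSimilarity(x))
  pops <- setNames(c(1, 1, 1, 2, 2, 2), rownames(d))
  res <- amova(d, pops, nPerm = 99, seed = 1)
  ora <- amovaOracle(d, pops)
  expect_equal(res$ssAmong, ora$ssAmong, tolerance = 1e-9)
  expect_equal(res$ssWithin, ora$ssWithin, tolerance = 1e-9)
  expect_equal(res$Va, ora$Va, tolerance = 1e-9)
  expect_equal(res$Vb, ora$Vb, tolerance = 1e-9)
  expect_equal(res$dfAmong + res$dfWithin, nrow(d) - 1)
  expect_equal(res$percentAmong + res$percentWithin, 100, tolerance = 1e-9)
  expect_equal(res$Va + res$Vb, res$totalVariance, tolerance = 1e-9)

  # unequal population sizes exercise the n0 correction
  pops2 <- setNames(c(1, 1, 1, 1, 2, 2), rownames(d))
  res2 <- amova(d, pops2, nPerm = 99, seed = 1)
  ora2 <- amovaOracle(d, pops2)
  expect_equal(res2$Va, ora2$Va, tolerance = 1e-9)
  expect_equal(res2$Vb, ora2$Vb, tolerance = 1e-9)
})

test_that("AMOVA permutation p is uniform under the null", {
  set.seed(123)
  pvals <- vapply(1:200, function(r) {
    m <- randomCalls(16, 25)
    m[, 1] <- 1                          # keep all pairs defined
    d <- distanceTransform(jaccardSimilarity(m))
    pops <- setNames(sample(rep(1:2, each = 8)), rownames(d))
    amova(d, pops, nPerm = 99)$pAmong
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})

test_that("Phi-st hits its boundary semantics exactly", {
  # duplicated population: two copies of the same four profiles -> 0
  base <- makeDart(c("1111100000", "1010101011", "1100110011", "0110011101"))
  dup <- rbind(bandCalls(base), bandCalls(base))
  rownames(dup) <- paste0("g", 1:8)
  d <- distanceTransform(jaccardSimilarity(dup))
  pops <- setNames(rep(1:2, each = 4), rownames(dup))
  ph <- pairwisePhiSt(d, pops, nPerm = 99, seed = 1)
  expect_identical(ph$phiST["Pop1", "Pop2"], 0)
  expect_lt(attr(ph$phiST, "raw")["Pop1", "Pop2"], 0)   # raw value retained

  # fully fixed disjoint profiles -> 1
  m <- rbind(matrix(1L, 4, 10), matrix(0L, 4, 10))
  dimnames(m) <- list(paste0("g", 1:8), paste0("m", 1:10))
  d2 <- distanceTransform(jaccardSimilarity(m, zeroDenominator = "one"))
  ph2 <- pairwisePhiSt(d2, pops, nPerm = 99, seed = 1)
  expect_identical(ph2$phiST["Pop1", "Pop2"], 1)
})

test_that("Phi-st of a random split of one population is near zero", {
  set.seed(31)
  phis <- vapply(1:20, function(r) {
    m <- randomCalls(20, 40)
    m[, 1] <- 1
    d <- distanceTransform(jaccardSimilarity(m))
    pops <- setNames(sample(rep(1:2, each = 10)), rownames(d))
    suppressWarnings(pairwisePhiSt(d, pops, nPerm = 0))$phiST[1, 2]
  }, numeric(1))
  expect_lt(mean(phis), 0.03)
})

test_that("Phi-st recovers simulated two-population differentiation", {
  cfg <- simulationConfig(nGenotypes = 60, nMarkers = 120, kTrue = 2,
                          fstDivergence = 0.25, admixtureAlpha = 0.02,
                          missingRateRange = c(0, 0), seed = 77)
  sim <- simulateMarkers(cfg)
  pops <- sim$truth$labels
  d <- distanceTransform(jaccardSimilarity(sim$markers))
  obs <- pairwisePhiSt(d, pops, nPerm = 99, seed = 2)
  # realized differentiation from the simulated cluster frequencies:
  # Phi-st analogue on the same distance using the true labels is the
  # reference; the fitted value must track it closely
  ref <- suppressWarnings(amova(d, pops, nPerm = 0))$phiST
  expect_lt(abs(obs$phiST[1, 2] - max(0, ref)), 0.08)
  expect_lt(obs$p[1, 2], 0.05)
})

test_that("Shannon diversity has its closed-form limits and additivity", {
  # fixed loci -> H' = 0 with zero Bowman variance
  fixed <- makeDart(c("1100", "1100", "1100"))
  sh <- shannonDiversity(fixed, setNames(rep(1, 3), paste0("g", 1:3)),
                         nBoot = 50, seed = 1)
  expect_equal(sh$H, 0)
  expect_equal(sh$varBowman, sum(1 / (2 * c(3, 3, 3, 3)^2)))

  # one locus at p = 1/2 contributes ln 2
  half <- DartSet(matrix(c(1L, 1L, 0L, 0L), 4, 1,
                         dimnames = list(paste0("g", 1:4), "m1")))
  sh2 <- shannonDiversity(half, setNames(rep(1, 4), paste0("g", 1:4)),
                          nBoot = 0)
  expect_equal(sh2$H, log(2), tolerance = 1e-12)

  # disjoint locus blocks contribute additively
  set.seed(41)
  a <- randomCalls(10, 8)
  b <- randomCalls(10, 6)
  colnames(b) <- paste0("n", 1:6)
  pops <- setNames(rep(1, 10), rownames(a))
  hA <- shannonDiversity(a, pops, nBoot = 0)$H
  hB <- shannonDiversity(b, pops, nBoot = 0)$H
  hAB <- shannonDiversity(cbind(a, b), pops, nBoot = 0)$H
  expect_equal(hAB, hA + hB, tolerance = 1e-12)
})

test_that("bootstrap variance matches exhaustive resample enumeration", {
  set.seed(55)
  m <- randomCalls(5, 6)
  pops <- setNames(rep(1, 5), rownames(m))
  # exact variance over all 5^5 equally likely ordered resamples
  perLocusH <- function(rows) {
    p <- colMeans(m[rows, , drop = FALSE])
    ent <- ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
    sum(ent)
  }
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  hs <- apply(grid, 1, perLocusH)
  exact <- mean(hs^2) - mean(hs)^2
  sh <- shannonDiversity(m, pops, nBoot = 20000, seed = 8)
  expect_equal(sh$varBootstrap, exact, tolerance = 0.08)
})

test_that("the Hutcheson t-test behaves at its limits and matches the CDF", {
  r1 <- list(H = 2.0, varBootstrap = 0.04, size = 10)
  r2 <- list(H = 2.0, varBootstrap = 0.09, size = 12)
  eq <- shannonTTest(r1, r2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  r3 <- list(H = 5.0, varBootstrap = 0.01, size = 10)
  expect_lt(shannonTTest(r3, r2)$p, 1e-6)

  # independent evaluation of the t CDF at the hand-computed statistic
  r4 <- list(H = 2.6, varBootstrap = 0.05, size = 8)
  got <- shannonTTest(r4, r2)
  tt <- (2.6 - 2.0) / sqrt(0.05 + 0.09)
  df <- (0.05 + 0.09)^2 / (0.05^2 / 8 + 0.09^2 / 12)
  expect_equal(got$t, tt, tolerance = 1e-12)
  expect_equal(got$df, df, tolerance = 1e-12)
  expect_equal(got$p, 2 * (1 - pt(tt, df)), tolerance = 1e-12)

  r0 <- list(H = 1, varBootstrap = 0, size = 5)
  expect_error(shannonTTest(r0, r2), "positive")
})
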