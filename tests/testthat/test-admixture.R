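# Brute-force posterior for the 2-cluster admixture model on a tiny
# instance: enumerate every cluster-indicator configuration z and average
# the conjugate posterior mean of p over P(z | X). Independent of the
# Gibbs code path.
enumeratePosteriorP <- function(X, alpha, lambda) {
  n <- nrow(X); L <- ncol(X); K <- 2
  cells <- which(!is.na(X), arr.ind = TRUE)
  nc <- nrow(cells)
  grid <- as.matrix(expand.grid(rep(list(1:K), nc)))
  logw <- numeric(nrow(grid))
  pmean <- array(0, c(K, L))
  store <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    n1 <- matrix(0, K, L); n0 <- matrix(0, K, L)
    cik <- matrix(0, n, K)
    for (c in seq_len(nc)) {
      i <- cells[c, 1]; l <- cells[c, 2]; k <- z[c]
      if (X[i, l] == 1) n1[k, l] <- n1[k, l] + 1 else n0[k, l] <- n0[k, l] + 1
      cik[i, k] <- cik[i, k] + 1
    }
    lw <- sum(lbeta(lambda + n1, lambda + n0) - lbeta(lambda, lambda))
    for (i in seq_len(n))
      lw <- lw + lgamma(K * alpha) - K * lgamma(alpha) +
        sum(lgamma(alpha + cik[i, ])) - lgamma(K * alpha + sum(cik[i, ]))
    logw[g] <- lw
    store[[g]] <- (lambda + n1) / (2 * lambda + n1 + n0)
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  for (g in seq_along(w)) pmean <- pmean + w[g] * store[[g]]
  pmean
}

test_that("the Gibbs sampler matches brute-force enumeration on a toy instance", {
  X <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("m1", "m2")))
  oracle <- enumeratePosteriorP(X, alpha = 0.7, lambda = 1)
  fit <- fitAdmixture(X, K = 2, burnIn = 2000, reps = 80000, alpha = 0.7,
                      lambda = 1, alignLabels = FALSE, seed = 77)
  # without alignment the chain mixes over the label-symmetric posterior,
  # whose per-cluster means coincide with the enumeration's symmetric mean
  sym <- matrix(colMeans(oracle), 2, 2, byrow = TRUE)
  expect_lt(max(abs(admixP(fit) - sym)), 0.02)
})

test_that("K = 1 degenerates to the single-cluster Bernoulli-Beta model", {
  set.seed(50)
  x <- randomCalls(12, 15)
  fit <- fitAdmixture(x, K = 1, burnIn = 500, reps = 4000, seed = 3)
  expect_equal(unname(admixQ(fit)[, 1]), rep(1, 12))
  expect_true(is.finite(lnPD(fit)))
  # lnPD approximates the exact Bernoulli-Beta log marginal likelihood,
  # bracketed by it and the plug-in log-likelihood at the posterior mean
  lml <- sum(lbeta(1 + colSums(x), 1 + nrow(x) - colSums(x)))
  phat <- (colSums(x) + 1) / (nrow(x) + 2)
  llhat <- sum(x %*% log(phat) + (1 - x) %*% log(1 - phat))
  expect_gt(lnPD(fit), lml - 1)
  expect_lt(lnPD(fit), llhat + 1)
  expect_lt(abs(lnPD(fit) - lml) / abs(lml), 0.1)
})

test_that("chains are deterministic given a seed and exchangeable over rows", {
  set.seed(51)
  x <- randomCalls(10, 12)
  f1 <- fitAdmixture(x, 2, burnIn = 200, reps = 500, seed = 9)
  f2 <- fitAdmixture(x, 2, burnIn = 200, reps = 500, seed = 9)
  expect_identical(admixQ(f1), admixQ(f2))
  expect_identical(lnPD(f1), lnPD(f2))

  # duplicated genotypes receive the same posterior admixture (within MC error)
  sim <- simulateMarkers(simulationConfig(nGenotypes = 20, nMarkers = 60,
                                          kTrue = 2, fstDivergence = 0.4,
                                          admixtureAlpha = 0.05,
                                          missingRateRange = c(0, 0),
                                          seed = 52))
  X <- bandCalls(sim$markers)
  Xd <- rbind(X, X)
  rownames(Xd) <- c(paste0("a", 1:20), paste0("b", 1:20))
  fd <- fitAdmixture(Xd, 2, burnIn = 1000, reps = 4000, seed = 10)
  Q <- admixQ(fd)
  expect_lt(max(abs(Q[1:20, ] - Q[21:40, ])), 0.12)
})

test_that("K out of range and invalid inputs are rejected", {
  x <- randomCalls(4, 6)
  expect_error(fitAdmixture(x, 0), ">= 1")
  expect_error(fitAdmixture(x, 5), "exceeds")
})

test_that("delta-K reproduces the printed-formula hand computation", {
  df <- data.frame(K = c(2, 2, 3, 3, 4, 4),
                   lnPD = c(-101, -101, -70, -72, -70, -70))
  dk <- suppressWarnings(deltaK(df))
  # means L(2) = -101, L(3) = -71, L(4) = -70; SD at K=3 is sqrt(2)
  # |L''(3)| = |-70 - 2(-71) + (-101)| = 29
  expect_equal(dk$deltaK[dk$K == 3], 29 / sqrt(2), tolerance = 1e-9)
  expect_equal(bestK(dk), 3)
  # endpoints are undefined
  expect_true(is.na(dk$deltaK[dk$K == 2]))
  expect_true(is.na(dk$deltaK[dk$K == 4]))
})

test_that("delta-K vanishes for linear lnPD and is scale invariant", {
  reps <- expand.grid(K = 2:6, r = 1:3)
  base <- data.frame(K = reps$K,
                     lnPD = -500 + 10 * reps$K + 0.5 * (reps$r - 2))
  dk <- deltaK(base)
  expect_equal(na.omit(dk$L2), rep(0, 3), ignore_attr = TRUE)
  expect_equal(na.omit(dk$deltaK), rep(0, 3), ignore_attr = TRUE)

  set.seed(60)
  rnd <- data.frame(K = reps$K, lnPD = -1000 + 30 * reps$K -
                      2 * reps$K^2 + rnorm(nrow(reps), 0, 3))
  d1 <- deltaK(rnd)
  d2 <- deltaK(transform(rnd, lnPD = lnPD * 7.5))
  expect_equal(d1$deltaK, d2$deltaK, tolerance = 1e-9)
  expect_error(deltaK(data.frame(K = c(2, 2, 4, 4), lnPD = 1:4)),
               "contiguous")
})

test_that("cluster divergence has the closed-form boundary values", {
  P <- rbind(K1 = rep(0.999999, 10), K2 = rep(1e-6, 10),
             K3 = rep(0.999999, 10))
  fit <- new("AdmixtureFit", K = 3L,
             Q = matrix(1 / 3, 2, 3,
                        dimnames = list(c("g1", "g2"), rownames(P))),
             P = P, lnPD = -1, logLik = c(-1, -1), settings = list())
  d <- clusterDivergence(fit)
  expect_equal(d["K1", "K3"], 0, tolerance = 1e-9)
  expect_equal(d["K1", "K2"], 1, tolerance = 1e-5)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), rownames(P)))
})

test_that("hard assignment takes the argmax with low-index tie-breaking", {
  Q <- rbind(g1 = c(0.9, 0.1), g2 = c(0.5, 0.5), g3 = c(0.2, 0.8))
  expect_message(lab <- hardAssignment(Q), "tie")
  expect_equal(unname(lab), c(1L, 1L, 2L))
})
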