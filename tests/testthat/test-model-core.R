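test_that("buildMu assembles the structured channel means", {
  expect_equal(buildMu(1, 10, 0.2, 0.05, 0.03), c(10, 2, 0.5, 0.3))
  expect_equal(buildMu(3, 10, 0.2, 0.05, 0.03), c(0.5, 0.3, 10, 2))
  # channel-pair symmetry for the other two classes
  expect_equal(buildMu(2, 10, 0.2, 0.05, 0.03), c(2, 10, 0.5, 0.3))
  expect_equal(buildMu(4, 10, 0.2, 0.05, 0.03), c(0.5, 0.3, 2, 10))
  # zero cross-talk limit: one-hot
  for (j in 1:4)
    expect_equal(buildMu(j, 7, 0, 0, 0), 7 * (1:4 == j) + 0)
  # bright channel dominates its partner for any fractions in [0, 1]
  set.seed(1)
  for (rep in 1:200) {
    j <- sample(4, 1)
    mu <- buildMu(j, runif(1, 0.1, 20), runif(1), runif(1), runif(1))
    expect_gte(mu[j], mu[c(2, 1, 4, 3)[j]])
    expect_true(all(mu >= 0))
  }
  expect_error(buildMu(5, 10, 0.2, 0.05, 0.03), "base index")
  expect_error(buildMu(1, -1, 0.2, 0.05, 0.03), "positive")
  expect_error(buildMu(1, 10, 1.2, 0.05, 0.03), "\\[0, 1\\]")
})

test_that("decayFactor follows exp(-beta * i^lambda)", {
  expect_equal(decayFactor(1:50, 0, 0.7), rep(1, 50))
  expect_equal(decayFactor(1, 0.37, 0.9), exp(-0.37))  # 1^lambda = 1
  expect_equal(decayFactor(36, 0.1, 0.5), 0.548811636094026, tolerance = 1e-12)
  # non-increasing in i across the whole support
  set.seed(2)
  for (rep in 1:50) {
    d <- decayFactor(1:40, runif(1), runif(1))
    expect_true(all(diff(d) <= 0))
    expect_true(all(d > 0 & d <= 1))
  }
  expect_error(decayFactor(0, 0.1, 0.5), ">= 1")
})

test_that("componentMean combines fading and autoregressive phasing", {
  p0 <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.01, gEps2 = 0.01,
                    alpha = 0, beta = 0)
  expect_equal(componentMean(1, 5, yPrev = c(1, 1, 1, 1), p0),
               buildMu(1, 10, 0.2, 0.01, 0.01))
  p <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.01, gEps2 = 0.01,
                   alpha = 0.5, beta = 0)
  m <- componentMean(1, 2, yPrev = c(1, 1, 1, 1), p)
  expect_equal(m, c(10, 2, 0.1, 0.1) + 0.5)
  # no carry-over at cycle 1, whatever alpha
  p9 <- ModelParams(alpha = 0.9, beta = 0)
  expect_equal(componentMean(2, 1, NULL, p9),
               buildMu(2, p9@mu11[2], p9@gPair[2], p9@gEps1[2], p9@gEps2[2]))
  expect_error(componentMean(1, 2, NULL, p), "yPrev")
})

test_that("truncation regions partition intensity space", {
  expect_true(truncationOk(c(5, 1, 0, 0), 1))
  expect_false(truncationOk(c(5, 1, 0, 0), 2))
  expect_true(truncationOk(c(3, 3, 0, 0), 1))  # non-strict ties
  expect_true(truncationOk(c(3, 3, 0, 0), 2))
  # any y with distinct entries lies in exactly one region
  set.seed(3)
  for (rep in 1:500) {
    y <- rnorm(4)
    expect_equal(sum(vapply(1:4, function(j) truncationOk(y, j), TRUE)), 1L)
  }
  expect_error(truncationOk(c(1, 2, 3, Inf), 1), "finite")
})

test_that("logComponentDensity matches an independent MVN evaluation", {
  p <- presetParams("moderate")
  set.seed(4)
  for (rep in 1:50) {
    j <- sample(4, 1)
    i <- sample(2:36, 1)
    yPrev <- abs(rnorm(4, 3))
    y <- rnorm(4, 2, 3)
    ld <- logComponentDensity(y, j, i, yPrev, p)
    if (!truncationOk(y, j)) {
      expect_identical(ld, -Inf)
    } else {
      m <- exp(-p@beta * i^p@lambda) *
        buildMu(j, p@mu11[j], p@gPair[j], p@gEps1[j], p@gEps2[j]) +
        p@alpha * yPrev
      expect_equal(ld, mvtnorm::dmvnorm(y, m, p@Sigma[[j]], log = TRUE),
                   tolerance = 1e-10)
    }
  }
})

test_that("isotropic log-density differences reduce to squared distances", {
  p <- ModelParams(mu11 = 5, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.05,
                   alpha = 0, beta = 0, Sigma = diag(4))
  m <- buildMu(1, 5, 0.2, 0.05, 0.05)
  y1 <- c(6, 1, 0.2, 0.1); y2 <- c(5.5, 2, 0.4, 0.3)
  d1 <- logComponentDensity(y1, 1, 1, NULL, p)
  d2 <- logComponentDensity(y2, 1, 1, NULL, p)
  expect_equal(d1 - d2,
               -0.5 * (sum((y1 - m)^2) - sum((y2 - m)^2)),
               tolerance = 1e-12)
})

test_that("normalized component density integrates to 1 over its region", {
  # rejection-sampling integration on a snug 4-cube around the component
  p <- ModelParams(mu11 = 1, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.05,
                   alpha = 0, beta = 0, Sigma = 0.09 * diag(4))
  lo <- -1.5; hi <- 2.5
  set.seed(5)
  M <- 4e6
  Y <- matrix(runif(4 * M, lo, hi), M, 4)
  inRegion <- Y[, 1] >= pmax(Y[, 2], pmax(Y[, 3], Y[, 4]))
  m <- buildMu(1, 1, 0.2, 0.05, 0.05)
  f <- numeric(M)
  ld <- mvtnorm::dmvnorm(Y[inRegion, ], m, p@Sigma[[1]], log = TRUE)
  Z <- truncationMass(1, m, p@Sigma[[1]])
  f[inRegion] <- exp(ld - log(Z))
  integral <- (hi - lo)^4 * mean(f)
  expect_equal(integral, 1, tolerance = 0.025)  # 3 sd of the MC estimator
  # and the same mass matches a direct Monte-Carlo fraction
  set.seed(6)
  draws <- mvtnorm::rmvnorm(1e5, m, p@Sigma[[1]])
  frac <- mean(draws[, 1] >= apply(draws, 1, max))
  expect_equal(Z, frac, tolerance = 0.02)
})

test_that("logPrior is the sum of independent textbook densities", {
  prior <- PriorConfig()
  p <- ModelParams(mu11 = c(8, 9, 10, 11), gPair = c(0.2, 0.3, 0.25, 0.15),
                   gEps1 = 0.05, gEps2 = 0.08, alpha = 0.3, beta = 0.1,
                   lambda = 0.5, Sigma = diag(4))
  # beta(1,1) terms are flat: zero contribution from gPair, alpha, beta,
  # lambda, so only mu11, gEps and the inverse-Wishart terms remain
  lmu <- sum(dlnorm(p@mu11, 0, 1, log = TRUE))
  leps <- sum(dbeta(c(p@gEps1, p@gEps2), 2, 10, log = TRUE))
  # inverse-Wishart(I4, 6) log density at the identity, written out:
  # (nu/2)log|Psi| - (nu d/2)log2 - log Gamma_4(nu/2)
  #   - ((nu+d+1)/2)log|X| - tr(Psi X^-1)/2, with X = Psi = I, nu = 6
  lgamma4 <- (4 * 3 / 4) * log(pi) +
    lgamma(3) + lgamma(2.5) + lgamma(2) + lgamma(1.5)
  liw <- -(6 * 4 / 2) * log(2) - lgamma4 - 4 / 2
  expect_equal(logPrior(p, prior), lmu + leps + 4 * liw, tolerance = 1e-10)
  # out of support: -Inf, not an error
  pBad <- p; pBad@gEps1[1] <- 1
  expect_identical(logPrior(pBad, prior), -Inf)
  # interior points are finite
  expect_true(is.finite(logPrior(presetParams("moderate"), prior)))
})

test_that("prior-predictive mean structure keeps leakage below the bright channel", {
  set.seed(7)
  n <- 1e4
  mu11 <- rlnorm(n); gPair <- rbeta(n, 1, 1)
  gEps1 <- rbeta(n, 2, 10); gEps2 <- rbeta(n, 2, 10)
  bright <- mu11
  partner <- gPair * mu11
  leak <- cbind(gEps1 * mu11, gEps2 * mu11)
  expect_true(all(bright >= partner))
  expect_gt(mean(bright), mean(leak))
  # beta(1,1) cross-talk (mean 1/2) exceeds beta(2,10) leakage (mean 1/6)
  expect_gt(mean(partner), mean(leak))
})
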