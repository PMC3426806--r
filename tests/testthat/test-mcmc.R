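test_that("categorical draws match their weights", {
  # unnormalized weights (0, 0, 1, 3): probabilities (0, 0, 0.25, 0.75)
  logW <- matrix(log(c(0, 0, 1, 3)), 1e5, 4, byrow = TRUE)
  set.seed(11)
  k <- phaseCall:::.sampleCategoricalRows(logW)
  freq <- tabulate(k, 4) / nrow(logW)
  se <- sqrt(0.25 * 0.75 / nrow(logW))
  expect_equal(freq[1:2], c(0, 0))
  expect_lt(abs(freq[3] - 0.25), 3 * se)
  expect_lt(abs(freq[4] - 0.75), 3 * se)
})

test_that("sampleK is uniform when all components are equivalent", {
  # all four component means coincide and y sits on a 4-way tie
  p <- symmetricParams()
  y <- array(1, dim = c(1, 4, 4000))
  cs <- ColonySet(y)
  set.seed(12)
  k <- sampleK(cs, p)
  freq <- tabulate(k, 4) / length(k)
  se <- sqrt(0.25 * 0.75 / length(k))
  expect_true(all(abs(freq - 0.25) < 4 * se))
})

test_that("clamped-parameter MCMC matches the exact enumeration posterior", {
  p <- presetParams("moderate")
  sim <- simulateReads(6, readLen = 10, params = p, seed = 13)
  # add a colony with exact pair ties so several components carry weight
  Y <- intensities(sim$colonies)
  Y[1, , 1] <- c(6, 6, 0.5, 0.4)
  Y[2, , 2] <- c(0.3, 0.2, 5, 5)
  cs <- ColonySet(Y, colonyId = colonyIds(sim$colonies))
  B <- 2000
  ps <- runMcmc(cs, config = McmcConfig(nIter = B + 100, nBurnin = 100,
                                        seed = 3),
                fixedParams = p)
  exact <- oracleEnumeration(cs, p)
  expect_lt(max(abs(posteriorProb(ps) - exact)), 3 * sqrt(0.25 / B))
  # the package's own enumeration agrees with the independent oracle
  expect_equal(enumeratePosterior(cs, p), exact, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("runMcmc is deterministic given the seed", {
  sim <- simulateReads(8, readLen = 8, params = presetParams("moderate"),
                       seed = 14)
  cfg <- McmcConfig(nIter = 60, nBurnin = 10, seed = 99, batchSize = 5)
  ps1 <- runMcmc(sim$colonies, config = cfg)
  ps2 <- runMcmc(sim$colonies, config = cfg)
  expect_identical(posteriorProb(ps1), posteriorProb(ps2))
  expect_identical(baseCalls(ps1), baseCalls(ps2))
  expect_identical(paramTrace(ps1), paramTrace(ps2))
})

test_that("posterior probabilities are a proper simplex", {
  sim <- simulateReads(10, readLen = 12, params = presetParams("moderate"),
                       seed = 15)
  ps <- runMcmc(sim$colonies, config = McmcConfig(nIter = 80, nBurnin = 20,
                                                  seed = 1))
  xi <- posteriorProb(ps)
  expect_true(all(xi >= 0 & xi <= 1))
  expect_lt(max(abs(apply(xi, c(1, 3), sum) - 1)), 1e-12)
  expect_identical(baseCalls(ps),
                   unname(apply(xi, c(1, 3), which.max)))
  expect_equal(as.vector(maxProb(ps)),
               as.vector(apply(xi, c(1, 3), max)))
})

test_that("noise-free colonies are called perfectly with near-unit probability", {
  p <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03,
                   alpha = 0, beta = 0, Sigma = 1e-6 * diag(4))
  sim <- simulateReads(20, readLen = 12, params = p, seed = 16)
  ps <- runMcmc(sim$colonies, config = McmcConfig(nIter = 120, nBurnin = 20,
                                                  seed = 2))
  expect_identical(baseCalls(ps), trueBases(sim$truth))
  expect_true(all(maxProb(ps) >= 0.99))
})

test_that("zero proposal scale freezes a parameter", {
  sim <- simulateReads(5, readLen = 8, params = presetParams("moderate"),
                       seed = 17)
  cfg <- McmcConfig(nIter = 40, nBurnin = 5, seed = 4,
                    proposalScales = c(mu11 = 0, gPair = 0.3, gEps = 0.3,
                                       alpha = 0, beta = 0.2, lambda = 0.2))
  ps <- runMcmc(sim$colonies, config = cfg)
  tr <- paramTrace(ps)
  init <- phaseCall:::.initParams(phaseCall:::.flattenColonies(sim$colonies))
  expect_true(all(tr$alpha == init@alpha))
  expect_true(all(tr$mu11.A == init@mu11[1]))
  expect_gt(length(unique(tr$beta)), 1)  # others do move
})

test_that("Sigma full conditional matches the conjugate closed form", {
  # clamp scalars (zero proposal scales) and fix k at truth: the Sigma
  # draws are then iid inverse-Wishart and their mean must match
  # (Psi + S) / (df + m - d - 1)
  p <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03,
                   alpha = 0, beta = 0, Sigma = 2 * diag(4))
  truth <- matrix(1L, 6, 30)  # all-A reads: one component gets all rows
  cs <- simulateColonies(truth, p, seed = 18)
  fl <- phaseCall:::.flattenColonies(cs)
  prior <- PriorConfig()
  k <- as.integer(truth)
  M <- phaseCall:::.componentMeanRows(fl, p, 1L)
  S <- crossprod(fl$X - M)
  m <- length(k)
  closedForm <- (prior@iwScale + S) / (prior@iwDf + m - 5)
  cfg <- McmcConfig(proposalScales = c(mu11 = 0, gPair = 0, gEps = 0,
                                       alpha = 0, beta = 0, lambda = 0))
  set.seed(19)
  acc <- matrix(0, 4, 4)
  nSweep <- 2000
  for (s in seq_len(nSweep)) {
    p <- sampleParams(cs, truth, p, prior, cfg)
    acc <- acc + p@Sigma[[1]]
  }
  expect_lt(norm(acc / nSweep - closedForm, "F") / norm(closedForm, "F"),
            0.05)
})

test_that("alpha is recovered as near zero when the data have no phasing", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- R[3, 4] <- R[4, 3] <- 0.5
  p <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03,
                   alpha = 0, beta = 0.05, lambda = 0.5, Sigma = 2.8^2 * R)
  sim <- simulateReads(60, readLen = 36, params = p, seed = 20)
  ps <- runMcmc(sim$colonies, config = McmcConfig(nIter = 250, nBurnin = 50,
                                                  seed = 5))
  expect_lt(mean(paramTrace(ps)$alpha), 0.1)
})

test_that("posterior covers the truth when truncation barely binds", {
  # simulation-based-calibration style rank check in the weak-truncation
  # regime, where the default unnormalized densities coincide with the
  # exact model to high accuracy
  R <- diag(4); R[1, 2] <- R[2, 1] <- R[3, 4] <- R[4, 3] <- 0.5
  # sd 1: the rejection sampler accepts every draw, so the unnormalized
  # component densities coincide with the exact truncated model
  p <- ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03,
                   alpha = 0.3, beta = 0.05, lambda = 0.5, Sigma = R)
  sim <- simulateReads(100, readLen = 36, params = p, seed = 21)
  expect_equal(attr(sim$colonies, "acceptance_rate"), 1)
  ps <- runMcmc(sim$colonies, config = McmcConfig(nIter = 400, nBurnin = 100,
                                                  seed = 6))
  tr <- paramTrace(ps)
  expect_lt(abs(mean(tr$alpha) - 0.3) / 0.3, 0.25)
  expect_lt(abs(mean(tr$mu11.A) - 10) / 10, 0.25)
  rankAlpha <- mean(tr$alpha < 0.3)
  expect_gt(rankAlpha, 0.05)
  expect_lt(rankAlpha, 0.95)
})

test_that("channel relabelling commutes with inference", {
  # swapping A<->C and G<->T in both the data and the parameter
  # convention permutes the posterior the same way
  perm <- c(2L, 1L, 4L, 3L)
  R <- diag(4); R[1, 2] <- R[2, 1] <- R[3, 4] <- R[4, 3] <- 0.5
  # equal leakage fractions so the mean structure is itself symmetric
  # under the pair swap
  p <- ModelParams(mu11 = c(8, 9, 10, 11), gPair = 0.2, gEps1 = 0.04,
                   gEps2 = 0.04, alpha = 0.1, beta = 0.05, lambda = 0.5,
                   Sigma = 2.8^2 * R)
  sim <- simulateReads(6, readLen = 10, params = p, seed = 22)
  Y <- intensities(sim$colonies)
  Yp <- Y[, perm, , drop = FALSE]
  csPerm <- ColonySet(Yp, colonyId = colonyIds(sim$colonies))
  pPerm <- p
  pPerm@mu11 <- p@mu11[perm]; pPerm@gPair <- p@gPair[perm]
  pPerm@gEps1 <- p@gEps1[perm]; pPerm@gEps2 <- p@gEps2[perm]
  pPerm@Sigma <- lapply(perm, function(j) p@Sigma[[j]][perm, perm])
  xi <- enumeratePosterior(sim$colonies, p)
  xiPerm <- enumeratePosterior(csPerm, pPerm)
  expect_equal(xiPerm, xi[, perm, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(runMcmc(list()), "ColonySet")
  expect_error(McmcConfig(nIter = 100, nBurnin = 100), "nBurnin")
  p <- presetParams("moderate")
  sim <- simulateReads(3, readLen = 5, params = p, seed = 23)
  badPrior <- PriorConfig()
  expect_error(PriorConfig(kPrior = c(1, 1, 0, 0)), "summing to 1")
})

test_that("normalized-density mode weighs components by truncation mass", {
  # a tied intensity vector is in two components' supports; including the
  # normalizing masses changes their relative weight, and the sampler
  # must track the normalized enumeration posterior
  # heteroscedastic components: their truncation masses differ, so the
  # two density modes disagree at tied intensities
  p <- ModelParams(mu11 = 2, gPair = 0.3, gEps1 = 0.1, gEps2 = 0.1,
                   alpha = 0, beta = 0,
                   Sigma = list(0.25 * diag(4), 4 * diag(4), diag(4),
                                diag(4)))
  Y <- array(0, c(2, 4, 2))
  Y[1, , 1] <- c(2, 2, 0.1, 0.1)
  Y[2, , 1] <- c(0.2, 0.1, 1.8, 1.8)
  Y[1, , 2] <- c(1.5, 1.5, 1.5, 1.5)
  Y[2, , 2] <- c(2.2, 0.4, 0.3, 0.2)
  cs <- ColonySet(Y)
  exactNorm <- enumeratePosterior(cs, p, normalized = TRUE)
  exactUnnorm <- enumeratePosterior(cs, p, normalized = FALSE)
  expect_gt(max(abs(exactNorm - exactUnnorm)), 1e-4)  # masses matter
  B <- 400
  ps <- runMcmc(cs, config = McmcConfig(nIter = B + 50, nBurnin = 50,
                                        seed = 15,
                                        normalizedDensities = TRUE),
                fixedParams = p)
  expect_lt(max(abs(posteriorProb(ps) - exactNorm)), 3 * sqrt(0.25 / B))
  # single-vector density drops by the log mass when normalized
  y <- c(2, 1, 0.1, 0.1)
  m <- componentMean(1, 1, NULL, p)
  expect_equal(logComponentDensity(y, 1, 1, NULL, p, normalized = TRUE),
               logComponentDensity(y, 1, 1, NULL, p) -
                 log(truncationMass(1, m, p@Sigma[[1]])),
               tolerance = 1e-8)
})
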