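#' @include AllClasses.R model-core.R
NULL

## ---- flattened batch representation -------------------------------------
## Colonies are flattened row-wise (cycle fastest, then colony) so every
## per-sweep computation is a handful of N x 4 matrix operations.

.flattenColonies <- function(colonies) {
  Y <- colonies@intensities
  I <- dim(Y)[1L]; n <- dim(Y)[3L]
  X <- matrix(aperm(Y, c(1L, 3L, 2L)), nrow = I * n, ncol = 4L)
  cyc <- rep.int(seq_len(I), n)
  colony <- rep(seq_len(n), each = I)
  prev <- matrix(0, I * n, 4L)
  if (I > 1L) {
    idx <- which(cyc > 1L)
    prev[idx, ] <- X[idx - 1L, ]
  }
  rowMax <- do.call(pmax, as.data.frame(X))
  truncOk <- X >= rowMax  # N x 4: channel j maximal
  list(X = X, prev = prev, cyc = cyc, colony = colony, truncOk = truncOk,
       I = I, n = n, N = I * n, colonyId = colonies@colonyId)
}

## Conditional mean rows for component j (decay * mu_j + alpha * prev).
.componentMeanRows <- function(fl, params, j, rows = NULL, decay = NULL) {
  if (is.null(decay))
    decay <- decayFactor(seq_len(fl$I), params@beta, params@lambda)
  mu <- buildMu(j, params@mu11[j], params@gPair[j], params@gEps1[j],
                params@gEps2[j])
  if (is.null(rows)) {
    tcrossprod(decay[fl$cyc], mu) + params@alpha * fl$prev
  } else {
    tcrossprod(decay[fl$cyc[rows]], mu) +
      params@alpha * fl$prev[rows, , drop = FALSE]
  }
}

## log truncation masses for rows under component j (normalized mode only).
.logMassRows <- function(M, Sigma, j) {
  vapply(seq_len(nrow(M)), function(r)
    log(truncationMass(j, M[r, ], Sigma)), 0)
}

## N x 4 matrix of component log densities (with truncation -Inf).
.componentLogLikMatrix <- function(fl, params, normalized = FALSE) {
  W <- matrix(-Inf, fl$N, 4L)
  decay <- decayFactor(seq_len(fl$I), params@beta, params@lambda)
  for (j in 1:4) {
    ok <- fl$truncOk[, j]
    if (!any(ok)) next
    rows <- which(ok)
    M <- .componentMeanRows(fl, params, j, rows, decay)
    ld <- .mvnLogDensityResid(fl$X[rows, , drop = FALSE] - M,
                              params@Sigma[[j]])
    if (normalized)
      ld <- ld - .logMassRows(M, params@Sigma[[j]], j)
    W[rows, j] <- ld
  }
  W
}

## Log likelihood of a row subset under the current assignment k.
.loglikRows <- function(fl, params, k, rows = NULL, normalized = FALSE) {
  if (is.null(rows)) rows <- seq_len(fl$N)
  total <- 0
  decay <- decayFactor(seq_len(fl$I), params@beta, params@lambda)
  for (j in 1:4) {
    rj <- rows[k[rows] == j]
    if (length(rj) == 0L) next
    M <- .componentMeanRows(fl, params, j, rj, decay)
    ld <- .mvnLogDensityResid(fl$X[rj, , drop = FALSE] - M,
                              params@Sigma[[j]])
    if (normalized)
      ld <- ld - .logMassRows(M, params@Sigma[[j]], j)
    total <- total + sum(ld)
  }
  total
}

## ---- categorical sampling ------------------------------------------------
## Gumbel-max draw per row of a matrix of (unnormalized) log weights.
.sampleCategoricalRows <- function(logW) {
  G <- matrix(-log(-log(stats::runif(length(logW)))), nrow(logW), ncol(logW))
  max.col(logW + G, ties.method = "first")
}

.sampleKInternal <- function(fl, params, prior, normalized = FALSE) {
  W <- .componentLogLikMatrix(fl, params, normalized)
  W <- sweep(W, 2L, log(prior@kPrior), "+")
  bad <- !is.finite(do.call(pmax, as.data.frame(W)))
  if (any(bad)) {
    r <- which(bad)[1L]
    stop(sprintf(
      "all four component weights vanish at cycle %d of colony '%s'",
      fl$cyc[r], fl$colonyId[fl$colony[r]]))
  }
  .sampleCategoricalRows(W)
}

#' Draw latent true-base indicators from their full conditional
#'
#' Conditional on the global parameters and the observed previous-cycle
#' intensities, the cycles decouple: each latent indicator is drawn from
#' the categorical distribution proportional to the k prior times the
#' (truncated) component density at that cycle. Components whose
#' truncation region excludes the observed intensity get zero weight.
#'
#' @param colonies a [ColonySet-class].
#' @param params a [ModelParams-class].
#' @param prior a [PriorConfig-class].
#' @param normalized use truncation-normalized component densities.
#' @return Integer matrix I x n of sampled base indices.
#' @export
sampleK <- function(colonies, params, prior = PriorConfig(),
                    normalized = FALSE) {
  fl <- .flattenColonies(colonies)
  k <- .sampleKInternal(fl, params, prior, normalized)
  matrix(k, fl$I, fl$n)
}

## ---- parameter updates ---------------------------------------------------

.rinvwishart <- function(df, scale) {
  W <- stats::rWishart(1L, df, chol2inv(chol(scale)))[, , 1L]
  S <- chol2inv(chol(W))
  (S + t(S)) / 2
}

## One conjugate inverse-Wishart draw per component covariance.
.updateSigma <- function(fl, params, k, prior) {
  decay <- decayFactor(seq_len(fl$I), params@beta, params@lambda)
  for (j in 1:4) {
    rows <- which(k == j)
    if (length(rows) > 0L) {
      M <- .componentMeanRows(fl, params, j, rows, decay)
      R <- fl$X[rows, , drop = FALSE] - M
      scalePost <- prior@iwScale + crossprod(R)
      dfPost <- prior@iwDf + length(rows)
    } else {
      scalePost <- prior@iwScale
      dfPost <- prior@iwDf
    }
    params@Sigma[[j]] <- .rinvwishart(dfPost, scalePost)
  }
  params
}

## Scalar parameter table: slot, per-class or global, transform, prior.
.SCALAR_UPDATES <- list(
  list(slot = "mu11", class = TRUE, transform = "log", scale = "mu11"),
  list(slot = "gPair", class = TRUE, transform = "logit", scale = "gPair"),
  list(slot = "gEps1", class = TRUE, transform = "logit", scale = "gEps"),
  list(slot = "gEps2", class = TRUE, transform = "logit", scale = "gEps"),
  list(slot = "alpha", class = FALSE, transform = "logit", scale = "alpha"),
  list(slot = "beta", class = FALSE, transform = "logit", scale = "beta"),
  list(slot = "lambda", class = FALSE, transform = "logit", scale = "lambda")
)

## Log prior term (plus log transform Jacobian) for one scalar.
.scalarLogPriorJac <- function(slotName, value, prior) {
  switch(slotName,
    mu11 = stats::dlnorm(value, 0, prior@mu11LogSd, log = TRUE) + log(value),
    gPair = stats::dbeta(value, prior@gPairPrior[1L], prior@gPairPrior[2L],
                         log = TRUE) + log(value) + log1p(-value),
    gEps1 = ,
    gEps2 = stats::dbeta(value, prior@gEpsPrior[1L], prior@gEpsPrior[2L],
                         log = TRUE) + log(value) + log1p(-value),
    stats::dbeta(value, prior@ablPrior[1L], prior@ablPrior[2L],
                 log = TRUE) + log(value) + log1p(-value))
}

.proposeScalar <- function(value, transform, step) {
  if (transform == "log") exp(log(value) + stats::rnorm(1L, 0, step))
  else stats::plogis(stats::qlogis(value) + stats::rnorm(1L, 0, step))
}

## Metropolis update of one scalar; rows limited to the affected subset.
.mhScalar <- function(fl, params, k, prior, upd, j = NULL, step,
                      normalized = FALSE) {
  if (step == 0) return(params)  # degenerate proposal: state unchanged
  slotName <- upd$slot
  cur <- if (upd$class) slot(params, slotName)[j] else slot(params, slotName)
  prop <- .proposeScalar(cur, upd$transform, step)
  if (prop <= 0 || (upd$transform == "logit" && prop >= 1))
    return(params)
  newParams <- params
  if (upd$class) {
    v <- slot(newParams, slotName); v[j] <- prop
    slot(newParams, slotName) <- v
  } else {
    slot(newParams, slotName) <- prop
  }
  rows <- if (upd$class) which(k == j) else NULL
  llCur <- .loglikRows(fl, params, k, rows, normalized)
  llNew <- .loglikRows(fl, newParams, k, rows, normalized)
  if (!is.finite(llCur))
    stop("non-finite log posterior at current state (slot '", slotName, "')")
  logRatio <- (llNew + .scalarLogPriorJac(slotName, prop, prior)) -
    (llCur + .scalarLogPriorJac(slotName, cur, prior))
  if (is.finite(logRatio) && log(stats::runif(1L)) < logRatio) newParams
  else params
}

.sampleParamsInternal <- function(fl, k, params, prior, config) {
  normalized <- config@normalizedDensities
  params <- .updateSigma(fl, params, k, prior)
  ps <- config@proposalScales
  for (upd in .SCALAR_UPDATES) {
    step <- ps[[upd$scale]]
    if (upd$class) {
      for (j in 1:4)
        params <- .mhScalar(fl, params, k, prior, upd, j, step, normalized)
    } else {
      params <- .mhScalar(fl, params, k, prior, upd, NULL, step, normalized)
    }
  }
  params
}

#' One sweep of global-parameter updates
#'
#' Performs a single update sweep given the current latent base
#' indicators: each component covariance by its conjugate inverse-Wishart
#' full-conditional draw (exact under unnormalized component densities),
#' then each scalar parameter (per-class mean structure, then alpha,
#' beta, lambda) by one random-walk Metropolis proposal on a transformed
#' scale (log for the bright-channel means, logit for unit-interval
#' parameters).
#'
#' @param colonies a [ColonySet-class].
#' @param k integer matrix I x n of current latent base indicators.
#' @param params current [ModelParams-class].
#' @param prior a [PriorConfig-class].
#' @param config an [McmcConfig-class] (proposal scales and density mode).
#' @return The updated [ModelParams-class].
#' @export
sampleParams <- function(colonies, k, params, prior = PriorConfig(),
                         config = McmcConfig()) {
  fl <- .flattenColonies(colonies)
  .sampleParamsInternal(fl, as.integer(k), params, prior, config)
}

## ---- initialization (argmax-based, starts near the posterior mode) ------

.initParams <- function(fl) {
  early <- fl$cyc <= min(5L, fl$I)
  m <- mean(apply(fl$X[early, , drop = FALSE], 1L, max))
  ModelParams(mu11 = max(m, 1e-3), gPair = 0.3, gEps1 = 0.1, gEps2 = 0.1,
              alpha = 0.1, beta = 0.1, lambda = 0.5, Sigma = diag(4))
}

.traceRow <- function(batch, sweep, params) {
  row <- c(batch = batch, sweep = sweep, alpha = params@alpha,
           beta = params@beta, lambda = params@lambda,
           stats::setNames(params@mu11, paste0("mu11.", .CHANNELS)),
           stats::setNames(params@gPair, paste0("gPair.", .CHANNELS)),
           stats::setNames(params@gEps1, paste0("gEps1.", .CHANNELS)),
           stats::setNames(params@gEps2, paste0("gEps2.", .CHANNELS)))
  as.data.frame(as.list(row))
}

#' Run the MCMC base caller
#'
#' Splits the colonies into batches of `batchSize`, runs one independent
#' chain per batch (each chain's RNG stream is derived from the seed and
#' the batch index, so results do not depend on scheduling), and within
#' each sweep draws the latent base indicators first, then the component
#' covariances, then the scalar parameters. After discarding the burn-in,
#' the posterior base probability `xi[i, j, c]` is the Monte-Carlo
#' frequency of indicator j among the B = nIter - nBurnin retained sweeps.
#'
#' With `fixedParams` supplied, the global-parameter updates are skipped
#' and the chain samples the indicators conditional on those parameters —
#' useful for validating the sampler against the exact per-cycle
#' enumeration posterior ([enumeratePosterior()]).
#'
#' @param colonies a [ColonySet-class] (all colonies share one read
#'   length by construction).
#' @param prior a [PriorConfig-class].
#' @param config an [McmcConfig-class].
#' @param fixedParams optional [ModelParams-class]; clamp the global
#'   parameters instead of sampling them.
#' @return A [PosteriorSummary-class].
#' @export
#' @examples
#' sim <- simulateReads(5, readLen = 8, params = presetParams("clean"),
#'                      seed = 1)
#' ps <- runMcmc(sim$colonies, config = McmcConfig(nIter = 50, nBurnin = 10,
#'                                                 seed = 1))
#' baseCalls(ps)[, 1]
runMcmc <- function(colonies, prior = PriorConfig(), config = McmcConfig(),
                    fixedParams = NULL) {
  if (!is(colonies, "ColonySet") || nColonies(colonies) == 0L)
    stop("'colonies' must be a non-empty ColonySet")
  n <- nColonies(colonies)
  I <- nCycles(colonies)
  B <- config@nIter - config@nBurnin
  batches <- split(seq_len(n), ceiling(seq_len(n) / config@batchSize))
  xi <- array(0, dim = c(I, 4L, n),
              dimnames = list(NULL, .CHANNELS, NULL))
  traces <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    fl <- .flattenColonies(colonies[idx])
    set.seed((config@seed + 7919L * (b - 1L)) %% 2147483647L)
    params <- if (is.null(fixedParams)) .initParams(fl) else fixedParams
    counts <- matrix(0L, fl$N, 4L)
    btrace <- vector("list", B)
    for (it in seq_len(config@nIter)) {
      k <- .sampleKInternal(fl, params, prior, config@normalizedDensities)
      if (is.null(fixedParams))
        params <- .sampleParamsInternal(fl, k, params, prior, config)
      if (it > config@nBurnin) {
        counts[cbind(seq_len(fl$N), k)] <- counts[cbind(seq_len(fl$N), k)] + 1L
        btrace[[it - config@nBurnin]] <- .traceRow(b, it, params)
      }
    }
    xi[, , idx] <- aperm(array(counts / B, dim = c(fl$I, fl$n, 4L)),
                         c(1L, 3L, 2L))
    traces[[b]] <- do.call(rbind, btrace)
  }
  .summarizePosterior(xi, colonies@colonyId, do.call(rbind, traces))
}

.summarizePosterior <- function(xi, colonyId, trace) {
  I <- dim(xi)[1L]; n <- dim(xi)[3L]
  call <- matrix(0L, I, n)
  maxp <- matrix(0, I, n)
  amb <- matrix(FALSE, I, n)
  for (c in seq_len(n)) {
    m <- xi[, , c, drop = FALSE][, , 1L]
    if (I == 1L) m <- matrix(m, 1L, 4L)
    mx <- do.call(pmax, as.data.frame(m))
    call[, c] <- max.col(m, ties.method = "first")
    maxp[, c] <- mx
    amb[, c] <- rowSums(m == mx) > 1L
  }
  new("PosteriorSummary", xi = xi, call = call, maxProb = maxp,
      ambiguous = amb, colonyId = colonyId,
      trace = if (is.null(trace)) data.frame() else trace)
}

#' Exact per-cycle posterior over the true base, given parameters
#'
#' Enumerates the four component weights (k prior times truncated
#' component density) at every cycle of every colony and normalizes —
#' the exact conditional posterior the MCMC indicator frequencies
#' converge to when the global parameters are clamped.
#'
#' @inheritParams sampleK
#' @return Numeric array I x 4 x n of exact posterior probabilities.
#' @export
enumeratePosterior <- function(colonies, params, prior = PriorConfig(),
                               normalized = FALSE) {
  fl <- .flattenColonies(colonies)
  W <- .componentLogLikMatrix(fl, params, normalized)
  W <- sweep(W, 2L, log(prior@kPrior), "+")
  mx <- do.call(pmax, as.data.frame(W))
  if (any(!is.finite(mx)))
    stop("all four component weights vanish at some cycle")
  P <- exp(W - mx)
  P <- P / rowSums(P)
  aperm(array(P, dim = c(fl$I, fl$n, 4L)), c(1L, 3L, 2L))
}
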