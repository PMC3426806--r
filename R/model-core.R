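#' @include AllClasses.R
NULL

## ---- component mean structure -------------------------------------------

#' Component mean vector for a true base class
#'
#' Builds the 4-channel mean intensity vector for the mixture component in
#' which the true base is j. The bright channel (j itself) carries `mu11`;
#' its cross-talk partner (A pairs with C, G with T) carries
#' `gPair * mu11`; the two channels of the opposite pair carry
#' `gEps1 * mu11` and `gEps2 * mu11` (in ascending channel order). Since
#' all fractions lie in \[0, 1\], the bright channel dominates its partner
#' by construction.
#'
#' @param j true base index in 1..4 (A, C, G, T).
#' @param mu11 positive bright-channel mean.
#' @param gPair cross-talk fraction into the paired channel, in \[0, 1\].
#' @param gEps1,gEps2 leakage fractions for the opposite channel pair, in
#'   \[0, 1\].
#' @return Nonnegative numeric 4-vector of channel means.
#' @export
#' @examples
#' buildMu(1, 10, 0.2, 0.05, 0.03)  # (10, 2, 0.5, 0.3)
#' buildMu(3, 10, 0.2, 0.05, 0.03)  # (0.5, 0.3, 10, 2)
buildMu <- function(j, mu11, gPair, gEps1, gEps2) {
  if (length(j) != 1L || !(j %in% 1:4))
    stop("'j' must be a single base index in 1..4")
  if (!is.finite(mu11) || mu11 <= 0)
    stop("'mu11' must be a positive finite number")
  for (g in c(gPair, gEps1, gEps2))
    if (!is.finite(g) || g < 0 || g > 1)
      stop("cross-talk and leakage fractions must lie in [0, 1]")
  mu <- numeric(4L)
  mu[j] <- mu11
  mu[.PARTNER[j]] <- gPair * mu11
  leak <- sort(setdiff(1:4, c(j, .PARTNER[j])))
  mu[leak] <- c(gEps1, gEps2) * mu11
  mu
}

## All four component mean vectors as a 4 x 4 matrix (row j = class j).
.muMatrix <- function(params) {
  t(vapply(1:4, function(j)
    buildMu(j, params@mu11[j], params@gPair[j], params@gEps1[j],
            params@gEps2[j]), numeric(4L)))
}

#' Fading decay factor
#'
#' The mean signal decays across cycles as `exp(-beta * i^lambda)`,
#' modelling material loss over the sequencing run. It equals 1 for every
#' cycle when `beta = 0` and is strictly decreasing in i otherwise.
#'
#' @param i cycle index (>= 1); vectorized.
#' @param beta fading rate in \[0, 1\].
#' @param lambda fading exponent in \[0, 1\].
#' @return Decay multiplier(s) in (0, 1\].
#' @export
#' @examples
#' decayFactor(36, beta = 0.1, lambda = 0.5)  # exp(-0.6)
decayFactor <- function(i, beta, lambda) {
  if (any(i < 1)) stop("cycle index 'i' must be >= 1")
  if (beta < 0 || beta > 1 || lambda < 0 || lambda > 1)
    stop("'beta' and 'lambda' must lie in [0, 1]")
  exp(-beta * i^lambda)
}

#' Conditional mean of the intensity vector at one cycle
#'
#' Combines fading and phasing: `decayFactor(i) * mu_j` plus, from cycle 2
#' on, the autoregressive carry-over `alpha * yPrev` from the previous
#' cycle's observed intensities. Cycle 1 has no carry-over term.
#'
#' @param j true base index in 1..4.
#' @param i cycle index (>= 1).
#' @param yPrev previous cycle's intensity 4-vector; must be NULL at
#'   i = 1 and present for i >= 2.
#' @param params a [ModelParams-class].
#' @return Numeric 4-vector.
#' @export
componentMean <- function(j, i, yPrev = NULL, params) {
  if (i >= 2 && is.null(yPrev))
    stop("'yPrev' is required for cycles i >= 2")
  mu <- buildMu(j, params@mu11[j], params@gPair[j], params@gEps1[j],
                params@gEps2[j])
  m <- decayFactor(i, params@beta, params@lambda) * mu
  if (i >= 2) m <- m + params@alpha * yPrev
  m
}

#' Truncation-region indicator
#'
#' Component j of the mixture is supported on the region where channel j
#' carries the (non-strictly) largest intensity — the prior belief that
#' the true base fluoresces brightest. Ties count as inside the region.
#'
#' @param y intensity 4-vector (finite).
#' @param j candidate base index in 1..4.
#' @return TRUE iff `y[j] >= y[m]` for all m.
#' @export
#' @examples
#' truncationOk(c(5, 1, 0, 0), 1)  # TRUE
#' truncationOk(c(5, 1, 0, 0), 2)  # FALSE
truncationOk <- function(y, j) {
  if (length(j) != 1L || !(j %in% 1:4))
    stop("'j' must be a single base index in 1..4")
  if (length(y) != 4L || any(!is.finite(y)))
    stop("'y' must be a finite 4-vector")
  y[j] >= max(y)
}

## ---- multivariate normal machinery --------------------------------------

## Cholesky-based MVN log density for a matrix of residuals (rows = obs).
## Returns one value per row; errors on (numerically) singular Sigma.
.mvnLogDensityResid <- function(R, Sigma) {
  U <- tryCatch(chol(Sigma), error = function(e)
    stop("singular or non-PD covariance matrix in component density: ",
         conditionMessage(e)))
  V <- R %*% backsolve(U, diag(4L))
  -0.5 * rowSums(V * V) - sum(log(diag(U))) - 2 * log(2 * pi)
}

#' Probability mass of a truncation region under a multivariate normal
#'
#' Computes P(Y_j >= Y_m for all m) for Y ~ MVN4(mean, Sigma) — the
#' normalizing constant of truncated component j — by reducing to a
#' 3-dimensional orthant probability over the channel differences, which
#' is evaluated with quasi-Monte-Carlo integration (Genz-Bretz) under a
#' locally fixed RNG state so repeated calls agree.
#'
#' @param j base index in 1..4.
#' @param mean numeric 4-vector.
#' @param Sigma 4 x 4 covariance matrix.
#' @param abseps absolute integration tolerance (default 1e-3).
#' @return Probability in \[0, 1\].
#' @export
truncationMass <- function(j, mean, Sigma, abseps = 1e-3) {
  D <- matrix(0, 3L, 4L)
  others <- setdiff(1:4, j)
  for (r in seq_len(3L)) {
    D[r, others[r]] <- 1
    D[r, j] <- -1
  }
  md <- as.numeric(D %*% mean)
  Sd <- D %*% Sigma %*% t(D)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(71L)
  p <- mvtnorm::pmvnorm(lower = rep(-Inf, 3L), upper = rep(0, 3L),
                        mean = md, sigma = Sd,
                        algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                       maxpts = 50000L))
  min(max(as.numeric(p), 0), 1)
}

#' Log density of one truncated mixture component
#'
#' Evaluates the log density of the intensity 4-vector `y` under mixture
#' component j at cycle i: `-Inf` outside the truncation region (channel j
#' not maximal), otherwise the MVN4 log density at mean
#' [componentMean()] with covariance `Sigma[[j]]`. With
#' `normalized = TRUE` the log of the truncation-region mass is
#' subtracted so the density integrates to 1 over the region; the
#' unnormalized form is the default used in the latent-base update.
#'
#' @param y intensity 4-vector.
#' @inheritParams componentMean
#' @param normalized divide by the truncation-region mass (default FALSE).
#' @return Log density (possibly `-Inf`).
#' @export
logComponentDensity <- function(y, j, i, yPrev = NULL, params,
                                normalized = FALSE) {
  if (!truncationOk(y, j)) return(-Inf)
  m <- componentMean(j, i, yPrev, params)
  ld <- .mvnLogDensityResid(matrix(y - m, 1L, 4L), params@Sigma[[j]])
  if (normalized) {
    Z <- truncationMass(j, m, params@Sigma[[j]])
    ld <- ld - log(Z)
  }
  as.numeric(ld)
}

## ---- priors --------------------------------------------------------------

## log multivariate gamma function, dimension d
.lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## Inverse-Wishart log density at X with scale Psi, df nu (dimension 4).
.logDinvWishart <- function(X, Psi, nu) {
  d <- 4L
  cX <- tryCatch(chol(X), error = function(e) NULL)
  if (is.null(cX)) return(-Inf)
  ldetX <- 2 * sum(log(diag(cX)))
  ldetPsi <- 2 * sum(log(diag(chol(Psi))))
  trTerm <- sum(diag(Psi %*% chol2inv(cX)))
  (nu / 2) * ldetPsi - (nu * d / 2) * log(2) - .lmvgamma(nu / 2, d) -
    ((nu + d + 1) / 2) * ldetX - trTerm / 2
}

#' Joint log prior density of the model parameters
#'
#' Sums the log prior over every global parameter: log-normal on each
#' bright-channel mean, beta on the cross-talk/leakage fractions and on
#' alpha, beta, lambda, and inverse-Wishart on each component covariance.
#' Parameters outside the support return `-Inf` rather than erroring.
#'
#' @param params a [ModelParams-class].
#' @param prior a [PriorConfig-class].
#' @return Log prior density (possibly `-Inf`).
#' @export
logPrior <- function(params, prior = PriorConfig()) {
  lp <- 0
  if (any(params@mu11 <= 0)) return(-Inf)
  lp <- lp + sum(stats::dlnorm(params@mu11, 0, prior@mu11LogSd, log = TRUE))
  lp <- lp + sum(stats::dbeta(params@gPair, prior@gPairPrior[1L],
                              prior@gPairPrior[2L], log = TRUE))
  lp <- lp + sum(stats::dbeta(c(params@gEps1, params@gEps2),
                              prior@gEpsPrior[1L], prior@gEpsPrior[2L],
                              log = TRUE))
  lp <- lp + sum(stats::dbeta(c(params@alpha, params@beta, params@lambda),
                              prior@ablPrior[1L], prior@ablPrior[2L],
                              log = TRUE))
  for (j in 1:4)
    lp <- lp + .logDinvWishart(params@Sigma[[j]], prior@iwScale, prior@iwDf)
  if (is.nan(lp)) -Inf else lp
}
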