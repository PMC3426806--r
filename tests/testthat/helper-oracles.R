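## Independent oracles used across the suite. These deliberately avoid the
## package's flattened/Cholesky code paths: densities come from
## mvtnorm::dmvnorm and the model is written out directly from its
## definition.

## Exact per-cycle posterior over the true base given fixed parameters:
## enumerate the four component weights at every cycle and normalize.
oracleEnumeration <- function(colonies, params, kPrior = rep(0.25, 4)) {
  Y <- intensities(colonies)
  I <- dim(Y)[1L]; n <- dim(Y)[3L]
  mu <- t(sapply(1:4, function(j)
    buildMu(j, params@mu11[j], params@gPair[j], params@gEps1[j],
            params@gEps2[j])))
  xi <- array(0, c(I, 4L, n))
  for (c in seq_len(n)) {
    for (i in seq_len(I)) {
      y <- Y[i, , c]
      w <- vapply(1:4, function(j) {
        if (y[j] < max(y)) return(0)
        m <- exp(-params@beta * i^params@lambda) * mu[j, ]
        if (i > 1) m <- m + params@alpha * Y[i - 1, , c]
        kPrior[j] * mvtnorm::dmvnorm(y, m, params@Sigma[[j]])
      }, 0)
      xi[i, , c] <- w / sum(w)
    }
  }
  xi
}

## Small parameter set in which ties across a channel pair are easy to
## construct: all four component means coincide, shared covariance.
symmetricParams <- function(sigma = diag(4)) {
  ModelParams(mu11 = 1, gPair = 1, gEps1 = 1, gEps2 = 1,
              alpha = 0, beta = 0, lambda = 0.5, Sigma = sigma)
}

## Build a PosteriorSummary directly from a xi array (tests of the
## call/FDR layer that do not need an MCMC run).
posteriorFromXi <- function(xi, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("1:1:%d:1", seq_len(dim(xi)[3L]))
  phaseCall:::.summarizePosterior(xi, ids, data.frame())
}

## Random xi arrays on the simplex (rows of independent gamma draws).
randomXi <- function(I, n, concentration = 1) {
  x <- array(rgamma(I * 4 * n, concentration), c(I, 4L, n))
  sweep(x, c(1, 3), apply(x, c(1, 3), sum), "/")
}
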