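#' @import methods
NULL

## Fixed channel convention: columns 1..4 are A, C, G, T everywhere.
## Cross-talk pairs the A-C and G-T channels.
.CHANNELS <- c("A", "C", "G", "T")
.PARTNER <- c(2L, 1L, 4L, 3L)

#' Channel order used throughout the package
#'
#' Intensity columns, base indices and posterior probability slices are
#' always ordered A, C, G, T (indices 1 to 4). Fluorophore cross-talk
#' couples the A-C pair and the G-T pair.
#'
#' @return Character vector `c("A", "C", "G", "T")`.
#' @export
#' @examples
#' channelOrder()
channelOrder <- function() .CHANNELS

#' ColonySet: per-colony cycle-by-channel intensity matrices
#'
#' Container for a set of colonies (amplified DNA clusters, one short read
#' each). Each colony carries an I x 4 matrix of fluorescence intensities,
#' one row per sequencing cycle and one column per channel in the fixed
#' order A, C, G, T. All colonies in a set share the same read length I.
#'
#' @slot intensities numeric array of dimension I x 4 x n (cycles x
#'   channels x colonies), arbitrary fluorescence units (normalized units
#'   after [normalizeIntensities()]).
#' @slot colonyId character vector of length n; unique colony identifiers,
#'   conventionally `lane:tile:x:y`.
#' @slot metadata data.frame with n rows of optional per-colony metadata
#'   (integer columns lane, tile, x, y when read from an intensity file).
#'
#' @seealso [readIntensityFile()], [simulateColonies()]
#' @export
setClass("ColonySet",
  representation(
    intensities = "array",
    colonyId = "character",
    metadata = "data.frame"
  )
)

setValidity("ColonySet", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L)
    return("'intensities' must be a 3-d array (cycles x channels x colonies)")
  if (d[2L] != 4L)
    return("'intensities' must have exactly 4 channel columns (A, C, G, T)")
  if (d[1L] < 1L)
    return("at least one cycle required")
  if (!all(is.finite(object@intensities)))
    return("all intensities must be finite")
  if (length(object@colonyId) != d[3L])
    return("length(colonyId) must equal the number of colonies")
  if (anyDuplicated(object@colonyId))
    return("colony identifiers must be unique")
  if (nrow(object@metadata) > 0L && nrow(object@metadata) != d[3L])
    return("metadata must have one row per colony (or zero rows)")
  TRUE
})

#' Construct a ColonySet
#'
#' @param intensities I x 4 x n array, or an I x 4 matrix for a single
#'   colony.
#' @param colonyId character vector of colony identifiers; generated as
#'   `colony_1 .. colony_n` when omitted.
#' @param metadata optional data.frame of per-colony metadata.
#' @return A [ColonySet-class] object.
#' @export
#' @examples
#' y <- matrix(c(10, 2, 0.5, 0.3, 9, 1.8, 0.4, 0.2), 2, 4, byrow = TRUE)
#' ColonySet(y)
ColonySet <- function(intensities, colonyId = NULL, metadata = NULL) {
  if (is.matrix(intensities))
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  if (is.null(colonyId))
    colonyId <- paste0("colony_", seq_len(dim(intensities)[3L]))
  if (is.null(metadata))
    metadata <- data.frame()
  dimnames(intensities) <- list(NULL, .CHANNELS, NULL)
  new("ColonySet", intensities = intensities, colonyId = as.character(colonyId),
      metadata = metadata)
}

#' ModelParams: global parameters of the intensity model
#'
#' Holds the full parameter state of the truncated multivariate-normal
#' mixture: per-base-class channel mean structure, the phasing and fading
#' coefficients, and the per-component noise covariances.
#'
#' For true base class j the component mean vector is built from four
#' numbers (see [buildMu()]): the bright-channel intensity `mu11[j]`, the
#' cross-talk fraction `gPair[j]` into the paired channel (A-C or G-T),
#' and two leakage fractions `gEps1[j]`, `gEps2[j]` for the opposite
#' channel pair. Fading multiplies the mean by `exp(-beta * i^lambda)` at
#' cycle i; phasing adds `alpha` times the previous cycle's intensity
#' vector.
#'
#' @slot mu11 numeric(4), bright-channel mean per base class, positive.
#' @slot gPair numeric(4) in \[0, 1\], paired-channel cross-talk fraction.
#' @slot gEps1,gEps2 numeric(4) in \[0, 1\], leakage fractions for the two
#'   opposite-pair channels (in ascending channel order).
#' @slot alpha numeric(1) in \[0, 1\], phasing carry-over coefficient.
#' @slot beta numeric(1) in \[0, 1\], fading rate.
#' @slot lambda numeric(1) in \[0, 1\], fading exponent.
#' @slot Sigma list of four 4 x 4 symmetric positive-definite covariance
#'   matrices, one per base class.
#' @export
setClass("ModelParams",
  representation(
    mu11 = "numeric",
    gPair = "numeric",
    gEps1 = "numeric",
    gEps2 = "numeric",
    alpha = "numeric",
    beta = "numeric",
    lambda = "numeric",
    Sigma = "list"
  )
)

.checkUnit <- function(x, nm, n = 4L) {
  if (length(x) != n) return(sprintf("'%s' must have length %d", nm, n))
  if (any(!is.finite(x) | x < 0 | x > 1))
    return(sprintf("'%s' must lie in [0, 1]", nm))
  NULL
}

setValidity("ModelParams", function(object) {
  if (length(object@mu11) != 4L || any(!is.finite(object@mu11)) ||
      any(object@mu11 <= 0))
    return("'mu11' must be 4 positive finite values")
  for (nm in c("gPair", "gEps1", "gEps2")) {
    msg <- .checkUnit(slot(object, nm), nm)
    if (!is.null(msg)) return(msg)
  }
  for (nm in c("alpha", "beta", "lambda")) {
    msg <- .checkUnit(slot(object, nm), nm, 1L)
    if (!is.null(msg)) return(msg)
  }
  if (length(object@Sigma) != 4L)
    return("'Sigma' must be a list of 4 covariance matrices")
  for (j in 1:4) {
    S <- object@Sigma[[j]]
    if (!is.matrix(S) || !identical(dim(S), c(4L, 4L)))
      return("each Sigma[[j]] must be a 4 x 4 matrix")
    if (!isSymmetric(unname(S), tol = 1e-8))
      return(sprintf("Sigma[[%d]] is not symmetric", j))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      return(sprintf("Sigma[[%d]] is not positive definite", j))
  }
  TRUE
})

#' Construct ModelParams
#'
#' Scalar values for `mu11`, `gPair`, `gEps1`, `gEps2` are recycled across
#' the four base classes; a single matrix for `Sigma` is recycled across
#' components.
#'
#' @param mu11,gPair,gEps1,gEps2 per-base-class mean structure (length 1
#'   or 4); see [ModelParams-class].
#' @param alpha,beta,lambda phasing, fading rate and fading exponent, each
#'   in \[0, 1\].
#' @param Sigma a 4 x 4 covariance matrix or a list of four of them.
#' @return A [ModelParams-class] object.
#' @export
#' @examples
#' ModelParams(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03)
ModelParams <- function(mu11 = 10, gPair = 0.2, gEps1 = 0.05, gEps2 = 0.03,
                        alpha = 0, beta = 0, lambda = 0.5,
                        Sigma = diag(4)) {
  if (is.matrix(Sigma)) Sigma <- list(Sigma, Sigma, Sigma, Sigma)
  new("ModelParams",
      mu11 = rep_len(as.numeric(mu11), 4L),
      gPair = rep_len(as.numeric(gPair), 4L),
      gEps1 = rep_len(as.numeric(gEps1), 4L),
      gEps2 = rep_len(as.numeric(gEps2), 4L),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      lambda = as.numeric(lambda),
      Sigma = lapply(Sigma, function(S) {
        S <- unname(as.matrix(S)); (S + t(S)) / 2
      }))
}

#' PriorConfig: prior hyperparameters
#'
#' Priors follow the hierarchical model: log-normal(0, `mu11LogSd`) on
#' each bright-channel mean, beta(`gPairPrior`) on the paired cross-talk
#' fractions, beta(`gEpsPrior`) (default beta(2, 10), concentrating near
#' zero) on the leakage fractions, beta(`ablPrior`) on alpha, beta and
#' lambda, inverse Wishart(`iwScale`, `iwDf`) on each component
#' covariance, and a categorical prior `kPrior` (default uniform 1/4) on
#' the latent true-base indicators.
#'
#' @slot mu11LogSd positive scale of the log-normal prior (default 1).
#' @slot gPairPrior,gEpsPrior,ablPrior length-2 positive beta shapes.
#' @slot iwScale 4 x 4 SPD inverse-Wishart scale matrix (default identity).
#' @slot iwDf inverse-Wishart degrees of freedom, > 3 (default 6).
#' @slot kPrior probability 4-vector over true bases, sums to 1.
#' @export
setClass("PriorConfig",
  representation(
    mu11LogSd = "numeric",
    gPairPrior = "numeric",
    gEpsPrior = "numeric",
    ablPrior = "numeric",
    iwScale = "matrix",
    iwDf = "numeric",
    kPrior = "numeric"
  )
)

setValidity("PriorConfig", function(object) {
  if (object@mu11LogSd <= 0) return("'mu11LogSd' must be positive")
  for (nm in c("gPairPrior", "gEpsPrior", "ablPrior")) {
    p <- slot(object, nm)
    if (length(p) != 2L || any(p <= 0))
      return(sprintf("'%s' must be two positive beta shapes", nm))
  }
  if (!identical(dim(object@iwScale), c(4L, 4L)))
    return("'iwScale' must be 4 x 4")
  ev <- eigen((object@iwScale + t(object@iwScale)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) return("'iwScale' must be positive definite")
  if (object@iwDf <= 3) return("'iwDf' must exceed dimension - 1 = 3")
  if (length(object@kPrior) != 4L || any(object@kPrior < 0) ||
      abs(sum(object@kPrior) - 1) > 1e-8)
    return("'kPrior' must be 4 probabilities summing to 1")
  TRUE
})

#' @rdname PriorConfig-class
#' @param mu11LogSd,gPairPrior,gEpsPrior,ablPrior,iwScale,iwDf,kPrior see
#'   the corresponding slots.
#' @return A [PriorConfig-class] object.
#' @export
PriorConfig <- function(mu11LogSd = 1, gPairPrior = c(1, 1),
                        gEpsPrior = c(2, 10), ablPrior = c(1, 1),
                        iwScale = diag(4), iwDf = 6,
                        kPrior = rep(0.25, 4)) {
  new("PriorConfig", mu11LogSd = mu11LogSd, gPairPrior = gPairPrior,
      gEpsPrior = gEpsPrior, ablPrior = ablPrior,
      iwScale = unname(as.matrix(iwScale)), iwDf = iwDf, kPrior = kPrior)
}

#' McmcConfig: sampler settings
#'
#' Defaults follow the batching scheme the model was designed around: 600
#' sweeps with 100 burn-in per batch of 100 colonies, so B = 500 retained
#' samples enter the posterior base probabilities.
#'
#' @slot nIter total sweeps per batch (default 600).
#' @slot nBurnin discarded sweeps, < nIter (default 100).
#' @slot batchSize colonies per independent chain (default 100).
#' @slot seed integer RNG seed; per-batch streams are derived from it.
#' @slot proposalScales named numeric random-walk standard deviations on
#'   the transformed scale (log for mu11, logit for unit-interval
#'   parameters); names mu11, gPair, gEps, alpha, beta, lambda.
#' @slot normalizedDensities logical; when TRUE the truncation-region
#'   masses enter the latent-base update and the Metropolis ratios
#'   (sensitivity-analysis mode, much slower).
#' @export
setClass("McmcConfig",
  representation(
    nIter = "integer",
    nBurnin = "integer",
    batchSize = "integer",
    seed = "integer",
    proposalScales = "numeric",
    normalizedDensities = "logical"
  )
)

setValidity("McmcConfig", function(object) {
  if (object@nIter < 1L) return("'nIter' must be positive")
  if (object@nBurnin < 0L || object@nBurnin >= object@nIter)
    return("'nBurnin' must satisfy 0 <= nBurnin < nIter")
  if (object@batchSize < 1L) return("'batchSize' must be >= 1")
  need <- c("mu11", "gPair", "gEps", "alpha", "beta", "lambda")
  if (!all(need %in% names(object@proposalScales)))
    return(paste("'proposalScales' must name", paste(need, collapse = ", ")))
  if (any(object@proposalScales < 0))
    return("'proposalScales' must be nonnegative")
  TRUE
})

#' @rdname McmcConfig-class
#' @param nIter,nBurnin,batchSize,seed,proposalScales,normalizedDensities
#'   see the corresponding slots.
#' @return An [McmcConfig-class] object.
#' @export
McmcConfig <- function(nIter = 600, nBurnin = 100, batchSize = 100,
                       seed = 1,
                       proposalScales = c(mu11 = 0.03, gPair = 0.25,
                                          gEps = 0.25, alpha = 0.25,
                                          beta = 0.25, lambda = 0.25),
                       normalizedDensities = FALSE) {
  new("McmcConfig", nIter = as.integer(nIter), nBurnin = as.integer(nBurnin),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      proposalScales = proposalScales,
      normalizedDensities = normalizedDensities)
}

#' PosteriorSummary: Monte-Carlo posterior base probabilities and calls
#'
#' Produced by [runMcmc()]. For cycle i of colony c, `xi[i, j, c]` is the
#' Monte-Carlo frequency with which the latent true base equalled j across
#' retained sweeps; the base call is the argmax over j (ties broken toward
#' the lowest base index and flagged ambiguous).
#'
#' @slot xi numeric array I x 4 x n of posterior base probabilities; each
#'   4-vector sums to 1.
#' @slot call integer matrix I x n of called base indices.
#' @slot maxProb numeric matrix I x n, `xi` at the call.
#' @slot ambiguous logical matrix I x n, TRUE where the argmax was tied.
#' @slot colonyId character vector of length n.
#' @slot trace data.frame of retained global-parameter draws (one row per
#'   retained sweep per batch) for diagnostics and posterior means.
#' @export
setClass("PosteriorSummary",
  representation(
    xi = "array",
    call = "matrix",
    maxProb = "matrix",
    ambiguous = "matrix",
    colonyId = "character",
    trace = "data.frame"
  )
)

setValidity("PosteriorSummary", function(object) {
  d <- dim(object@xi)
  if (length(d) != 3L || d[2L] != 4L)
    return("'xi' must be an I x 4 x n array")
  if (any(object@xi < 0) || any(object@xi > 1))
    return("'xi' entries must lie in [0, 1]")
  s <- apply(object@xi, c(1, 3), sum)
  if (max(abs(s - 1)) > 1e-12)
    return("each xi 4-vector must sum to 1 (tolerance 1e-12)")
  if (!identical(dim(object@call), d[c(1L, 3L)]))
    return("'call' must be I x n")
  if (length(object@colonyId) != d[3L])
    return("length(colonyId) must equal the number of colonies")
  TRUE
})

#' SimTruth: ground truth of a simulated colony set
#'
#' @slot sequences integer matrix I x n of true base indices (1..4 for
#'   A, C, G, T), one column per colony.
#' @slot colonyId character vector of length n.
#' @slot params the [ModelParams-class] used to generate the intensities,
#'   or NULL for sequences that have not been pushed through the
#'   simulator yet.
#' @slot seed integer seed the sequences were drawn with.
#' @export
setClass("SimTruth",
  representation(
    sequences = "matrix",
    colonyId = "character",
    params = "ANY",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  k <- object@sequences
  if (!is.numeric(k) || any(!(k %in% 1:4)))
    return("'sequences' must contain base indices in 1..4")
  if (length(object@colonyId) != ncol(k))
    return("length(colonyId) must equal the number of colonies")
  if (!is.null(object@params) && !is(object@params, "ModelParams"))
    return("'params' must be NULL or a ModelParams object")
  TRUE
})
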