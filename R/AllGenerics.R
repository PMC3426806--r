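#' @include AllClasses.R
NULL

#' Accessors for phaseCall objects
#'
#' @param x a [ColonySet-class], [PosteriorSummary-class] or
#'   [SimTruth-class] object, as documented per method.
#' @name accessors
NULL

#' @describeIn accessors intensity array (cycles x channels x colonies).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @describeIn accessors colony identifiers.
#' @export
setGeneric("colonyIds", function(x) standardGeneric("colonyIds"))

#' @describeIn accessors read length I (number of cycles).
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' @describeIn accessors number of colonies.
#' @export
setGeneric("nColonies", function(x) standardGeneric("nColonies"))

#' @describeIn accessors posterior base probability array xi
#'   (cycles x 4 x colonies).
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' @describeIn accessors called base indices (cycles x colonies matrix).
#' @export
setGeneric("baseCalls", function(x) standardGeneric("baseCalls"))

#' @describeIn accessors posterior probability of the called base.
#' @export
setGeneric("maxProb", function(x) standardGeneric("maxProb"))

#' @describeIn accessors logical matrix flagging tied (ambiguous) calls.
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))

#' @describeIn accessors retained global-parameter draws (data.frame).
#' @export
setGeneric("paramTrace", function(x) standardGeneric("paramTrace"))

#' @describeIn accessors true base indices (cycles x colonies matrix).
#' @export
setGeneric("trueBases", function(x) standardGeneric("trueBases"))

#' @describeIn accessors generating [ModelParams-class] (or NULL).
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname accessors
#' @export
setMethod("intensities", "ColonySet", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("colonyIds", "ColonySet", function(x) x@colonyId)

#' @rdname accessors
#' @export
setMethod("colonyIds", "PosteriorSummary", function(x) x@colonyId)

#' @rdname accessors
#' @export
setMethod("colonyIds", "SimTruth", function(x) x@colonyId)

#' @rdname accessors
#' @export
setMethod("nCycles", "ColonySet", function(x) dim(x@intensities)[1L])

#' @rdname accessors
#' @export
setMethod("nCycles", "PosteriorSummary", function(x) dim(x@xi)[1L])

#' @rdname accessors
#' @export
setMethod("nCycles", "SimTruth", function(x) nrow(x@sequences))

#' @rdname accessors
#' @export
setMethod("nColonies", "ColonySet", function(x) dim(x@intensities)[3L])

#' @rdname accessors
#' @export
setMethod("nColonies", "PosteriorSummary", function(x) dim(x@xi)[3L])

#' @rdname accessors
#' @export
setMethod("nColonies", "SimTruth", function(x) ncol(x@sequences))

#' @rdname accessors
#' @export
setMethod("posteriorProb", "PosteriorSummary", function(x) x@xi)

#' @rdname accessors
#' @export
setMethod("baseCalls", "PosteriorSummary", function(x) x@call)

#' @rdname accessors
#' @export
setMethod("maxProb", "PosteriorSummary", function(x) x@maxProb)

#' @rdname accessors
#' @export
setMethod("isAmbiguous", "PosteriorSummary", function(x) x@ambiguous)

#' @rdname accessors
#' @export
setMethod("paramTrace", "PosteriorSummary", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("trueBases", "SimTruth", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("simParams", "SimTruth", function(x) x@params)

#' Subset a ColonySet by colony
#'
#' @param x a [ColonySet-class].
#' @param i colony indices (numeric, logical or colony ids).
#' @param j,...,drop ignored.
#' @return A [ColonySet-class] with the selected colonies.
#' @export
setMethod("[", "ColonySet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@colonyId)
  md <- x@metadata
  if (nrow(md) > 0L) md <- md[i, , drop = FALSE]
  new("ColonySet", intensities = x@intensities[, , i, drop = FALSE],
      colonyId = x@colonyId[i], metadata = md)
})

setMethod("show", "ColonySet", function(object) {
  cat(sprintf("ColonySet: %d colonies x %d cycles (channels A,C,G,T)\n",
              nColonies(object), nCycles(object)))
  rng <- range(object@intensities)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1L], rng[2L]))
  ids <- object@colonyId
  cat("  colonyId:", paste(utils::head(ids, 3L), collapse = ", "),
      if (length(ids) > 3L) "..." else "", "\n")
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat(sprintf("  alpha (phasing) %.4g | beta (fading rate) %.4g | lambda %.4g\n",
              object@alpha, object@beta, object@lambda))
  cat("  per-class mean structure (rows A,C,G,T):\n")
  m <- cbind(mu11 = object@mu11, gPair = object@gPair,
             gEps1 = object@gEps1, gEps2 = object@gEps2)
  rownames(m) <- .CHANNELS
  print(round(m, 4))
  cat(sprintf("  Sigma: 4 covariance matrices, mean diag %.4g\n",
              mean(vapply(object@Sigma, function(S) mean(diag(S)), 0))))
})

setMethod("show", "PriorConfig", function(object) {
  cat("PriorConfig\n")
  cat(sprintf("  mu11 ~ logN(0, %.3g); gPair ~ beta(%g, %g); gEps ~ beta(%g, %g)\n",
              object@mu11LogSd, object@gPairPrior[1L], object@gPairPrior[2L],
              object@gEpsPrior[1L], object@gEpsPrior[2L]))
  cat(sprintf("  alpha, beta, lambda ~ beta(%g, %g); Sigma_j ~ invWishart(scale, df = %g)\n",
              object@ablPrior[1L], object@ablPrior[2L], object@iwDf))
  cat("  k prior:", paste(format(object@kPrior), collapse = " "), "\n")
})

setMethod("show", "McmcConfig", function(object) {
  cat(sprintf("McmcConfig: %d sweeps (%d burn-in) per batch of %d colonies; seed %d\n",
              object@nIter, object@nBurnin, object@batchSize, object@seed))
  cat(sprintf("  densities: %s\n",
              if (object@normalizedDensities) "normalized (truncation masses included)"
              else "unnormalized (default)"))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: %d colonies x %d cycles\n",
              nColonies(object), nCycles(object)))
  cat(sprintf("  mean max posterior probability %.4f; %d ambiguous calls\n",
              mean(object@maxProb), sum(object@ambiguous)))
  comp <- table(factor(.CHANNELS[object@call], levels = .CHANNELS))
  cat("  call composition:",
      paste(sprintf("%s=%d", names(comp), comp), collapse = " "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d colonies x %d cycles (seed %d)\n",
              nColonies(object), nCycles(object), object@seed))
  cat(sprintf("  generating parameters: %s\n",
              if (is.null(object@params)) "not attached" else "attached"))
})
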