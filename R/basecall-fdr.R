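#' @include AllClasses.R
NULL

#' Extract base calls from a posterior summary
#'
#' The call at each cycle is the base with the largest posterior
#' probability; ties go to the lowest base index and are flagged in the
#' `ambiguous` column.
#'
#' @param ps a [PosteriorSummary-class].
#' @return data.frame with one row per (cycle, colony): `colony_id`,
#'   `cycle` (1-based), `call` (A/C/G/T), `call_index`, `max_prob`,
#'   `ambiguous`.
#' @export
callBases <- function(ps) {
  I <- nCycles(ps); n <- nColonies(ps)
  data.frame(
    colony_id = rep(ps@colonyId, each = I),
    cycle = rep.int(seq_len(I), n),
    call = .CHANNELS[as.vector(ps@call)],
    call_index = as.vector(ps@call),
    max_prob = as.vector(ps@maxProb),
    ambiguous = as.vector(ps@ambiguous),
    stringsAsFactors = FALSE
  )
}

#' Local false discovery rate of a single call
#'
#' The posterior probability of making a wrong call at one cycle:
#' one minus the posterior probability of the reference base. When the
#' truth is known the reference is the true base; otherwise the call
#' itself is substituted, which makes the estimate optimistic (never
#' larger than the truth-based value).
#'
#' @param xiVec posterior probability 4-vector (sums to 1).
#' @param refBase reference base index in 1..4.
#' @return Local FDR in \[0, 1\].
#' @export
#' @examples
#' localFdr(c(0.7, 0.1, 0.1, 0.1), 1)  # 0.3
localFdr <- function(xiVec, refBase) {
  if (length(refBase) != 1L || !(refBase %in% 1:4))
    stop("'refBase' must be a single base index in 1..4")
  if (length(xiVec) != 4L || abs(sum(xiVec) - 1) > 1e-6)
    stop("'xiVec' must be 4 probabilities summing to 1")
  1 - xiVec[[refBase]]
}

#' Per-call local FDRs from a posterior summary
#'
#' Builds the (colony, cycle, local FDR) table that feeds
#' [estimateFdrCurve()]. With `truth` supplied the reference base is the
#' true base; without it the estimated call is used and a warning notes
#' that the resulting FDR estimate is anti-conservative.
#'
#' @param ps a [PosteriorSummary-class].
#' @param truth optional [SimTruth-class] or integer matrix I x n of true
#'   base indices (colonies in the same order as `ps`).
#' @return data.frame with columns `colony_id`, `cycle`, `ref_base`,
#'   `local_fdr`.
#' @export
posteriorLocalFdrs <- function(ps, truth = NULL) {
  I <- nCycles(ps); n <- nColonies(ps)
  if (is.null(truth)) {
    warning("no truth supplied: using estimated calls as reference; ",
            "the FDR estimate is anti-conservative")
    ref <- ps@call
  } else {
    ref <- if (is(truth, "SimTruth")) truth@sequences else truth
    if (!identical(dim(ref), dim(ps@call)))
      stop("truth dimensions do not match the posterior summary")
  }
  idx <- cbind(rep.int(seq_len(I), n), as.vector(ref),
               rep(seq_len(n), each = I))
  data.frame(
    colony_id = rep(ps@colonyId, each = I),
    cycle = rep.int(seq_len(I), n),
    ref_base = as.vector(ref),
    local_fdr = 1 - ps@xi[idx],
    stringsAsFactors = FALSE
  )
}

#' Ranked cumulative Bayesian FDR curve
#'
#' Ranks the calls by increasing local FDR (stable sort: ties keep input
#' order) and reports, for every depth G, the estimated FDR of the top-G
#' calls as the running mean of their local FDRs — which is
#' non-decreasing in G by construction.
#'
#' @param localFdrs data.frame with columns `colony_id`, `cycle`,
#'   `local_fdr` (e.g. from [posteriorLocalFdrs()]).
#' @return data.frame ordered by rank with columns `rank` (G),
#'   `colony_id`, `cycle`, `ref_base` (when present in the input),
#'   `local_fdr`, `cumulative_fdr`.
#' @export
#' @examples
#' tab <- data.frame(colony_id = "c1", cycle = 1:3,
#'                   local_fdr = c(0.2, 0.0, 0.1))
#' estimateFdrCurve(tab)$cumulative_fdr  # 0, 0.05, 0.10
estimateFdrCurve <- function(localFdrs) {
  if (nrow(localFdrs) == 0L) stop("'localFdrs' must be non-empty")
  lf <- localFdrs$local_fdr
  if (any(!is.finite(lf) | lf < 0 | lf > 1))
    stop("local FDR values must lie in [0, 1]")
  ord <- order(lf)  # radix sort: stable, ties keep input order
  out <- localFdrs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$cumulative_fdr <- cumsum(out$local_fdr) / out$rank
  rownames(out) <- NULL
  keep <- intersect(c("rank", "colony_id", "cycle", "ref_base",
                      "local_fdr", "cumulative_fdr"), names(out))
  out[, keep]
}

.asCallMatrix <- function(calls, I = NULL, n = NULL) {
  if (is(calls, "PosteriorSummary")) return(calls@call)
  if (is.data.frame(calls)) {
    idx <- if ("call_index" %in% names(calls)) calls$call_index
           else match(calls$call, .CHANNELS)
    I <- max(calls$cycle)
    return(matrix(idx, nrow = I))
  }
  as.matrix(calls)
}

.asTruthMatrix <- function(truth) {
  if (is(truth, "SimTruth")) truth@sequences else as.matrix(truth)
}

#' Evaluate base calls against known truth
#'
#' Cross-tabulates calls against true bases and summarizes the error
#' structure the way base callers are usually reported: a 4 x 4 matrix
#' of row percentages (each true-base row sums to 100), the proportion of
#' wrong calls at each cycle, and the overall error rate.
#'
#' @param calls a [PosteriorSummary-class], a data.frame from
#'   [callBases()], or an I x n matrix of called base indices.
#' @param truth a [SimTruth-class] or I x n matrix of true base indices.
#' @return list of class `phaseCallEval` with elements `confusion`
#'   (4 x 4 percentage matrix, rows = true base; `NaN` rows for bases
#'   that never occur), `error_by_cycle` (length I) and `overall_error`.
#' @export
evaluateCalls <- function(calls, truth) {
  s <- .asCallMatrix(calls)
  t <- .asTruthMatrix(truth)
  if (!identical(dim(s), dim(t)))
    stop(sprintf("calls are %d x %d but truth is %d x %d",
                 nrow(s), ncol(s), nrow(t), ncol(t)))
  tab <- table(factor(t, levels = 1:4), factor(s, levels = 1:4))
  conf <- 100 * tab / rowSums(tab)  # NaN row when a true base never occurs
  conf <- matrix(as.numeric(conf), 4L, 4L,
                 dimnames = list(true = .CHANNELS, called = .CHANNELS))
  wrong <- s != t
  res <- list(confusion = conf,
              error_by_cycle = rowMeans(wrong),
              overall_error = mean(wrong))
  class(res) <- "phaseCallEval"
  res
}

#' @export
print.phaseCallEval <- function(x, ...) {
  cat(sprintf("Base-call evaluation: overall error %.4f over %d cycles\n",
              x$overall_error, length(x$error_by_cycle)))
  cat("Confusion (row percentages, true base x called base):\n")
  print(round(x$confusion, 2))
  invisible(x)
}

#' Compare the estimated FDR curve with the realized error
#'
#' Walks down the FDR ranking and, at each depth G, reports the estimated
#' cumulative Bayesian FDR next to the realized error — the fraction of
#' the top-G calls that are actually wrong. On well-calibrated runs the
#' two curves track each other; when the ranking's reference base is the
#' estimated call rather than the truth, the estimate is pointwise no
#' larger than the truth-based one.
#'
#' @param fdrTable output of [estimateFdrCurve()].
#' @param calls calls matched to `fdrTable` rows (see [evaluateCalls()]
#'   for accepted forms); matched by colony id and cycle.
#' @param truth a [SimTruth-class] or I x n matrix of true base indices,
#'   with colony ids matching `calls` when given as `SimTruth`.
#' @param ps the [PosteriorSummary-class] the table came from (used to
#'   map colony ids to columns); required when `calls` is a matrix whose
#'   columns are not in `fdrTable` colony order.
#' @return data.frame with columns `rank`, `estimated_fdr`,
#'   `realized_error`.
#' @export
fdrCalibration <- function(fdrTable, calls, truth, ps = NULL) {
  s <- .asCallMatrix(calls)
  t <- .asTruthMatrix(truth)
  ids <- if (!is.null(ps)) ps@colonyId
         else if (is(truth, "SimTruth")) truth@colonyId
         else unique(fdrTable$colony_id)
  col <- match(fdrTable$colony_id, ids)
  if (any(is.na(col)))
    stop("colony ids in 'fdrTable' do not match the supplied truth/calls")
  idx <- cbind(fdrTable$cycle, col)
  wrong <- s[idx] != t[idx]
  data.frame(rank = fdrTable$rank,
             estimated_fdr = fdrTable$cumulative_fdr,
             realized_error = cumsum(wrong) / fdrTable$rank)
}
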