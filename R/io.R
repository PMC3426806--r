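#' @include AllClasses.R
NULL

#' Read a plain-text colony intensity file
#'
#' One colony per line: four integer metadata fields (lane, tile, x, y)
#' followed by 4 x I whitespace-separated intensities in cycle-major,
#' channel-minor (A, C, G, T) order. The colony id is synthesized as
#' `lane:tile:x:y`. All colonies in a file must share the same read
#' length.
#'
#' @param path file path.
#' @return A [ColonySet-class]; an empty file yields a zero-colony error
#'   downstream — here it returns a usage error.
#' @export
readIntensityFile <- function(path) {
  if (!file.exists(path)) stop("intensity file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("intensity file '", path, "' contains no colonies")
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 8L) || any((nf - 4L) %% 4L != 0L)) {
    bad <- which(nf < 8L | (nf - 4L) %% 4L != 0L)[1L]
    stop(sprintf(
      "line %d: expected 4 metadata fields plus a multiple of 4 intensities, got %d fields",
      bad, nf[bad]))
  }
  I <- (nf[1L] - 4L) / 4L
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("line %d: inconsistent cycle count (%d vs %d)",
                 bad, (nf[bad] - 4L) / 4L, I))
  }
  n <- length(toks)
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(nf[1L])))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[1L]
    stop(sprintf("line %d: non-numeric token", bad))
  }
  meta <- t(vals[1:4, , drop = FALSE])
  colnames(meta) <- c("lane", "tile", "x", "y")
  inten <- vals[-(1:4), , drop = FALSE]  # (4 * I) x n, channel fastest
  Y <- aperm(array(inten, dim = c(4L, I, n)), c(2L, 1L, 3L))
  ids <- apply(meta, 1L, paste, collapse = ":")
  ColonySet(Y, colonyId = ids, metadata = as.data.frame(meta))
}

#' Write colonies in the plain-text intensity dialect
#'
#' Inverse of [readIntensityFile()]. Metadata columns lane, tile, x, y
#' are taken from the object's metadata when present, otherwise
#' reconstructed from `lane:tile:x:y`-style colony ids, otherwise
#' synthesized as `1 1 <index> 1`. Intensities are printed with 6
#' significant digits, which the reader reproduces exactly.
#'
#' @param colonies a [ColonySet-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeIntensityFile <- function(colonies, path) {
  n <- nColonies(colonies)
  md <- colonies@metadata
  if (all(c("lane", "tile", "x", "y") %in% names(md))) {
    meta <- md[, c("lane", "tile", "x", "y")]
  } else {
    parts <- strsplit(colonies@colonyId, ":", fixed = TRUE)
    if (all(lengths(parts) == 4L) &&
        !anyNA(suppressWarnings(as.integer(unlist(parts))))) {
      meta <- as.data.frame(t(vapply(parts, as.integer, integer(4L))))
    } else {
      meta <- data.frame(1L, 1L, seq_len(n), 1L)
    }
  }
  lines <- vapply(seq_len(n), function(c) {
    y <- t(colonies@intensities[, , c])  # channel fastest within cycle
    paste(c(format(unlist(meta[c, ]), trim = TRUE, scientific = FALSE),
            format(as.vector(y), digits = 6, trim = TRUE)),
          collapse = " ")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write truth files
#'
#' A truth file has one line per colony: the colony id, a tab, and the
#' true sequence as an ACGT string.
#'
#' @param path file path.
#' @return `readTruthFile`: a [SimTruth-class] (no parameters attached).
#' @export
readTruthFile <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("each truth line must be 'colony_id<TAB>sequence'")
  ids <- vapply(parts, `[[`, character(1L), 1L)
  seqs <- vapply(parts, `[[`, character(1L), 2L)
  if (length(unique(nchar(seqs))) != 1L)
    stop("truth sequences have inconsistent lengths")
  k <- vapply(strsplit(seqs, ""), function(s) {
    idx <- match(s, .CHANNELS)
    if (anyNA(idx)) stop("truth sequences may only contain A, C, G, T")
    idx
  }, integer(nchar(seqs[1L])))
  if (is.vector(k)) k <- matrix(k, nrow = 1L)
  new("SimTruth", sequences = k, colonyId = ids, params = NULL, seed = NA_integer_)
}

#' @rdname readTruthFile
#' @param truth a [SimTruth-class].
#' @export
writeTruthFile <- function(truth, path) {
  seqs <- apply(truth@sequences, 2L, function(k)
    paste(.CHANNELS[k], collapse = ""))
  writeLines(paste(truth@colonyId, seqs, sep = "\t"), path)
  invisible(path)
}

#' Normalize intensities across a colony set
#'
#' Shifts and scales every intensity value by statistics pooled over the
#' whole input set: subtract the overall minimum, divide by the overall
#' (sample, N-1) standard deviation. The minimum of the output is 0.
#'
#' @param colonies a [ColonySet-class].
#' @return A [ColonySet-class] in normalized units.
#' @export
normalizeIntensities <- function(colonies) {
  y <- colonies@intensities
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stop("cannot normalize: intensities have zero standard deviation")
  colonies@intensities <- (y - min(y)) / s
  colonies
}

#' Phred quality from a posterior call probability
#'
#' `Q = round(-10 * log10(1 - p))`, capped to \[0, 40\]; a call
#' probability of 1 maps to the cap.
#'
#' @param maxProb call probability (vectorized, in \[0, 1\]).
#' @return Integer vector of qualities in 0..40.
#' @export
#' @examples
#' phredQuality(c(0.25, 0.999, 1))  # 1 30 40
phredQuality <- function(maxProb) {
  if (any(!is.finite(maxProb)) || any(maxProb < 0 | maxProb > 1))
    stop("'maxProb' must lie in [0, 1]")
  q <- round(-10 * log10(1 - maxProb))
  q[!is.finite(q)] <- 40
  as.integer(pmin(pmax(q, 0), 40))
}

#' Write base calls as FASTQ
#'
#' Emits one standard 4-line FASTQ record per colony (Sanger Phred+33
#' encoding) via Biostrings. Sequences are the called bases; qualities
#' come from [phredQuality()] applied to the posterior call
#' probabilities. Ambiguous (tied) positions are written as the called
#' base; the ambiguity flag lives in the posterior table, not in the
#' FASTQ.
#'
#' @param ps a [PosteriorSummary-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(ps, path) {
  I <- nCycles(ps)
  seqs <- apply(ps@call, 2L, function(k) paste(.CHANNELS[k], collapse = ""))
  quals <- apply(ps@maxProb, 2L, function(p) {
    q <- phredQuality(p)
    if (any(q < 0L | q > 93L)) stop("quality out of encodable range")
    rawToChar(as.raw(q + 33L))
  })
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ps@colonyId)),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Posterior probability table
#'
#' Long-format table of the posterior summary, one row per (colony,
#' cycle): posterior probabilities for the four bases, the call, its
#' probability and the ambiguity flag. This is the table the `call`
#' subcommand writes alongside the FASTQ.
#'
#' @param ps a [PosteriorSummary-class].
#' @return data.frame with columns `colony_id`, `cycle`, `xi_A`, `xi_C`,
#'   `xi_G`, `xi_T`, `call`, `max_prob`, `ambiguous`.
#' @export
xiTable <- function(ps) {
  I <- nCycles(ps); n <- nColonies(ps)
  xi <- matrix(aperm(ps@xi, c(1L, 3L, 2L)), nrow = I * n, ncol = 4L)
  data.frame(
    colony_id = rep(ps@colonyId, each = I),
    cycle = rep.int(seq_len(I), n),
    xi_A = xi[, 1L], xi_C = xi[, 2L], xi_G = xi[, 3L], xi_T = xi[, 4L],
    call = .CHANNELS[as.vector(ps@call)],
    max_prob = as.vector(ps@maxProb),
    ambiguous = as.vector(ps@ambiguous),
    stringsAsFactors = FALSE
  )
}

#' Read and write flat key=value run configuration files
#'
#' The run configuration (sampler settings, seeds, flags) round-trips
#' losslessly through a flat `key=value` text form.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return `readRunConfig`: named list with numeric/logical values
#'   restored; `writeRunConfig`: invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 17)
    else if (is.logical(v)) as.character(v)
    else as.character(v)
  }, character(1L))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line (need key=value)")
  vals <- lapply(kv, function(p) {
    v <- p[[2L]]
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1L), 1L))
}
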