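#' Define a motif model
#'
#' A motif model bundles a position weight matrix (log-odds scores over
#' A/C/G/T), a hit threshold, and per-context activation weights. The toy
#' accessibility predictor ([toy_predictor()]) treats every PWM match scoring
#' at or above the threshold as a transcription-factor footprint whose excess
#' score, weighted by the context's beta, opens chromatin.
#'
#' @param motif_id Single string naming the motif.
#' @param pwm Numeric k x 4 matrix of per-position log-odds scores, columns
#'   ordered A, C, G, T; k >= 4.
#' @param threshold Scalar hit threshold tau (score units): offsets scoring
#'   `>= threshold` count as hits.
#' @param betas Named numeric vector mapping context ids to activation
#'   weights (log-count units per unit of excess score). Contexts absent from
#'   `betas` are inert (beta = 0).
#'
#' @return An object of class `motif_model`.
#' @examples
#' pwm <- pwm_consensus_matrix("TGACTCA")
#' motif_model("AP1", pwm, threshold = 6, betas = c(asc_SMC = 1.5))
#' @export
motif_model <- function(motif_id, pwm, threshold, betas) {
  stopifnot(is.character(motif_id), length(motif_id) == 1L)
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L || nrow(pwm) < 4L || !all(is.finite(pwm))) {
    abort("invalid-argument: `pwm` must be a finite k x 4 matrix with k >= 4",
          class = "sitefx_invalid_argument")
  }
  colnames(pwm) <- DNA_BASES
  check_scalar_number(threshold, "threshold")
  if (length(betas) < 1L || is.null(names(betas)) || any(!nzchar(names(betas)))) {
    abort("invalid-argument: `betas` must be a named numeric vector with >= 1 context",
          class = "sitefx_invalid_argument")
  }
  structure(
    list(motif_id = motif_id, pwm = pwm, threshold = threshold,
         betas = betas),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: %d bp, threshold %.3g, contexts: %s\n",
              x$motif_id, nrow(x$pwm), x$threshold,
              paste(names(x$betas), collapse = ", ")))
  invisible(x)
}

#' @export
length.motif_model <- function(x) nrow(x$pwm)

#' Consensus sequence of a motif PWM
#'
#' The consensus takes the arg-max base of each PWM column; ties break to the
#' first base in A < C < G < T order.
#'
#' @param x A `motif_model` or a k x 4 log-odds matrix.
#' @return A single string of length k.
#' @export
motif_consensus <- function(x) {
  pwm <- if (inherits(x, "motif_model")) x$pwm else as.matrix(x)
  paste(DNA_BASES[apply(pwm, 1L, which.max)], collapse = "")
}

#' Maximum attainable PWM score
#'
#' @param x A `motif_model` or a k x 4 log-odds matrix.
#' @return The score of the consensus sequence (sum of columnwise maxima).
#' @export
motif_max_score <- function(x) {
  pwm <- if (inherits(x, "motif_model")) x$pwm else as.matrix(x)
  sum(apply(pwm, 1L, max))
}

#' Build a sharp PWM from a consensus string
#'
#' Convenience constructor for synthetic grammars: the consensus base of each
#' column scores `match`, every other base scores `mismatch`.
#'
#' @param consensus String over ACGT.
#' @param match,mismatch Per-position scores for the consensus base and the
#'   other three bases.
#' @return A k x 4 log-odds matrix.
#' @export
pwm_consensus_matrix <- function(consensus, match = 2, mismatch = -2) {
  ints <- seq_to_ints(consensus, "consensus")
  k <- length(ints)
  pwm <- matrix(mismatch, nrow = k, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  pwm[cbind(seq_len(k), ints)] <- match
  pwm
}

#' Convert a position frequency matrix to log-odds
#'
#' Columns are normalised to probabilities with an additive pseudocount and
#' scored as log2(p / background) against a uniform background.
#'
#' @param counts k x 4 matrix of base counts or frequencies (columns A,C,G,T).
#' @param pseudocount Additive pseudocount, default 0.01.
#' @return A k x 4 log-odds matrix (bits).
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4L, all(counts >= 0))
  probs <- (counts + pseudocount) / rowSums(counts + pseudocount)
  lo <- log2(probs / 0.25)
  colnames(lo) <- DNA_BASES
  lo
}

#' Read a JASPAR-style .pfm file as a log-odds PWM
#'
#' Expects the 4-row JASPAR layout (rows A, C, G, T, optional `>` header and
#' row labels with or without bracketed counts).
#'
#' @param path Path to a .pfm / .jaspar text file.
#' @inheritParams pwm_from_counts
#' @return A k x 4 log-odds matrix.
#' @export
read_pfm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), ">") & nzchar(trimws(lines))]
  if (length(lines) != 4L) {
    abort("invalid-argument: expected 4 count rows (A, C, G, T) in PFM file",
          class = "sitefx_invalid_argument")
  }
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGTacgt]", "", trimws(l))
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1L) {
    abort("invalid-argument: PFM rows have unequal lengths",
          class = "sitefx_invalid_argument")
  }
  counts <- t(do.call(rbind, rows))  # k x 4, columns A,C,G,T
  pwm_from_counts(counts, pseudocount)
}
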