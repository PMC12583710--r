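#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Split an ACGT string into a character vector, validating the alphabet.
seq_to_chars <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !chars %in% DNA_BASES
  if (any(bad)) {
    abort(
      sprintf(
        "invalid-sequence: %s contains characters outside ACGT (first offender %s at position %d)",
        what, chars[which(bad)[1]], which(bad)[1]
      ),
      class = "sitefx_invalid_sequence"
    )
  }
  chars
}

# Integer encoding A=1, C=2, G=3, T=4.
seq_to_ints <- function(seq, what = "sequence") {
  match(seq_to_chars(seq, what), DNA_BASES)
}

ints_to_seq <- function(ints) {
  paste(DNA_BASES[ints], collapse = "")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf(
      "invalid-argument: `%s` must be a single finite number in [%s, %s]",
      name, format(lower), format(upper)
    ), class = "sitefx_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("invalid-argument: `%s` must be an integer >= %d", name, min),
          class = "sitefx_invalid_argument")
  }
  invisible(as.integer(x))
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
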