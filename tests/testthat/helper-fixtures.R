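# Shared fixture builders. Everything is generated in code at test time.

# Sharp single-consensus motif: consensus scores k * match, any single
# mismatch drops the score by (match - mismatch).
test_motif <- function(consensus = "TGACTCAC", threshold_gap = 0.5,
                       betas = c(asc = 1, desc = 0), id = "M1",
                       match = 2, mismatch = -2) {
  pwm <- pwm_consensus_matrix(consensus, match = match, mismatch = mismatch)
  motif_model(id, pwm, threshold = nchar(consensus) * match - threshold_gap,
              betas = betas)
}

# Dense continuous-valued grammar: centered random PWM with threshold 0, so
# roughly half of all offsets are hits and scores vary continuously with the
# background. Used for null-calibration checks.
dense_motif <- function(seed = 11, k = 8, beta = 0.2, context = "ctx") {
  pwm <- with_seed_local(seed, matrix(stats::rnorm(4 * k), k, 4))
  pwm <- pwm - rowMeans(pwm)
  motif_model("dense", pwm, threshold = 0, betas = setNames(beta, context))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All distinct permutations of a character multiset (n <= 8 in practice).
multiset_permutations <- function(chars) {
  n <- length(chars)
  if (n <= 1L) return(list(chars))
  out <- list()
  for (b in unique(chars)) {
    rest <- chars[-match(b, chars)]
    for (p in multiset_permutations(rest)) {
      out[[length(out) + 1L]] <- c(b, p)
    }
  }
  out
}

# Brute-force enumeration of every string with the same dinucleotide count
# matrix and endpoints as `seq` (the valid dinucleotide-shuffle outcomes).
enumerate_dinuc_set <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 3L) return(seq)
  target <- dinucleotide_counts(seq)
  interior <- chars[2:(n - 1L)]
  perms <- multiset_permutations(interior)
  cands <- unique(vapply(perms, function(p) {
    paste(c(chars[1L], p, chars[n]), collapse = "")
  }, character(1)))
  cands[vapply(cands, function(s) identical(dinucleotide_counts(s), target),
               logical(1))]
}

# Two-context toy genome with a shared motif (active in both contexts) and a
# context-A-specific motif, planted and ready for scoring.
toy_two_context_setup <- function(chrom_lengths = c(chr1 = 50000),
                                  n_per_motif = 20, seed = 101) {
  shared <- test_motif("TGACGTCATG", betas = c(ctx_A = 0.8, ctx_B = 0.8),
                       id = "shared")
  a_only <- test_motif("CCATATAAGG", betas = c(ctx_A = 0.8, ctx_B = 0),
                       id = "a_only")
  genome <- simulate_genome(chrom_lengths, gc = 0.41, seed = seed)
  genome <- plant_motifs(genome, list(shared, a_only), n_per_motif,
                         seed = seed + 1)
  list(
    genome = genome, shared = shared, a_only = a_only,
    predictors = list(
      ctx_A = toy_predictor(list(shared, a_only), "ctx_A"),
      ctx_B = toy_predictor(list(shared, a_only), "ctx_B")
    )
  )
}
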