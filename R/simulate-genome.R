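#' Simulate a random genome
#'
#' Draws i.i.d. bases with the requested GC content, symmetric within the
#' G/C and A/T pairs: P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc GC fraction in `[0, 1]`, default 0.41 (mammalian-like).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#'
#' @return A `synthetic_genome`: list with `sequences` (named character
#'   vector of chromosome sequences) and `motif_instances` (tibble with
#'   columns `chrom`, `start` (0-based), `motif_id`; empty until
#'   [plant_motifs()] is called).
#' @examples
#' g <- simulate_genome(c(chr1 = 1000), gc = 0.4, seed = 1)
#' nchar(g$sequences[["chr1"]])
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.41, seed = NULL) {
  if (length(chrom_lengths) < 1L || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths)))) {
    abort("invalid-argument: `chrom_lengths` must be a named vector",
          class = "sitefx_invalid_argument")
  }
  if (any(chrom_lengths < 1)) {
    abort("invalid-argument: chromosome lengths must be >= 1",
          class = "sitefx_invalid_argument")
  }
  check_scalar_number(gc, "gc", 0, 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequences <- with_seed(seed, {
    vapply(chrom_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
  new_synthetic_genome(sequences)
}

new_synthetic_genome <- function(sequences, motif_instances = NULL) {
  if (is.null(motif_instances)) {
    motif_instances <- tibble::tibble(
      chrom = character(), start = integer(), motif_id = character()
    )
  }
  structure(
    list(sequences = sequences, motif_instances = motif_instances),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chromosome(s), %s bp total, %d planted motif instance(s)\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              nrow(x$motif_instances)))
  invisible(x)
}

chrom_lengths_of <- function(genome) {
  vapply(genome$sequences, nchar, integer(1))
}

# Fetch genome bases on [start, end) (0-based, half-open).
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$sequences)) {
    abort(sprintf("invalid-argument: unknown chromosome '%s'", chrom),
          class = "sitefx_invalid_argument")
  }
  substr(genome$sequences[[chrom]], start + 1L, end)
}

#' Plant motif consensus sequences into a genome
#'
#' Writes `n_per_motif` copies of each motif's consensus (arg-max base per
#' PWM column) at non-overlapping, uniformly drawn forward-strand positions,
#' and records them in the genome's instance table. Placement uses rejection
#' sampling; if a non-overlapping position cannot be found within
#' `max_retries` draws the function fails rather than silently overlapping.
#'
#' @param genome A `synthetic_genome`.
#' @param motifs List of [motif_model()] objects (a single model is accepted).
#' @param n_per_motif Copies to plant per motif.
#' @param seed Integer seed.
#' @param max_retries Rejection-sampling cap per instance, default 1000.
#'
#' @return The updated `synthetic_genome`.
#' @export
plant_motifs <- function(genome, motifs, n_per_motif, seed = NULL,
                         max_retries = 1000L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  n_per_motif <- check_count(n_per_motif, "n_per_motif")
  lens <- chrom_lengths_of(genome)
  if (any(vapply(motifs, length, integer(1)) > min(lens))) {
    abort("invalid-argument: motif longer than shortest chromosome",
          class = "sitefx_invalid_argument")
  }
  if (n_per_motif == 0L) return(genome)

  seqs <- lapply(genome$sequences, function(s) strsplit(s, "")[[1]])
  occupied <- lapply(lens, function(len) logical(len))
  placed <- list()

  with_seed(seed, {
    for (m in motifs) {
      cons <- strsplit(motif_consensus(m), "")[[1]]
      k <- length(cons)
      for (i in seq_len(n_per_motif)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          chrom <- sample(names(lens), 1L, prob = pmax(lens - k + 1, 0))
          start <- sample.int(lens[[chrom]] - k + 1L, 1L) - 1L  # 0-based
          idx <- (start + 1L):(start + k)
          if (!any(occupied[[chrom]][idx])) {
            seqs[[chrom]][idx] <- cons
            occupied[[chrom]][idx] <- TRUE
            placed[[length(placed) + 1L]] <- tibble::tibble(
              chrom = chrom, start = start, motif_id = m$motif_id
            )
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "placement-failure: could not place instance %d of motif '%s' without overlap after %d retries",
            i, m$motif_id, max_retries
          ), class = "sitefx_placement_failure")
        }
      }
    }
  })

  sequences <- vapply(seqs, paste, character(1), collapse = "")
  new_synthetic_genome(
    sequences,
    dplyr::bind_rows(genome$motif_instances, dplyr::bind_rows(placed))
  )
}

#' Simulate a SNP variant list over a synthetic genome
#'
#' A fraction of variants is aimed at planted motif instances: each such
#' variant sits at the motif's highest-information PWM column (largest gap
#' between best and worst base), keeps the genome (consensus) base as the
#' reference allele, and substitutes that column's lowest-scoring base as the
#' alternate — the strongest possible single-base hit disruption. The
#' remaining variants fall uniformly on positions outside every instance and
#' mutate to a random non-reference base.
#'
#' @param genome A `synthetic_genome` (with planted instances if
#'   `frac_in_motif > 0`).
#' @param motifs The motif models used for planting (needed to pick the
#'   disrupted column); ignored when `frac_in_motif = 0`.
#' @param n_total Total number of SNPs.
#' @param frac_in_motif Fraction of SNPs placed inside motif instances.
#' @param min_flank Keep every variant at least this many bases away from
#'   its chromosome's ends (default 0), so scoring/shuffle windows of up to
#'   `2 * min_flank` bp stay in bounds.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `chrom`, `pos` (0-based), `id`, `ref`, `alt`,
#'   `in_motif`, `motif_id` (`NA` for background variants).
#' @export
simulate_variants <- function(genome, n_total, frac_in_motif = 0,
                              motifs = list(), min_flank = 0L, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  n_total <- check_count(n_total, "n_total", min = 1L)
  check_scalar_number(frac_in_motif, "frac_in_motif", 0, 1)
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  n_motif <- round(frac_in_motif * n_total)
  if (n_motif > 0L && nrow(genome$motif_instances) == 0L) {
    abort("invalid-argument: frac_in_motif > 0 but genome has no planted instances",
          class = "sitefx_invalid_argument")
  }
  motif_by_id <- setNames(motifs, vapply(motifs, `[[`, character(1), "motif_id"))

  min_flank <- check_count(min_flank, "min_flank")
  lens_all <- chrom_lengths_of(genome)

  with_seed(seed, {
    rows <- list()
    if (n_motif > 0L) {
      inst <- genome$motif_instances
      if (min_flank > 0L && nrow(inst) > 0L) {
        k_max <- if (length(motifs)) max(vapply(motifs, length, integer(1))) else 0L
        inst <- inst[inst$start >= min_flank &
                       inst$start < lens_all[inst$chrom] - min_flank - k_max, ,
                     drop = FALSE]
      }
      if (n_motif > nrow(inst)) {
        abort("invalid-argument: more motif-hitting variants requested than planted instances",
              class = "sitefx_invalid_argument")
      }
      pick <- inst[sample.int(nrow(inst), n_motif), , drop = FALSE]
      for (j in seq_len(nrow(pick))) {
        m <- motif_by_id[[pick$motif_id[j]]]
        if (is.null(m)) {
          abort(sprintf("invalid-argument: motif model '%s' not supplied", pick$motif_id[j]),
                class = "sitefx_invalid_argument")
        }
        gaps <- apply(m$pwm, 1L, function(r) max(r) - min(r))
        col <- which.max(gaps)
        pos <- pick$start[j] + col - 1L
        ref <- genome_slice(genome, pick$chrom[j], pos, pos + 1L)
        alt <- DNA_BASES[which.min(m$pwm[col, ])]
        if (alt == ref) {  # consensus is also the minimum only in degenerate PWMs
          alt <- DNA_BASES[order(m$pwm[col, ])][2L]
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = pick$chrom[j], pos = pos, ref = ref, alt = alt,
          in_motif = TRUE, motif_id = pick$motif_id[j]
        )
      }
    }
    n_bg <- n_total - n_motif
    if (n_bg > 0L) {
      lens <- chrom_lengths_of(genome)
      blocked <- genome$motif_instances
      candidates <- dplyr::bind_rows(lapply(names(lens), function(ch) {
        excl <- integer(0)
        b <- blocked[blocked$chrom == ch, , drop = FALSE]
        if (nrow(b) > 0L) {
          widths <- vapply(b$motif_id, function(id) {
            m <- motif_by_id[[id]]
            if (is.null(m)) 0L else length(m)
          }, integer(1))
          excl <- unlist(mapply(function(s, w) if (w > 0) s:(s + w - 1L) else integer(0),
                                b$start, widths, SIMPLIFY = FALSE))
        }
        lo <- min_flank
        hi <- lens[[ch]] - 1L - min_flank
        if (hi < lo) return(NULL)
        pos <- setdiff(lo:hi, excl)
        tibble::tibble(chrom = ch, pos = as.integer(pos))
      }))
      if (n_bg > nrow(candidates)) {
        abort("invalid-argument: n_total exceeds available positions",
              class = "sitefx_invalid_argument")
      }
      sel <- candidates[sample.int(nrow(candidates), n_bg), , drop = FALSE]
      ref <- vapply(seq_len(nrow(sel)), function(i) {
        genome_slice(genome, sel$chrom[i], sel$pos[i], sel$pos[i] + 1L)
      }, character(1))
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = sel$chrom, pos = sel$pos, ref = ref, alt = unname(alt),
        in_motif = FALSE, motif_id = NA_character_
      )
    }
    out <- dplyr::bind_rows(rows)
    out <- dplyr::arrange(out, .data$chrom, .data$pos)
    out$id <- sprintf("var_%s_%d_%s_%s", out$chrom, out$pos + 1L, out$ref, out$alt)
    dplyr::select(out, "chrom", "pos", "id", "ref", "alt", "in_motif", "motif_id")
  })
}
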