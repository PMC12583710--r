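#' Dinucleotide-preserving sequence shuffle
#'
#' Randomly permutes a sequence while exactly conserving all 16 adjacent
#' dinucleotide counts and the first and last base, by sampling a uniform
#' Eulerian arrangement of the dinucleotide transition multigraph
#' (Altschul-Erickson random-arborescence construction): a uniformly random
#' last-exit edge set forming an arborescence into the terminal base is
#' drawn by rejection, the remaining out-edges of every vertex are permuted
#' uniformly, and the Euler path is walked from the first base.
#'
#' @param seq String over ACGT, length >= 1.
#' @return A shuffled string with identical dinucleotide count matrix and
#'   endpoints. Uses the current RNG stream (seed with [set.seed()] for
#'   reproducibility).
#' @examples
#' set.seed(1)
#' dinucleotide_shuffle("ACGTACGTAC")
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- seq_to_ints(seq, "shuffle input")
  n <- length(s)
  if (n <= 3L) return(seq)  # endpoints + <=1 interior edge: arrangement unique

  last <- s[n]
  # out-edge target multisets per source base
  targets <- split(s[-1L], s[-n])
  src <- as.integer(names(targets))

  pick_last <- src[src != last]
  repeat {
    # candidate last-exit edge per non-terminal source
    last_edge <- vapply(pick_last, function(u) {
      tu <- targets[[as.character(u)]]
      tu[sample.int(length(tu), 1L)]
    }, integer(1))
    names(last_edge) <- pick_last
    # arborescence check: every source must reach `last` via last-exit edges
    ok <- TRUE
    for (u in pick_last) {
      v <- u
      steps <- 0L
      while (v != last) {
        nxt <- last_edge[as.character(v)]
        if (is.na(nxt)) { ok <- FALSE; break }
        v <- nxt
        steps <- steps + 1L
        if (steps > length(src)) { ok <- FALSE; break }  # cycle
      }
      if (!ok) break
    }
    if (ok) break
  }

  # order out-edges: uniform permutation, reserved last-exit edge at the end
  ordered <- lapply(seq_along(targets), function(i) {
    u <- src[i]
    tu <- targets[[i]]
    if (u == last) {
      tu[sample.int(length(tu))]
    } else {
      le <- last_edge[[as.character(u)]]
      rest <- tu[-match(le, tu)]
      c(if (length(rest)) rest[sample.int(length(rest))], le)
    }
  })
  names(ordered) <- as.character(src)

  # walk the Euler path
  out <- integer(n)
  out[1L] <- s[1L]
  ptr <- setNames(rep(1L, length(src)), as.character(src))
  v <- s[1L]
  for (i in 2:n) {
    key <- as.character(v)
    v <- ordered[[key]][ptr[[key]]]
    ptr[[key]] <- ptr[[key]] + 1L
    out[i] <- v
  }
  ints_to_seq(out)
}

#' Count dinucleotides in a sequence
#'
#' @param seq String over ACGT.
#' @return 4 x 4 integer matrix of adjacent-pair counts (row = first base).
#' @export
dinucleotide_counts <- function(seq) {
  s <- seq_to_ints(seq, "sequence")
  m <- matrix(0L, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  if (length(s) >= 2L) {
    tab <- table(factor(s[-length(s)], levels = 1:4),
                 factor(s[-1L], levels = 1:4))
    m[] <- as.integer(tab)
  }
  m
}

#' Generate shuffled-background allele pairs for one variant
#'
#' For each of `n_null` draws the window around the variant is
#' dinucleotide-shuffled once, duplicated, and the reference or alternate
#' allele written at the center — so each pair differs at exactly the center
#' base and carries an accessibility-background with the observed window's
#' dinucleotide composition.
#'
#' @param window Shuffle window string (length `L_shuf`) centered on the
#'   variant; its center base must equal `ref`.
#' @param ref,alt Variant alleles.
#' @param n_null Number of pairs to draw.
#' @return List of `n_null` lists with elements `ref` and `alt`.
#' @export
make_null_pairs <- function(window, ref, alt, n_null) {
  n_null <- check_count(n_null, "n_null", min = 1L)
  L <- nchar(window)
  center <- L %/% 2L + 1L  # 1-based
  if (substr(window, center, center) != ref) {
    abort(sprintf("invalid-argument: window center base %s != ref %s",
                  substr(window, center, center), ref),
          class = "sitefx_invalid_argument")
  }
  lapply(seq_len(n_null), function(i) {
    sh <- dinucleotide_shuffle(window)
    r <- sh; substr(r, center, center) <- ref
    a <- sh; substr(a, center, center) <- alt
    list(ref = r, alt = a)
  })
}

new_null_distribution <- function(scores, metric, context_id = NA_character_) {
  scores <- sort(as.numeric(scores))
  if (length(scores) < 1L) {
    abort("invalid-state: empty null distribution", class = "sitefx_invalid_state")
  }
  structure(
    list(context_id = context_id, metric = metric, scores = scores,
         n_null = length(scores)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> metric %s, n_null = %d, range [%.4g, %.4g]\n",
              x$metric, x$n_null, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Score null pairs into per-metric null distributions
#'
#' Each null pair is scored with the same procedure as observed variants:
#' the central `L_pred` bases of each allele copy are run through the
#' predictor and abs_logFC / JSD computed.
#'
#' @param predictor A predictor.
#' @param pairs Output of [make_null_pairs()].
#' @param L_pred Prediction window length (must not exceed the pair length).
#' @param context_id Optional context label carried into the result.
#' @return List with `abs_logFC` and `jsd`, each a `null_distribution`.
#' @export
build_null <- function(predictor, pairs, L_pred, context_id = NA_character_) {
  L_shuf <- nchar(pairs[[1L]]$ref)
  L_pred <- check_count(L_pred, "L_pred", min = 1L)
  if (L_pred > L_shuf) {
    abort("invalid-argument: L_pred must not exceed the shuffle window length",
          class = "sitefx_invalid_argument")
  }
  # align centers: variant stays at floor(L_pred/2) of the scored window
  start <- (L_shuf %/% 2L) - (L_pred %/% 2L) + 1L  # 1-based
  stop <- start + L_pred - 1L
  scores <- purrr::map(pairs, function(pr) {
    score_variant(predictor,
                  substr(pr$ref, start, stop),
                  substr(pr$alt, start, stop))
  })
  list(
    abs_logFC = new_null_distribution(
      abs(vapply(scores, `[[`, numeric(1), "logFC")), "abs_logFC", context_id),
    jsd = new_null_distribution(
      vapply(scores, `[[`, numeric(1), "jsd"), "jsd", context_id)
  )
}

#' Empirical p-value against a null distribution
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)` by default (add-one
#' convention: p is never 0 and the minimum attainable p is
#' `1/(1 + n_null)`). With `add_one = FALSE` the literal proportion
#' `#\{null >= observed\} / n_null` is returned instead.
#'
#' @param null A `null_distribution` (or a numeric vector of null scores).
#' @param observed Observed score(s) on the same non-negative metric.
#' @param add_one Use the add-one convention (default TRUE).
#' @return Empirical p-value(s) in `(0, 1]` (or `[0, 1]` when
#'   `add_one = FALSE`).
#' @export
empirical_pvalue <- function(null, observed, add_one = TRUE) {
  scores <- if (inherits(null, "null_distribution")) null$scores else sort(as.numeric(null))
  if (length(scores) < 1L) {
    abort("invalid-state: empty null distribution", class = "sitefx_invalid_state")
  }
  if (any(!is.finite(observed))) {
    abort("invalid-argument: observed scores must be finite",
          class = "sitefx_invalid_argument")
  }
  n <- length(scores)
  # scores sorted ascending: #{null >= obs} = n - #{null < obs}
  r <- n - findInterval(observed, scores, left.open = TRUE)
  if (add_one) (1 + r) / (1 + n) else r / n
}

#' Attach empirical p-values to a score table
#'
#' Builds dinucleotide-shuffle nulls and converts each observed abs_logFC
#' and JSD into an empirical p-value (columns `p_logfc`, `p_jsd`). By
#' default one null of `n_null` draws is built per (variant, context) — the
#' statistically conservative reading. With `pool_null = TRUE` a single
#' null per context, pooled over the observed variants' shuffled
#' backgrounds (`n_null` draws total, distributed round-robin across
#' variants), is shared by all variants — approximating the
#' one-large-null-per-scored-set economy.
#'
#' @param scores Score tibble from [score_variants()].
#' @param predictors Named list of per-context predictors (must cover every
#'   context in `scores`).
#' @param genome The genome the variants were scored against.
#' @param L_pred Prediction window length (same as used for scoring).
#' @param L_shuf Shuffle window length, default 2114.
#' @param n_null Null draws, default 10000.
#' @param seed Integer seed.
#' @param pool_null Share one pooled null per context (default FALSE).
#' @param add_one Add-one p-value convention (default TRUE).
#' @return `scores` with `p_logfc` and `p_jsd` columns appended. Variants
#'   whose shuffle window leaves the chromosome get `NA` p-values and are
#'   listed in `attr(, "null_failures")`.
#' @export
add_empirical_pvalues <- function(scores, predictors, genome,
                                  L_pred = 1000L, L_shuf = 2114L,
                                  n_null = 10000L, seed = NULL,
                                  pool_null = FALSE, add_one = TRUE) {
  L_shuf <- check_count(L_shuf, "L_shuf", min = 1L)
  if (L_shuf < L_pred) {
    abort("invalid-argument: L_shuf must be >= L_pred",
          class = "sitefx_invalid_argument")
  }
  n_null <- check_count(n_null, "n_null", min = 1L)
  contexts <- unique(scores$context)
  missing_ctx <- setdiff(contexts, names(predictors))
  if (length(missing_ctx)) {
    abort(sprintf("invalid-argument: no predictor for context(s): %s",
                  paste(missing_ctx, collapse = ", ")),
          class = "sitefx_invalid_argument")
  }
  variants <- dplyr::distinct(scores, .data$variant_id, .data$chrom,
                              .data$pos, .data$ref, .data$alt)
  with_seed(seed, {
    # shuffle windows (shared across contexts)
    windows <- vector("list", nrow(variants))
    fail <- list()
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      windows[[i]] <- tryCatch(
        extract_allele_windows(genome, v$chrom, v$pos, v$ref, v$alt, L_shuf)$ref,
        error = function(e) {
          fail[[length(fail) + 1L]] <<- tibble::tibble(
            variant_id = v$variant_id, reason = conditionMessage(e))
          NULL
        })
    }
    usable <- !vapply(windows, is.null, logical(1))

    p_lfc <- setNames(rep(NA_real_, nrow(scores)), NULL)
    p_jsd <- rep(NA_real_, nrow(scores))

    if (pool_null) {
      idx_usable <- which(usable)
      # round-robin allocation of n_null draws across usable variants
      alloc <- rep(0L, nrow(variants))
      if (length(idx_usable)) {
        reps <- rep(idx_usable, length.out = n_null)
        tb <- table(reps)
        alloc[as.integer(names(tb))] <- as.integer(tb)
      }
      pairs <- unlist(lapply(which(alloc > 0L), function(i) {
        make_null_pairs(windows[[i]], variants$ref[i], variants$alt[i], alloc[i])
      }), recursive = FALSE)
      for (ctx in contexts) {
        nulls <- build_null(predictors[[ctx]], pairs, L_pred, ctx)
        sel <- scores$context == ctx &
          scores$variant_id %in% variants$variant_id[usable]
        p_lfc[sel] <- empirical_pvalue(nulls$abs_logFC, scores$abs_logFC[sel], add_one)
        p_jsd[sel] <- empirical_pvalue(nulls$jsd, scores$jsd[sel], add_one)
      }
    } else {
      for (i in seq_len(nrow(variants))) {
        if (!usable[i]) next
        pairs <- make_null_pairs(windows[[i]], variants$ref[i],
                                 variants$alt[i], n_null)
        for (ctx in contexts) {
          nulls <- build_null(predictors[[ctx]], pairs, L_pred, ctx)
          sel <- scores$context == ctx &
            scores$variant_id == variants$variant_id[i]
          p_lfc[sel] <- empirical_pvalue(nulls$abs_logFC, scores$abs_logFC[sel], add_one)
          p_jsd[sel] <- empirical_pvalue(nulls$jsd, scores$jsd[sel], add_one)
        }
      }
    }
    out <- scores
    out$p_logfc <- p_lfc
    out$p_jsd <- p_jsd
    attr(out, "null_failures") <- dplyr::bind_rows(
      tibble::tibble(variant_id = character(), reason = character()), fail)
    out
  })
}
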