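#' Extract reference and alternate allele windows around a variant
#'
#' Both windows span `[pos - floor(L/2), pos - floor(L/2) + L)` with the
#' variant base at offset `floor(L/2)` (0-based); they are identical except
#' at that center base. The genome base at the variant position must equal
#' the declared reference allele.
#'
#' @param genome A `synthetic_genome` (or anything from
#'   [read_genome_fasta()]).
#' @param chrom,pos Variant location (`pos` 0-based).
#' @param ref,alt Reference and alternate alleles (single bases, different).
#' @param L Window length in bp, default 1000 (the predictor's 1 kb input).
#'
#' @return List with `ref`, `alt` (window strings), `start` (0-based window
#'   start) and `center` (offset of the variant inside the window).
#' @export
extract_allele_windows <- function(genome, chrom, pos, ref, alt, L = 1000L) {
  L <- check_count(L, "L", min = 1L)
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES || ref == alt) {
    abort("invalid-argument: ref and alt must be distinct single bases in ACGT",
          class = "sitefx_invalid_argument")
  }
  center <- L %/% 2L
  start <- pos - center
  len <- chrom_lengths_of(genome)[[chrom]]
  if (start < 0L || start + L > len) {
    abort(sprintf(
      "window-bounds-error: window [%d, %d) exceeds %s bounds [0, %d)",
      start, start + L, chrom, len
    ), class = "sitefx_window_bounds_error")
  }
  win <- genome_slice(genome, chrom, start, start + L)
  genome_base <- substr(win, center + 1L, center + 1L)
  if (genome_base != ref) {
    abort(sprintf(
      "ref-allele-error: genome base at %s:%d is %s, variant declares ref %s",
      chrom, pos + 1L, genome_base, ref
    ), class = "sitefx_ref_allele_error")
  }
  alt_win <- win
  substr(alt_win, center + 1L, center + 1L) <- alt
  list(ref = win, alt = alt_win, start = start, center = center)
}

#' Jensen-Shannon distance between two probability vectors
#'
#' `JSD(p, q) = sqrt(KL(p || m)/2 + KL(q || m)/2)` with `m = (p + q)/2` and
#' base-2 logarithms; `0 * log(0/x)` is taken as 0. The distance is
#' symmetric, bounded in `[0, 1]`, and reaches 1 exactly for distributions
#' with disjoint support.
#'
#' @param p,q Non-negative vectors of equal length summing to 1 (within
#'   1e-6).
#' @return A scalar in `[0, 1]`.
#' @examples
#' jensen_shannon_distance(c(0.5, 0.5), c(0.5, 0.5))  # 0
#' jensen_shannon_distance(c(1, 0), c(0, 1))          # 1
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q)) {
    abort("invalid-distribution: p and q must have equal length",
          class = "sitefx_invalid_distribution")
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("invalid-distribution: p and q must be probability vectors (non-negative, sum 1)",
          class = "sitefx_invalid_distribution")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(m[nz])))
  }
  jsdiv <- (kl(p) + kl(q)) / 2
  # divergence is bounded by 1 bit; clamp tiny negative rounding
  sqrt(min(max(jsdiv, 0), 1))
}

#' Score one variant under one predictor
#'
#' Effect sizes of an alternate versus reference allele: the log2 fold
#' change of total predicted coverage (computed on the log scale, never by
#' exponentiating counts) and the Jensen-Shannon distance between the two
#' per-base probability profiles (profile-shape change).
#'
#' @param predictor A predictor with a [predict_accessibility()] method.
#' @param ref_win,alt_win Window strings from [extract_allele_windows()].
#' @return List with `logFC` (log2 units) and `jsd`.
#' @export
score_variant <- function(predictor, ref_win, alt_win) {
  pr <- validate_profile(predict_accessibility(predictor, ref_win), nchar(ref_win))
  pa <- validate_profile(predict_accessibility(predictor, alt_win), nchar(alt_win))
  list(
    logFC = (pa$log_total - pr$log_total) / log(2),
    jsd = jensen_shannon_distance(pr$profile, pa$profile)
  )
}

#' Score every variant under every context predictor
#'
#' Produces the long variant-by-context score matrix. Variants that fail
#' window extraction or prediction (reference mismatch, window out of
#' bounds, invalid sequence) are excluded from the matrix and reported in
#' the `failures` attribute with their reason — never silently dropped.
#'
#' @param predictors Named list of predictors (names are context ids).
#' @param variants Variant tibble (`chrom`, `pos` 0-based, `id`, `ref`,
#'   `alt`).
#' @param genome A `synthetic_genome`.
#' @param L Prediction window length, default 1000.
#'
#' @return Tibble with one row per (variant, context): `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `context`, `logFC`, `abs_logFC`, `jsd`.
#'   Failed variants are recorded in `attr(, "failures")` (tibble
#'   `variant_id`, `reason`).
#' @export
score_variants <- function(predictors, variants, genome, L = 1000L) {
  if (length(predictors) < 1L || is.null(names(predictors))) {
    abort("invalid-argument: `predictors` must be a non-empty named list",
          class = "sitefx_invalid_argument")
  }
  contexts <- names(predictors)
  rows <- vector("list", nrow(variants))
  failures <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    res <- tryCatch({
      win <- extract_allele_windows(genome, v$chrom, v$pos, v$ref, v$alt, L)
      purrr::map_dfr(contexts, function(ctx) {
        s <- score_variant(predictors[[ctx]], win$ref, win$alt)
        tibble::tibble(
          variant_id = v$id, chrom = v$chrom, pos = v$pos,
          ref = v$ref, alt = v$alt, context = ctx,
          logFC = s$logFC, abs_logFC = abs(s$logFC), jsd = s$jsd
        )
      })
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- tibble::tibble(
        variant_id = v$id, reason = conditionMessage(e)
      )
      NULL
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), context = character(),
      logFC = double(), abs_logFC = double(), jsd = double()
    )
  }
  attr(out, "failures") <- dplyr::bind_rows(
    tibble::tibble(variant_id = character(), reason = character()), failures
  )
  out
}
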