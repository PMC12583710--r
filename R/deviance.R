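#' Detect variants with context-dependent effects
#'
#' Regresses one context's per-variant effect sizes on another's (ordinary
#' least squares of `context_y` on `context_x`, with intercept), computes
#' externally studentized residuals, and selects the top quantile of
#' variants furthest from the regression line — variants whose predicted
#' effect deviates between the two contexts (e.g. ascending versus
#' descending aortic cells of one cell type).
#'
#' Externally studentized residuals are `t_i = r_i / (s_(i) sqrt(1 - h_i))`
#' with `s_(i)` the leave-one-out residual standard deviation and `h_i` the
#' leverage; two-sided p-values use the t distribution with `n - 3` degrees
#' of freedom. Points with leverage numerically 1 are flagged
#' (`infinite_leverage`) and excluded from selection.
#'
#' @param scores Long score tibble from [score_variants()] (one row per
#'   variant and context).
#' @param context_x,context_y Context ids; `context_y` is regressed on
#'   `context_x`.
#' @param metric Score column to compare, default `"abs_logFC"` (`"jsd"` is
#'   also accepted).
#' @param q Selection quantile in (0, 1], default 0.01 (top 1% of deviant
#'   SNPs); `k = max(1, floor(q * n))` variants are selected.
#'
#' @return A `deviance_fit` object; see [tidy.deviance_fit()] and
#'   [glance.deviance_fit()] for tabular views.
#' @export
context_deviance <- function(scores, context_x, context_y,
                             metric = c("abs_logFC", "jsd"), q = 0.01) {
  metric <- match.arg(metric)
  check_scalar_number(q, "q", lower = 1e-12, upper = 1)
  wide <- scores |>
    dplyr::filter(.data$context %in% c(context_x, context_y)) |>
    dplyr::select("variant_id", "chrom", "pos", "context",
                  value = dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "context", values_from = "value")
  if (!all(c(context_x, context_y) %in% names(wide))) {
    abort(sprintf("invalid-argument: contexts %s / %s not both present in scores",
                  context_x, context_y),
          class = "sitefx_invalid_argument")
  }
  wide <- dplyr::filter(wide, is.finite(.data[[context_x]]),
                        is.finite(.data[[context_y]]))
  x <- wide[[context_x]]
  y <- wide[[context_y]]
  n <- length(x)
  if (n < 5L) {
    abort("invalid-argument: need >= 5 complete variant pairs",
          class = "sitefx_invalid_argument")
  }
  if (stats::var(x) == 0) {
    abort("degenerate-design: predictor context has zero variance",
          class = "sitefx_degenerate_design")
  }
  fit <- stats::lm(y ~ x)
  h <- unname(stats::hatvalues(fit))
  r <- unname(stats::residuals(fit))
  inf_lev <- h >= 1 - 1e-10
  t_ext <- rep(NA_real_, n)
  t_ext[!inf_lev] <- unname(stats::rstudent(fit))[!inf_lev]
  p <- 2 * stats::pt(-abs(t_ext), df = n - 3L)
  # residual exactly 0 => t = 0, p = 1 (pt gives this; keep NA only for leverage 1)

  sel <- select_deviants(t_ext, q, p = p, ids = wide$variant_id)

  data <- tibble::tibble(
    variant_id = wide$variant_id,
    chrom = wide$chrom, pos = wide$pos,
    x = x, y = y,
    residual = r, leverage = h,
    t = t_ext, p = p,
    infinite_leverage = inf_lev,
    selected = wide$variant_id %in% sel$selected
  )
  structure(
    list(
      data = data,
      context_x = context_x, context_y = context_y, metric = metric,
      slope = unname(stats::coef(fit))[2L],
      intercept = unname(stats::coef(fit))[1L],
      sigma = summary(fit)$sigma,
      r_squared = summary(fit)$r.squared,
      n = n, q = q, k = sel$k,
      selected = sel$selected,
      threshold_p = sel$threshold_p
    ),
    class = "deviance_fit"
  )
}

#' Select the top quantile of deviant variants
#'
#' Picks the `k = max(1, floor(q * n))` variants with the largest absolute
#' studentized residual; ties break by smaller p-value, then lexicographic
#' variant id. `NA` statistics (flagged infinite-leverage points) are never
#' selected.
#'
#' @param t Studentized residual vector.
#' @param q Selection quantile in (0, 1].
#' @param p Two-sided outlier p-values (defaults to ranking by `|t|` only).
#' @param ids Variant identifiers (defaults to index strings).
#' @return List with `selected` (ids), `k`, and `threshold_p` (largest
#'   selected p-value).
#' @export
select_deviants <- function(t, q, p = NULL, ids = NULL) {
  if (length(t) == 0L) {
    abort("invalid-argument: empty residual vector",
          class = "sitefx_invalid_argument")
  }
  check_scalar_number(q, "q", lower = 1e-12, upper = 1)
  n <- length(t)
  if (is.null(ids)) ids <- sprintf("v%0*d", nchar(n), seq_len(n))
  if (is.null(p)) p <- rep(NA_real_, n)
  k <- max(1L, as.integer(floor(q * n)))
  ord <- order(-abs(t), p, ids, na.last = TRUE)
  ord <- ord[!is.na(t[ord])]
  take <- ord[seq_len(min(k, length(ord)))]
  list(selected = ids[take], k = k,
       threshold_p = if (all(is.na(p[take]))) NA_real_ else max(p[take], na.rm = TRUE))
}

#' @export
print.deviance_fit <- function(x, ...) {
  cat(sprintf(
    "<deviance_fit> %s: %s ~ %s, n = %d\n  slope %.4f, intercept %.4f, R^2 %.3f\n  top %.3g%% deviants: %d selected, threshold p = %.3g\n",
    x$metric, x$context_y, x$context_x, x$n, x$slope, x$intercept,
    x$r_squared, 100 * x$q, x$k, x$threshold_p))
  invisible(x)
}

#' Per-variant deviance table
#'
#' @param x A `deviance_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variant: observed effects in both
#'   contexts, raw residual, leverage, externally studentized residual `t`,
#'   two-sided outlier p-value, and the `selected` flag.
#' @export
tidy.deviance_fit <- function(x, ...) {
  x$data
}

#' One-row deviance fit summary
#'
#' @param x A `deviance_fit`.
#' @param ... Unused.
#' @return One-row tibble: contexts, metric, n, OLS coefficients, residual
#'   sigma, R^2, selection quantile, number selected, threshold p.
#' @export
glance.deviance_fit <- function(x, ...) {
  tibble::tibble(
    context_x = x$context_x, context_y = x$context_y, metric = x$metric,
    n = x$n, slope = x$slope, intercept = x$intercept, sigma = x$sigma,
    r_squared = x$r_squared, q = x$q, n_selected = x$k,
    threshold_p = x$threshold_p
  )
}

#' Deviance scatter plot
#'
#' Scatter of the two contexts' effect sizes with the fitted regression
#' line; selected deviant variants are highlighted.
#'
#' @param object A `deviance_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deviance_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = "deviant") +
    ggplot2::labs(
      x = sprintf("%s (%s)", object$metric, object$context_x),
      y = sprintf("%s (%s)", object$metric, object$context_y),
      title = sprintf("Cross-context deviance: top %.3g%%", 100 * object$q)
    ) +
    ggplot2::theme_minimal()
}

#' Export deviant-variant windows for motif discovery
#'
#' Writes the `2 * flank` bp window around each selected variant
#' (`[pos - flank, pos + flank)`, 0-based half-open, variant at offset
#' `flank`) as a BED file and a FASTA file ready for de novo motif
#' discovery (MEME-style input). Windows running off a chromosome end are
#' clipped, flagged in the BED name, and a warning is raised.
#'
#' @param genome A `synthetic_genome` (or [read_genome_fasta()] result).
#' @param variants Tibble with `chrom`, `pos` (0-based), `id` for the
#'   selected variants.
#' @param flank Flank size in bp, default 100 (200 bp windows).
#' @param bed,fasta Optional output paths; omitted outputs are not written.
#' @return Tibble of exported windows (`id`, `chrom`, `start`, `end`,
#'   `clipped`, `seq`), invisibly if any file was written.
#' @export
export_deviant_windows <- function(genome, variants, flank = 100L,
                                   bed = NULL, fasta = NULL) {
  flank <- check_count(flank, "flank", min = 1L)
  lens <- chrom_lengths_of(genome)
  out <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    start <- v$pos - flank
    end <- v$pos + flank
    clipped <- start < 0L || end > lens[[v$chrom]]
    if (clipped) {
      warn(sprintf("window for %s clipped to chromosome bounds", v$id))
      start <- max(start, 0L)
      end <- min(end, lens[[v$chrom]])
    }
    tibble::tibble(
      id = v$id, chrom = v$chrom, start = start, end = end,
      clipped = clipped,
      seq = genome_slice(genome, v$chrom, start, end)
    )
  })
  if (!is.null(bed)) {
    bed_name <- ifelse(out$clipped, paste0(out$id, "|clipped"), out$id)
    readr::write_tsv(
      tibble::tibble(out$chrom, out$start, out$end, bed_name),
      bed, col_names = FALSE)
  }
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(out$seq)
    names(seqs) <- sprintf("%s::%s:%d-%d", out$id, out$chrom, out$start, out$end)
    Biostrings::writeXStringSet(seqs, fasta, width = 80L)
  }
  if (is.null(bed) && is.null(fasta)) out else invisible(out)
}
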