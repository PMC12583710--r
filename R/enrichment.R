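#' Overlap of a GWAS gene set with differentially expressed genes
#'
#' Counts how many GWAS nearest-genes are differentially expressed
#' (adjusted p below `alpha`). Gene symbols are case-normalized before
#' matching; genes absent from the DE table count as not differentially
#' expressed.
#'
#' @param gwas_genes Character vector of GWAS nearest-genes (non-empty).
#' @param de_table Tibble with columns `gene` and `padj` (Benjamini-
#'   Hochberg adjusted p-values).
#' @param alpha DE significance threshold on `padj`, default 0.05.
#' @return List with `k` (DE GWAS genes), `n` (GWAS set size) and
#'   `proportion`.
#' @export
de_overlap <- function(gwas_genes, de_table, alpha = 0.05) {
  if (length(gwas_genes) == 0L) {
    abort("invalid-argument: empty GWAS gene set",
          class = "sitefx_invalid_argument")
  }
  check_scalar_number(alpha, "alpha", lower = 1e-300, upper = 1)
  gwas <- unique(toupper(gwas_genes))
  de_set <- toupper(de_table$gene[!is.na(de_table$padj) & de_table$padj < alpha])
  k <- sum(gwas %in% de_set)
  list(k = k, n = length(gwas), proportion = k / length(gwas))
}

#' Pooled random-gene-set DE baseline
#'
#' Draws `n_draws` random gene sets of `set_size` genes (without
#' replacement within a draw, independently across draws) from the
#' expressed genes and pools their DE counts into one baseline.
#'
#' @param expressed_genes Character vector of expressed genes.
#' @param de_set Character vector of differentially expressed genes.
#' @param set_size Genes per random draw, default 100.
#' @param n_draws Number of draws, default 1000.
#' @return List with pooled `k_rand`, `n_rand`, `proportion`, and
#'   `draw_proportions` (per-draw DE fractions, for the empirical variant).
#' @export
random_baseline <- function(expressed_genes, de_set, set_size = 100L,
                            n_draws = 1000L) {
  set_size <- check_count(set_size, "set_size", min = 1L)
  n_draws <- check_count(n_draws, "n_draws", min = 1L)
  pool <- unique(toupper(expressed_genes))
  if (set_size > length(pool)) {
    abort("invalid-argument: set_size exceeds the number of expressed genes",
          class = "sitefx_invalid_argument")
  }
  de <- pool %in% toupper(de_set)
  ks <- vapply(seq_len(n_draws), function(i) {
    sum(de[sample.int(length(pool), set_size)])
  }, integer(1))
  list(
    k_rand = sum(ks), n_rand = set_size * n_draws,
    proportion = sum(ks) / (set_size * n_draws),
    draw_proportions = ks / set_size
  )
}

#' Pearson chi-squared test of DE enrichment
#'
#' Tests the 2x2 table `[[k, n-k], [k_rand, n_rand-k_rand]]` (GWAS versus
#' pooled random baseline) with the plain Pearson statistic (df = 1, no
#' continuity correction) and an upper-tail p-value.
#'
#' @param k,n DE count and size of the GWAS gene set.
#' @param k_rand,n_rand Pooled DE count and size of the random baseline.
#' @return List with `chi2`, `df`, `p_value`, and the input proportions.
#' @export
chi_squared_enrichment <- function(k, n, k_rand, n_rand) {
  if (any(c(k, n, k_rand, n_rand) < 0) || n <= 0 || n_rand <= 0 ||
      k > n || k_rand > n_rand) {
    abort("invalid-argument: counts must satisfy 0 <= k <= n",
          class = "sitefx_invalid_argument")
  }
  tab <- matrix(c(k, n - k, k_rand, n_rand - k_rand), nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("undefined-test: a zero marginal leaves the chi-squared test undefined",
          class = "sitefx_undefined_test")
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(
    chi2 = unname(ht$statistic), df = 1L, p_value = unname(ht$p.value),
    proportion_gwas = k / n, proportion_random = k_rand / n_rand
  )
}

#' GWAS gene-set enrichment among differentially expressed genes
#'
#' End-to-end wrapper: overlap the GWAS nearest-gene set with the DE genes
#' of a cell type, build a pooled random-gene-set baseline from the
#' expressed genes, and test enrichment with a Pearson chi-squared test
#' (optionally also reporting an empirical p: the fraction of random draws
#' with a DE proportion at least as high as observed).
#'
#' @inheritParams de_overlap
#' @param expressed_genes Character vector of expressed genes (the random-
#'   draw universe).
#' @param set_size,n_draws Random baseline parameters (default 100-gene
#'   sets, 1000 draws).
#' @param seed Integer seed for the random draws.
#' @param empirical Also compute the per-draw empirical p-value.
#' @return An `enrichment_result`; see [tidy.enrichment_result()].
#' @examples
#' de <- tibble::tibble(gene = c("ANGPT1", "PRDM6", "MSRA"),
#'                      padj = c(0.001, 0.2, 0.01))
#' gwas_enrichment(c("ANGPT1", "MSRA", "ULK4"), de,
#'                 expressed_genes = c(de$gene, sprintf("G%d", 1:200)),
#'                 set_size = 50, n_draws = 100, seed = 1)
#' @export
gwas_enrichment <- function(gwas_genes, de_table, expressed_genes,
                            alpha = 0.05, set_size = 100L, n_draws = 1000L,
                            seed = NULL, empirical = FALSE) {
  obs <- de_overlap(gwas_genes, de_table, alpha)
  de_set <- toupper(de_table$gene[!is.na(de_table$padj) & de_table$padj < alpha])
  base <- with_seed(seed, {
    random_baseline(expressed_genes, de_set, set_size, n_draws)
  })
  test <- chi_squared_enrichment(obs$k, obs$n, base$k_rand, base$n_rand)
  p_emp <- if (empirical) {
    mean(base$draw_proportions >= obs$proportion)
  } else {
    NA_real_
  }
  structure(
    list(
      n_gwas = obs$n, k_gwas_de = obs$k, proportion_gwas = obs$proportion,
      set_size = set_size, n_draws = n_draws,
      k_rand = base$k_rand, n_rand = base$n_rand,
      proportion_random = base$proportion,
      chi2 = test$chi2, df = test$df, p_value = test$p_value,
      p_empirical = p_emp, alpha = alpha
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d/%d GWAS genes DE (%.1f%%) vs %.1f%% in %d random %d-gene sets\n  chi2(1) = %.3f, p = %.3g%s\n",
    x$k_gwas_de, x$n_gwas, 100 * x$proportion_gwas,
    100 * x$proportion_random, x$n_draws, x$set_size,
    x$chi2, x$p_value,
    if (is.na(x$p_empirical)) "" else sprintf(", empirical p = %.3g", x$p_empirical)))
  invisible(x)
}

#' Enrichment result as a one-row tibble
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with counts, proportions, chi-squared statistic
#'   and p-values.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_gwas = x$n_gwas, k_gwas_de = x$k_gwas_de,
    proportion_gwas = x$proportion_gwas,
    n_rand = x$n_rand, k_rand = x$k_rand,
    proportion_random = x$proportion_random,
    chi2 = x$chi2, df = x$df, p_value = x$p_value,
    p_empirical = x$p_empirical
  )
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- tidy.enrichment_result
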