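#' Simulate a correlated two-context effect-size matrix
#'
#' Emulates the scatter of per-variant abs_logFC scores between two
#' contexts: each variant carries a shared latent effect plus independent
#' per-context noise, with the noise component scaled so that the two
#' columns have Pearson correlation `rho` and per-context standard
#' deviation `sigma` (latent SD `sigma * sqrt(rho)`, noise SD
#' `sigma * sqrt(1 - rho)`). A fraction of variants is deviant: each gets
#' `+delta` added to exactly one context (chosen at random), and the truth
#' flags are returned for recovery benchmarks.
#'
#' @param n Number of variants (>= 10).
#' @param rho Target inter-context correlation in `[0, 1]`, default 0.95.
#' @param sigma Per-context effect-size SD (abs_logFC units), default 0.5.
#' @param frac_deviant Fraction of deviant variants; exactly
#'   `round(frac_deviant * n)` are flagged. Default 0.
#' @param delta Deviation added to one context of each deviant (abs_logFC
#'   units), default 0.
#' @param mu Mean effect size, default 1 (keeps scores on the positive
#'   abs_logFC scale; values are not clamped).
#' @param context_ids Length-2 character vector of context names.
#' @param seed Integer seed.
#'
#' @return List with `scores` (tibble `variant_id`, one column per context)
#'   and `truth` (tibble `variant_id`, `deviant`, `deviant_context`, plus
#'   the generating parameters as attributes).
#' @examples
#' sim <- simulate_score_matrix(1000, rho = 0.9, sigma = 0.5, seed = 1)
#' cor(sim$scores$context_A, sim$scores$context_B)
#' @export
simulate_score_matrix <- function(n, rho = 0.95, sigma = 0.5,
                                  frac_deviant = 0, delta = 0, mu = 1,
                                  context_ids = c("context_A", "context_B"),
                                  seed = NULL) {
  n <- check_count(n, "n", min = 10L)
  check_scalar_number(rho, "rho", 0, 1)
  check_scalar_number(sigma, "sigma", lower = 0)
  check_scalar_number(frac_deviant, "frac_deviant", 0, 1)
  check_scalar_number(delta, "delta", lower = 0)
  stopifnot(length(context_ids) == 2L)
  with_seed(seed, {
    latent <- mu + rnorm(n, 0, sigma * sqrt(rho))
    a <- latent + rnorm(n, 0, sigma * sqrt(1 - rho))
    b <- latent + rnorm(n, 0, sigma * sqrt(1 - rho))
    n_dev <- round(frac_deviant * n)
    deviant <- logical(n)
    dev_ctx <- rep(NA_character_, n)
    if (n_dev > 0L) {
      idx <- sample.int(n, n_dev)
      deviant[idx] <- TRUE
      which_ctx <- sample(c(1L, 2L), n_dev, replace = TRUE)
      a[idx[which_ctx == 1L]] <- a[idx[which_ctx == 1L]] + delta
      b[idx[which_ctx == 2L]] <- b[idx[which_ctx == 2L]] + delta
      dev_ctx[idx] <- context_ids[which_ctx]
    }
    ids <- sprintf("var%0*d", nchar(n), seq_len(n))
    scores <- tibble::tibble(variant_id = ids)
    scores[[context_ids[1L]]] <- a
    scores[[context_ids[2L]]] <- b
    truth <- tibble::tibble(variant_id = ids, deviant = deviant,
                            deviant_context = dev_ctx)
    attr(truth, "params") <- list(rho = rho, sigma = sigma, delta = delta,
                                  frac_deviant = frac_deviant, mu = mu)
    list(scores = scores, truth = truth)
  })
}

#' Convert a wide simulated score matrix to the long scoring layout
#'
#' Helper so simulated matrices can flow into [context_deviance()] exactly
#' like predictor-derived scores.
#'
#' @param scores Wide tibble from [simulate_score_matrix()].
#' @param metric Name the values should take, default `"abs_logFC"`.
#' @return Long tibble (`variant_id`, `chrom`, `pos`, `context`, metric).
#' @export
score_matrix_to_long <- function(scores, metric = "abs_logFC") {
  long <- tidyr::pivot_longer(scores, -"variant_id",
                              names_to = "context", values_to = metric)
  long$chrom <- NA_character_
  long$pos <- NA_integer_
  long
}

#' Simulate expressed, differentially expressed, and GWAS gene tables
#'
#' Each expressed gene is differentially expressed with probability
#' `frac_de`; GWAS nearest-genes are drawn from the expressed genes and are
#' DE with probability `min(1, enrichment_factor * frac_de)` (clamped with
#' a warning if the product exceeds 1). The DE table carries simulated
#' `log2FC` and BH-adjusted-style `padj` columns: DE genes get
#' `padj ~ U(0, alpha)`, others `padj ~ U(alpha, 1)`.
#'
#' @param n_genes Number of expressed genes.
#' @param frac_de Marginal DE probability, default 0.1.
#' @param n_gwas GWAS gene-set size (<= n_genes), default 82.
#' @param enrichment_factor Multiplier on the GWAS genes' DE probability,
#'   default 1 (no enrichment).
#' @param alpha DE padj threshold used to encode DE status, default 0.05.
#' @param seed Integer seed.
#'
#' @return List with `expressed` (character vector), `de_table` (tibble
#'   `gene`, `log2FC`, `padj`, `de`), and `gwas_genes` (character vector).
#' @export
simulate_de_tables <- function(n_genes, frac_de = 0.1, n_gwas = 82L,
                               enrichment_factor = 1, alpha = 0.05,
                               seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_gwas <- check_count(n_gwas, "n_gwas", min = 0L)
  check_scalar_number(frac_de, "frac_de", 0, 1)
  check_scalar_number(enrichment_factor, "enrichment_factor", lower = 0)
  if (n_gwas > n_genes) {
    abort("invalid-argument: n_gwas must not exceed n_genes",
          class = "sitefx_invalid_argument")
  }
  p_gwas <- enrichment_factor * frac_de
  if (p_gwas > 1) {
    warn(sprintf("GWAS DE probability %.3g clamped to 1", p_gwas))
    p_gwas <- 1
  }
  with_seed(seed, {
    genes <- sprintf("GENE%0*d", nchar(n_genes), seq_len(n_genes))
    gwas <- if (n_gwas > 0L) sample(genes, n_gwas) else character(0)
    is_gwas <- genes %in% gwas
    de <- logical(n_genes)
    de[!is_gwas] <- runif(sum(!is_gwas)) < frac_de
    de[is_gwas] <- runif(sum(is_gwas)) < p_gwas
    de_table <- tibble::tibble(
      gene = genes,
      log2FC = rnorm(n_genes, 0, 0.25) + ifelse(de, sample(c(-1, 1), n_genes, replace = TRUE) * 2, 0),
      padj = ifelse(de, runif(n_genes) * alpha, alpha + runif(n_genes) * (1 - alpha)),
      de = de
    )
    if (frac_de == 0 && enrichment_factor * frac_de == 0) {
      de_table$de <- FALSE
      de_table$padj <- pmax(de_table$padj, alpha)
    }
    list(expressed = genes, de_table = de_table, gwas_genes = gwas)
  })
}
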