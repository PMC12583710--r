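test_that("dinucleotide shuffle conserves pair counts and endpoints", {
  # unique arrangements map to themselves
  expect_identical(dinucleotide_shuffle("AAAA"), "AAAA")
  # exhaustive enumeration shows ACGT is alone in its arrangement class
  expect_identical(enumerate_dinuc_set("ACGT"), "ACGT")
  set.seed(1)
  expect_identical(dinucleotide_shuffle("ACGT"), "ACGT")

  set.seed(2)
  for (i in 1:200) {
    s <- random_dna(200)
    sh <- dinucleotide_shuffle(s)
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 200, 200), substr(s, 200, 200))
  }

  expect_error(dinucleotide_shuffle("ACGNT"), class = "sitefx_invalid_sequence")
})

test_that("shuffle outputs lie in the brute-force arrangement set", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_dna(8, alphabet = c("A", "C", "G"))
    valid <- enumerate_dinuc_set(s)
    draws <- replicate(30, dinucleotide_shuffle(s))
    expect_true(all(draws %in% valid))
  }
})

test_that("null pairs differ only at the center and are reproducible", {
  set.seed(4)
  win <- random_dna(101)
  ref <- substr(win, 51, 51)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

  set.seed(5)
  pairs <- make_null_pairs(win, ref, alt, 1)
  expect_length(pairs, 1)
  d <- which(strsplit(pairs[[1]]$ref, "")[[1]] != strsplit(pairs[[1]]$alt, "")[[1]])
  expect_identical(d, 51L)
  expect_identical(substr(pairs[[1]]$ref, 51, 51), ref)
  expect_identical(substr(pairs[[1]]$alt, 51, 51), alt)

  # reproducibility under a fixed seed
  set.seed(6); a <- make_null_pairs(win, ref, alt, 10)
  set.seed(6); b <- make_null_pairs(win, ref, alt, 10)
  expect_identical(a, b)

  # the pre-insertion background is the dinucleotide shuffle of the window:
  # re-running the RNG stream reproduces it, and its counts match the input
  set.seed(7); sh <- dinucleotide_shuffle(win)
  set.seed(7); pr <- make_null_pairs(win, ref, alt, 1)[[1]]
  expected_ref <- sh; substr(expected_ref, 51, 51) <- ref
  expect_identical(pr$ref, expected_ref)
  expect_identical(dinucleotide_counts(sh), dinucleotide_counts(win))

  # center base must equal ref
  expect_error(make_null_pairs(win, alt, ref, 1),
               class = "sitefx_invalid_argument")
})

test_that("build_null scores pairs like observed variants", {
  set.seed(8)
  win <- random_dna(121)
  ref <- substr(win, 61, 61)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pairs <- make_null_pairs(win, ref, alt, 25)

  # inert predictor: every null score is exactly 0
  inert <- toy_predictor(test_motif(betas = c(other = 1)), "ctx")
  nulls0 <- build_null(inert, pairs, 81L, "ctx")
  expect_equal(nulls0$abs_logFC$scores, rep(0, 25))
  expect_equal(nulls0$jsd$scores, rep(0, 25))
  expect_equal(nulls0$abs_logFC$n_null, 25)

  # active predictor: n scores per metric, sorted ascending
  pred <- toy_predictor(dense_motif(), "ctx")
  nulls <- build_null(pred, pairs, 81L, "ctx")
  expect_length(nulls$abs_logFC$scores, 25)
  expect_identical(nulls$abs_logFC$scores, sort(nulls$abs_logFC$scores))

  # relabeling ref/alt leaves the abs_logFC null invariant
  swapped <- lapply(pairs, function(p) list(ref = p$alt, alt = p$ref))
  nulls_sw <- build_null(pred, swapped, 81L, "ctx")
  expect_equal(nulls_sw$abs_logFC$scores, nulls$abs_logFC$scores)
  expect_equal(nulls_sw$jsd$scores, nulls$jsd$scores)

  expect_error(build_null(pred, pairs, 200L), class = "sitefx_invalid_argument")
})

test_that("empirical p-values follow the add-one counting rule", {
  null <- new_null <- sort(runif(999))
  nd <- structure(list(context_id = "c", metric = "abs_logFC",
                       scores = null, n_null = 999L),
                  class = "null_distribution")
  # observed beyond every null: minimum attainable p
  expect_equal(empirical_pvalue(nd, max(null) + 1), 1 / 1000)
  # observed at or below every null: p = 1
  expect_equal(empirical_pvalue(nd, min(null) - 1), 1)
  # exact median of 999 distinct nulls: 500 are >= median
  expect_equal(empirical_pvalue(nd, stats::median(null)), 501 / 1000)
  # literal proportion variant
  expect_equal(empirical_pvalue(nd, max(null) + 1, add_one = FALSE), 0)
  expect_equal(empirical_pvalue(nd, stats::median(null), add_one = FALSE),
               500 / 999)
  # monotone non-increasing in the observed score
  obs <- seq(0, 1.1, length.out = 50)
  p <- empirical_pvalue(nd, obs)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))

  expect_error(empirical_pvalue(numeric(0), 1), class = "sitefx_invalid_state")
  expect_error(empirical_pvalue(nd, NaN), class = "sitefx_invalid_argument")
})

test_that("score tables gain calibrated p-value columns end to end", {
  setup <- toy_two_context_setup(chrom_lengths = c(chr1 = 20000),
                                 n_per_motif = 6)
  v <- simulate_variants(setup$genome, 6, frac_in_motif = 0.5,
                         motifs = list(setup$shared, setup$a_only), seed = 20)
  sc <- score_variants(setup$predictors, v, setup$genome, L = 200L)

  aug <- add_empirical_pvalues(sc, setup$predictors, setup$genome,
                               L_pred = 200L, L_shuf = 400L, n_null = 49L,
                               seed = 21)
  expect_true(all(aug$p_logfc > 0 & aug$p_logfc <= 1))
  expect_true(all(aug$p_jsd > 0 & aug$p_jsd <= 1))
  expect_gte(min(aug$p_logfc), 1 / 50)

  # strong a_only-motif variants reach the minimum attainable p in ctx_A
  a_hit <- aug$variant_id %in% v$id[v$in_motif & v$motif_id == "a_only"]
  expect_true(all(aug$p_logfc[a_hit & aug$context == "ctx_A"] == 1 / 50))

  # pooled null: same contract, one shared null per context
  pooled <- add_empirical_pvalues(sc, setup$predictors, setup$genome,
                                  L_pred = 200L, L_shuf = 400L, n_null = 60L,
                                  seed = 22, pool_null = TRUE)
  expect_true(all(pooled$p_logfc > 0 & pooled$p_logfc <= 1))

  # reproducibility
  aug2 <- add_empirical_pvalues(sc, setup$predictors, setup$genome,
                                L_pred = 200L, L_shuf = 400L, n_null = 49L,
                                seed = 21)
  expect_identical(aug$p_logfc, aug2$p_logfc)

  expect_error(
    add_empirical_pvalues(sc, setup$predictors, setup$genome,
                          L_pred = 500L, L_shuf = 400L, n_null = 10L),
    class = "sitefx_invalid_argument")
})
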