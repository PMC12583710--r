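long_from_xy <- function(x, y, ids = NULL) {
  n <- length(x)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(n))
  tibble::tibble(
    variant_id = rep(ids, 2),
    chrom = NA_character_, pos = NA_integer_,
    context = rep(c("ctx_x", "ctx_y"), each = n),
    abs_logFC = c(x, y)
  )
}

test_that("OLS coefficients match the closed-form normal equations", {
  # exact linear data: slope 2, intercept 1, zero residuals
  x <- c(0.1, 0.4, 0.7, 1.1, 1.6, 2.0)
  # an exact fit makes lm's summary warn about perfect residuals; the
  # coefficients are still the quantity under test
  fit <- suppressWarnings(
    context_deviance(long_from_xy(x, 2 * x + 1), "ctx_x", "ctx_y"))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$data$residual, rep(0, 6), tolerance = 1e-12)

  # 10-point hand dataset against the normal equations
  set.seed(1)
  x10 <- runif(10, 0, 2)
  y10 <- 0.6 * x10 + 0.3 + rnorm(10, 0, 0.2)
  b_hat <- sum((x10 - mean(x10)) * (y10 - mean(y10))) / sum((x10 - mean(x10))^2)
  a_hat <- mean(y10) - b_hat * mean(x10)
  fit10 <- context_deviance(long_from_xy(x10, y10), "ctx_x", "ctx_y")
  expect_equal(fit10$slope, b_hat, tolerance = 1e-12)
  expect_equal(fit10$intercept, a_hat, tolerance = 1e-12)
  expect_equal(fit10$data$residual, y10 - (a_hat + b_hat * x10),
               tolerance = 1e-12)

  # constant x is a degenerate design
  expect_error(
    context_deviance(long_from_xy(rep(1, 6), rnorm(6)), "ctx_x", "ctx_y"),
    class = "sitefx_degenerate_design")
  expect_error(
    context_deviance(long_from_xy(1:3 / 3, 1:3 / 3), "ctx_x", "ctx_y"),
    class = "sitefx_invalid_argument")
})

test_that("externally studentized residuals match brute-force leave-one-out refits", {
  set.seed(2)
  n <- 50
  x <- runif(n, 0, 3)
  y <- 0.8 * x + 0.1 + rnorm(n, 0, 0.3)
  fit <- context_deviance(long_from_xy(x, y), "ctx_x", "ctx_y")
  d <- dplyr::arrange(fit$data, variant_id)

  # oracle: refit without point i, predict i, scale by the LOO sigma
  for (i in seq_len(n)) {
    loo <- stats::lm(y[-i] ~ x[-i])
    pred_i <- stats::coef(loo)[1] + stats::coef(loo)[2] * x[i]
    s_i <- summary(loo)$sigma
    xb <- x[-i]
    h_new <- 1 / (n - 1) + (x[i] - mean(xb))^2 / sum((xb - mean(xb))^2)
    t_oracle <- (y[i] - pred_i) / (s_i * sqrt(1 + h_new))
    expect_equal(d$t[i], unname(t_oracle), tolerance = 1e-8)
  }

  # two-sided p from t with n - 3 df, monotone decreasing in |t|
  expect_equal(d$p, 2 * stats::pt(-abs(d$t), df = n - 3), tolerance = 1e-12)
  ord <- order(abs(d$t))
  expect_true(all(diff(d$p[ord]) <= 1e-12))

  # a point with zero residual studentizes to 0 with p = 1: antisymmetric
  # design puts the fitted line exactly through the middle point
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(-2.5, -0.8, 0, 0.8, 2.5)
  f0 <- context_deviance(long_from_xy(x0, y0), "ctx_x", "ctx_y")
  mid <- which(f0$data$x == 0)
  expect_equal(f0$data$residual[mid], 0, tolerance = 1e-12)
  expect_equal(f0$data$t[mid], 0, tolerance = 1e-9)
  expect_equal(f0$data$p[mid], 1, tolerance = 1e-9)
})

test_that("deviant selection takes the top quantile of |t| deterministically", {
  set.seed(3)
  t <- rnorm(200)
  sel <- select_deviants(t, q = 0.01)
  expect_equal(sel$k, 2)
  expect_setequal(match(sel$selected, sprintf("v%03d", 1:200)),
                  order(-abs(t))[1:2])

  # k = max(1, floor(q n))
  expect_equal(select_deviants(rnorm(50), q = 0.01)$k, 1)
  expect_equal(select_deviants(rnorm(1000), q = 0.0155)$k, 15)

  # ties break by smaller p then lexicographic id
  t_tied <- c(2, -2, 2, 0.1)
  p_tied <- c(0.2, 0.1, 0.2, 0.9)
  sel_tied <- select_deviants(t_tied, q = 0.5, p = p_tied,
                              ids = c("b", "c", "a", "d"))
  expect_identical(sel_tied$selected, c("c", "a"))
  expect_equal(sel_tied$threshold_p, 0.2)

  # NA statistics (infinite leverage) are never selected
  sel_na <- select_deviants(c(NA, 1, -3), q = 1, ids = c("x", "y", "z"))
  expect_identical(sel_na$selected, c("z", "y"))

  expect_error(select_deviants(numeric(0), 0.01),
               class = "sitefx_invalid_argument")
})

test_that("injected deviants are recovered from simulated score matrices", {
  sim <- simulate_score_matrix(2000, rho = 0.95, sigma = 0.5,
                               frac_deviant = 0.01, delta = 3, seed = 4)
  fit <- context_deviance(score_matrix_to_long(sim$scores),
                          "context_A", "context_B", q = 0.01)
  expect_equal(fit$k, 20)
  truth <- sim$truth$variant_id[sim$truth$deviant]
  expect_gte(mean(fit$selected %in% truth), 0.9)
  expect_equal(sum(fit$data$selected), 20)
  expect_equal(sort(fit$data$variant_id[fit$data$selected]),
               sort(fit$selected))
  expect_true(all(fit$data$p > 0 & fit$data$p <= 1))
})

test_that("selection is invariant under affine rescaling of y", {
  sim <- simulate_score_matrix(500, rho = 0.9, sigma = 0.4,
                               frac_deviant = 0.02, delta = 2.5, seed = 5)
  long <- score_matrix_to_long(sim$scores)
  fit1 <- context_deviance(long, "context_A", "context_B", q = 0.02)
  long2 <- long
  sel_y <- long2$context == "context_B"
  long2$abs_logFC[sel_y] <- 3.5 * long2$abs_logFC[sel_y] - 2
  fit2 <- context_deviance(long2, "context_A", "context_B", q = 0.02)
  expect_setequal(fit1$selected, fit2$selected)
  expect_equal(fit1$data$t, fit2$data$t, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_score_matrix(100, rho = 0.9, sigma = 0.3, seed = 6)
  fit <- context_deviance(score_matrix_to_long(sim$scores),
                          "context_A", "context_B")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 100)
  expect_true(all(c("variant_id", "x", "y", "residual", "t", "p",
                    "selected") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 100)
  expect_equal(gl$n_selected, 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "deviance_fit")
})

test_that("deviant windows export as MEME-ready BED and FASTA", {
  g <- simulate_genome(c(chr1 = 3000), seed = 7)
  v <- tibble::tibble(chrom = "chr1", pos = c(1057L, 200L),
                      id = c("va", "vb"))
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fa")
  win <- export_deviant_windows(g, v, flank = 100L, bed = bed, fasta = fa)

  # coordinate arithmetic: pos 1057 spans [957, 1157), width 200
  expect_equal(win$start[1], 957)
  expect_equal(win$end[1], 1157)
  expect_equal(win$end - win$start, c(200L, 200L))
  expect_identical(win$seq[1], substr(g$sequences[["chr1"]], 958, 1157))

  bed_tab <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name"),
                             show_col_types = FALSE)
  expect_equal(bed_tab$end - bed_tab$start, c(200L, 200L))
  fa_seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(unname(Biostrings::width(fa_seqs)), c(200L, 200L))
  expect_identical(names(fa_seqs)[1], "va::chr1:957-1157")

  # out-of-bounds windows are clipped, flagged, and warned about
  v_edge <- tibble::tibble(chrom = "chr1", pos = 50L, id = "vc")
  expect_warning(win_edge <- export_deviant_windows(g, v_edge, flank = 100L,
                                                    bed = bed),
                 "clipped")
  expect_true(win_edge$clipped)
  expect_equal(win_edge$start, 0)
  bed_edge <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_match(bed_edge$X4[1], "clipped")
})
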