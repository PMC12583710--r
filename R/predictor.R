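#' Toy motif-grammar accessibility predictor
#'
#' A deterministic, desk-scale stand-in for a trained sequence-to-profile
#' chromatin-accessibility model (one per cellular context). The predictor
#' scans the window with each motif's PWM on the forward strand; every offset
#' scoring at or above the motif threshold is a hit with excess
#' `e = score - threshold`. Hits open chromatin in proportion to the
#' context's activation weight beta: the per-base activation is the sum of
#' `beta * e` over hits whose footprint covers the base, the profile is the
#' softmax of the activation vector, and the predicted log total coverage is
#' `baseline + sum(beta * e)` (natural log).
#'
#' Any external predictor can stand behind the same contract: downstream
#' scoring only requires a `predict_accessibility()` method returning a
#' per-base probability profile plus a finite `log_total`.
#'
#' @param motifs List of [motif_model()] objects (or a single one).
#' @param context_id Context this predictor models (selects each motif's
#'   beta; motifs without a beta for this context are inert).
#' @param baseline Baseline log total coverage b0 (natural-log counts),
#'   default `log(10000)`.
#'
#' @return An object of class `toy_predictor`.
#' @examples
#' m <- motif_model("M1", pwm_consensus_matrix("TGACTCAC"), threshold = 10,
#'                  betas = c(asc = 1, desc = 0))
#' p <- toy_predictor(m, "asc")
#' pred <- predict_accessibility(p, strrep("A", 100))
#' pred$log_total  # baseline: no hits in a poly-A window
#' @export
toy_predictor <- function(motifs, context_id, baseline = log(10000)) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L, all(vapply(motifs, inherits, logical(1), "motif_model")))
  stopifnot(is.character(context_id), length(context_id) == 1L)
  check_scalar_number(baseline, "baseline")
  structure(
    list(motifs = motifs, context_id = context_id, baseline = baseline),
    class = "toy_predictor"
  )
}

#' @export
print.toy_predictor <- function(x, ...) {
  cat(sprintf("<toy_predictor> context '%s', %d motif(s), baseline %.3f\n",
              x$context_id, length(x$motifs), x$baseline))
  invisible(x)
}

# Forward-strand PWM scan: returns per-offset scores (length L - k + 1).
scan_pwm <- function(pwm, ints) {
  k <- nrow(pwm)
  L <- length(ints)
  if (L < k) return(numeric(0))
  nw <- L - k + 1L
  s <- numeric(nw)
  for (i in seq_len(k)) {
    s <- s + pwm[i, ][ints[i:(i + nw - 1L)]]
  }
  unname(s)
}

#' Predict an accessibility profile for a sequence window
#'
#' @param object A predictor (e.g. [toy_predictor()]).
#' @param seq A string over ACGT.
#' @param ... Passed to methods.
#' @return List with `profile` (length-L probability vector summing to 1)
#'   and `log_total` (natural-log predicted total coverage).
#' @export
predict_accessibility <- function(object, seq, ...) {
  UseMethod("predict_accessibility")
}

#' @export
predict_accessibility.toy_predictor <- function(object, seq, ...) {
  ints <- seq_to_ints(seq, "window")
  L <- length(ints)
  activation <- numeric(L)
  total_act <- 0
  for (m in object$motifs) {
    beta <- unname(m$betas[object$context_id])
    if (is.na(beta) || beta == 0) next
    scores <- scan_pwm(m$pwm, ints)
    hits <- which(scores >= m$threshold)
    if (length(hits) == 0L) next
    k <- nrow(m$pwm)
    for (j in hits) {
      e <- scores[j] - m$threshold
      activation[j:(j + k - 1L)] <- activation[j:(j + k - 1L)] + beta * e
      total_act <- total_act + beta * e
    }
  }
  a <- activation - max(activation)  # stable softmax
  p <- exp(a)
  list(profile = p / sum(p), log_total = object$baseline + total_act)
}

validate_profile <- function(pred, L = NULL) {
  p <- pred$profile
  ok <- is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= 1e-9 &&
    is.finite(pred$log_total) && (is.null(L) || length(p) == L)
  if (!ok) {
    abort("predictor returned an invalid profile (negative mass, sum != 1, or non-finite log_total)",
          class = "sitefx_invalid_prediction")
  }
  invisible(pred)
}

#' Serialize predictor specifications to YAML
#'
#' One document describing a set of per-context toy predictors sharing a
#' motif grammar; PWMs are stored inline as row lists.
#'
#' @param predictors Named list of [toy_predictor()] objects (names are
#'   context ids).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_predictor_yaml <- function(predictors, path) {
  stopifnot(length(predictors) >= 1L)
  ctx <- lapply(predictors, function(p) {
    list(
      context_id = p$context_id,
      baseline = p$baseline,
      motifs = lapply(p$motifs, function(m) {
        list(
          motif_id = m$motif_id,
          threshold = m$threshold,
          betas = as.list(m$betas),
          pwm = apply(unname(m$pwm), 1L, as.list)
        )
      })
    )
  })
  yaml::write_yaml(list(contexts = unname(ctx)), path, precision = 15L)
  invisible(path)
}

#' Read predictor specifications from YAML
#'
#' @param path YAML path written by [write_predictor_yaml()].
#' @return Named list of `toy_predictor` objects keyed by context id.
#' @export
read_predictor_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc$contexts, function(ctx) {
    motifs <- lapply(ctx$motifs, function(m) {
      pwm <- do.call(rbind, lapply(m$pwm, unlist))
      motif_model(m$motif_id, pwm, m$threshold, unlist(m$betas))
    })
    toy_predictor(motifs, ctx$context_id, ctx$baseline)
  })
  setNames(out, vapply(out, `[[`, character(1), "context_id"))
}
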