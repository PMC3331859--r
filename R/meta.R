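# Cross-study heterogeneity and DerSimonian-Laird random-effects
# pooling of odds ratios.

#' Build a study-effects table
#'
#' Standard errors absent from the input are recovered from the 95%
#' confidence bounds as `(log(ci_high) - log(ci_low)) / (2 * 1.96)`.
#'
#' @param study_id Study labels.
#' @param or Per-study odds ratios.
#' @param ci_low,ci_high Optional 95% CI bounds.
#' @param se Optional standard errors of the log odds ratio.
#' @return Data frame: `study_id`, `log_or`, `se_log_or`.
#' @export
study_effects <- function(study_id, or, ci_low = NULL, ci_high = NULL,
                          se = NULL) {
  if (is.null(se)) {
    stopifnot(!is.null(ci_low), !is.null(ci_high))
    se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  }
  stopifnot(all(se > 0))
  data.frame(study_id = study_id, log_or = log(or), se_log_or = se,
             stringsAsFactors = FALSE)
}

#' Cochran's Q and I-squared heterogeneity
#'
#' Q is the inverse-variance-weighted sum of squared deviations from
#' the fixed-effect mean; its p-value comes from a chi-square with
#' k - 1 degrees of freedom; I-squared is
#' `max(0, (Q - (k-1)) / Q) * 100` (0 when Q = 0).
#'
#' @param effects Data frame from [study_effects()].
#' @return List: `k`, `q`, `q_p`, `i2` (percent).
#' @export
heterogeneity <- function(effects) {
  k <- nrow(effects)
  if (k == 1) {
    warning("single study: heterogeneity is degenerate")
    return(list(k = 1L, q = 0, q_p = 1, i2 = 0))
  }
  stopifnot(k >= 2)
  w <- 1 / effects$se_log_or^2
  fe <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - fe)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- if (q == 0) 0 else max(0, (q - (k - 1)) / q) * 100
  list(k = as.integer(k), q = q, q_p = q_p, i2 = i2)
}

#' DerSimonian-Laird random-effects meta-analysis of odds ratios
#'
#' Moment estimator of the between-study variance:
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2`; studies are re-weighted by
#' `1 / (se^2 + tau2)`; the pooled log odds ratio is their weighted
#' mean with `SE = 1/sqrt(sum(w*))`, 95% CI
#' `exp(pooled +/- 1.96 * SE)`, and a two-sided Z test.
#'
#' @param effects Data frame from [study_effects()].
#' @return List of class `meta_result`: `k`, `q`, `q_p`, `i2`, `tau2`,
#'   `pooled_or`, `ci_low`, `ci_high`, `z_p`.
#' @export
dl_random_effects <- function(effects) {
  k <- nrow(effects)
  stopifnot(k >= 1)
  if (k == 1) {
    se <- effects$se_log_or
    mu <- effects$log_or
    return(structure(list(k = 1L, q = 0, q_p = 1, i2 = 0, tau2 = 0,
                          pooled_or = exp(mu),
                          ci_low = exp(mu - 1.96 * se),
                          ci_high = exp(mu + 1.96 * se),
                          z_p = 2 * stats::pnorm(-abs(mu / se))),
                     class = "meta_result"))
  }
  het <- heterogeneity(effects)
  w <- 1 / effects$se_log_or^2
  tau2 <- max(0, (het$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (effects$se_log_or^2 + tau2)
  mu <- sum(ws * effects$log_or) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  structure(list(k = het$k, q = het$q, q_p = het$q_p, i2 = het$i2,
                 tau2 = tau2, pooled_or = exp(mu),
                 ci_low = exp(mu - 1.96 * se),
                 ci_high = exp(mu + 1.96 * se),
                 z_p = 2 * stats::pnorm(-abs(mu / se))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  pooled OR %.3f (95%% CI %.3f-%.3f), Z p = %.3g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$z_p))
  cat(sprintf("  Q = %.4f (p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$q_p, x$i2, x$tau2))
  invisible(x)
}
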