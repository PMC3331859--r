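# Analytic power for the case-control allelic comparison.

#' Analytic power of the two-proportion allelic comparison
#'
#' Normal-approximation power of the two-sided two-proportion test of
#' the case frequency `p1 = or*p0 / (1 + p0*(or-1))` against the
#' control frequency `p0`:
#' `power = pnorm((|p1-p0| - z * SE0) / SE1)` with
#' `z = qnorm(1 - alpha/2)`, null standard error
#' `SE0 = sqrt(pbar(1-pbar)(1/n1 + 1/n2))` at the pooled frequency
#' `pbar = (n1 p1 + n2 p0) / (n1 + n2)`, and alternative standard error
#' `SE1 = sqrt(p1(1-p1)/n1 + p0(1-p0)/n2)`.
#'
#' With `counting = "subjects"` (default), the allele frequency is
#' treated as a per-subject proportion and n1/n2 are subject counts;
#' `"alleles"` doubles the effective sample sizes. The optional
#' continuity correction subtracts `(1/n1 + 1/n2) / 2` from the
#' frequency difference.
#'
#' @param p0 Control minor-allele frequency in (0, 0.5].
#' @param odds_ratio Allelic odds ratio (> 0).
#' @param n_case,n_control Group sizes (subjects).
#' @param alpha Two-sided significance level.
#' @param counting `"subjects"` (default) or `"alleles"`.
#' @param continuity_correction Apply the continuity correction
#'   (default `FALSE`).
#' @return Power in (0, 1).
#' @export
#' @examples
#' allelic_power(0.2, 2.0, 630, 690, alpha = 1e-3)  # 0.9865
allelic_power <- function(p0, odds_ratio, n_case, n_control,
                          alpha = 0.05,
                          counting = c("subjects", "alleles"),
                          continuity_correction = FALSE) {
  counting <- match.arg(counting)
  stopifnot(p0 > 0, p0 <= 0.5, odds_ratio > 0,
            n_case >= 1, n_control >= 1, alpha > 0, alpha < 1)
  p1 <- case_allele_freq(p0, odds_ratio)
  if (p1 <= 0 || p1 >= 1) stop("implied case frequency out of (0, 1)")
  mult <- if (counting == "alleles") 2 else 1
  n1 <- mult * n_case; n2 <- mult * n_control
  pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(p1 - p0)
  if (continuity_correction)
    delta <- max(0, delta - (1 / n1 + 1 / n2) / 2)
  # both rejection tails; the far tail vanishes for any real effect but
  # makes the null (odds ratio 1) value equal alpha exactly
  stats::pnorm((delta - z * se0) / se1) +
    stats::pnorm((-delta - z * se0) / se1)
}

#' Power over a grid of control frequencies and odds ratios
#'
#' Evaluates [allelic_power()] on the Cartesian grid of `p0_grid` and
#' `or_grid`; the attribute `range_by_or` gives the min/max power per
#' odds ratio.
#'
#' @param p0_grid Control-frequency grid.
#' @param or_grid Odds-ratio grid.
#' @param n_case,n_control,alpha,counting,continuity_correction Passed
#'   to [allelic_power()].
#' @return Data frame: `p0`, `odds_ratio`, `power`.
#' @export
power_grid <- function(p0_grid, or_grid, n_case, n_control,
                       alpha = 0.05, counting = "subjects",
                       continuity_correction = FALSE) {
  g <- expand.grid(p0 = p0_grid, odds_ratio = or_grid,
                   KEEP.OUT.ATTRS = FALSE)
  if (!nrow(g)) {
    g$power <- numeric(0)
    return(g)
  }
  g$power <- mapply(function(p0, or)
    allelic_power(p0, or, n_case, n_control, alpha, counting,
                  continuity_correction),
    g$p0, g$odds_ratio)
  rng <- do.call(rbind, lapply(split(g, g$odds_ratio), function(d)
    data.frame(odds_ratio = d$odds_ratio[1L], min_power = min(d$power),
               max_power = max(d$power))))
  rownames(rng) <- NULL
  attr(g, "range_by_or") <- rng
  g
}
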