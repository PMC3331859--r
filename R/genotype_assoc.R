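# Individual-genotyping stage: QC filters, Hardy-Weinberg exact test,
# allelic and logistic-regression association, multiple-testing
# correction, pooled-vs-individual concordance, and the case-only
# age-at-onset scan.

#' Quality-control configuration for genotype matrices
#'
#' @param max_snp_missing Drop SNPs with missingness at or above this
#'   (default 0.05; keep requires < threshold).
#' @param max_ind_missing Drop individuals likewise (default 0.05).
#' @param hwe_p_min Drop SNPs whose control-group Hardy-Weinberg exact
#'   p is below this (default 0.001).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_snp_missing = 0.05, max_ind_missing = 0.05,
                      hwe_p_min = 0.001) {
  stopifnot(max_snp_missing > 0, max_snp_missing < 1,
            max_ind_missing > 0, max_ind_missing < 1,
            hwe_p_min > 0, hwe_p_min < 1)
  structure(list(max_snp_missing = max_snp_missing,
                 max_ind_missing = max_ind_missing,
                 hwe_p_min = hwe_p_min), class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: the p-value is the sum of probabilities of
#' all heterozygote counts no more probable than the observed one,
#' given the allele counts. Computed with a numerically stable
#' probability recurrence in the heterozygote count, so totals up to
#' about 1e5 are handled. Monomorphic markers give p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (minor homozygote,
#'   heterozygote, major homozygote in any orientation).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  n_a <- 2 * n_AA + n_Aa            # minor-allele count (orientation-free)
  if (n_a > n) n_a <- 2 * n - n_a   # work with the rarer allele
  if (n_a == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  h <- seq(n_a %% 2, n_a, by = 2)
  het <- h
  # log conditional probability of each heterozygote count given the
  # allele counts (multinomial / hypergeometric form, stable via lgamma)
  lp <- lgamma(n + 1) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
    lgamma(n - (n_a + h) / 2 + 1) + h * log(2) +
    lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele count")
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

genotype_counts <- function(dosage_row) {
  c(n2 = sum(dosage_row == 2L, na.rm = TRUE),
    n1 = sum(dosage_row == 1L, na.rm = TRUE),
    n0 = sum(dosage_row == 0L, na.rm = TRUE))
}

#' Filter a genotype matrix on missingness and Hardy-Weinberg equilibrium
#'
#' Single pass in a fixed order: (1) drop SNPs with missingness at or
#' above `max_snp_missing`; (2) drop individuals with missingness at or
#' above `max_ind_missing`, computed on the surviving SNPs; (3) drop
#' SNPs whose control-group Hardy-Weinberg exact p is below `hwe_p_min`.
#'
#' @param genotypes A `genotype_matrix` with a `samples` manifest whose
#'   `group` column identifies `control_group`.
#' @param config A [qc_config()].
#' @param control_group Group label of controls (default "control").
#' @return List: `genotypes` (filtered matrix), `report` (data frame of
#'   every exclusion: `item`, `type`, `reason`, `value`).
#' @export
qc_filter <- function(genotypes, config = qc_config(),
                      control_group = "control") {
  dos <- genotypes$dosage
  samples <- genotypes$samples
  report <- list()
  snp_miss <- rowMeans(is.na(dos))
  drop_snp <- snp_miss >= config$max_snp_missing
  if (any(drop_snp))
    report[[1L]] <- data.frame(item = rownames(dos)[drop_snp],
                               type = "snp", reason = "missingness",
                               value = snp_miss[drop_snp],
                               stringsAsFactors = FALSE)
  dos <- dos[!drop_snp, , drop = FALSE]
  ind_miss <- colMeans(is.na(dos))
  drop_ind <- ind_miss >= config$max_ind_missing
  if (any(drop_ind))
    report[[2L]] <- data.frame(item = colnames(dos)[drop_ind],
                               type = "individual", reason = "missingness",
                               value = ind_miss[drop_ind],
                               stringsAsFactors = FALSE)
  dos <- dos[, !drop_ind, drop = FALSE]
  samples <- samples[match(colnames(dos), samples$sample_id), ]
  ctrl <- samples$sample_id[samples$group == control_group]
  if (!length(ctrl))
    stop("no samples in control group '", control_group,
         "'; Hardy-Weinberg filtering refused")
  hwe_p <- apply(dos[, ctrl, drop = FALSE], 1L, function(r) {
    gc <- genotype_counts(r)
    if (sum(gc) == 0) return(1)
    hwe_exact_p(gc["n2"], gc["n1"], gc["n0"])
  })
  drop_hwe <- hwe_p < config$hwe_p_min
  if (any(drop_hwe))
    report[[3L]] <- data.frame(item = rownames(dos)[drop_hwe],
                               type = "snp", reason = "hwe",
                               value = hwe_p[drop_hwe],
                               stringsAsFactors = FALSE)
  dos <- dos[!drop_hwe, , drop = FALSE]
  out <- genotypes
  out$dosage <- dos
  out$samples <- samples
  out$map <- genotypes$map[match(rownames(dos), genotypes$map$snp_id), ,
                           drop = FALSE]
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(item = character(0), type = character(0),
               reason = character(0), value = numeric(0),
               stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  list(genotypes = out, report = rep_df)
}

#' Odds ratio from two allele frequencies
#'
#' The allelic cross-product odds ratio `[f1(1-f2)] / [f2(1-f1)]`.
#'
#' @param f1,f2 Minor-allele frequencies in cases and controls.
#' @return Odds ratio.
#' @export
#' @examples
#' odds_ratio_from_freq(0.373, 0.233)  # 1.96
odds_ratio_from_freq <- function(f1, f2) {
  f1 * (1 - f2) / (f2 * (1 - f1))
}

# 2x2 allele-count machinery: a,b = minor/major counts in cases,
# c,d in controls. Haldane-Anscombe 0.5 only when some cell is zero.
allelic_table_stats <- function(a, b, cc, d) {
  chi_tot <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi <- if (denom > 0) chi_tot * (a * d - b * cc)^2 / denom else NA_real_
  p <- if (is.na(chi)) NA_real_ else
    stats::pchisq(chi, 1L, lower.tail = FALSE)
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se), p = p, chi = chi)
}

minor_allele_in_controls <- function(dosage, control_ids) {
  f <- rowMeans(dosage[, control_ids, drop = FALSE], na.rm = TRUE) / 2
  ifelse(is.na(f) | f <= 0.5, "A", "B")  # dosage counts allele A
}

#' Allelic case-control association with odds ratio and 95% CI
#'
#' Per SNP: minor allele fixed in the control group; F1/F2 are the
#' case/control minor-allele frequencies from allele counts; the odds
#' ratio is the 2x2 cross-product with a log-OR normal 95% CI
#' (0.5 added to every cell only when a cell is zero); p from the 1-df
#' Pearson chi-square without continuity correction. SNPs monomorphic
#' in both groups are flagged untestable.
#'
#' @param genotypes A post-QC `genotype_matrix`.
#' @param case_group,control_group Group labels in the manifest.
#' @param comparison Label recorded in the result (e.g. "CRC vs N").
#' @return Data frame of per-SNP results with `model = "allelic"`:
#'   `snp_id`, `model`, `f_case`, `f_control`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_raw`, `testable`, `comparison`.
#' @export
allelic_assoc <- function(genotypes, case_group = "case",
                          control_group = "control",
                          comparison = paste(case_group, "vs",
                                             control_group)) {
  dos <- genotypes$dosage
  s <- genotypes$samples
  ca <- s$sample_id[s$group == case_group]
  co <- s$sample_id[s$group == control_group]
  stopifnot(length(ca) > 0, length(co) > 0)
  ma <- minor_allele_in_controls(dos, co)
  res <- lapply(seq_len(nrow(dos)), function(i) {
    x <- dos[i, ]
    if (ma[i] == "B") x <- 2L - x
    xa <- x[ca]; xo <- x[co]
    a <- sum(xa, na.rm = TRUE); b <- 2 * sum(!is.na(xa)) - a
    cc <- sum(xo, na.rm = TRUE); d <- 2 * sum(!is.na(xo)) - cc
    testable <- (a + cc) > 0 && (b + d) > 0
    st <- if (testable) allelic_table_stats(a, b, cc, d) else
      list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_)
    data.frame(snp_id = rownames(dos)[i], model = "allelic",
               f_case = if (a + b > 0) a / (a + b) else NA_real_,
               f_control = if (cc + d > 0) cc / (cc + d) else NA_real_,
               odds_ratio = st$or, ci_low = st$ci_low,
               ci_high = st$ci_high, p_raw = st$p, testable = testable,
               comparison = comparison, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

code_genotype <- function(dosage_minor, model) {
  switch(model,
         additive = dosage_minor,
         dominant = as.integer(dosage_minor >= 1L),
         recessive = as.integer(dosage_minor == 2L),
         stop("unknown model: ", model))
}

#' Binomial logistic regression for one coded predictor
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (via `stats::glm`). Complete separation (|beta| > 15 or
#' non-convergence) is flagged and no p-value is reported; a constant
#' predictor is untestable.
#'
#' @param x Coded genotype predictor (additive dosage, carrier, or
#'   homozygote indicator).
#' @param y Binary outcome (0/1).
#' @param covariates Optional data frame of additional covariates.
#' @return List: `beta`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p` (Wald), `converged`, `separation`, `testable`.
#' @export
fit_logistic <- function(x, y, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2)
    return(list(beta = NA_real_, se = NA_real_, odds_ratio = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                converged = FALSE, separation = FALSE, testable = FALSE))
  dat <- data.frame(y = y, x = x)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  fit <- suppressWarnings(stats::glm(
    y ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  sep <- !fit$converged || abs(beta) > 15
  p <- if (sep) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, se = se, odds_ratio = exp(beta),
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       p = p, converged = fit$converged, separation = sep,
       testable = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment within one
#' comparison family (wrapper over `stats::p.adjust`).
#'
#' @param p Vector of raw p-values (NA passed through).
#' @return Adjusted p-values, each at least the raw value, capped at 1.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Case-control association under allelic and genotypic models
#'
#' Runs [allelic_assoc()] and/or logistic regression with additive
#' (dosage 0/1/2), dominant (carrier) and recessive (minor homozygote)
#' codings, with the minor allele fixed in the control group.
#' Benjamini-Hochberg correction is applied across SNPs within each
#' (comparison, model) family.
#'
#' @param genotypes A post-QC `genotype_matrix`.
#' @param case_group,control_group Group labels.
#' @param models Subset of `c("allelic", "additive", "dominant",
#'   "recessive")`.
#' @param comparison Family label.
#' @param covariates Optional covariate data frame (logistic models).
#' @return Data frame of `AssocResult` rows: `snp_id`, `model`,
#'   `f_case`, `f_control`, `odds_ratio`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_bh`, `testable`, `comparison`.
#' @export
genotype_association <- function(genotypes, case_group = "case",
                                 control_group = "control",
                                 models = c("allelic", "additive"),
                                 comparison = paste(case_group, "vs",
                                                    control_group),
                                 covariates = NULL) {
  dos <- genotypes$dosage
  s <- genotypes$samples
  ca <- s$sample_id[s$group == case_group]
  co <- s$sample_id[s$group == control_group]
  ids <- c(ca, co)
  y <- rep(c(1L, 0L), c(length(ca), length(co)))
  ma <- minor_allele_in_controls(dos, co)
  out <- list()
  if ("allelic" %in% models) {
    al <- allelic_assoc(genotypes, case_group, control_group, comparison)
    al$p_bh <- bh_adjust(al$p_raw)
    out[["allelic"]] <- al
  }
  for (m in intersect(models, c("additive", "dominant", "recessive"))) {
    res <- lapply(seq_len(nrow(dos)), function(i) {
      x <- dos[i, ids]
      if (ma[i] == "B") x <- 2L - x
      f1 <- mean(x[seq_along(ca)], na.rm = TRUE) / 2
      f2 <- mean(x[-seq_along(ca)], na.rm = TRUE) / 2
      ft <- fit_logistic(code_genotype(x, m), y, covariates)
      data.frame(snp_id = rownames(dos)[i], model = m, f_case = f1,
                 f_control = f2, odds_ratio = ft$odds_ratio,
                 ci_low = ft$ci_low, ci_high = ft$ci_high,
                 p_raw = ft$p, testable = ft$testable,
                 comparison = comparison, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_bh <- bh_adjust(res$p_raw)
    out[[m]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("snp_id", "model", "f_case", "f_control", "odds_ratio",
        "ci_low", "ci_high", "p_raw", "p_bh", "testable", "comparison")]
}

#' Concordance between pooled and individual association results
#'
#' Each candidate is labelled `confirmed` (same odds-ratio direction
#' and individual raw p below `p_eligible`), `discordant-direction`
#' (significant but opposite direction), or `not-significant`.
#'
#' @param pooled Data frame with `snp_id` and `pooled_or` (odds ratio on
#'   the same allele orientation as the individual results).
#' @param individual Data frame with `snp_id`, `odds_ratio`, `p_raw`.
#' @param p_eligible Eligibility threshold on the individual raw p
#'   (default 0.01).
#' @return Merged data frame with a `status` column.
#' @export
validate_concordance <- function(pooled, individual, p_eligible = 0.01) {
  m <- merge(pooled[c("snp_id", "pooled_or")],
             individual[c("snp_id", "odds_ratio", "p_raw")],
             by = "snp_id")
  same_dir <- sign(log(m$pooled_or)) == sign(log(m$odds_ratio))
  m$status <- ifelse(is.na(m$p_raw) | m$p_raw >= p_eligible,
                     "not-significant",
                     ifelse(same_dir, "confirmed", "discordant-direction"))
  m
}

#' Case-only scan for association with early age at onset
#'
#' Cases are dichotomized at `cutoff_years` (age at diagnosis at or
#' below the cutoff coded 1, above coded 0) and each marker is tested
#' by logistic regression under additive, dominant and recessive
#' codings; Benjamini-Hochberg correction is applied across the whole
#' scan.
#'
#' @param genotypes A `genotype_matrix` restricted to cases, with `age`
#'   in the manifest.
#' @param cutoff_years Dichotomization age (default 65).
#' @param models Genetic models to fit.
#' @return Data frame of `AssocResult` rows (f columns are the young /
#'   old minor-allele frequencies).
#' @export
age_onset_scan <- function(genotypes, cutoff_years = 65L,
                           models = c("additive", "dominant",
                                      "recessive")) {
  s <- genotypes$samples
  stopifnot(!is.null(s$age))
  young <- as.integer(s$age <= cutoff_years)
  if (all(young == 1L) || all(young == 0L))
    stop("age cutoff leaves all cases on one side")
  dos <- genotypes$dosage
  f <- rowMeans(dos, na.rm = TRUE) / 2
  out <- list()
  for (m in models) {
    res <- lapply(seq_len(nrow(dos)), function(i) {
      x <- dos[i, ]
      if (!is.na(f[i]) && f[i] > 0.5) x <- 2L - x
      ft <- fit_logistic(code_genotype(x, m), young)
      data.frame(snp_id = rownames(dos)[i], model = m,
                 f_case = mean(x[young == 1L], na.rm = TRUE) / 2,
                 f_control = mean(x[young == 0L], na.rm = TRUE) / 2,
                 odds_ratio = ft$odds_ratio, ci_low = ft$ci_low,
                 ci_high = ft$ci_high, p_raw = ft$p,
                 testable = ft$testable,
                 comparison = paste0("onset<=", cutoff_years),
                 stringsAsFactors = FALSE)
    })
    out[[m]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  res$p_bh <- bh_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Pick a tagging marker from a declared LD set
#'
#' Among `snp_ids`, returns the marker with the lowest missingness;
#' ties are broken by the largest control-group Hardy-Weinberg exact p.
#'
#' @param genotypes A `genotype_matrix`.
#' @param snp_ids Markers forming one LD set.
#' @param control_group Control label for the HWE tie-break.
#' @return The selected marker id.
#' @export
tag_snp_select <- function(genotypes, snp_ids, control_group = "control") {
  dos <- genotypes$dosage[snp_ids, , drop = FALSE]
  miss <- rowMeans(is.na(dos))
  co <- genotypes$samples$sample_id[genotypes$samples$group ==
                                      control_group]
  hwe <- apply(dos[, co, drop = FALSE], 1L, function(r) {
    gc <- genotype_counts(r)
    hwe_exact_p(gc["n2"], gc["n1"], gc["n0"])
  })
  snp_ids[order(miss, -hwe)][1L]
}
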