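make_gm <- function(dosage, group, age = NULL) {
  n <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("i%04d", seq_len(n))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  samples <- data.frame(sample_id = colnames(dosage), group = group,
                        stringsAsFactors = FALSE)
  if (!is.null(age)) samples$age <- age
  structure(list(dosage = dosage,
                 map = data.frame(snp_id = rownames(dosage),
                                  stringsAsFactors = FALSE),
                 samples = samples),
            class = "genotype_matrix")
}

test_that("HWE exact test matches the recurrence oracle on spec tables", {
  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-10)
  expect_equal(hwe_exact_p(0, 20, 0), oracle_hwe(0, 20, 0),
               tolerance = 1e-10)
  expect_equal(hwe_exact_p(100, 0, 0), 1.0)
  expect_equal(hwe_exact_p(10, 40, 50), oracle_hwe(10, 40, 50),
               tolerance = 1e-10)
  # orientation-free: swapping homozygote labels changes nothing
  expect_equal(hwe_exact_p(7, 21, 72), hwe_exact_p(72, 21, 7))
})

test_that("HWE exact test is stable at large totals", {
  p <- hwe_exact_p(9000, 42000, 49000)  # ~HWE at f = 0.3, n = 1e5
  expect_true(p > 0.1 && p <= 1)
  expect_lt(hwe_exact_p(15000, 30000, 55000), 1e-10)
})

test_that("QC filter applies thresholds in order with boundary conventions", {
  set.seed(21)
  dos <- matrix(rbinom(50 * 100, 2, 0.3), 50, 100)
  gm <- make_gm(dos, rep(c("case", "control"), each = 50))
  # SNP with 6% missing among 100 samples is dropped at step 1
  gm$dosage[1, 1:6] <- NA
  # individual with exactly 5% missing (of surviving 49 SNPs) dropped:
  # give individual 2 missingness in ceiling(0.05*49)=3 SNPs -> 3/49 > 5%
  gm$dosage[2:4, 2] <- NA
  out <- qc_filter(gm)
  expect_false("s001" %in% rownames(out$genotypes$dosage))
  expect_false("i0002" %in% colnames(out$genotypes$dosage))
  expect_true(all(c("snp", "individual") %in% out$report$type))
  # idempotence: filtering a filtered matrix removes nothing
  again <- qc_filter(out$genotypes)
  expect_equal(nrow(again$report), 0)
  expect_identical(again$genotypes$dosage, out$genotypes$dosage)
})

test_that("QC drops HWE-violating SNPs in controls and requires controls", {
  p <- generate_panel(20, c(0.3, 0.3), block_length = 1,
                      within_block_r2 = 0, seed = 22)
  g <- simulate_genotypes(p, cohort_spec(500, 1000, seed = 22))
  bad <- rownames(g$dosage)[1:5]
  dg <- degrade_genotypes(g, hwe_violating_snps = bad, seed = 23)
  out <- qc_filter(dg)
  expect_true(all(!bad %in% rownames(out$genotypes$dosage)))
  expect_setequal(out$report$item[out$report$reason == "hwe"], bad)
  no_ctrl <- dg; no_ctrl$samples$group <- "case"
  expect_error(qc_filter(no_ctrl), "control")
})

test_that("allelic odds ratio reproduces printed worked examples", {
  expect_equal(round(odds_ratio_from_freq(0.373, 0.233), 2), 1.96)
  expect_equal(round(odds_ratio_from_freq(0.464, 0.356), 2), 1.57)
  expect_equal(odds_ratio_from_freq(0.25, 0.25), 1.0)
})

test_that("allelic association matches the direct 2x2 oracle", {
  # counts (a,b,c,d) = (30,70,20,80) as minor/major alleles
  # 50 case subjects with 30 minor alleles; 50 controls with 20
  case_dos <- rep(c(2L, 1L, 0L), c(5, 20, 25))
  ctrl_dos <- rep(c(2L, 1L, 0L), c(2, 16, 32))
  gm <- make_gm(matrix(c(case_dos, ctrl_dos), 1),
                rep(c("case", "control"), each = 50))
  res <- allelic_assoc(gm)
  expect_equal(res$f_case, 0.30)
  expect_equal(res$f_control, 0.20)
  expect_equal(res$odds_ratio, (30 * 80) / (70 * 20), tolerance = 1e-12)
  oracle <- suppressWarnings(
    chisq.test(matrix(c(30, 70, 20, 80), 2, byrow = TRUE),
               correct = FALSE))
  expect_equal(res$p_raw, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$odds_ratio,
               odds_ratio_from_freq(res$f_case, res$f_control),
               tolerance = 1e-12)
})

test_that("swapping case and control labels inverts the odds ratio", {
  set.seed(24)
  dos <- matrix(rbinom(5 * 200, 2, runif(5, 0.1, 0.45)), 5, 200)
  gm <- make_gm(dos, rep(c("case", "control"), each = 100))
  r1 <- allelic_assoc(gm)
  r2 <- allelic_assoc(gm, case_group = "control",
                      control_group = "case")
  # same minor allele here (frequencies close between groups)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-9)
  expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-12)
})

test_that("zero allele-count cells trigger the Haldane correction", {
  case_dos <- rep(c(1L, 0L), c(10, 40))
  ctrl_dos <- rep(0L, 50)
  gm <- make_gm(matrix(c(case_dos, ctrl_dos), 1),
                rep(c("case", "control"), each = 50))
  res <- allelic_assoc(gm)
  expect_equal(res$odds_ratio, (10.5 * 100.5) / (90.5 * 0.5),
               tolerance = 1e-12)
  expect_true(res$testable)
  mono <- make_gm(matrix(0L, 1, 100),
                  rep(c("case", "control"), each = 50))
  expect_false(allelic_assoc(mono)$testable)
})

test_that("dominant-coded logistic OR equals the carrier-table odds ratio", {
  set.seed(25)
  x <- rbinom(400, 2, 0.3)
  y <- rbinom(400, 1, plogis(-0.5 + 0.6 * (x >= 1)))
  ft <- fit_logistic(as.integer(x >= 1), y)
  tab <- table(carrier = x >= 1, y)
  or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
    (tab["TRUE", "0"] * tab["FALSE", "1"])
  expect_equal(ft$odds_ratio, unname(or), tolerance = 1e-6)
})

test_that("logistic fit flags separation and constant predictors", {
  y <- rep(c(0L, 1L), each = 30)
  expect_true(fit_logistic(y, y)$separation)
  expect_true(is.na(fit_logistic(y, y)$p))
  expect_false(fit_logistic(rep(1L, 60), y)$testable)
})

test_that("null logistic fits are unbiased with uniform p-values", {
  set.seed(26)
  betas <- pvals <- numeric(60)
  for (k in 1:60) {
    x <- rbinom(2000, 2, 0.3)
    y <- rbinom(2000, 1, 0.5)
    ft <- fit_logistic(x, y)
    betas[k] <- ft$beta; pvals[k] <- ft$p
  }
  expect_lt(mean(abs(betas)), 0.1)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(27)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("concordance labels follow the direction and eligibility rules", {
  pooled <- data.frame(snp_id = c("a", "b", "c"),
                       pooled_or = c(1.5, 1.5, 1.5))
  indiv <- data.frame(snp_id = c("a", "b", "c"),
                      odds_ratio = c(1.3, 0.8, 1.4),
                      p_raw = c(0.005, 0.001, 0.02))
  out <- validate_concordance(pooled, indiv)
  expect_equal(out$status[match(c("a", "b", "c"), out$snp_id)],
               c("confirmed", "discordant-direction", "not-significant"))
})

test_that("age-at-onset scan recovers a planted dominant effect", {
  correct_sign <- 0
  for (k in 1:20) {
    set.seed(400 + k)
    x <- rbinom(400, 2, 0.35)
    # carriers enriched among OLD cases: OR(young) = 0.6 for carriers
    young <- rbinom(400, 1, plogis(log(171 / 247) +
                                     log(0.6) * (x >= 1)))
    age <- ifelse(young == 1, sample(45:65, 400, TRUE),
                  sample(66:83, 400, TRUE))
    gm <- make_gm(matrix(x, 1), rep("case", 400), age = age)
    res <- age_onset_scan(gm, cutoff_years = 65, models = "dominant")
    correct_sign <- correct_sign + (res$odds_ratio < 1)
  }
  expect_gte(correct_sign / 20, 0.9)
})

test_that("age scan validates the cutoff and runs all codings", {
  set.seed(28)
  gm <- make_gm(matrix(rbinom(3 * 100, 2, 0.3), 3), rep("case", 100),
                age = sample(45:85, 100, TRUE))
  expect_error(age_onset_scan(gm, cutoff_years = 20), "one side")
  res <- age_onset_scan(gm)
  expect_setequal(unique(res$model),
                  c("additive", "dominant", "recessive"))
  expect_true(all(res$p_bh >= res$p_raw, na.rm = TRUE))
})

test_that("tagging-SNP choice minimizes missingness, ties broken by HWE", {
  set.seed(29)
  dos <- matrix(rbinom(3 * 200, 2, 0.3), 3, 200)
  dos[1, 1:20] <- NA                # most missing
  dos[3, ] <- rep(c(0L, 1L), 100)   # het excess -> low HWE p
  gm <- make_gm(dos, rep(c("case", "control"), each = 100))
  expect_equal(tag_snp_select(gm, c("s001", "s002", "s003")), "s002")
})

test_that("allelic OR recovery and CI coverage at moderate effect size", {
  ors <- cover <- numeric(50)
  for (k in 1:50) {
    p <- generate_panel(1, c(0.3, 0.3), block_length = 1,
                        within_block_r2 = 0, seed = 600 + k,
                        effect_blocks = 1, effect_or = 1.5,
                        effect_maf = 0.3)
    g <- simulate_genotypes(p, cohort_spec(1000, 1000, seed = 600 + k))
    a <- allelic_assoc(g)
    ors[k] <- a$odds_ratio
    cover[k] <- a$ci_low <= 1.5 && a$ci_high >= 1.5
  }
  expect_lt(abs(mean(ors) - 1.5) / 1.5, 0.05)
  expect_gte(mean(cover), 0.88)
})
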