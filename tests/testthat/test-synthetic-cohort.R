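test_that("case frequency inverts the allelic odds ratio exactly", {
  expect_equal(case_allele_freq(0.3, 2.0), 0.6 / 1.3)
  expect_equal(case_allele_freq(0.3, 1.0), 0.3)
  f1 <- case_allele_freq(0.17, 1.8)
  expect_equal(odds_ratio_from_freq(f1, 0.17), 1.8)
})

test_that("perfect-copy blocks duplicate genotype columns", {
  p <- generate_panel(10, c(0.2, 0.4), block_length = 2,
                      within_block_r2 = 1.0, seed = 1)
  g <- simulate_genotypes(p, cohort_spec(50, 50, seed = 1))
  for (b in unique(p$snps$ld_block)) {
    rows <- which(p$snps$ld_block == b)
    expect_identical(g$dosage[rows[1], ], g$dosage[rows[2], ])
    expect_equal(dosage_r2(p$ref[rows[1], ], p$ref[rows[2], ]), 1.0)
  }
})

test_that("zero within-block r2 gives independent markers", {
  p <- generate_panel(200, c(0.2, 0.5), block_length = 5,
                      within_block_r2 = 0, seed = 2, n_ref = 500)
  set.seed(11)
  pairs <- cbind(sample(200, 1000, TRUE), sample(200, 1000, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  r2 <- apply(pairs, 1, function(ij)
    dosage_r2(p$ref[ij[1], ], p$ref[ij[2], ]))
  expect_lt(mean(r2), 0.02)
})

test_that("adjacent within-block r2 tracks its target", {
  p <- generate_panel(400, c(0.1, 0.5), block_length = 4,
                      within_block_r2 = 0.8, seed = 3, n_ref = 800)
  adj <- which(diff(p$snps$ld_block) == 0)
  keep <- p$snps$control_maf[adj] >= 0.1
  r2 <- vapply(adj[keep], function(i)
    dosage_r2(p$ref[i, ], p$ref[i + 1, ]), numeric(1))
  expect_lt(abs(mean(r2) - 0.8), 0.1)
})

test_that("generation is a pure function of spec and seed", {
  p1 <- generate_panel(50, c(0.1, 0.5), seed = 7)
  p2 <- generate_panel(50, c(0.1, 0.5), seed = 7)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cohort_spec(40, 40, seed = 7))
  g2 <- simulate_genotypes(p2, cohort_spec(40, 40, seed = 7))
  expect_identical(g1, g2)
  f1 <- tempfile(); f2 <- tempfile()
  write_snp_map(p1$snps, f1); write_snp_map(p2$snps, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate maf_range is rejected", {
  expect_error(generate_panel(10, c(0, 0)))
  expect_error(generate_panel(10, c(0.6, 0.6)))
})

test_that("case minor-allele frequency matches the closed form", {
  p <- generate_panel(1, c(0.3, 0.3), block_length = 1,
                      within_block_r2 = 0, seed = 4,
                      effect_blocks = 1, effect_or = 2.0,
                      effect_maf = 0.3)
  g <- simulate_genotypes(p, cohort_spec(5000, 5000, seed = 4))
  ca <- g$samples$sample_id[g$samples$group == "case"]
  co <- g$samples$sample_id[g$samples$group == "control"]
  expect_lt(abs(mean(g$dosage[1, ca]) / 2 - 0.6 / 1.3), 0.01)
  expect_lt(abs(mean(g$dosage[1, co]) / 2 - 0.3), 0.01)
})

test_that("null markers have equal case and control frequencies", {
  p <- generate_panel(50, c(0.2, 0.4), block_length = 1,
                      within_block_r2 = 0, seed = 5)
  g <- simulate_genotypes(p, cohort_spec(3000, 3000, seed = 5))
  grp <- g$samples$group
  dif <- rowMeans(g$dosage[, grp == "case"]) -
    rowMeans(g$dosage[, grp == "control"])
  expect_lt(max(abs(dif)) / 2, 0.03)
})

test_that("simulated null genotypes satisfy the module's own HWE test", {
  p <- generate_panel(1000, c(0.1, 0.5), block_length = 1,
                      within_block_r2 = 0, seed = 6)
  g <- simulate_genotypes(p, cohort_spec(500, 500, seed = 6))
  pv <- apply(g$dosage, 1, function(r)
    hwe_exact_p(sum(r == 2), sum(r == 1), sum(r == 0)))
  expect_gte(mean(pv > 0.001), 0.99)
})

test_that("pool construction chunks groups and logs the remainder", {
  man <- data.frame(
    sample_id = c(sprintf("x%03d", 1:270), sprintf("y%03d", 1:100)),
    group = rep(c("control", "case"), c(270, 100)),
    stringsAsFactors = FALSE)
  d <- suppressMessages(build_pools(man, cohort_spec(100, 270, 15,
                                                     seed = 1)))
  expect_equal(sum(d$group == "control"), 18)
  expect_equal(sum(d$group == "case"), 6)
  expect_length(attr(d, "unpooled"), 10)
  members <- unlist(strsplit(d$sample_ids, ","))
  expect_false(anyDuplicated(members) > 0)   # disjoint pools
  expect_true(all(vapply(strsplit(d$sample_ids, ","), length, 1L) == 15))
})

test_that("noiseless intensities reproduce pool frequencies exactly", {
  p <- generate_panel(20, c(0.2, 0.4), block_length = 1,
                      within_block_r2 = 0, seed = 8)
  co <- cohort_spec(30, 30, pool_size = 15, seed = 8)
  g <- simulate_genotypes(p, co)
  d <- build_pools(g$samples, co)
  ints <- simulate_intensities(d, g, intensity_model(gain = 1000,
                                                     noise_cv = 0),
                               n_replicates = 2, seed = 8)
  ras <- compute_ras(ints)
  mem <- strsplit(d$sample_ids, ",")
  truth <- vapply(seq_len(nrow(d)), function(k)
    rowMeans(g$dosage[, mem[[k]]]) / 2, numeric(20))
  for (k in seq_len(nrow(d))) {
    got <- ras$ras[ras$pool_id == d$pool_id[k]]
    expect_equal(unname(got),
                 rep(unname(truth[, k]), 2), tolerance = 1e-12)
  }
  half <- ints[abs(ints$intensity_A - 500) < 1e-9, ]
  expect_true(all(abs(half$intensity_B - 500) < 1e-9))
})

test_that("replicate RAS is unbiased for the pool frequency under noise", {
  # one pool fixed at f = 0.3 measured 10,000 times
  dos <- matrix(rep(c(0L, 1L), c(6, 9)), nrow = 1,
                dimnames = list("s1", sprintf("i%02d", 1:15)))
  expect_equal(mean(dos) / 2, 0.3)
  g <- list(dosage = dos,
            map = data.frame(snp_id = "s1"),
            samples = data.frame(sample_id = colnames(dos),
                                 group = "case"))
  class(g) <- "genotype_matrix"
  d <- structure(data.frame(pool_id = "case_pool001", group = "case",
                            sample_ids = paste(colnames(dos),
                                               collapse = ",")),
                 class = c("pool_design", "data.frame"))
  ints <- simulate_intensities(d, g, intensity_model(noise_cv = 0.05),
                               n_replicates = 10000, seed = 9)
  ras <- compute_ras(ints)
  expect_lt(abs(mean(ras$ras) - 0.3), 0.005)
})

test_that("degradation respects rates and injects detectable HWE violations", {
  p <- generate_panel(200, c(0.3, 0.3), block_length = 1,
                      within_block_r2 = 0, seed = 10)
  g <- simulate_genotypes(p, cohort_spec(1000, 1000, seed = 10))
  expect_identical(degrade_genotypes(g, 0, 0, 0, seed = 1)$dosage,
                   g$dosage)
  dg <- degrade_genotypes(g, snp_missing_rate = 0.10, seed = 2)
  miss <- rowMeans(is.na(dg$dosage))
  expect_true(all(abs(miss - 0.10) < 0.02))
  # injected excess heterozygosity is caught by the exact test
  dh <- degrade_genotypes(g, hwe_violating_snps = rownames(g$dosage),
                          seed = 3)
  pv <- apply(dh$dosage, 1, function(r)
    hwe_exact_p(sum(r == 2, na.rm = TRUE), sum(r == 1, na.rm = TRUE),
                sum(r == 0, na.rm = TRUE)))
  expect_gte(mean(pv < 0.001), 0.90)
})

test_that("genotyping errors stay within the dosage alphabet", {
  p <- generate_panel(50, c(0.2, 0.4), block_length = 1,
                      within_block_r2 = 0, seed = 11)
  g <- simulate_genotypes(p, cohort_spec(200, 200, seed = 11))
  dg <- degrade_genotypes(g, error_rate = 0.2, seed = 4)
  expect_true(all(dg$dosage %in% 0:2))
  expect_gt(mean(dg$dosage != g$dosage), 0.1)
})
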