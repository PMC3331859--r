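# End-to-end orchestration: simulate -> allelotype -> clump-select ->
# validate on individual genotypes -> replicate in an extended cohort
# -> per-marker heterogeneity/meta across the two stages.

#' Pipeline run configuration
#'
#' Collects the stage parameters of a full synthetic run. Unknown
#' arguments are rejected. Defaults mirror the pooled study design the
#' package emulates: 15-subject pools in technical triplicate, clump
#' selection at p < 1e-3 with an r-squared > 0.7 proxy within 100 kb,
#' QC at 5% missingness and control Hardy-Weinberg p >= 1e-3,
#' validation eligibility p < 0.01, replication significance at
#' Benjamini-Hochberg-corrected p < 0.05.
#'
#' @param n_snps Markers on the simulated chromosome.
#' @param block_length Markers per LD block.
#' @param within_block_r2 Adjacent-marker r-squared inside blocks.
#' @param maf_range Control MAF interval for null blocks.
#' @param spacing Marker spacing, bp.
#' @param n_effect_blocks Number of planted effect blocks.
#' @param effect_or Allelic odds ratio of planted blocks.
#' @param effect_maf Control MAF of planted blocks.
#' @param gwas_cases,gwas_controls Pooled-stage cohort sizes.
#' @param rep_cases,rep_controls Replication cohort sizes.
#' @param pool_size,n_replicates Pool design.
#' @param noise_cv,gain,background Intensity model.
#' @param n_outlier_pools Aberrant pools injected per run.
#' @param outlier_shift Frequency bias of aberrant pools.
#' @param pca_z Robust-z threshold of the pool filter.
#' @param clump A [clump_config()].
#' @param qc A [qc_config()].
#' @param snp_missing_rate,ind_missing_rate,error_rate Genotyping
#'   degradation applied before QC.
#' @param n_hwe_violating Null markers injected with excess
#'   heterozygosity among the genotyped candidates.
#' @param p_eligible Validation eligibility threshold.
#' @param alpha_replication BH-corrected significance threshold in the
#'   replication stage.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_snps = 2000L, block_length = 5L,
                       within_block_r2 = 0.9,
                       maf_range = c(0.1, 0.5), spacing = 10000L,
                       n_effect_blocks = 10L, effect_or = 2.0,
                       effect_maf = 0.3,
                       gwas_cases = 630L, gwas_controls = 690L,
                       rep_cases = 800L, rep_controls = 800L,
                       pool_size = 15L, n_replicates = 3L,
                       noise_cv = 0.05, gain = 2000, background = 0,
                       n_outlier_pools = 1L, outlier_shift = 0.1,
                       pca_z = 3.5,
                       clump = clump_config(), qc = qc_config(),
                       snp_missing_rate = 0.01,
                       ind_missing_rate = 0.005, error_rate = 0.002,
                       n_hwe_violating = 0L,
                       p_eligible = 0.01, alpha_replication = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$clump, "clump_config"),
            inherits(cfg$qc, "qc_config"),
            cfg$p_eligible > 0, cfg$p_eligible < 1,
            cfg$alpha_replication > 0, cfg$alpha_replication < 1)
  structure(cfg, class = "run_config")
}

#' Packaged demonstration configuration
#'
#' A scaled synthetic run: 2,000 markers in 5-marker blocks
#' (r-squared 0.9), ten planted effect blocks (allelic OR 2.0 at
#' control MAF 0.3), a 630 + 690 pooled stage (42 + 46 pools of 15,
#' one aberrant pool), and an 800 + 800 replication cohort.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 20260929L) run_config(seed = seed)

#' Run the full pooled-GWAS pipeline on a synthetic study
#'
#' Stages, in order: panel generation with planted effect blocks;
#' pooled-stage cohort simulation, pooling, and array intensities (with
#' injected aberrant pools); RAS computation, replicate averaging, PCA
#' pool exclusion, and pooled association; LD-proxy clump selection;
#' technical validation on degraded individual genotypes of the same
#' cohort (QC filters, allelic test, concordance with the pooled odds
#' ratio); replication of confirmed candidates in an independent
#' extended cohort under allelic and additive models with
#' Benjamini-Hochberg correction; and per-marker DerSimonian-Laird
#' meta-analysis of the validation and replication allelic effects.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV and the run manifest as JSON.
#' @return List with elements `manifest`, `panel`, `pooled`, `clumps`,
#'   `validation`, `replication`, `meta` (see the stage functions for
#'   the table schemata).
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  n_blocks <- ceiling(config$n_snps / config$block_length)
  effect_blocks <- if (config$n_effect_blocks > 0)
    unique(round(seq(1, n_blocks, length.out = config$n_effect_blocks)))
  else integer(0)

  ## stage 1: panel + pooled-stage cohort
  panel <- generate_panel(
    n_snps = config$n_snps, maf_range = config$maf_range,
    block_length = config$block_length,
    within_block_r2 = config$within_block_r2,
    spacing = config$spacing, seed = child_seed(seed, 11L),
    effect_blocks = effect_blocks, effect_or = config$effect_or,
    effect_maf = config$effect_maf)
  gwas_cohort <- cohort_spec(config$gwas_cases, config$gwas_controls,
                             config$pool_size, config$n_replicates,
                             seed = child_seed(seed, 12L))
  genotypes <- simulate_genotypes(panel, gwas_cohort, "gwas")
  design <- build_pools(genotypes$samples, gwas_cohort)
  set.seed(child_seed(seed, 13L))
  outliers <- if (config$n_outlier_pools > 0)
    sample(design$pool_id, config$n_outlier_pools) else character(0)
  model <- intensity_model(gain = config$gain,
                           noise_cv = config$noise_cv,
                           background = config$background,
                           outlier_shift = config$outlier_shift)
  intensities <- simulate_intensities(design, genotypes, model,
                                      config$n_replicates, outliers,
                                      seed = child_seed(seed, 14L))

  ## stage 2: allelotyping
  ras_tab <- compute_ras(intensities)
  ras <- average_replicates(
    ras_tab, stats::setNames(design$group, design$pool_id),
    n_subjects_per_pool = config$pool_size)
  filt <- pca_pool_filter(ras, z_threshold = config$pca_z)
  pooled <- pooled_association(filt$kept)

  ## stage 3: clump selection
  clumps <- clump_select(pooled, panel$snps, panel$ref, config$clump)
  cand_ids <- clumps$index_snp

  ## stage 4: technical validation on the same cohort
  validation <- NULL; concordance <- NULL; qc_rep <- NULL
  confirmed_ids <- character(0)
  if (length(cand_ids)) {
    sub <- genotypes
    keep <- rownames(genotypes$dosage) %in% cand_ids
    sub$dosage <- genotypes$dosage[keep, , drop = FALSE]
    sub$map <- genotypes$map[keep, , drop = FALSE]
    hwe_bad <- utils::head(cand_ids, config$n_hwe_violating)
    sub <- degrade_genotypes(sub, config$snp_missing_rate,
                             config$ind_missing_rate,
                             config$error_rate,
                             hwe_violating_snps = hwe_bad,
                             seed = child_seed(seed, 15L))
    qc <- qc_filter(sub, config$qc)
    qc_rep <- qc$report
    if (nrow(qc$genotypes$dosage)) {
      validation <- allelic_assoc(qc$genotypes, comparison = "validation")
      # pooled OR re-oriented to the validation minor allele
      po <- pooled[match(validation$snp_id, pooled$snp_id), ]
      ctrl_ids <- qc$genotypes$samples$sample_id[
        qc$genotypes$samples$group == "control"]
      ma <- minor_allele_in_controls(qc$genotypes$dosage, ctrl_ids)
      m1 <- ifelse(ma == "A", po$mean_ras_case, 1 - po$mean_ras_case)
      m2 <- ifelse(ma == "A", po$mean_ras_control,
                   1 - po$mean_ras_control)
      pooled_or <- data.frame(snp_id = validation$snp_id,
                              pooled_or = odds_ratio_from_freq(m1, m2),
                              stringsAsFactors = FALSE)
      concordance <- validate_concordance(pooled_or, validation,
                                          config$p_eligible)
      confirmed_ids <- concordance$snp_id[
        concordance$status == "confirmed"]
    }
  }

  ## stage 5: replication in an extended cohort
  replication <- NULL
  significant_ids <- character(0)
  if (length(confirmed_ids)) {
    sub_panel <- panel
    keep <- panel$snps$snp_id %in% confirmed_ids
    sub_panel$snps <- panel$snps[keep, , drop = FALSE]
    rep_cohort <- cohort_spec(config$rep_cases, config$rep_controls,
                              config$pool_size, config$n_replicates,
                              seed = child_seed(seed, 16L))
    rep_geno <- simulate_genotypes(sub_panel, rep_cohort, "replication")
    rep_geno <- degrade_genotypes(rep_geno, config$snp_missing_rate,
                                  config$ind_missing_rate,
                                  config$error_rate,
                                  seed = child_seed(seed, 17L))
    rep_qc <- qc_filter(rep_geno, config$qc)
    if (nrow(rep_qc$genotypes$dosage)) {
      replication <- genotype_association(
        rep_qc$genotypes, models = c("allelic", "additive"),
        comparison = "replication")
      add <- replication[replication$model == "additive", ]
      conc <- concordance[match(add$snp_id, concordance$snp_id), ]
      significant_ids <- add$snp_id[
        !is.na(add$p_bh) & add$p_bh < config$alpha_replication &
          sign(log(add$odds_ratio)) == sign(log(conc$pooled_or))]
    }
  }

  ## stage 6: per-marker meta across validation and replication
  meta <- NULL
  if (!is.null(replication)) {
    rep_al <- replication[replication$model == "allelic", ]
    both <- intersect(validation$snp_id, rep_al$snp_id)
    meta <- do.call(rbind, lapply(both, function(id) {
      v <- validation[validation$snp_id == id, ]
      r <- rep_al[rep_al$snp_id == id, ]
      if (any(is.na(c(v$odds_ratio, r$odds_ratio, v$ci_low, r$ci_low))))
        return(NULL)
      eff <- study_effects(c("validation", "replication"),
                           or = c(v$odds_ratio, r$odds_ratio),
                           ci_low = c(v$ci_low, r$ci_low),
                           ci_high = c(v$ci_high, r$ci_high))
      m <- dl_random_effects(eff)
      data.frame(snp_id = id, k = m$k, pooled_or = m$pooled_or,
                 ci_low = m$ci_low, ci_high = m$ci_high, z_p = m$z_p,
                 q = m$q, q_p = m$q_p, i2 = round(m$i2, 1),
                 stringsAsFactors = FALSE)
    }))
  }

  recovered_blocks <- unique(panel$snps$ld_block[
    panel$snps$snp_id %in% significant_ids])
  planted_blocks <- unique(panel$snps$ld_block[
    panel$snps$allelic_or != 1])
  manifest <- list(
    version = as.character(utils::packageVersion("poolgwas")),
    seed = seed,
    config = config[setdiff(names(config), c("clump", "qc"))],
    clump = unclass(config$clump), qc = unclass(config$qc),
    counts = list(
      snps = config$n_snps,
      pools = nrow(design),
      pools_excluded = length(filt$excluded),
      snps_testable = sum(pooled$testable),
      clumps = nrow(clumps),
      candidates = length(cand_ids),
      qc_exclusions = if (is.null(qc_rep)) 0L else nrow(qc_rep),
      confirmed = length(confirmed_ids),
      replicated_significant = length(significant_ids),
      planted_blocks = length(planted_blocks),
      recovered_blocks = length(intersect(recovered_blocks,
                                          planted_blocks))),
    excluded_pools = filt$excluded,
    injected_outlier_pools = outliers,
    significant_snps = significant_ids)

  out <- list(manifest = manifest, panel = panel, pooled = pooled,
              clumps = clumps, pool_filter = filt,
              validation = validation, concordance = concordance,
              qc_report = qc_rep, replication = replication,
              meta = meta)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_snp_map(panel$snps, p("snp_map.tsv"))
    write_manifest(genotypes$samples, p("sample_manifest.tsv"))
    write_pool_design(design, p("pool_design.tsv"))
    write_intensities(intensities, p("intensities.tsv"))
    write_tsv(data.frame(pool_id = rownames(ras$values),
                         ras$values, check.names = FALSE),
              p("ras_matrix.tsv"))
    if (!is.null(filt$coords)) write_tsv(filt$coords, p("pool_pca.tsv"))
    write_tsv(data.frame(pool_id = filt$excluded),
              p("excluded_pools.tsv"))
    write_tsv(merge(pooled, panel$snps[c("snp_id", "chrom", "pos")],
                    by = "snp_id"), p("pooled_association.tsv"))
    write_tsv(clumps, p("clumps.tsv"))
    if (!is.null(qc_rep)) write_tsv(qc_rep, p("qc_report.tsv"))
    if (!is.null(validation))
      write_tsv(validation, p("validation_association.tsv"))
    if (!is.null(concordance))
      write_tsv(concordance, p("concordance.tsv"))
    if (!is.null(replication))
      write_tsv(replication, p("replication_association.tsv"))
    if (!is.null(meta)) write_tsv(meta, p("meta_analysis.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, p("run_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
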