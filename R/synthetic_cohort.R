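# Synthetic cohorts, pools, and pooled-array intensities.
#
# The generator emulates the design the downstream statistics assume:
# HWE genotypes at specified control minor-allele frequencies, case
# frequencies implied by allelic odds ratios, equimolar 15-sample pools
# measured in technical triplicate with multiplicative channel noise,
# blockwise LD so proxy markers exist, and degradable individual
# genotype tables for QC testing.

#' Case minor-allele frequency implied by an allelic odds ratio
#'
#' Inverts the allelic odds-ratio definition: given a control frequency
#' `p0` and an odds ratio `or` for the minor allele, returns the case
#' frequency `F1 = or*p0 / (1 + p0*(or - 1))`, so that
#' `[F1(1-p0)] / [p0(1-F1)] = or` exactly.
#'
#' @param p0 Control minor-allele frequency, in (0, 1).
#' @param or Allelic odds ratio, positive; 1 gives `F1 = p0`.
#' @return Case minor-allele frequency in (0, 1).
#' @export
#' @examples
#' case_allele_freq(0.3, 2.0)  # 0.4615...
case_allele_freq <- function(p0, or) {
  stopifnot(all(p0 > 0 & p0 < 1), all(or > 0))
  or * p0 / (1 + p0 * (or - 1))
}

# Deterministic child-seed derivation so one run seed fans out to stages.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629L)
}

#' Cohort design specification
#'
#' @param n_cases,n_controls Numbers of case and control subjects.
#' @param pool_size Subjects per DNA pool (default 15).
#' @param n_replicates Technical array replicates per pool (default 3).
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, pool_size = 15L,
                        n_replicates = 3L, seed = 1L) {
  stopifnot(pool_size >= 1, n_replicates >= 1,
            n_cases >= pool_size, n_controls >= pool_size)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 pool_size = as.integer(pool_size),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Two-channel array intensity model
#'
#' Channel A of a pool with allele-A frequency f has expectation
#' `gain * f + background`; channel B the complement. Noise is
#' multiplicative with coefficient of variation `noise_cv` (log-normal,
#' unit mean, hence strictly positive). Pools designated as outliers get
#' their frequency shifted by `outlier_shift` (clamped to [0, 1]) before
#' intensities are drawn, mimicking aberrant DNA quality/hybridization.
#' A finite `pooling_concentration` draws per-sample Dirichlet
#' contribution weights instead of exactly equimolar mixing.
#'
#' @param gain Expected channel intensity at frequency 1 (> 0).
#' @param noise_cv Multiplicative noise CV (>= 0, default 0.05).
#' @param background Additive channel offset (>= 0, default 0).
#' @param outlier_shift Frequency-scale bias for outlier pools (default 0.1).
#' @param pooling_concentration Dirichlet concentration for sample
#'   contributions; `Inf` (default) means exactly equimolar.
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(gain = 2000, noise_cv = 0.05, background = 0,
                            outlier_shift = 0.1, pooling_concentration = Inf) {
  stopifnot(gain > 0, noise_cv >= 0, background >= 0,
            pooling_concentration > 0)
  structure(list(gain = gain, noise_cv = noise_cv, background = background,
                 outlier_shift = outlier_shift,
                 pooling_concentration = pooling_concentration),
            class = "intensity_model")
}

# Sample n_hap haplotypes for one LD block: first marker Bernoulli(p);
# each subsequent marker copies its left neighbour with probability
# `fidelity`, else is a fresh Bernoulli(p) draw. All markers in a block
# share p, so copying preserves the marginal frequency exactly and the
# allele-level correlation between adjacent markers equals `fidelity`.
sample_block_haplotypes <- function(n_hap, n_snp, p, fidelity) {
  h <- matrix(0L, n_hap, n_snp)
  h[, 1L] <- stats::rbinom(n_hap, 1L, p)
  if (n_snp > 1L) {
    for (j in 2:n_snp) {
      copy <- stats::runif(n_hap) < fidelity
      fresh <- stats::rbinom(n_hap, 1L, p)
      h[, j] <- ifelse(copy, h[, j - 1L], fresh)
    }
  }
  h
}

# Genotypes (SNP x sample dosage of allele A) for one group given the
# per-block frequency; two independent haplotypes per subject (HWE).
sample_group_genotypes <- function(panel, n, freqs) {
  snps <- panel$snps
  blocks <- split(seq_len(nrow(snps)), snps$ld_block)
  g <- matrix(0L, nrow(snps), n)
  for (b in blocks) {
    p <- freqs[b[1L]]
    h1 <- sample_block_haplotypes(n, length(b), p, panel$copy_fidelity)
    h2 <- sample_block_haplotypes(n, length(b), p, panel$copy_fidelity)
    g[b, ] <- t(h1 + h2)
  }
  g
}

#' Generate a synthetic SNP panel with blockwise LD
#'
#' Lays `n_snps` markers at fixed spacing on one chromosome, grouped into
#' LD blocks of `block_length` consecutive markers. All markers of a
#' block share one minor-allele frequency drawn from `maf_range` and one
#' allelic odds ratio; within a block, adjacent markers have expected
#' allele-dosage r-squared equal to `within_block_r2` (haplotype copying
#' with fidelity `sqrt(within_block_r2)`), while markers in different
#' blocks are independent. Blocks listed in `effect_blocks` carry
#' `effect_or` (and `effect_maf`, if given) so that proxy-supported
#' association signals exist by construction; all other markers are null
#' (odds ratio 1).
#'
#' A reference genotype panel of `n_ref` subjects drawn at the control
#' frequencies is attached for LD (r-squared) estimation, standing in
#' for an externally genotyped reference cohort.
#'
#' @param n_snps Number of markers (>= 1).
#' @param maf_range Length-2 interval within (0, 0.5] for block MAFs.
#' @param block_length Markers per LD block.
#' @param within_block_r2 Target adjacent-marker r-squared in [0, 1].
#' @param spacing Distance between adjacent markers, base pairs.
#' @param seed Integer seed.
#' @param chrom Chromosome label.
#' @param effect_blocks Integer ids of blocks given `effect_or`.
#' @param effect_or Allelic odds ratio planted in `effect_blocks`.
#' @param effect_maf Optional fixed control MAF for effect blocks.
#' @param n_ref Reference-panel size (subjects).
#' @return A list of class `snp_panel` with elements `snps` (data frame:
#'   snp_id, chrom, pos, allele_A, allele_B, control_maf, allelic_or,
#'   ld_block), `ref` (SNP x subject dosage matrix) and `copy_fidelity`.
#' @export
generate_panel <- function(n_snps, maf_range = c(0.05, 0.5),
                           block_length = 5L, within_block_r2 = 0.8,
                           spacing = 10000L, seed = 1L, chrom = "1",
                           effect_blocks = integer(0), effect_or = 2.0,
                           effect_maf = NULL, n_ref = 400L) {
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[2] >= maf_range[1],
            within_block_r2 >= 0, within_block_r2 <= 1,
            block_length >= 1, spacing > 0)
  if (maf_range[1] == maf_range[2] && maf_range[1] <= 0)
    stop("degenerate maf_range at boundary 0")
  set.seed(child_seed(seed, 1L))
  n_blocks <- ceiling(n_snps / block_length)
  block_of <- rep(seq_len(n_blocks), each = block_length)[seq_len(n_snps)]
  block_maf <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  block_or <- rep(1.0, n_blocks)
  if (length(effect_blocks)) {
    stopifnot(all(effect_blocks >= 1 & effect_blocks <= n_blocks))
    block_or[effect_blocks] <- effect_or
    if (!is.null(effect_maf)) block_maf[effect_blocks] <- effect_maf
  }
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = chrom,
    pos = as.integer(seq_len(n_snps)) * as.integer(spacing),
    allele_A = "A", allele_B = "B",
    control_maf = block_maf[block_of],
    allelic_or = block_or[block_of],
    ld_block = block_of,
    stringsAsFactors = FALSE
  )
  panel <- structure(list(snps = snps,
                          copy_fidelity = sqrt(within_block_r2)),
                     class = "snp_panel")
  ref <- sample_group_genotypes(panel, n_ref, snps$control_maf)
  dimnames(ref) <- list(snps$snp_id, sprintf("ref%04d", seq_len(n_ref)))
  panel$ref <- ref
  panel
}

#' Simulate case/control genotypes under the panel's effect model
#'
#' Controls are drawn at each marker's `control_maf`; cases at the
#' frequency implied by the marker's allelic odds ratio via
#' [case_allele_freq()]. Genotypes are sums of two independent block
#' haplotypes, so Hardy-Weinberg proportions hold marginally and LD is
#' preserved within blocks.
#'
#' @param panel A `snp_panel` from [generate_panel()].
#' @param cohort A [cohort_spec()].
#' @param cohort_label Label recorded in the sample manifest.
#' @return A list of class `genotype_matrix`: `dosage` (SNP x sample
#'   integer matrix of minor-allele counts), `map` (the panel's SNP
#'   table), `samples` (manifest: sample_id, group, sex, age, cohort).
#' @export
simulate_genotypes <- function(panel, cohort, cohort_label = "cohort1") {
  stopifnot(inherits(panel, "snp_panel"), nrow(panel$snps) >= 1,
            inherits(cohort, "cohort_spec"))
  set.seed(child_seed(cohort$seed, 2L))
  snps <- panel$snps
  f_case <- case_allele_freq(snps$control_maf, snps$allelic_or)
  # block frequency is shared within blocks because or/maf are blockwise
  g_case <- sample_group_genotypes(panel, cohort$n_cases, f_case)
  g_ctrl <- sample_group_genotypes(panel, cohort$n_controls,
                                   snps$control_maf)
  dosage <- cbind(g_case, g_ctrl)
  ids <- c(sprintf("case%04d", seq_len(cohort$n_cases)),
           sprintf("ctrl%04d", seq_len(cohort$n_controls)))
  dimnames(dosage) <- list(snps$snp_id, ids)
  n <- ncol(dosage)
  samples <- data.frame(
    sample_id = ids,
    group = rep(c("case", "control"), c(cohort$n_cases, cohort$n_controls)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = pmin(89L, pmax(27L, round(stats::rnorm(
      n, mean = rep(c(65, 57), c(cohort$n_cases, cohort$n_controls)),
      sd = 9)))),
    cohort = cohort_label,
    stringsAsFactors = FALSE
  )
  structure(list(dosage = dosage, map = snps, samples = samples),
            class = "genotype_matrix")
}

#' Assign samples to phenotype-homogeneous equimolar pools
#'
#' Samples of each group are chunked, in manifest order, into pools of
#' `pool_size`; leftover samples that cannot fill a pool are excluded
#' and reported in the `unpooled` attribute.
#'
#' @param manifest Sample manifest (`sample_id`, `group`).
#' @param cohort A [cohort_spec()] (supplies `pool_size`).
#' @return Data frame of class `pool_design` with columns `pool_id`,
#'   `group`, `sample_ids` (comma-joined); attribute `unpooled`.
#' @export
build_pools <- function(manifest, cohort) {
  stopifnot(all(c("sample_id", "group") %in% names(manifest)))
  ps <- cohort$pool_size
  groups <- split(manifest$sample_id, manifest$group)
  if (any(vapply(groups, length, 1L) < ps))
    stop("each group must have at least pool_size samples")
  rows <- list(); unpooled <- character(0)
  for (g in names(groups)) {
    ids <- groups[[g]]
    n_pools <- length(ids) %/% ps
    for (k in seq_len(n_pools)) {
      mem <- ids[((k - 1L) * ps + 1L):(k * ps)]
      rows[[length(rows) + 1L]] <- data.frame(
        pool_id = sprintf("%s_pool%03d", g, k), group = g,
        sample_ids = paste(mem, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(ids) > n_pools * ps)
      unpooled <- c(unpooled, ids[(n_pools * ps + 1L):length(ids)])
  }
  design <- do.call(rbind, rows)
  if (length(unpooled))
    message(length(unpooled), " samples left unpooled")
  attr(design, "unpooled") <- unpooled
  class(design) <- c("pool_design", "data.frame")
  design
}

pool_members <- function(design) {
  stats::setNames(strsplit(design$sample_ids, ",", fixed = TRUE),
                  design$pool_id)
}

# True pool allele-A frequencies (pool x 1 per SNP): equimolar mean of
# member dosages / 2, or Dirichlet-weighted when concentration is finite.
pool_frequencies <- function(design, genotypes, model) {
  members <- pool_members(design)
  dos <- genotypes$dosage
  f <- vapply(members, function(mem) {
    sub <- dos[, mem, drop = FALSE]
    if (is.finite(model$pooling_concentration)) {
      w <- stats::rgamma(length(mem), shape = model$pooling_concentration)
      w <- w / sum(w)
      as.numeric(sub %*% w) / 2
    } else {
      rowMeans(sub) / 2
    }
  }, numeric(nrow(dos)))
  # SNP x pool matrix
  if (is.null(dim(f))) f <- matrix(f, nrow = nrow(dos))
  dimnames(f) <- list(rownames(dos), design$pool_id)
  f
}

#' Simulate pooled two-channel array intensities
#'
#' For each (SNP, pool, replicate), channel A has expectation
#' `gain * f + background` and channel B `gain * (1 - f) + background`,
#' where f is the pool's allele-A frequency (equimolar mean of member
#' dosages over `2 * pool_size`, or Dirichlet-weighted). Channels get
#' independent multiplicative log-normal noise of CV `noise_cv`. Pools
#' named in `outlier_pools` have f shifted by `model$outlier_shift`
#' (clamped to [0, 1]) before intensity generation.
#'
#' @param design A `pool_design` from [build_pools()].
#' @param genotypes A `genotype_matrix` covering all pool members.
#' @param model An [intensity_model()].
#' @param n_replicates Technical replicates per pool.
#' @param outlier_pools Character vector of aberrant pool ids.
#' @param seed Integer seed.
#' @return Data frame (`snp_id`, `pool_id`, `replicate`, `intensity_A`,
#'   `intensity_B`), one row per (SNP, pool, replicate).
#' @export
simulate_intensities <- function(design, genotypes, model = intensity_model(),
                                 n_replicates = 3L,
                                 outlier_pools = character(0), seed = 1L) {
  members <- pool_members(design)
  missing_mem <- setdiff(unlist(members), colnames(genotypes$dosage))
  if (length(missing_mem))
    stop("pool members absent from genotype matrix: ",
         paste(utils::head(missing_mem, 3), collapse = ", "))
  set.seed(child_seed(seed, 3L))
  f <- pool_frequencies(design, genotypes, model)
  if (length(outlier_pools)) {
    bad <- colnames(f) %in% outlier_pools
    f[, bad] <- pmin(1, pmax(0, f[, bad] + model$outlier_shift))
  }
  n_snp <- nrow(f); n_pool <- ncol(f)
  grid <- expand.grid(snp_id = rownames(f), pool_id = colnames(f),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fv <- rep(as.vector(f), times = n_replicates)
  n <- length(fv)
  mult <- function() {
    if (model$noise_cv == 0) return(rep(1, n))
    s2 <- log(1 + model$noise_cv^2)
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  grid$intensity_A <- (model$gain * fv + model$background) * mult()
  grid$intensity_B <- (model$gain * (1 - fv) + model$background) * mult()
  grid
}

#' Degrade a genotype matrix with missingness, errors, and HWE violations
#'
#' Applies entry-wise missingness at `snp_missing_rate` and
#' `ind_missing_rate`, random genotyping errors that shift a dosage by
#' one step within {0, 1, 2}, and, for markers named in
#' `hwe_violating_snps`, a redraw with heterozygote probability inflated
#' by `het_inflation` (renormalized), giving the Hardy-Weinberg filter
#' true positives.
#'
#' @param genotypes A `genotype_matrix`.
#' @param snp_missing_rate,ind_missing_rate,error_rate Rates in [0, 1].
#' @param hwe_violating_snps Character vector of marker ids to distort.
#' @param het_inflation Heterozygosity inflation factor (default 1.5).
#' @param seed Integer seed.
#' @return A degraded `genotype_matrix` (dosages may contain `NA`).
#' @export
degrade_genotypes <- function(genotypes, snp_missing_rate = 0,
                              ind_missing_rate = 0, error_rate = 0,
                              hwe_violating_snps = character(0),
                              het_inflation = 1.5, seed = 1L) {
  stopifnot(snp_missing_rate >= 0, snp_missing_rate <= 1,
            ind_missing_rate >= 0, ind_missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  set.seed(child_seed(seed, 4L))
  dos <- genotypes$dosage
  n <- length(dos)
  if (length(hwe_violating_snps)) {
    idx <- match(hwe_violating_snps, rownames(dos))
    idx <- idx[!is.na(idx)]
    for (i in idx) {
      fobs <- mean(dos[i, ], na.rm = TRUE) / 2
      pr <- c((1 - fobs)^2, 2 * fobs * (1 - fobs) * het_inflation, fobs^2)
      pr <- pr / sum(pr)
      dos[i, ] <- sample(0:2, ncol(dos), replace = TRUE, prob = pr)
    }
  }
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate & !is.na(dos))
    if (length(err)) {
      cur <- dos[err]
      step <- ifelse(cur == 0L, 1L,
              ifelse(cur == 2L, -1L,
                     sample(c(-1L, 1L), length(err), replace = TRUE)))
      dos[err] <- cur + step
    }
  }
  if (snp_missing_rate > 0)
    dos[stats::runif(n) < snp_missing_rate] <- NA_integer_
  if (ind_missing_rate > 0)
    dos[stats::runif(n) < ind_missing_rate] <- NA_integer_
  out <- genotypes
  out$dosage <- dos
  out
}
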