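# Pooled-array allelotyping: relative allele signal, replicate
# averaging, PCA-based pool screening, and the dual t-test / chi-square
# pooled association.

#' Relative allele signal from two-channel intensities
#'
#' RAS = A / (A + B) per (SNP, pool, replicate). Entries with
#' A + B <= 0 are set missing and counted in the `qc` attribute.
#' Negative intensities are an input error.
#'
#' @param panel Intensity table with columns `snp_id`, `pool_id`,
#'   `replicate`, `intensity_A`, `intensity_B`.
#' @return The table with a `ras` column; attribute `qc` holds the
#'   number of degenerate (zero-signal) entries.
#' @export
compute_ras <- function(panel) {
  need <- c("snp_id", "pool_id", "replicate", "intensity_A", "intensity_B")
  stopifnot(all(need %in% names(panel)))
  neg <- which(panel$intensity_A < 0 | panel$intensity_B < 0)
  if (length(neg))
    stop("negative intensity at row ", neg[1L], " (snp ",
         panel$snp_id[neg[1L]], ", pool ", panel$pool_id[neg[1L]], ")")
  tot <- panel$intensity_A + panel$intensity_B
  ras <- ifelse(tot > 0, panel$intensity_A / tot, NA_real_)
  out <- panel[c("snp_id", "pool_id", "replicate")]
  out$ras <- ras
  attr(out, "qc") <- c(zero_signal = sum(tot <= 0))
  out
}

#' Average replicate RAS values into a pool x SNP matrix
#'
#' Arithmetic mean over non-missing replicates; (SNP, pool) cells with
#' fewer than `min_replicates` usable replicates are set missing.
#'
#' @param ras_table Output of [compute_ras()].
#' @param pool_groups Named character vector mapping pool id to group
#'   label (e.g. from a `pool_design`: `setNames(design$group,
#'   design$pool_id)`).
#' @param n_subjects_per_pool Subjects represented by each pool.
#' @param min_replicates Minimum usable replicates per cell (default 2).
#' @return A list of class `ras_matrix`: `values` (pool x SNP numeric
#'   matrix in [0, 1], `NA` allowed), `pool_groups`,
#'   `n_subjects_per_pool`.
#' @export
average_replicates <- function(ras_table, pool_groups = NULL,
                               n_subjects_per_pool = 15L,
                               min_replicates = 2L) {
  key_pool <- factor(ras_table$pool_id)
  key_snp <- factor(ras_table$snp_id, levels = unique(ras_table$snp_id))
  ok <- !is.na(ras_table$ras)
  idx <- (as.integer(key_snp) - 1L) * nlevels(key_pool) +
    as.integer(key_pool)
  sums <- rowsum(ifelse(ok, ras_table$ras, 0), idx)
  counts <- rowsum(as.numeric(ok), idx)
  vals <- matrix(NA_real_, nlevels(key_pool), nlevels(key_snp),
                 dimnames = list(levels(key_pool), levels(key_snp)))
  pos <- as.integer(rownames(sums))
  vals[pos] <- ifelse(counts >= min_replicates, sums / counts, NA_real_)
  if (is.null(pool_groups)) {
    grp <- sub("_pool[0-9]+$", "", levels(key_pool))
    pool_groups <- stats::setNames(grp, levels(key_pool))
  }
  structure(list(values = vals,
                 pool_groups = pool_groups[rownames(vals)],
                 n_subjects_per_pool = as.integer(n_subjects_per_pool)),
            class = "ras_matrix")
}

#' Exclude aberrant pools by principal-component screening
#'
#' Principal components are computed on the column-centered pool x SNP
#' RAS matrix (missing cells imputed with the per-SNP mean for the
#' decomposition only). A pool is excluded when the robust z-score
#' (median/MAD, MAD scaled by 1.4826) of its coordinate on PC1 or PC2
#' exceeds `z_threshold`. One pass only; no iteration.
#'
#' @param ras A `ras_matrix`.
#' @param z_threshold Robust z cut-off (default 3.5); `Inf` disables.
#' @return List: `kept` (filtered `ras_matrix`), `excluded` (pool ids),
#'   `coords` (data frame of PC1/PC2 coordinates and robust z-scores).
#' @export
pca_pool_filter <- function(ras, z_threshold = 3.5) {
  v <- ras$values
  if (nrow(v) < 3) {
    warning("fewer than 3 pools; no PCA filtering performed")
    return(list(kept = ras, excluded = character(0), coords = NULL))
  }
  imp <- v
  if (anyNA(imp)) {
    mu <- colMeans(imp, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    na_idx <- which(is.na(imp), arr.ind = TRUE)
    imp[na_idx] <- mu[na_idx[, 2L]]
  }
  cvar <- apply(imp, 2L, stats::var)
  if (all(cvar == 0)) {
    coords <- data.frame(pool_id = rownames(v), pc1 = 0, pc2 = 0,
                         z1 = 0, z2 = 0, stringsAsFactors = FALSE)
    return(list(kept = ras, excluded = character(0), coords = coords))
  }
  pc <- stats::prcomp(imp, center = TRUE, scale. = FALSE, rank. = 2L)
  sc <- pc$x
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  robust_z <- function(x) {
    s <- stats::mad(x)
    if (s == 0) rep(0, length(x)) else (x - stats::median(x)) / s
  }
  z1 <- robust_z(sc[, 1L]); z2 <- robust_z(sc[, 2L])
  out <- abs(z1) > z_threshold | abs(z2) > z_threshold
  coords <- data.frame(pool_id = rownames(v), pc1 = sc[, 1L],
                       pc2 = sc[, 2L], z1 = z1, z2 = z2,
                       excluded = out, stringsAsFactors = FALSE)
  kept <- ras
  kept$values <- v[!out, , drop = FALSE]
  kept$pool_groups <- ras$pool_groups[!out]
  list(kept = kept, excluded = rownames(v)[out], coords = coords)
}

#' Pooled case-control association: Student's t-test and 1-df chi-square
#'
#' Per SNP, `p_ttest` comes from a two-sample equal-variance Student's
#' t-test on pool-level mean RAS (df = n1 + n2 - 2), capturing
#' between-pool variation; `p_chi2` from a Pearson chi-square with one
#' degree of freedom on the 2x2 table of continuous allele counts
#' (group mean RAS x 2 x subjects represented by that group's
#' non-missing pools, and complement), without continuity correction.
#' SNPs with fewer than 2 usable pools in either group are untestable.
#' Zero-variance SNPs: equal group means give `p_ttest = 1`; unequal
#' means are untestable.
#'
#' @param ras A `ras_matrix` (typically `pca_pool_filter(...)$kept`).
#' @param case_group,control_group Group labels in `ras$pool_groups`.
#' @return Data frame: `snp_id`, `n_case_pools`, `n_control_pools`,
#'   `mean_ras_case`, `mean_ras_control`, `p_ttest`, `p_chi2`,
#'   `testable`.
#' @export
pooled_association <- function(ras, case_group = "case",
                               control_group = "control") {
  v <- ras$values
  grp <- ras$pool_groups
  ca <- v[grp == case_group, , drop = FALSE]
  co <- v[grp == control_group, , drop = FALSE]
  n1 <- colSums(!is.na(ca)); n2 <- colSums(!is.na(co))
  m1 <- colMeans(ca, na.rm = TRUE); m2 <- colMeans(co, na.rm = TRUE)
  s1 <- apply(ca, 2L, stats::var, na.rm = TRUE)
  s2 <- apply(co, 2L, stats::var, na.rm = TRUE)
  testable <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p_t <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- testable & !is.na(sp2) & sp2 == 0
  p_t[zero_var & m1 == m2] <- 1
  testable[zero_var & m1 != m2] <- FALSE
  # chi-square on continuous allele counts
  N1 <- 2 * n1 * ras$n_subjects_per_pool
  N2 <- 2 * n2 * ras$n_subjects_per_pool
  a <- m1 * N1; b <- (1 - m1) * N1
  cc <- m2 * N2; d <- (1 - m2) * N2
  tot <- N1 + N2
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi <- ifelse(denom > 0, tot * (a * d - b * cc)^2 / denom, 0)
  p_c <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  p_t[!testable] <- NA_real_
  p_c[!testable] <- NA_real_
  m1[n1 == 0] <- NA_real_; m2[n2 == 0] <- NA_real_
  data.frame(snp_id = colnames(v),
             n_case_pools = as.integer(n1),
             n_control_pools = as.integer(n2),
             mean_ras_case = m1, mean_ras_control = m2,
             p_ttest = p_t, p_chi2 = p_c, testable = testable,
             row.names = NULL, stringsAsFactors = FALSE)
}
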