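# Independent oracle implementations used to cross-check package
# results. Each deliberately takes a different computational route from
# the implementation it checks.

# Hardy-Weinberg exact p by the probability *recurrence* in the
# heterozygote count: P(h+2)/P(h) = (na-h)(2n-na-h) / ((h+2)(h+1)),
# whereas the package uses direct lgamma evaluation.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  h <- seq(na %% 2, na, by = 2)
  pr <- numeric(length(h))
  pr[1] <- 1
  for (k in seq_along(h)[-1]) {
    hk <- h[k - 1]
    pr[k] <- pr[k - 1] * (na - hk) * (2 * n - na - hk) /
      ((hk + 2) * (hk + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Brute-force greedy clumping: enumerates every (index, proxy) pair and
# applies the selection rules directly, without any of the package's
# bookkeeping shortcuts.
oracle_clump <- function(assoc, map, ref, config) {
  d <- merge(assoc, map[c("snp_id", "chrom", "pos")], by = "snp_id")
  cand <- d[d$testable & !is.na(d$p_chi2) & d$p_chi2 < config$p_index &
              !is.na(d$p_ttest) & d$p_ttest < config$p_index &
              d$snp_id %in% rownames(ref), ]
  cand <- cand[order(cand$p_chi2, cand$pos, cand$snp_id), ]
  claimed <- character(0)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$snp_id[i]
    if (id %in% claimed) next
    prox <- character(0)
    for (j in seq_len(nrow(d))) {
      pid <- d$snp_id[j]
      if (pid == id || pid %in% claimed) next
      if (d$chrom[j] != cand$chrom[i]) next
      if (abs(d$pos[j] - cand$pos[i]) > config$window_bp) next
      if (is.na(d$p_chi2[j]) || d$p_chi2[j] >= config$p_proxy) next
      if (!pid %in% rownames(ref)) next
      r2 <- suppressWarnings(dosage_r2(ref[id, ], ref[pid, ]))
      if (r2 > config$r2_min) prox <- c(prox, pid)
    }
    if (!length(prox)) next
    claimed <- c(claimed, id, prox)
    out[[id]] <- sort(prox)
  }
  out
}

# Quick genotype simulation for one marker under HWE.
sim_snp <- function(n, f) stats::rbinom(n, 2L, f)

# Builds a minimal ras_matrix by hand for small worked examples.
make_ras <- function(values, groups, n_per_pool = 15L) {
  structure(list(values = values,
                 pool_groups = stats::setNames(groups, rownames(values)),
                 n_subjects_per_pool = as.integer(n_per_pool)),
            class = "ras_matrix")
}
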