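# LD-proxy clumping: candidate loci are index markers that are
# significant under both pooled tests and are corroborated by at least
# one correlated proxy marker nearby.

#' Squared dosage correlation between two markers
#'
#' Composite LD: squared Pearson correlation of unphased allele dosages
#' over pairwise-complete samples. A monomorphic marker gives r2 = 0 by
#' convention; fewer than 10 complete pairs gives 0 with a warning.
#'
#' @param x,y Equal-length dosage vectors over {0, 1, 2, NA}.
#' @return r-squared in [0, 1].
#' @export
dosage_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10) {
    warning("fewer than 10 complete pairs; r2 undefined, returning 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Clumping configuration
#'
#' @param p_index Significance threshold for index markers (default 1e-3).
#' @param p_proxy Chi-square p threshold for proxies (default 1e-3).
#' @param r2_min Minimum r-squared, exclusive (default 0.7).
#' @param window_bp Maximum index-proxy distance in bp (default 100000).
#' @param index_rule `"both"` (default) requires the index to pass both
#'   the t-test and the chi-square at `p_index`; `"chi2"` requires only
#'   the chi-square.
#' @return A list of class `clump_config`.
#' @export
clump_config <- function(p_index = 1e-3, p_proxy = 1e-3, r2_min = 0.7,
                         window_bp = 100000L,
                         index_rule = c("both", "chi2")) {
  stopifnot(p_index > 0, p_index < 1, p_proxy > 0, p_proxy < 1,
            r2_min >= 0, r2_min < 1, window_bp > 0)
  structure(list(p_index = p_index, p_proxy = p_proxy, r2_min = r2_min,
                 window_bp = as.numeric(window_bp),
                 index_rule = match.arg(index_rule)),
            class = "clump_config")
}

#' Select candidate loci by greedy LD-proxy clumping
#'
#' Index candidates are testable markers significant at `p_index`
#' (under both pooled tests by default). Candidates are processed
#' greedily in ascending chi-square p (ties: ascending position, then
#' id). A clump is emitted only if at least one distinct same-chromosome
#' marker within `window_bp` has r-squared above `r2_min` with the index
#' (strict) and chi-square p below `p_proxy`. Every marker belongs to at
#' most one clump, as index or proxy; claimed markers are unavailable to
#' later clumps. Markers absent from the reference panel cannot serve as
#' index or proxy.
#'
#' @param assoc Pooled association table from [pooled_association()].
#' @param map SNP map with `snp_id`, `chrom`, `pos`.
#' @param ref Reference dosage matrix (SNP x sample) for r-squared.
#' @param config A [clump_config()].
#' @return Data frame (one row per clump): `index_snp`, `chrom`, `pos`,
#'   `index_p_ttest`, `index_p_chi2`, `n_proxies`, `best_proxy_id`,
#'   `best_r2`; attribute `proxies` is a named list of per-clump proxy
#'   data frames (`snp_id`, `r2`, `distance_bp`).
#' @export
clump_select <- function(assoc, map, ref, config = clump_config()) {
  d <- merge(assoc, map[c("snp_id", "chrom", "pos")], by = "snp_id")
  in_ref <- d$snp_id %in% rownames(ref)
  if (any(!in_ref))
    message(sum(!in_ref), " markers absent from reference panel")
  sig_chi <- !is.na(d$p_chi2) & d$p_chi2 < config$p_index
  sig_t <- !is.na(d$p_ttest) & d$p_ttest < config$p_index
  is_cand <- d$testable & in_ref & sig_chi &
    (if (config$index_rule == "both") sig_t else TRUE)
  cand <- d[is_cand, ]
  cand <- cand[order(cand$p_chi2, cand$pos, cand$snp_id), ]
  proxy_ok <- !is.na(d$p_chi2) & d$p_chi2 < config$p_proxy & in_ref
  claimed <- character(0)
  rows <- list(); proxies <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$snp_id[i]
    if (id %in% claimed) next
    near <- d$chrom == cand$chrom[i] &
      abs(d$pos - cand$pos[i]) <= config$window_bp &
      d$snp_id != id & proxy_ok & !(d$snp_id %in% claimed)
    cand_prox <- d[near, ]
    if (!nrow(cand_prox)) next
    r2 <- vapply(cand_prox$snp_id, function(p)
      dosage_r2(ref[id, ], ref[p, ]), numeric(1))
    keep <- r2 > config$r2_min
    if (!any(keep)) next
    prox <- data.frame(snp_id = cand_prox$snp_id[keep],
                       r2 = unname(r2[keep]),
                       distance_bp = abs(cand_prox$pos[keep] - cand$pos[i]),
                       stringsAsFactors = FALSE)
    prox <- prox[order(-prox$r2, prox$snp_id), ]
    claimed <- c(claimed, id, prox$snp_id)
    proxies[[id]] <- prox
    rows[[length(rows) + 1L]] <- data.frame(
      index_snp = id, chrom = cand$chrom[i], pos = cand$pos[i],
      index_p_ttest = cand$p_ttest[i], index_p_chi2 = cand$p_chi2[i],
      n_proxies = nrow(prox), best_proxy_id = prox$snp_id[1L],
      best_r2 = prox$r2[1L], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(index_snp = character(0), chrom = character(0),
               pos = integer(0), index_p_ttest = numeric(0),
               index_p_chi2 = numeric(0), n_proxies = integer(0),
               best_proxy_id = character(0), best_r2 = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "proxies") <- proxies
  out
}
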