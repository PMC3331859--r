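# Tabular formats: TSV dialects for maps, manifests, pool designs,
# intensities and dosage matrices, plus GT-only VCF 4.2 export/import.
# All tables are plain tab-separated text with a header row, readable
# back by the functions here.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read the SNP map table
#'
#' Columns: `snp_id`, `chrom`, `pos`, `allele_A`, `allele_B`,
#' `control_maf`, `allelic_or`, `ld_block`.
#'
#' @param map SNP map data frame (e.g. `panel$snps`).
#' @param path File path.
#' @return `read_snp_map` returns the map data frame.
#' @export
write_snp_map <- function(map, path) write_tsv(map, path)

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  read_tsv(path, colClasses = c(chrom = "character"))
}

#' Write / read the sample manifest
#'
#' Columns: `sample_id`, `group`, `sex`, `age`, `cohort`.
#'
#' @param manifest Manifest data frame.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) write_tsv(manifest, path)

#' @rdname write_manifest
#' @export
read_manifest <- function(path) read_tsv(path)

#' Write / read a pool design
#'
#' Columns: `pool_id`, `group`, `sample_ids` (comma-joined member ids).
#'
#' @param design A `pool_design` data frame.
#' @param path File path.
#' @export
write_pool_design <- function(design, path)
  write_tsv(as.data.frame(design), path)

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  d <- read_tsv(path)
  class(d) <- c("pool_design", "data.frame")
  d
}

#' Write / read the pooled intensity table
#'
#' Columns: `snp_id`, `pool_id`, `replicate`, `intensity_A`,
#' `intensity_B`.
#'
#' @param panel Intensity data frame.
#' @param path File path.
#' @export
write_intensities <- function(panel, path) write_tsv(panel, path)

#' @rdname write_intensities
#' @export
read_intensities <- function(path) read_tsv(path)

#' Write / read a dosage matrix as TSV
#'
#' Rows are SNPs, columns samples; first column `snp_id`; values are
#' minor-allele dosages 0/1/2 or `NA`.
#'
#' @param genotypes A `genotype_matrix`, or a bare dosage matrix.
#' @param path File path.
#' @return `read_dosage_tsv` returns a SNP x sample integer matrix.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
         else genotypes
  df <- data.frame(snp_id = rownames(dos), dos, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$snp_id
  m
}

#' Write a genotype matrix as a minimal GT-only VCF 4.2
#'
#' One biallelic record per SNP: REF is `allele_B`, ALT `allele_A`, so
#' the unphased GT ALT-allele count equals the stored dosage; missing
#' dosages become `./.`.
#'
#' @param genotypes A `genotype_matrix` (map supplies chrom/pos/alleles).
#' @param path File path.
#' @export
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage
  map <- genotypes$map[match(rownames(dos), genotypes$map$snp_id), ]
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos))
  gt[is.na(dos)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(dos)), collapse = "\t"),
    paste(map$chrom, map$pos, map$snp_id, map$allele_B, map$allele_A,
          ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
}

#' Read individual genotypes from dosage TSV or VCF
#'
#' For VCF input (via the vcfR package), the GT field of each biallelic
#' record is parsed to an ALT-allele dosage; `./.` becomes `NA`;
#' multi-allelic records are skipped with a warning. With
#' `orient = "minor"` dosages at markers whose ALT frequency exceeds
#' 0.5 are flipped so dosage always counts the minor allele;
#' `orient = "alt"` (default) keeps ALT counts, which round-trips
#' [write_vcf()] output exactly.
#'
#' @param path File path.
#' @param format `"dosage-tsv"` or `"vcf"`.
#' @param orient Allele orientation for VCF input.
#' @return A SNP x sample integer dosage matrix.
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "vcf"),
                           orient = c("alt", "minor")) {
  format <- match.arg(format)
  orient <- match.arg(orient)
  if (format == "dosage-tsv") return(read_dosage_tsv(path))
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic records skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(gsub("\\|", "/", g[known]), "/", fixed = FALSE)
    out[known] <- vapply(alleles,
                         function(a) sum(a == "1"), integer(1))
    out
  }
  m <- apply(gt, 2L, count_alt)
  if (is.null(dim(m)))  # single record: apply simplifies to a vector
    m <- matrix(m, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  rownames(m) <- fix[, "ID"]
  if (orient == "minor") {
    f <- rowMeans(m, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    m[flip, ] <- 2L - m[flip, ]
  }
  m
}
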