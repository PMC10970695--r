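#' Construct a variant table
#'
#' The central genotype-observation container: one row per biallelic SNP
#' with parental genotypes, plus two integer matrices of per-line read
#' counts supporting each parent's allele. A cell with zero counts for
#' both alleles is a missing observation.
#'
#' @param snps data.frame with `chrom`, `pos` (1-based bp), `ref`, `alt`,
#'   `p1_gt`, `p2_gt`
#' @param ad_p1,ad_p2 integer matrices (SNP x line) of reads supporting
#'   the P1 (ref in simulated data) and P2 allele
#' @param lines character vector of line identifiers (column order)
#' @param parent_ad optional list of two-column count matrices for the
#'   parent samples themselves
#' @return an object of class `variant_table`
#' @export
variant_table <- function(snps, ad_p1, ad_p2, lines,
                          parent_ad = NULL) {
  stopifnot(nrow(snps) == nrow(ad_p1), nrow(snps) == nrow(ad_p2),
            ncol(ad_p1) == length(lines), ncol(ad_p2) == length(lines))
  if (any(ad_p1 < 0, na.rm = TRUE) || any(ad_p2 < 0, na.rm = TRUE))
    stop("allele observation counts must be non-negative")
  ord_ok <- all(tapply(snps$pos, snps$chrom, function(p) all(diff(p) > 0)))
  if (!ord_ok) stop("positions must be strictly increasing within chromosome")
  structure(list(snps = snps, ad_p1 = ad_p1, ad_p2 = ad_p2,
                 lines = lines, parent_ad = parent_ad),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$snps), "SNPs x", length(x$lines),
      "lines on", length(unique(x$snps$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
`[.variant_table` <- function(x, i, ...) {
  variant_table(x$snps[i, , drop = FALSE],
                x$ad_p1[i, , drop = FALSE],
                x$ad_p2[i, , drop = FALSE],
                x$lines,
                if (!is.null(x$parent_ad))
                  lapply(x$parent_ad, function(m) m[i, , drop = FALSE]))
}

#' Write a variant table as VCF v4.2
#'
#' Minimal writer for the subset used by this package: CHROM/POS/REF/ALT
#' plus GT:AD per sample; parent samples `P1` and `P2` come first. F2
#' genotypes are called naively from the allele counts (both alleles
#' seen: 0/1; one: the matching homozygote; none: ./.) — downstream
#' analysis uses the AD counts, not these calls.
#'
#' @param vt a [variant_table]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_variant_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=binQTL",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "P1", "P2", vt$lines), collapse = "\t"))
  gt_of <- function(a1, a2) {
    out <- rep("./.", length(a1))
    out[a1 > 0 & a2 > 0] <- "0/1"
    out[a1 > 0 & a2 == 0] <- "0/0"
    out[a1 == 0 & a2 > 0] <- "1/1"
    out
  }
  nsnp <- nrow(vt$snps)
  samp_cols <- matrix("", nsnp, length(vt$lines))
  for (j in seq_along(vt$lines)) {
    a1 <- vt$ad_p1[, j]; a2 <- vt$ad_p2[, j]
    samp_cols[, j] <- paste0(gt_of(a1, a2), ":", a1, ",", a2)
  }
  if (!is.null(vt$parent_ad)) {
    pa <- vt$parent_ad
    p1 <- paste0(vt$snps$p1_gt, ":", pa$P1[, 1], ",", pa$P1[, 2])
    p2 <- paste0(vt$snps$p2_gt, ":", pa$P2[, 1], ",", pa$P2[, 2])
  } else {
    p1 <- paste0(vt$snps$p1_gt, ":.")
    p2 <- paste0(vt$snps$p2_gt, ":.")
  }
  body <- paste(vt$snps$chrom, as.integer(vt$snps$pos), ".",
                vt$snps$ref, vt$snps$alt, ".", "PASS", ".", "GT:AD",
                p1, p2, sep = "\t")
  if (length(vt$lines))
    body <- paste(body, apply(samp_cols, 1, paste, collapse = "\t"),
                  sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load a variant table from a VCF file
#'
#' Reads a VCF (via \pkg{vcfR}) and extracts, for every biallelic SNP,
#' the parental genotypes and each line's allelic depths re-oriented to
#' counts of the P1 and P2 allele. Multi-allelic records are skipped
#' with a logged count.
#'
#' @param vcf_path path to a VCF (plain or gzipped)
#' @param p1_id,p2_id sample names of the two parents
#' @return a [variant_table]
#' @export
load_variants <- function(vcf_path, p1_id = "P1", p2_id = "P2") {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (p in c(p1_id, p2_id))
    if (!p %in% samples)
      stop("parent sample '", p, "' not present in VCF")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message(sum(multi), " multi-allelic record(s) skipped")
  keep <- !multi
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  line_ids <- setdiff(samples, c(p1_id, p2_id))
  ad_ref <- vcfR::masplit(ad[, line_ids, drop = FALSE], record = 1,
                          sort = 0, decreasing = 0)
  ad_alt <- vcfR::masplit(ad[, line_ids, drop = FALSE], record = 2,
                          sort = 0, decreasing = 0)
  ad_ref[is.na(ad_ref)] <- 0L
  ad_alt[is.na(ad_alt)] <- 0L
  snps <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     p1_gt = unname(gt[, p1_id]),
                     p2_gt = unname(gt[, p2_id]),
                     stringsAsFactors = FALSE)
  # re-orient depths: P1 allele count = ref count where P1 is 0/0,
  # alt count where P1 is 1/1; undetermined parents keep ref orientation
  p1_is_alt <- gt_code(snps$p1_gt) == 2L & gt_code(snps$p2_gt) == 0L
  a1 <- ad_ref; a2 <- ad_alt
  if (any(p1_is_alt, na.rm = TRUE)) {
    sw <- which(p1_is_alt)
    a1[sw, ] <- ad_alt[sw, , drop = FALSE]
    a2[sw, ] <- ad_ref[sw, , drop = FALSE]
  }
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(NULL, line_ids)
  variant_table(snps, a1, a2, line_ids)
}

# genotype string -> dose of ALT alleles (0, 1, 2) or NA; phased or not
gt_code <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  g <- gsub("\\|", "/", gt)
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  out
}

#' Keep SNPs informative in an F2 (parents homozygous and different)
#'
#' @param vt a [variant_table]
#' @return the filtered [variant_table]
#' @export
filter_informative <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  c1 <- gt_code(vt$snps$p1_gt)
  c2 <- gt_code(vt$snps$p2_gt)
  keep <- !is.na(c1) & !is.na(c2) & c1 %in% c(0L, 2L) &
    c2 %in% c(0L, 2L) & c1 != c2
  vt[keep]
}

#' Per-SNP quality-control statistics
#'
#' For every SNP: the minor allele frequency from per-line allele
#' dosages (a line with reads for both alleles counts as heterozygous),
#' the missing rate (fraction of lines with no observation), and a
#' segregation-distortion chi-square of the allele counts against the
#' 1 : 1 expected in an F2.
#'
#' @param vt a [variant_table] of informative SNPs
#' @param genotype_level if `TRUE`, test genotype counts against 1:2:1
#'   instead of allele counts against 1:1
#' @return data.frame with `maf`, `missing_rate`, `chisq`, `p_distortion`
#' @export
compute_qc <- function(vt, genotype_level = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  has1 <- vt$ad_p1 > 0L
  has2 <- vt$ad_p2 > 0L
  obs <- has1 | has2
  n_obs <- rowSums(obs)
  n_lines <- length(vt$lines)
  # per-line dosage of the P1 allele: 2 (only P1 reads), 1 (both), 0
  d_p1 <- 2L * rowSums(has1 & !has2) + rowSums(has1 & has2)
  d_p2 <- 2L * rowSums(has2 & !has1) + rowSums(has1 & has2)
  tot <- d_p1 + d_p2
  f1 <- ifelse(tot > 0, d_p1 / tot, NA_real_)
  maf <- pmin(f1, 1 - f1)
  missing_rate <- 1 - n_obs / n_lines
  if (genotype_level) {
    o <- cbind(rowSums(has1 & !has2), rowSums(has1 & has2),
               rowSums(has2 & !has1))
    stat <- gof_stat_rows(o, c(1, 2, 1))
    df <- 2
  } else {
    stat <- gof_stat_rows(cbind(d_p1, d_p2), c(1, 1))
    df <- 1
  }
  p <- pchisq(stat, df, lower.tail = FALSE)
  p[tot == 0] <- NA_real_
  data.frame(maf = maf, missing_rate = missing_rate,
             chisq = stat, p_distortion = p)
}

# row-wise GOF statistic against an expected ratio (no correction)
gof_stat_rows <- function(obs, ratio) {
  tot <- rowSums(obs)
  prop <- ratio / sum(ratio)
  e <- outer(tot, prop)
  stat <- rowSums((obs - e)^2 / e)
  stat[tot == 0] <- NA_real_
  stat
}

#' Chi-square goodness-of-fit test against an expected ratio
#'
#' Computes `sum((O - E)^2 / E)` with expected counts taken from the
#' exact ratio (no rounding), optionally with Yates' continuity
#' correction. Used both for SNP segregation-distortion screening and
#' for testing the 3 : 1 segregation of a dominant trait.
#'
#' @param observed integer vector of category counts (length >= 2)
#' @param ratio expected ratio, e.g. `c(3, 1)` or `c(1, 2, 1)`
#' @param yates apply the continuity correction `(|O - E| - 0.5)^2 / E`
#' @return list with `statistic`, `df`, `p_value`, `expected`
#' @export
#' @examples
#' chi_square_gof(c(146, 47), c(3, 1))   # dominant-trait segregation
chi_square_gof <- function(observed, ratio = rep(1, length(observed)),
                           yates = FALSE) {
  if (length(observed) < 2L) stop("need at least two categories")
  if (length(ratio) != length(observed))
    stop("ratio and observed must have the same length")
  tot <- sum(observed)
  if (tot <= 0) stop("total count must be positive")
  expected <- tot * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected count of zero")
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Apply the SNP retention filters
#'
#' Retains SNPs with minor allele frequency above `maf_min`, missing
#' rate below `miss_max`, and segregation-distortion p-value at or above
#' `distortion_p` (extreme distortion discarded). All inequalities are
#' strict, and every removed SNP is accounted to the filters it failed.
#'
#' @param vt a [variant_table] of informative SNPs
#' @param qc the matching [compute_qc()] output (recomputed if missing)
#' @param maf_min,miss_max,distortion_p filter thresholds
#' @return the filtered [variant_table]; attribute `"filter_counts"`
#'   holds per-criterion removal counts, attribute `"reasons"` a
#'   per-removed-SNP reason matrix
#' @export
apply_filters <- function(vt, qc = NULL, maf_min = 0.05, miss_max = 0.1,
                          distortion_p = 1e-8) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.null(qc)) qc <- compute_qc(vt)
  fail_maf <- !(qc$maf > maf_min) | is.na(qc$maf)
  fail_miss <- !(qc$missing_rate < miss_max)
  fail_dist <- !is.na(qc$p_distortion) & qc$p_distortion < distortion_p
  keep <- !(fail_maf | fail_miss | fail_dist)
  out <- vt[keep]
  counts <- c(maf = sum(fail_maf), missing = sum(fail_miss),
              distortion = sum(fail_dist), removed = sum(!keep),
              retained = sum(keep))
  attr(out, "filter_counts") <- counts
  attr(out, "reasons") <- cbind(maf = fail_maf, missing = fail_miss,
                                distortion = fail_dist)[!keep, , drop = FALSE]
  message("SNP filters: ", counts["removed"], " removed (maf ",
          counts["maf"], ", missing ", counts["missing"], ", distortion ",
          counts["distortion"], "), ", counts["retained"], " retained")
  out
}
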