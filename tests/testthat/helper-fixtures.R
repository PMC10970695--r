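# Small deterministic builders used across the test files.

# variant_table with fully controlled allele-observation counts.
# ad1/ad2: SNP x line integer matrices (single chromosome "chr01").
make_vt <- function(ad1, ad2, pos = NULL, chrom = "chr01") {
  nsnp <- nrow(ad1)
  if (is.null(pos)) pos <- seq_len(nsnp) * 1000
  lines <- sprintf("L%03d", seq_len(ncol(ad1)))
  dimnames(ad1) <- dimnames(ad2) <- list(NULL, lines)
  variant_table(
    snps = data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "T",
                      p1_gt = "0/0", p2_gt = "1/1",
                      stringsAsFactors = FALSE),
    ad_p1 = ad1, ad_p2 = ad2, lines = lines)
}

# window_calls object built directly from per-line call sequences
# (list of integer vectors, codes 1/2/3/NA), windows centred at
# `centers`.
make_wc <- function(call_list, centers = NULL, chrom = "chr01") {
  calls <- do.call(cbind, call_list)
  nw <- nrow(calls)
  if (is.null(centers)) centers <- seq_len(nw) * 1000
  lines <- sprintf("L%03d", seq_len(ncol(calls)))
  colnames(calls) <- lines
  cc <- list(first = centers - 500, last = centers + 500,
             center = centers,
             snpp1 = calls * 0, snpp2 = calls * 0,
             informative = calls * 0 + 15L,
             calls = calls, truncated = FALSE,
             range = c(centers[1] - 500, centers[nw] + 500),
             n_snp = nw)
  structure(list(chrom = stats::setNames(list(cc), chrom), lines = lines,
                 params = list(window = 15L, step = 1L, ratio = 13,
                               min_informative = 13L, rule = "ratio")),
            class = "window_calls")
}

# bin_geno from an explicit genotype matrix (bins x lines, codes 1/2/3)
make_bg <- function(geno, starts = NULL, width = 1e5, chrom = "chr01") {
  nb <- nrow(geno)
  if (is.null(starts)) starts <- (seq_len(nb) - 1L) * width + 1
  bins <- data.frame(bin = sprintf("bin%04d", seq_len(nb)),
                     chrom = chrom, start = starts,
                     end = starts + width - 1, stringsAsFactors = FALSE)
  rownames(geno) <- bins$bin
  lines <- sprintf("L%03d", seq_len(ncol(geno)))
  colnames(geno) <- lines
  structure(list(bins = bins, geno = geno, lines = lines),
            class = "bin_geno")
}

# Draw an F2 genotype pair table with true recombination fraction r:
# two gametes per line, each recombinant with probability r.
sim_geno_pair <- function(n, r) {
  g1a <- stats::rbinom(n, 1, 0.5)  # gamete 1 allele at locus 1 (1 = P1)
  g2a <- stats::rbinom(n, 1, 0.5)
  g1b <- ifelse(stats::rbinom(n, 1, r) == 1, 1 - g1a, g1a)
  g2b <- ifelse(stats::rbinom(n, 1, r) == 1, 1 - g2a, g2a)
  list(a = 3L - (g1a + g2a), b = 3L - (g1b + g2b))
}

# deterministic high-depth F2 population for scan tests: true genotype
# matrix (bins x lines) drawn by independent meioses along one or more
# chromosomes with per-interval recombination probability r_step.
sim_bin_geno <- function(n_lines, n_bins, r_step = 0.05, n_chrom = 1) {
  geno <- matrix(0L, n_bins * n_chrom, n_lines)
  for (ch in seq_len(n_chrom)) {
    for (li in seq_len(n_lines)) {
      g1 <- stats::rbinom(1, 1, 0.5)
      g2 <- stats::rbinom(1, 1, 0.5)
      for (b in seq_len(n_bins)) {
        if (b > 1) {
          if (stats::rbinom(1, 1, r_step)) g1 <- 1 - g1
          if (stats::rbinom(1, 1, r_step)) g2 <- 1 - g2
        }
        geno[(ch - 1) * n_bins + b, li] <- 3L - (g1 + g2)
      }
    }
  }
  geno
}
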