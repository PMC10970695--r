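#' Simulation settings for a synthetic F2 resequencing experiment
#'
#' Describes a biparental F2 population genotyped by low-coverage
#' whole-genome resequencing, with a single dominant presence/absence
#' locus planted on one chromosome. Defaults emulate a typical pulse-crop
#' mapping study: 193 lines over 11 chromosomes, parents sequenced at
#' 13-14x and progeny at a mean of 2.92x, with the trait-bearing parent
#' (P1) carrying the dominant allele so the trait segregates 3:1.
#'
#' @param n_lines number of F2 lines
#' @param n_chrom number of chromosomes
#' @param chrom_len_bp chromosome length in bp (recycled across chromosomes)
#' @param snp_spacing_bp mean spacing of parent-informative SNPs (bp);
#'   SNP counts per chromosome are Poisson with mean
#'   `chrom_len_bp / snp_spacing_bp`, positions uniform
#' @param depth_mean mean sequencing depth per F2 line
#' @param parent_depth sequencing depth for the parents
#' @param error_rate per-read probability that the observed allele is
#'   flipped to the other parent's allele
#' @param missing_rate per site x line probability that all data are
#'   dropped regardless of depth (library/alignment dropout). The
#'   default is 0: at a mean depth of 2.92x the Poisson depth model
#'   already leaves ~5.4 percent of cells with no reads, the dominant
#'   source of missingness in low-coverage resequencing
#' @param qtl_chrom chromosome carrying the planted locus (default:
#'   the middle chromosome)
#' @param qtl_pos_bp position of the planted locus (default: mid-chromosome)
#' @param penetrance probability that a line carrying at least one P1
#'   allele at the locus expresses the trait
#' @param recomb_rate_cM_per_Mb genome-wide map scaling (cM per Mb)
#' @param seed master RNG seed; all stages draw from named substreams of it
#'
#' @return an object of class `sim_config`
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 20, n_chrom = 2, chrom_len_bp = 5e6,
#'                   snp_spacing_bp = 2e4, seed = 1)
sim_config <- function(n_lines = 193L,
                       n_chrom = 11L,
                       chrom_len_bp = 50e6,
                       snp_spacing_bp = 3000,
                       depth_mean = 2.92,
                       parent_depth = 13,
                       error_rate = 0.005,
                       missing_rate = 0,
                       qtl_chrom = NULL,
                       qtl_pos_bp = NULL,
                       penetrance = 1,
                       recomb_rate_cM_per_Mb = 2.8,
                       seed = 1L) {
  n_lines <- as.integer(n_lines)
  n_chrom <- as.integer(n_chrom)
  chrom_len_bp <- rep_len(as.numeric(chrom_len_bp), n_chrom)
  if (n_lines < 1L) stop("n_lines must be >= 1")
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (any(chrom_len_bp <= 0)) stop("chromosome lengths must be positive")
  if (snp_spacing_bp <= 0) stop("snp_spacing_bp must be positive")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  for (nm in c("error_rate", "missing_rate", "penetrance")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
  }
  if (is.null(qtl_chrom)) qtl_chrom <- ceiling(n_chrom / 2)
  qtl_chrom <- as.integer(qtl_chrom)
  if (qtl_chrom < 1L || qtl_chrom > n_chrom)
    stop("qtl_chrom outside the simulated genome")
  if (is.null(qtl_pos_bp)) qtl_pos_bp <- chrom_len_bp[qtl_chrom] / 2
  if (qtl_pos_bp < 1 || qtl_pos_bp > chrom_len_bp[qtl_chrom])
    stop("qtl_pos_bp outside its chromosome")
  structure(list(
    n_lines = n_lines, n_chrom = n_chrom, chrom_len_bp = chrom_len_bp,
    snp_spacing_bp = snp_spacing_bp, depth_mean = depth_mean,
    parent_depth = parent_depth, error_rate = error_rate,
    missing_rate = missing_rate, qtl_chrom = qtl_chrom,
    qtl_pos_bp = qtl_pos_bp, penetrance = penetrance,
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("F2 simulation config:", x$n_lines, "lines,", x$n_chrom,
      "chromosomes\n")
  cat("  depth", x$depth_mean, "x (parents", x$parent_depth,
      "x), error", x$error_rate, ", missing", x$missing_rate, "\n")
  cat("  QTL on chr", x$qtl_chrom, "at", format(x$qtl_pos_bp, big.mark = ","),
      "bp, penetrance", x$penetrance, "\n")
  invisible(x)
}

chrom_names <- function(config) sprintf("chr%02d", seq_len(config$n_chrom))

#' Place parent-informative SNPs along the simulated genome
#'
#' Both parents are inbred and homozygous for different alleles at every
#' emitted site (the only sites informative in an F2). SNP counts per
#' chromosome are Poisson with mean `chrom_len_bp / snp_spacing_bp`,
#' positions uniform; at least one SNP is always emitted per chromosome
#' so that degenerate configurations still yield a usable marker set.
#'
#' @param config a [sim_config()]
#' @return a data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `p1_gt` (`"0/0"`), `p2_gt` (`"1/1"`); the P1 allele is always REF
#' @export
simulate_parent_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "variants"))
  cn <- chrom_names(config)
  per_chr <- lapply(seq_len(config$n_chrom), function(i) {
    len <- config$chrom_len_bp[i]
    n <- max(1L, rpois(1L, len / config$snp_spacing_bp))
    pos <- sort(sample.int(as.integer(len), n))
    data.frame(chrom = cn[i], pos = pos, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, per_chr)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(snps), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  snps$ref <- ref
  snps$alt <- unname(alt)
  snps$p1_gt <- "0/0"
  snps$p2_gt <- "1/1"
  rownames(snps) <- NULL
  snps
}

# Parental origin (1 = P1, 2 = P2) of one gamete at arbitrary positions,
# given its crossover positions and the origin carried at position 0.
gamete_origin_at <- function(pos, crossovers, start_origin) {
  k <- findInterval(pos, crossovers)
  ifelse(k %% 2 == 0, start_origin, 3L - start_origin)
}

#' Simulate F2 meioses: crossovers and true genotypes
#'
#' Each line inherits two independent gametes per chromosome. Crossovers
#' per gamete follow a Poisson process along the chromosome with rate
#' equal to its map length in Morgans (`recomb_rate_cM_per_Mb`), i.e. the
#' Haldane no-interference model; positions are uniform. The true
#' genotype at a SNP is the pair of parental origins of the two gametes.
#'
#' @param config a [sim_config()]
#' @param variants data.frame from [simulate_parent_variants()]
#' @return a `truth_set`: list with `crossovers` (data.frame `line`,
#'   `chrom`, `gamete`, `pos`), `geno` (integer matrix SNP x line, codes
#'   1 = A, 2 = H, 3 = B), `lines`, `variants`, plus enough information
#'   to recover the true genotype at any genome position
#' @export
simulate_f2_meiosis <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "meiosis"))
  cn <- chrom_names(config)
  lines <- sprintf("F2_%03d", seq_len(config$n_lines))
  nsnp <- nrow(variants)
  geno <- matrix(NA_integer_, nsnp, config$n_lines,
                 dimnames = list(NULL, lines))
  co_list <- vector("list", config$n_lines * config$n_chrom * 2L)
  gametes <- vector("list", config$n_chrom)  # per chrom: list of per-line info
  k <- 0L
  for (ci in seq_len(config$n_chrom)) {
    len <- config$chrom_len_bp[ci]
    morgans <- len / 1e6 * config$recomb_rate_cM_per_Mb / 100
    idx <- which(variants$chrom == cn[ci])
    pos <- variants$pos[idx]
    chrom_gam <- vector("list", config$n_lines)
    for (li in seq_len(config$n_lines)) {
      dos <- integer(length(idx))
      gam <- vector("list", 2L)
      for (g in 1:2) {
        nco <- rpois(1L, morgans)
        co <- sort(runif(nco, 0, len))
        start <- sample(1:2, 1L)
        gam[[g]] <- list(co = co, start = start)
        orig <- gamete_origin_at(pos, co, start)
        dos <- dos + (orig == 1L)
        if (nco > 0L) {
          k <- k + 1L
          co_list[[k]] <- data.frame(line = lines[li], chrom = cn[ci],
                                     gamete = g, pos = co,
                                     stringsAsFactors = FALSE)
        }
      }
      chrom_gam[[li]] <- gam
      # dosage of P1 alleles 2/1/0 -> codes 1 (A) / 2 (H) / 3 (B)
      geno[idx, li] <- 3L - dos
    }
    gametes[[ci]] <- chrom_gam
  }
  co <- if (k > 0L) do.call(rbind, co_list[seq_len(k)]) else
    data.frame(line = character(), chrom = character(),
               gamete = integer(), pos = numeric())
  structure(list(crossovers = co, geno = geno, lines = lines,
                 variants = variants, gametes = gametes, config = config),
            class = "truth_set")
}

#' True genotype of every line at one genome position
#'
#' @param truth a `truth_set`
#' @param chrom chromosome index
#' @param pos_bp position in bp
#' @return integer vector per line (1 = A, 2 = H, 3 = B)
#' @export
true_genotype_at <- function(truth, chrom, pos_bp) {
  chrom_gam <- truth$gametes[[chrom]]
  vapply(chrom_gam, function(gam) {
    dos <- sum(vapply(gam, function(g)
      gamete_origin_at(pos_bp, g$co, g$start) == 1L, logical(1)))
    3L - as.integer(dos)
  }, integer(1))
}

#' Simulate per-line allele observations from low-coverage reads
#'
#' Per site and line, read depth is Poisson(`depth_mean`); each read
#' carries one of the line's two parental alleles (both equally likely
#' in heterozygotes) and is flipped to the other parent's allele with
#' probability `error_rate`. A site x line cell is additionally dropped
#' entirely with probability `missing_rate`. Cells with zero observed
#' reads are missing.
#'
#' @param truth a `truth_set` from [simulate_f2_meiosis()]
#' @param config the same [sim_config()]
#' @return a [variant_table] with per-line P1/P2 allele counts and
#'   parental samples at `parent_depth`
#' @export
simulate_read_observations <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(substream_seed(config$seed, "reads"))
  geno <- truth$geno
  n <- length(geno)
  depth <- rpois(n, config$depth_mean)
  depth[runif(n) < config$missing_rate] <- 0L
  e <- config$error_rate
  # P(read observed as P1 allele) by true genotype
  p1prob <- c(1 - e, 0.5, e)[geno]
  ad1 <- rbinom(n, depth, p1prob)
  ad2 <- depth - ad1
  dn <- dimnames(geno)
  ad1 <- matrix(as.integer(ad1), nrow(geno), dimnames = dn)
  ad2 <- matrix(as.integer(ad2), nrow(geno), dimnames = dn)
  nsnp <- nrow(truth$variants)
  pd <- as.integer(round(config$parent_depth))
  p1_err <- rbinom(nsnp, pd, e)   # P2-looking reads in P1
  p2_err <- rbinom(nsnp, pd, e)   # P1-looking reads in P2
  variant_table(
    snps = truth$variants,
    ad_p1 = ad1, ad_p2 = ad2,
    lines = truth$lines,
    parent_ad = list(P1 = cbind(pd - p1_err, p1_err),
                     P2 = cbind(p2_err, pd - p2_err))
  )
}

#' Assign the dominant presence/absence phenotype
#'
#' Lines carrying at least one P1 allele at the planted locus (genotype
#' A or H) express the trait with probability `penetrance`; homozygous
#' P2 lines never do. With full penetrance the population segregates
#' 3 : 1 trait-bearing : glabrous.
#'
#' @param truth a `truth_set`
#' @param config the same [sim_config()]
#' @return data.frame with `line`, `qtl_geno` (`"A"/"H"/"B"`),
#'   `phenotype` (1 = trait present, 0 = absent)
#' @export
assign_trichome_phenotype <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"))
  if (config$qtl_chrom > length(truth$gametes))
    stop("QTL locus outside the simulated genome")
  set.seed(substream_seed(config$seed, "phenotype"))
  g <- true_genotype_at(truth, config$qtl_chrom, config$qtl_pos_bp)
  carrier <- g <= 2L
  phen <- integer(length(g))
  phen[carrier] <- rbinom(sum(carrier), 1L, config$penetrance)
  data.frame(line = truth$lines, qtl_geno = int_to_geno(g),
             phenotype = phen, stringsAsFactors = FALSE)
}

#' Simulate a complete F2 resequencing experiment
#'
#' Convenience wrapper chaining [simulate_parent_variants()],
#' [simulate_f2_meiosis()], [simulate_read_observations()] and
#' [assign_trichome_phenotype()].
#'
#' @param config a [sim_config()]
#' @return an object of class `f2_sim`: list with `config`, `variants`
#'   (a [variant_table]), `truth` (a `truth_set`) and `phenotype`
#' @export
simulate_f2_population <- function(config = sim_config()) {
  skel <- simulate_parent_variants(config)
  truth <- simulate_f2_meiosis(config, skel)
  vt <- simulate_read_observations(truth, config)
  phen <- assign_trichome_phenotype(truth, config)
  structure(list(config = config, variants = vt, truth = truth,
                 phenotype = phen), class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat("Simulated F2 population:", x$config$n_lines, "lines,",
      nrow(x$variants$snps), "SNPs on", x$config$n_chrom, "chromosomes\n")
  cat("  trait-bearing:", sum(x$phenotype$phenotype), "  glabrous:",
      sum(x$phenotype$phenotype == 0), "\n")
  invisible(x)
}

#' Write a simulated population to disk as plain-text fixtures
#'
#' Emits a VCF v4.2 subset (GT:AD per sample, parents `P1`/`P2`), a
#' two-column phenotype TSV, and ground-truth tables (crossovers, true
#' genotypes, true locus genotype per line). The VCF round-trips
#' losslessly through [load_variants()].
#'
#' @param sim an `f2_sim` from [simulate_f2_population()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a named vector of the files written
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "f2_sim"))
  if (sim$config$n_lines < 1L || length(sim$truth$lines) == 0L)
    stop("empty population: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(vcf = file.path(out_dir, "population.vcf"),
             phenotype = file.path(out_dir, "phenotypes.tsv"),
             crossovers = file.path(out_dir, "truth_crossovers.tsv"),
             genotypes = file.path(out_dir, "truth_genotypes.tsv"),
             qtl = file.path(out_dir, "truth_qtl.tsv"))
  write_variant_vcf(sim$variants, files["vcf"])
  write.table(sim$phenotype[, c("line", "phenotype")], files["phenotype"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$crossovers, files["crossovers"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- data.frame(chrom = sim$variants$snps$chrom,
                   pos = sim$variants$snps$pos,
                   matrix(int_to_geno(sim$truth$geno), nrow(sim$truth$geno),
                          dimnames = list(NULL, sim$truth$lines)),
                   check.names = FALSE)
  write.table(gt, files["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$phenotype, files["qtl"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(files)
}
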