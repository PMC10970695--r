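#' Load gene models from a GFF3 file
#'
#' Reads `gene` features (and any `exon` features attached to them via
#' `Parent`) through \pkg{rtracklayer}. Malformed coordinates (end
#' before start) are rejected with the offending feature named.
#'
#' @param gff_path path to a GFF3 file
#' @return an object of class `gene_models`: list with data.frames
#'   `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `annotation`) and `exons` (`gene_id`, `start`, `end`), plus a
#'   `GRanges` of the gene spans for overlap queries
#' @export
load_gene_models <- function(gff_path) {
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path)
  raw <- read.table(gff_path, sep = "\t", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  bad <- which(raw$V5 < raw$V4)
  if (length(bad)) {
    id <- sub(".*ID=([^;]+).*", "\\1", raw$V9[bad[1]])
    stop("malformed coordinates (end < start) for feature '", id, "'")
  }
  g <- rtracklayer::import(gff_path)
  genes <- g[g$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", gff_path)
  note <- if ("Note" %in% names(S4Vectors::mcols(genes)))
    vapply(genes$Note, function(x)
      if (length(x)) paste(x, collapse = "; ") else NA_character_, "")
  else rep(NA_character_, length(genes))
  gdf <- data.frame(
    gene_id = genes$ID,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    annotation = note, stringsAsFactors = FALSE)
  gdf <- gdf[order(gdf$chrom, gdf$start), ]
  rownames(gdf) <- NULL
  ex <- g[g$type == "exon"]
  exons <- if (length(ex)) {
    parent <- vapply(ex$Parent, function(x)
      if (length(x)) x[[1]] else NA_character_, "")
    data.frame(gene_id = parent,
               start = GenomicRanges::start(ex),
               end = GenomicRanges::end(ex), stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), start = integer(),
                    end = integer())
  gr <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$start, gdf$end),
    strand = gdf$strand, gene_id = gdf$gene_id)
  structure(list(genes = gdf, exons = exons, gr = gr),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "gene(s) on",
      length(unique(x$genes$chrom)), "chromosome(s);",
      nrow(x$exons), "exon record(s)\n")
  invisible(x)
}

#' Write gene models back to GFF3
#'
#' @param models a [load_gene_models()] result
#' @param path output file
#' @return invisibly, `path`
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  attr9 <- paste0("ID=", g$gene_id,
                  ifelse(is.na(g$annotation), "",
                         paste0(";Note=", g$annotation)))
  lines <- paste(g$chrom, "binQTL", "gene", g$start, g$end, ".",
                 g$strand, ".", attr9, sep = "\t")
  if (nrow(models$exons)) {
    e <- models$exons
    lines <- c(lines, paste(
      g$chrom[match(e$gene_id, g$gene_id)], "binQTL", "exon",
      e$start, e$end, ".",
      g$strand[match(e$gene_id, g$gene_id)], ".",
      paste0("Parent=", e$gene_id), sep = "\t"))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Genes overlapping a genomic interval
#'
#' @param interval list or vector with `chrom`, `start`, `end`
#'   (1-based, end-inclusive)
#' @param models a [load_gene_models()] result
#' @return the rows of `models$genes` whose span overlaps the interval
#' @export
genes_in_interval <- function(interval, models) {
  stopifnot(inherits(models, "gene_models"))
  chrom <- as.character(interval[["chrom"]])
  if (!chrom %in% models$genes$chrom) {
    warning("chromosome '", chrom, "' not present in the gene models")
    return(models$genes[0, ])
  }
  q <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.numeric(interval[["start"]]),
                            as.numeric(interval[["end"]])))
  hits <- GenomicRanges::findOverlaps(q, models$gr, ignore.strand = TRUE)
  out <- models$genes[sort(unique(S4Vectors::subjectHits(hits))), ]
  rownames(out) <- NULL
  out
}

#' Classify a parent-polymorphic variant by gene context
#'
#' A variant inside a gene span is `intron` unless it falls in an
#' annotated exon, in which case it is a coding SNP or, for indels, an
#' in-frame (`coding_inframe_indel`) or frameshift
#' (`coding_frameshift`) indel according to whether the allele length
#' difference is divisible by 3. Outside genes, the variant is assigned
#' to the nearest gene within `flank` bp as `upstream`/`downstream`
#' (strand-adjusted when the strand is known), otherwise `intergenic`.
#' Genes without exon annotation yield `intron` for internal variants,
#' with `exon_annotated = FALSE` recording the limitation.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `p1`,
#'   `p2` (parental alleles)
#' @param models a [load_gene_models()] result
#' @param flank maximum distance (bp) for upstream/downstream calls
#' @return one-row data.frame with `chrom`, `pos`, `p1`, `p2`, `gene`,
#'   `category`, `distance`, `exon_annotated`
#' @export
classify_variant <- function(variant, models, flank = 5000) {
  stopifnot(inherits(models, "gene_models"))
  chrom <- as.character(variant[["chrom"]])
  pos <- as.numeric(variant[["pos"]])
  p1 <- as.character(variant[["p1"]])
  p2 <- as.character(variant[["p2"]])
  if (is.na(p1) || is.na(p2) || p1 == p2)
    stop("classify_variant expects differing, non-missing parental alleles")
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  res <- function(gene, category, distance, exon_ann = NA)
    data.frame(chrom = chrom, pos = pos, p1 = p1, p2 = p2,
               gene = gene, category = category, distance = distance,
               exon_annotated = exon_ann, stringsAsFactors = FALSE)
  inside <- which(g$start <= pos & pos <= g$end)
  if (length(inside) > 0L) {
    if (length(inside) > 1L) {
      warning("position ", pos, " overlaps ", length(inside),
              " genes; nearest-start gene chosen")
      inside <- inside[which.min(abs(pos - g$start[inside]))]
    }
    gene <- g$gene_id[inside]
    ex <- models$exons[models$exons$gene_id == gene, , drop = FALSE]
    has_exons <- nrow(ex) > 0L
    in_exon <- has_exons && any(ex$start <= pos & pos <= ex$end)
    if (!in_exon)
      return(res(gene, "intron", 0, has_exons))
    len_diff <- abs(nchar(p1) - nchar(p2))
    cat <- if (len_diff == 0L) "coding_snp"
    else if (len_diff %% 3L == 0L) "coding_inframe_indel"
    else "coding_frameshift"
    return(res(gene, cat, 0, TRUE))
  }
  if (nrow(g) == 0L) return(res(NA_character_, "intergenic", NA_real_))
  dist <- pmax(g$start - pos, pos - g$end)   # positive: outside the span
  j <- which.min(dist)
  if (dist[j] > flank) return(res(NA_character_, "intergenic", dist[j]))
  before <- pos < g$start[j]
  minus <- !is.na(g$strand[j]) && g$strand[j] == "-"
  category <- if (xor(before, minus)) "upstream" else "downstream"
  res(g$gene_id[j], category, dist[j])
}

#' Classify a table of variants
#'
#' Row-wise [classify_variant()] over a data.frame with `chrom`, `pos`,
#' `p1`, `p2`.
#'
#' @inheritParams classify_variant
#' @param variants data.frame of variants
#' @return data.frame with one classification row per variant
#' @export
classify_variants <- function(variants, models, flank = 5000) {
  out <- lapply(seq_len(nrow(variants)), function(i)
    classify_variant(variants[i, ], models, flank))
  do.call(rbind, out)
}

#' Retain variants polymorphic between the two parents
#'
#' @param variants data.frame with parental allele columns
#' @param p1_col,p2_col names of the parental allele columns
#' @return the subset with differing, non-missing parental alleles;
#'   attribute `"n_dropped_missing"` counts excluded missing-allele rows
#' @export
compare_parent_alleles <- function(variants, p1_col = "p1",
                                   p2_col = "p2") {
  a <- as.character(variants[[p1_col]])
  b <- as.character(variants[[p2_col]])
  miss <- is.na(a) | is.na(b) | a == "" | b == "" | a == "." | b == "."
  if (any(miss))
    warning(sum(miss), " variant(s) with a missing parental allele excluded")
  keep <- !miss & a != b
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- sum(miss)
  out
}

#' Built-in candidate-gene models for the mapped trichome interval
#'
#' Six published gene models on Chr6 spanning the trichome QTL support
#' interval, shipped as a GFF3 fixture. Exon spans for the Rtf1-like
#' gene (`...164`) are synthetic placeholders (the published record
#' gives only the gene span) and are marked as such in the file.
#'
#' @return a [load_gene_models()] result
#' @export
candidate_gene_models <- function() {
  load_gene_models(system.file("extdata", "candidate_genes_chr6.gff3",
                               package = "binQTL", mustWork = TRUE))
}

#' Built-in parent-polymorphic variants near the candidate genes
#'
#' The published table of SNPs/indels differing between the
#' trichome-bearing (P1) and glabrous (P2) parent around the candidate
#' genes, with the published location/effect label in
#' `reported_category`.
#'
#' @return a data.frame with `gene_id`, `chrom`, `pos`, `p1`, `p2`,
#'   `reported_category`
#' @export
candidate_variants <- function() {
  read.table(system.file("extdata", "candidate_variants_chr6.tsv",
                         package = "binQTL", mustWork = TRUE),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
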