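#' Maximum-likelihood recombination fraction between two F2 markers
#'
#' EM estimate of the recombination fraction r from two codominant
#' genotype vectors in an F2. The double-heterozygote class mixes
#' parental and double-recombinant configurations; EM resolves the
#' ambiguity by iterating the expected number of recombinant gametes.
#'
#' @param g1,g2 genotype vectors over `"A"/"H"/"B"` (or codes 1/2/3),
#'   `NA` = missing; pairwise-complete observations are used
#' @param tol convergence tolerance on r
#' @param maxit maximum EM iterations
#' @return the ML estimate of r in `[0, 0.5]`, or `NA` (with a warning)
#'   if no complete pairs exist; attribute `"n"` = pairs used
#' @export
estimate_recfrac_f2 <- function(g1, g2, tol = 1e-9, maxit = 2000L) {
  a <- geno_to_int(g1)
  b <- geno_to_int(g2)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    warning("no pairwise-complete genotype pairs; r undefined")
    return(structure(NA_real_, n = 0L))
  }
  n9 <- matrix(tabulate((a[ok] - 1L) * 3L + b[ok], 9L), 1L)
  r <- recfrac_em_counts(n9, tol = tol, maxit = maxit)
  structure(as.numeric(r), n = sum(ok))
}

# Vectorised EM over rows of a pairs x 9 count matrix.
# Cell order: AA AH AB HA HH HB BA BH BB.
# Recombinant gametes per cell: 0 1 2 1 (EM) 1 2 1 0; the HH cell
# contributes 2 r^2 / ((1-r)^2 + r^2) in expectation.
recfrac_em_counts <- function(n9, tol = 1e-9, maxit = 2000L) {
  stopifnot(ncol(n9) == 9L)
  N <- rowSums(n9)
  w <- c(0, 1, 2, 1, 0, 1, 2, 1, 0)
  base_rec <- as.numeric(n9 %*% w)
  r <- rep(0.25, nrow(n9))
  for (it in seq_len(maxit)) {
    hh <- 2 * r^2 / ((1 - r)^2 + r^2)
    r_new <- (base_rec + n9[, 5L] * hh) / (2 * N)
    r_new <- pmin(pmax(r_new, 0), 0.5)
    if (max(abs(r_new - r), na.rm = TRUE) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  r
}

# Log-likelihood of a 9-cell F2 joint-genotype count vector at r
# (exported for use as an independent grid-search check).
#' F2 two-locus log-likelihood at a given recombination fraction
#'
#' @param n9 counts in cell order AA AH AB HA HH HB BA BH BB
#' @param r recombination fraction (vectorised)
#' @return log-likelihood values
#' @export
recfrac_loglik <- function(n9, r) {
  vapply(r, function(ri) {
    p <- c((1 - ri)^2 / 4, ri * (1 - ri) / 2, ri^2 / 4,
           ri * (1 - ri) / 2, ((1 - ri)^2 + ri^2) / 2, ri * (1 - ri) / 2,
           ri^2 / 4, ri * (1 - ri) / 2, (1 - ri)^2 / 4)
    sum(n9[p > 0] * log(p[p > 0])) + ifelse(any(n9[p == 0] > 0), -Inf, 0)
  }, 0)
}

#' Map functions: recombination fraction to centimorgans
#'
#' Kosambi `d = 25 ln((1 + 2r) / (1 - 2r))` (partial interference) or
#' Haldane `d = -50 ln(1 - 2r)` (no interference). Values at or above
#' 0.5 are capped just below with a warning.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`
#' @param kind `"kosambi"` (default) or `"haldane"`
#' @return distance(s) in cM
#' @export
#' @examples
#' map_function(0.1)              # 10.14 cM (Kosambi)
#' map_function(0.1, "haldane")   # 11.16 cM
map_function <- function(r, kind = c("kosambi", "haldane")) {
  kind <- match.arg(kind)
  if (any(r < 0, na.rm = TRUE)) stop("r must be non-negative")
  if (any(r >= 0.5, na.rm = TRUE)) {
    warning("recombination fraction >= 0.5 capped at 0.4999")
    r <- pmin(r, 0.4999)
  }
  if (kind == "kosambi") 25 * log((1 + 2 * r) / (1 - 2 * r))
  else -50 * log(1 - 2 * r)
}

# inverse map function: cM -> r
inverse_map_function <- function(d, kind = c("kosambi", "haldane")) {
  kind <- match.arg(kind)
  if (kind == "kosambi") {
    e <- exp(d / 25)
    (e - 1) / (2 * (e + 1))
  } else {
    (1 - exp(-d / 50)) / 2
  }
}

#' Build a genetic linkage map from bin genotypes
#'
#' One linkage group per chromosome, bins kept in physical order (marker
#' order is taken from the reference; collinearity with the genetic
#' ranks can be checked afterwards with [collinearity()]). Adjacent-bin
#' recombination fractions are estimated by EM ([estimate_recfrac_f2()])
#' and converted to cM through the chosen map function.
#'
#' @param bg a [genotype_bins()] result
#' @param kind map function, `"kosambi"` (default) or `"haldane"`
#' @return an object of class `genetic_map`: data.frame `table` with
#'   `bin`, `lg`, `chrom`, `start`, `end`, `r_next`, `cM`, plus the map
#'   `kind`
#' @export
build_genetic_map <- function(bg, kind = c("kosambi", "haldane")) {
  stopifnot(inherits(bg, "bin_geno"))
  kind <- match.arg(kind)
  bins <- bg$bins
  chroms <- unique(bins$chrom)
  tabs <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(bins$chrom == chroms[k])
    m <- length(idx)
    r_next <- rep(NA_real_, m)
    cM <- numeric(m)
    if (m < 2L) {
      warning("linkage group ", chroms[k], " has fewer than 2 bins; ",
              "zero-length group")
    } else {
      n9 <- matrix(0L, m - 1L, 9L)
      for (j in seq_len(m - 1L)) {
        a <- bg$geno[idx[j], ]
        b <- bg$geno[idx[j + 1L], ]
        ok <- !is.na(a) & !is.na(b)
        n9[j, ] <- tabulate((a[ok] - 1L) * 3L + b[ok], 9L)
      }
      r <- recfrac_em_counts(n9)
      none <- rowSums(n9) == 0L
      if (any(none)) {
        warning(sum(none), " adjacent bin pair(s) without complete data; ",
                "zero distance assigned")
        r[none] <- 0
      }
      d <- map_function(r, kind)
      cM <- cumsum(c(0, d))
      r_next <- c(r, NA_real_)
    }
    tabs[[k]] <- data.frame(bins[idx, , drop = FALSE],
                            lg = paste0("LG_", chroms[k]),
                            r_next = r_next, cM = cM,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  structure(list(table = tab, kind = kind), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- summarize_map(x)
  cat("genetic_map (", x$kind, "): ", s$global$n_marker, " bin markers, ",
      length(unique(x$table$lg)), " linkage groups, ",
      round(s$global$total_cM, 2), " cM total\n", sep = "")
  invisible(x)
}

#' Per-linkage-group and global map summaries
#'
#' For each linkage group: marker count, total genetic length, average
#' marker interval (total cM / marker count), maximum adjacent gap, and
#' percentage of gaps shorter than `gap_cM`. The global summary pools
#' all groups (average interval = summed cM / summed markers).
#'
#' @param map a [build_genetic_map()] result
#' @param gap_cM gap-size threshold for the percentage column
#' @return list with data.frames `per_lg` and `global`
#' @export
summarize_map <- function(map, gap_cM = 5) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  lgs <- unique(tab$lg)
  per <- lapply(lgs, function(lg) {
    cm <- tab$cM[tab$lg == lg]
    gaps <- diff(cm)
    data.frame(lg = lg, n_marker = length(cm),
               total_cM = max(cm) - min(cm),
               avg_interval_cM = (max(cm) - min(cm)) / length(cm),
               max_gap_cM = if (length(gaps)) max(gaps) else 0,
               pct_gaps_lt = if (length(gaps))
                 100 * mean(gaps < gap_cM) else 100,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_lg = per, global = summarize_lg_table(per))
}

#' Global statistics from a per-linkage-group summary table
#'
#' Pools per-LG rows (as produced by [summarize_map()], or read from a
#' published map summary) into genome totals: summed marker and SNP
#' counts, summed genetic length, global average marker interval
#' (total cM / total markers) and the largest per-LG maximum gap.
#'
#' @param per_lg data.frame with columns `n_marker`, `total_cM`,
#'   `max_gap_cM` and optionally `n_snp`
#' @return one-row data.frame with `n_marker`, `n_snp` (if present),
#'   `total_cM`, `avg_interval_cM`, `max_gap_cM`
#' @export
summarize_lg_table <- function(per_lg) {
  stopifnot(all(c("n_marker", "total_cM", "max_gap_cM") %in% names(per_lg)))
  out <- data.frame(
    n_marker = sum(per_lg$n_marker),
    total_cM = sum(per_lg$total_cM),
    avg_interval_cM = sum(per_lg$total_cM) / sum(per_lg$n_marker),
    max_gap_cM = max(per_lg$max_gap_cM))
  if ("n_snp" %in% names(per_lg))
    out <- data.frame(out[, 1, drop = FALSE], n_snp = sum(per_lg$n_snp),
                      out[, -1, drop = FALSE])
  out
}

#' Built-in published linkage-group summary table
#'
#' Per-linkage-group summary of the published black gram bin-marker
#' map (marker and SNP counts, genetic lengths, interval statistics),
#' shipped as a TSV fixture; feed it to [summarize_lg_table()] for the
#' genome-wide totals.
#'
#' @return data.frame with `lg`, `n_marker`, `n_snp`, `total_cM`,
#'   `avg_interval_cM`, `max_gap_cM`, `pct_gaps_lt5`
#' @export
published_lg_summary <- function() {
  read.table(system.file("extdata", "linkage_group_summary.tsv",
                         package = "binQTL", mustWork = TRUE),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Collinearity between genetic and physical marker order
#'
#' Spearman rank correlation, per linkage group, between the cumulative
#' genetic position and the physical bin start. A map whose genetic
#' order follows the chromosome gives rho = 1.
#'
#' @param map a [build_genetic_map()] result
#' @return named numeric vector of rho per linkage group (`NA` for
#'   groups with fewer than 3 bins)
#' @export
collinearity <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  lgs <- unique(tab$lg)
  out <- vapply(lgs, function(lg) {
    s <- tab[tab$lg == lg, ]
    if (nrow(s) < 3L) return(NA_real_)
    suppressWarnings(cor(s$cM, s$start, method = "spearman"))
  }, 0)
  names(out) <- lgs
  out
}

#' Write a genetic map as TSV
#'
#' @param map a `genetic_map`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_genetic_map <- function(map, path) {
  write.table(map$table[, c("bin", "lg", "cM", "chrom", "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
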