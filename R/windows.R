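#' Sliding-window genotype calls from low-coverage allele observations
#'
#' Scans each chromosome of each line with a window of `window`
#' consecutive SNPs advanced by `step` SNPs. Within a window, each SNP
#' with reads supporting only the P1 allele adds 1 to `SNPP1`, only the
#' P2 allele adds 1 to `SNPP2`, and a SNP with reads for both alleles
#' adds 1 to each. Under the default ratio rule the window is called
#' homozygous P1 (`A`) when `SNPP1 >= ratio * SNPP2`, homozygous P2
#' (`B`) when `SNPP2 >= ratio * SNPP1`, and heterozygous (`H`)
#' otherwise; windows with fewer than `min_informative` SNPs carrying
#' any reads are missing.
#'
#' @param vt a filtered [variant_table]
#' @param window window size in SNPs
#' @param step sliding step in SNPs
#' @param ratio count ratio required to call a homozygote
#' @param min_informative minimum SNPs with data before calling. The
#'   default equals `ratio`: a homozygous window containing a single
#'   discordant site can only satisfy the `ratio`:1 test when at least
#'   `ratio` sites are informative, so calling sparser windows
#'   systematically biases homozygous tracts towards `H`
#' @param rule `"ratio"` (default, `SNPP1 >= ratio * SNPP2`) or
#'   `"count"` (absolute majority count `SNPP1 >= ratio`)
#' @return an object of class `window_calls`: per chromosome, window
#'   metadata (`first`, `last`, `center` SNP positions) and an integer
#'   call matrix (windows x lines; 1 = A, 2 = H, 3 = B, NA = missing)
#' @export
call_windows <- function(vt, window = 15L, step = 1L, ratio = 13,
                         min_informative = 13L,
                         rule = c("ratio", "count")) {
  stopifnot(inherits(vt, "variant_table"))
  rule <- match.arg(rule)
  chroms <- unique(vt$snps$chrom)
  res <- vector("list", length(chroms))
  names(res) <- chroms
  for (ch in chroms) {
    idx <- which(vt$snps$chrom == ch)
    pos <- vt$snps$pos[idx]
    s1 <- (vt$ad_p1[idx, , drop = FALSE] > 0L) &
      (vt$ad_p2[idx, , drop = FALSE] == 0L)
    s2 <- (vt$ad_p2[idx, , drop = FALSE] > 0L) &
      (vt$ad_p1[idx, , drop = FALSE] == 0L)
    sb <- (vt$ad_p1[idx, , drop = FALSE] > 0L) &
      (vt$ad_p2[idx, , drop = FALSE] > 0L)
    nsnp <- length(idx)
    truncated <- nsnp < window
    w <- min(window, nsnp)
    starts <- seq.int(1L, nsnp - w + 1L, by = step)
    winsum <- function(m) {
      cs <- rbind(0, apply(m, 2, cumsum))
      cs[starts + w, , drop = FALSE] - cs[starts, , drop = FALSE]
    }
    n1 <- winsum(s1) + winsum(sb)
    n2 <- winsum(s2) + winsum(sb)
    ninf <- winsum(s1 | s2 | sb)
    if (rule == "ratio") {
      isA <- n1 >= ratio * n2
      isB <- n2 >= ratio * n1
    } else {
      isA <- n1 >= ratio & n1 > n2
      isB <- n2 >= ratio & n2 > n1
    }
    calls <- matrix(2L, length(starts), ncol(n1))
    calls[isA] <- 1L
    calls[isB] <- 3L
    calls[isA & isB] <- NA_integer_  # no data in window
    calls[ninf < min_informative] <- NA_integer_
    colnames(calls) <- vt$lines
    res[[ch]] <- list(
      first = pos[starts], last = pos[starts + w - 1L],
      center = pos[starts + (w - 1L) %/% 2L],
      snpp1 = n1, snpp2 = n2, informative = ninf,
      calls = calls, truncated = truncated,
      range = c(pos[1L], pos[nsnp]), n_snp = nsnp)
    if (truncated)
      warning("chromosome ", ch, " has fewer SNPs (", nsnp,
              ") than the window size; one truncated window used")
  }
  structure(list(chrom = res, lines = vt$lines,
                 params = list(window = window, step = step, ratio = ratio,
                               min_informative = min_informative,
                               rule = rule)),
            class = "window_calls")
}

#' @export
print.window_calls <- function(x, ...) {
  nw <- sum(vapply(x$chrom, function(c) length(c$first), 0))
  cat("window_calls:", nw, "windows x", length(x$lines), "lines on",
      length(x$chrom), "chromosome(s) (window ",
      x$params$window, ", step ", x$params$step, ")\n", sep = "")
  invisible(x)
}

# collapse one line's window calls into runs, ignoring missing windows
call_runs <- function(calls) {
  ok <- which(!is.na(calls))
  if (length(ok) == 0L)
    return(list(values = integer(), start = integer(), end = integer()))
  r <- rle(calls[ok])
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  list(values = r$values, start = ok[starts], end = ok[ends])
}

#' Detect recombination breakpoints from window calls
#'
#' Consecutive windows with the same call are collapsed into runs
#' (missing windows never terminate a run); each transition between two
#' runs with different calls is a breakpoint. Its uncertainty interval
#' is bounded by the center SNPs of the two adjacent informative
#' windows, and the point estimate is the interval midpoint.
#'
#' @param wc a [call_windows()] result
#' @return data.frame with `line`, `chrom`, `left`, `right`, `pos`
#'   (midpoint), `from`, `to` (`"A"/"H"/"B"`)
#' @export
detect_breakpoints <- function(wc) {
  stopifnot(inherits(wc, "window_calls"))
  out <- list()
  k <- 0L
  for (ch in names(wc$chrom)) {
    cc <- wc$chrom[[ch]]
    for (li in seq_along(wc$lines)) {
      runs <- call_runs(cc$calls[, li])
      nr <- length(runs$values)
      if (nr < 2L) next
      left_w <- runs$end[-nr]
      right_w <- runs$start[-1L]
      left <- cc$center[left_w]
      right <- cc$center[right_w]
      k <- k + 1L
      out[[k]] <- data.frame(
        line = wc$lines[li], chrom = ch,
        left = left, right = right, pos = (left + right) / 2,
        from = int_to_geno(runs$values[-nr]),
        to = int_to_geno(runs$values[-1L]),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(line = character(), chrom = character(),
                      left = numeric(), right = numeric(), pos = numeric(),
                      from = character(), to = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build population-level bin boundaries from pooled breakpoints
#'
#' Pools all lines' breakpoint point estimates per chromosome, sorts
#' them, and greedily merges (left to right) any boundary closer than
#' `min_span` to the previously kept one. The surviving boundaries
#' partition each chromosome into bins; a chromosome with no breakpoint
#' is a single bin.
#'
#' @param breakpoints data.frame from [detect_breakpoints()]
#' @param chrom_ranges data.frame with `chrom`, `start`, `end` giving
#'   the physical extent of each chromosome (e.g. from
#'   [chrom_ranges_of()])
#' @param min_span minimum bin span in bp (default 100 kb)
#' @return data.frame with `bin`, `chrom`, `start`, `end` (1-based,
#'   end-inclusive, consecutive within chromosome)
#' @export
build_bins <- function(breakpoints, chrom_ranges, min_span = 100000) {
  out <- list()
  for (i in seq_len(nrow(chrom_ranges))) {
    ch <- chrom_ranges$chrom[i]
    lo <- chrom_ranges$start[i]
    hi <- chrom_ranges$end[i]
    pts <- sort(breakpoints$pos[breakpoints$chrom == ch])
    pts <- pts[pts > lo & pts < hi]
    kept <- numeric(0)
    last <- -Inf
    for (p in pts) {
      if (p - last >= min_span) {
        kept <- c(kept, p)
        last <- p
      }
    }
    bnd <- c(lo, floor(kept), hi)
    out[[i]] <- data.frame(
      chrom = ch,
      start = bnd[-length(bnd)] + c(0, rep(1, length(kept))),
      end = bnd[-1L],
      stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  bins <- data.frame(bin = sprintf("bin%04d", seq_len(nrow(bins))), bins,
                     stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  bins
}

#' Physical extent of each chromosome in a window-call set
#'
#' @param wc a [call_windows()] result
#' @return data.frame with `chrom`, `start`, `end` (first/last SNP)
#' @export
chrom_ranges_of <- function(wc) {
  stopifnot(inherits(wc, "window_calls"))
  data.frame(chrom = names(wc$chrom),
             start = vapply(wc$chrom, function(c) c$range[1], 0),
             end = vapply(wc$chrom, function(c) c$range[2], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype every line at every bin
#'
#' A line's call at a bin is the majority call over the windows whose
#' center SNP lies in the bin; a tie or the absence of any informative
#' window gives a missing call.
#'
#' @param wc a [call_windows()] result
#' @param bins bin definitions from [build_bins()]
#' @return an object of class `bin_geno`: list with `bins` and an
#'   integer matrix `geno` (bins x lines; 1 = A, 2 = H, 3 = B, NA)
#' @export
genotype_bins <- function(wc, bins) {
  stopifnot(inherits(wc, "window_calls"))
  nlines <- length(wc$lines)
  geno <- matrix(NA_integer_, nrow(bins), nlines,
                 dimnames = list(bins$bin, wc$lines))
  for (ch in names(wc$chrom)) {
    bidx <- which(bins$chrom == ch)
    if (length(bidx) == 0L) next
    cc <- wc$chrom[[ch]]
    grp <- findInterval(cc$center, bins$start[bidx])
    ok <- grp >= 1L & grp <= length(bidx)
    counts <- lapply(1:3, function(code) {
      m <- (cc$calls[ok, , drop = FALSE] == code)
      m[is.na(m)] <- FALSE
      rowsum(m + 0L, grp[ok])
    })
    present <- as.integer(rownames(counts[[1]]))
    cA <- counts[[1]]; cH <- counts[[2]]; cB <- counts[[3]]
    top <- pmax(cA, cH, cB)
    n_top <- (cA == top) + (cH == top) + (cB == top)
    call <- matrix(NA_integer_, nrow(cA), ncol(cA))
    call[cA == top] <- 1L
    call[cH == top] <- 2L
    call[cB == top] <- 3L
    call[n_top > 1L | top == 0L] <- NA_integer_
    geno[bidx[present], ] <- call
  }
  structure(list(bins = bins, geno = geno, lines = wc$lines),
            class = "bin_geno")
}

#' @export
print.bin_geno <- function(x, ...) {
  cat("bin_geno:", nrow(x$bins), "bins x", length(x$lines), "lines on",
      length(unique(x$bins$chrom)), "chromosome(s); missing ",
      round(100 * mean(is.na(x$geno)), 2), "%\n")
  invisible(x)
}

#' Fraction of bin genotype calls matching the simulated truth
#'
#' Compares every non-missing bin call with the true genotype at the
#' bin midpoint (crossovers inside a bin make its single call genuinely
#' ambiguous; midpoints sidestep window-edge effects).
#'
#' @param bg a [genotype_bins()] result from simulated data
#' @param truth the matching `truth_set`
#' @return proportion of non-missing calls equal to truth
#' @export
bin_accuracy <- function(bg, truth) {
  cn <- chrom_names(truth$config)
  ok <- 0L; tot <- 0L
  for (ci in seq_along(cn)) {
    rows <- which(bg$bins$chrom == cn[ci])
    if (!length(rows)) next
    mids <- (bg$bins$start[rows] + bg$bins$end[rows]) / 2
    for (li in seq_along(truth$lines)) {
      gam <- truth$gametes[[ci]][[li]]
      dos <- (gamete_origin_at(mids, gam[[1]]$co, gam[[1]]$start) == 1L) +
        (gamete_origin_at(mids, gam[[2]]$co, gam[[2]]$start) == 1L)
      tg <- 3L - dos
      obs <- bg$geno[rows, li]
      m <- !is.na(obs)
      ok <- ok + sum(obs[m] == tg[m])
      tot <- tot + sum(m)
    }
  }
  ok / tot
}

#' Write a bin genotype matrix as TSV
#'
#' @param bg a `bin_geno`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_bin_matrix <- function(bg, path) {
  df <- data.frame(bg$bins,
                   matrix(int_to_geno(bg$geno), nrow(bg$geno),
                          dimnames = list(NULL, bg$lines)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
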