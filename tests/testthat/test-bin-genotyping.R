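test_that("window calls follow the published count-ratio rule", {
  mk <- function(n1, n2, nmiss = 15 - n1 - n2) {
    ad1 <- matrix(c(rep(1L, n1), rep(0L, n2 + nmiss)), ncol = 1)
    ad2 <- matrix(c(rep(0L, n1), rep(1L, n2), rep(0L, nmiss)), ncol = 1)
    wc <- call_windows(make_vt(ad1, ad2))
    unname(wc$chrom[[1]]$calls[1, 1])
  }
  expect_equal(mk(14, 1), 1L)   # 14 >= 13 * 1 -> A
  expect_equal(mk(15, 0), 1L)   # division-free dominant case
  expect_equal(mk(7, 8), 2L)    # both ratios < 13 -> H
  expect_equal(mk(13, 1, 1), 1L)  # boundary: 13 >= 13 * 1 -> A
  expect_equal(mk(1, 14), 3L)   # symmetric B call
  expect_true(is.na(mk(5, 5, 5)))  # 10 informative < 13 -> missing

  # sites with reads for both alleles add one to each count:
  # 12 pure P1 + 2 both-allele sites -> 14:2, not an A call
  ad1 <- matrix(c(rep(1L, 12), 1L, 1L, 0L), ncol = 1)
  ad2 <- matrix(c(rep(0L, 12), 1L, 1L, 1L), ncol = 1)
  wc <- call_windows(make_vt(ad1, ad2))
  expect_equal(unname(wc$chrom[[1]]$snpp1[1, 1]), 14)
  expect_equal(unname(wc$chrom[[1]]$snpp2[1, 1]), 3)
  expect_equal(unname(wc$chrom[[1]]$calls[1, 1]), 2L)
})

test_that("window caller equals the exhaustive re-count oracle", {
  set.seed(42)
  for (i in 1:100) {
    nsnp <- sample(6:30, 1)
    nlines <- sample(1:4, 1)
    ad1 <- matrix(rpois(nsnp * nlines, 0.8), nsnp, nlines)
    ad2 <- matrix(rpois(nsnp * nlines, 0.8), nsnp, nlines)
    storage.mode(ad1) <- storage.mode(ad2) <- "integer"
    window <- sample(3:8, 1); ratio <- sample(2:5, 1)
    min_inf <- sample(1:3, 1)
    wc <- suppressWarnings(
      call_windows(make_vt(ad1, ad2), window = window, step = 1,
                   ratio = ratio, min_informative = min_inf))
    oracle <- recount_oracle(ad1, ad2, window, 1, ratio, min_inf)
    expect_equal(unname(wc$chrom[[1]]$calls), oracle)
  }
})

test_that("a chromosome shorter than the window yields one flagged window", {
  ad1 <- matrix(1L, 5, 2); ad2 <- matrix(0L, 5, 2)
  expect_warning(wc <- call_windows(make_vt(ad1, ad2), window = 15,
                                    min_informative = 3),
                 "truncated")
  expect_equal(length(wc$chrom[[1]]$first), 1L)
  expect_true(wc$chrom[[1]]$truncated)
})

test_that("breakpoints are run transitions; missing never breaks runs", {
  wc <- make_wc(list(c(1L, 1L, 1L, 2L, 2L)))
  bp <- detect_breakpoints(wc)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$from, "A"); expect_equal(bp$to, "H")
  expect_equal(bp$left, 3000); expect_equal(bp$right, 4000)
  expect_equal(bp$pos, 3500)

  # all-A chromosome: no breakpoints
  expect_equal(nrow(detect_breakpoints(make_wc(list(rep(1L, 6))))), 0L)

  # missing windows are bridged: A, NA, A, B -> one A->B breakpoint
  bp <- detect_breakpoints(make_wc(list(c(1L, NA, 1L, 3L))))
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$from, "A"); expect_equal(bp$to, "B")
  expect_equal(bp$left, 3000); expect_equal(bp$right, 4000)
})

test_that("breakpoint count equals a brute-force run scan, and bounds nest", {
  set.seed(7)
  for (i in 1:100) {
    calls <- sample(c(1L, 2L, 3L, NA), sample(5:40, 1), replace = TRUE,
                    prob = c(0.3, 0.3, 0.3, 0.1))
    bp <- detect_breakpoints(make_wc(list(calls)))
    obs <- calls[!is.na(calls)]
    n_trans <- if (length(obs) < 2) 0L else sum(diff(obs) != 0)
    expect_equal(nrow(bp), n_trans)
    if (nrow(bp))
      expect_true(all(bp$left < bp$pos & bp$pos <= bp$right))
  }
})

test_that("bin building merges nearby boundaries and partitions chroms", {
  cr <- data.frame(chrom = "chr01", start = 1, end = 2e6)
  # no breakpoints -> single bin spanning the chromosome
  bins <- build_bins(detect_breakpoints(make_wc(list(rep(1L, 4)))), cr)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$start, 1); expect_equal(bins$end, 2e6)

  mk_bp <- function(pos) data.frame(line = "L1", chrom = "chr01",
                                    left = pos - 1, right = pos + 1,
                                    pos = pos, from = "A", to = "H")
  # two boundaries 40 kb apart merge into one (first kept)
  bins <- build_bins(mk_bp(c(5e5, 5.4e5)), cr)
  expect_equal(nrow(bins), 2L)
  expect_equal(bins$end[1], 5e5)

  # 0.5 / 0.7 / 1.2 Mb all survive a 100 kb merge -> 4 bins
  bins <- build_bins(mk_bp(c(5e5, 7e5, 1.2e6)), cr)
  expect_equal(nrow(bins), 4L)
  expect_equal(bins$end, c(5e5, 7e5, 1.2e6, 2e6))
  # surviving boundaries pairwise >= min_span apart
  expect_true(all(diff(bins$end) >= 1e5))
})

test_that("surviving boundaries are always >= min_span apart", {
  set.seed(13)
  cr <- data.frame(chrom = "chr01", start = 1, end = 5e6)
  for (i in 1:50) {
    pos <- sort(runif(sample(2:60, 1), 0, 5e6))
    bp <- data.frame(line = "L1", chrom = "chr01", left = pos - 1,
                     right = pos + 1, pos = pos, from = "A", to = "H")
    bins <- build_bins(bp, cr, min_span = 1e5)
    bnd <- bins$end[-nrow(bins)]
    if (length(bnd) > 1) expect_true(all(diff(bnd) >= 1e5 - 1))
  }
})

test_that("bin genotyping takes the majority call, ties become missing", {
  # 6 windows at 1..6 kb; bins [1, 3500], [3501, 7000]
  wc <- make_wc(list(c(1L, 1L, 1L, 2L, 2L, 2L),   # tie 1A/2H in bin 1? no:
                     c(1L, 1L, 1L, 1L, 3L, 3L),
                     c(NA, NA, NA, NA, NA, NA)))
  bins <- data.frame(bin = c("b1", "b2"), chrom = "chr01",
                     start = c(1, 3501), end = c(3500, 7000))
  bg <- genotype_bins(wc, bins)
  # line 1: windows 1-3 (A,A,H... centers 1000,2000,3000) -> calls A,A,A?
  expect_equal(unname(bg$geno[, 1]), c(1L, 2L))  # majority A then H
  expect_equal(unname(bg$geno[, 2]), c(1L, 3L))  # A run then B majority
  expect_true(all(is.na(bg$geno[, 3])))          # no informative windows

  # an exact tie across a within-line breakpoint -> missing
  wc <- make_wc(list(c(1L, 1L, 3L, 3L)))
  bins <- data.frame(bin = "b1", chrom = "chr01", start = 1, end = 4500)
  bg <- genotype_bins(wc, bins)
  expect_true(is.na(bg$geno[1, 1]))
})

test_that("bin calls recover true genotypes away from crossovers", {
  # error-free, high depth: bin genotypes equal truth except within one
  # window span of a true crossover
  cfg <- sim_config(n_lines = 40, n_chrom = 1, chrom_len_bp = 5e6,
                    snp_spacing_bp = 5e3, depth_mean = 20,
                    error_rate = 0, missing_rate = 0, seed = 77)
  sim <- simulate_f2_population(cfg)
  vt <- filter_informative(sim$variants)
  wc <- call_windows(vt)
  bins <- build_bins(detect_breakpoints(wc), chrom_ranges_of(wc))
  bg <- genotype_bins(wc, bins)
  win_span <- 15 * 5e3
  mids <- (bg$bins$start + bg$bins$end) / 2
  tg <- vapply(mids, function(m) true_genotype_at(sim$truth, 1, m),
               integer(length(sim$truth$lines)))  # lines x bins
  for (li in seq_along(sim$truth$lines)) {
    gam <- sim$truth$gametes[[1]][[li]]
    co <- sort(c(gam[[1]]$co, gam[[2]]$co))
    obs <- bg$geno[, li]
    ok <- !is.na(obs)
    if (length(co))
      ok <- ok & vapply(mids, function(m) min(abs(co - m)) > win_span, TRUE)
    expect_true(all(obs[ok] == tg[li, ok]))
  }
})
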