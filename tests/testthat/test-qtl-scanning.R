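test_that("F2 covariate coding and zero-variance marker dropping", {
  geno <- rbind(c(1L, 2L, 3L, 1L),   # informative
                c(2L, 2L, 2L, 2L),   # all heterozygous: no additive info
                c(1L, 1L, 1L, 1L))   # monomorphic
  bg <- make_bg(geno)
  expect_warning(design <- encode_f2_covariates(bg), "dropped")
  expect_equal(ncol(design$x), 1L)
  expect_equal(unname(design$x[, 1]), c(1, 0, -1, 1))
  expect_equal(unname(design$z[, 1]), c(0, 1, 0, 0))
  # missing calls imputed by the marker mean
  geno2 <- rbind(c(1L, 3L, NA, 1L, 3L))
  d2 <- encode_f2_covariates(make_bg(geno2))
  expect_equal(unname(d2$x[3, 1]), 0)  # mean of (1,-1,1,-1)
})

test_that("stepwise selection finds a true marker among null markers", {
  set.seed(202)
  n <- 193
  geno <- matrix(sample(c(1L, 2L, 3L), n * 51, TRUE, c(0.25, 0.5, 0.25)),
                 51, n)
  y <- as.integer(geno[25, ] <= 2L)   # fully determined by marker 25
  design <- encode_f2_covariates(make_bg(geno))
  sel <- select_cofactors_stepwise(design, y)
  expect_true(25L %in% sel$selected)
  # exhaustive single-marker R^2 oracle confirms marker 25 is best
  r2 <- vapply(seq_len(ncol(design$x)), function(j) {
    suppressWarnings(summary(lm(y ~ design$x[, j] + design$z[, j]))$r.squared)
  }, 0)
  expect_equal(which.max(r2), 25L)
})

test_that("stepwise is near-empty under pure noise", {
  set.seed(203)
  hits <- vapply(1:20, function(i) {
    geno <- matrix(sample(c(1L, 2L, 3L), 150 * 40, TRUE,
                          c(0.25, 0.5, 0.25)), 40, 150)
    y <- rbinom(150, 1, 0.75)
    design <- encode_f2_covariates(make_bg(geno))
    length(select_cofactors_stepwise(design, y)$selected)
  }, 0)
  expect_gte(mean(hits == 0), 0.8)
  expect_lte(max(hits), 2)
})

test_that("duplicate marker columns: only the lower index enters", {
  set.seed(204)
  base <- sample(c(1L, 2L, 3L), 120, TRUE, c(0.25, 0.5, 0.25))
  geno <- rbind(base, base, base)  # three identical markers
  y <- as.integer(base <= 2L)
  design <- encode_f2_covariates(make_bg(geno))
  sel <- select_cofactors_stepwise(design, y)
  expect_equal(sel$selected, 1L)
})

test_that("interval-scan priors are coherent probabilities", {
  set.seed(99)
  for (i in 1:25) {
    r1 <- runif(1, 0.001, 0.4); r2 <- runif(1, 0.001, 0.4)
    gL <- sample(c(1:3, NA), 20, TRUE)
    gR <- sample(c(1:3, NA), 20, TRUE)
    P <- binQTL:::qtl_genotype_priors(gL, gR, r1, r2)
    both_missing <- is.na(gL) & is.na(gR)
    expect_equal(unname(rowSums(P)[!both_missing]),
                 rep(1, sum(!both_missing)), tolerance = 1e-9)
    expect_true(all(rowSums(P)[both_missing] == 0))
    expect_true(all(P >= 0))
  }
  # at r1 -> 0 the prior collapses onto the left marker genotype
  P <- binQTL:::qtl_genotype_priors(c(1L, 2L, 3L), c(NA, NA, NA),
                                    1e-9, 0.2)
  expect_equal(P, diag(3), tolerance = 1e-6)
})

test_that("scan LOD at marker positions equals the regression oracle", {
  set.seed(301)
  n_checked <- 0
  for (rep in 1:10) {
    n <- sample(80:150, 1)
    geno <- sim_bin_geno(n, n_bins = sample(10:15, 1), r_step = 0.1)
    bg <- make_bg(geno)
    qmark <- sample(nrow(geno), 1)
    eff <- c(1, 0.6, 0)[geno[qmark, ]]
    y <- eff + rnorm(n, 0, 0.5)
    map <- build_genetic_map(bg)
    design <- encode_f2_covariates(bg)
    prof <- scan_icim(map, design, y, cofactors = NULL, step_cM = 1)
    for (k in seq_len(nrow(map$table))) {
      cm <- map$table$cM[k]
      row <- which(abs(prof$cM - cm) < 1e-8)[1]
      g <- geno[match(map$table$bin[k], design$markers), ]
      x <- c(1, 0, -1)[g]; z <- as.numeric(g == 2L)
      rss1 <- sum(resid(lm(y ~ x + z))^2)
      rss0 <- sum((y - mean(y))^2)
      lod_oracle <- n / 2 * log10(rss0 / rss1)
      expect_equal(prof$lod[row], lod_oracle, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("a phenotype determined by one marker peaks at that marker", {
  set.seed(302)
  geno <- sim_bin_geno(150, n_bins = 20, r_step = 0.08)
  bg <- make_bg(geno)
  y <- as.integer(geno[12, ] <= 2L)   # dominant, fully penetrant
  map <- build_genetic_map(bg)
  design <- encode_f2_covariates(bg)
  prof <- scan_icim(map, design, y, NULL)
  pk <- prof[which.max(prof$lod), ]
  expect_equal(pk$cM, map$table$cM[12], tolerance = 1e-8)
  # LOD is non-negative everywhere
  expect_true(all(prof$lod >= 0))
})

test_that("EM mixture scan agrees with regression at informative markers", {
  # with complete genotypes and a continuous phenotype the EM route and
  # the regression route coincide at marker positions
  set.seed(303)
  geno <- sim_bin_geno(100, n_bins = 8, r_step = 0.15)
  bg <- make_bg(geno)
  y <- c(1.5, 1.0, 0)[geno[4, ]] + rnorm(100, 0, 0.7)
  map <- build_genetic_map(bg)
  design <- encode_f2_covariates(bg)
  p_em <- scan_icim(map, design, y, NULL, method = "em")
  p_hk <- scan_icim(map, design, y, NULL, method = "hk")
  for (k in seq_len(nrow(map$table))) {
    rows <- which(abs(p_em$cM - map$table$cM[k]) < 1e-8)[1]
    expect_equal(p_em$lod[rows], p_hk$lod[rows], tolerance = 1e-4)
  }
})

test_that("ICIM adjustment excludes flanking cofactors from the model", {
  # a cofactor that IS a flank must not absorb its own interval's QTL:
  # phenotype defined by marker 5; marker 5 selected as cofactor; the
  # LOD at marker 5 must stay at the unadjusted value
  set.seed(304)
  geno <- sim_bin_geno(160, n_bins = 10, r_step = 0.1)
  bg <- make_bg(geno)
  y <- as.integer(geno[5, ] <= 2L)
  map <- build_genetic_map(bg)
  design <- encode_f2_covariates(bg)
  cof <- select_cofactors_stepwise(design, y)
  expect_true(5L %in% cof$selected)
  prof_c <- scan_icim(map, design, y, cof)
  prof_0 <- scan_icim(map, design, y, NULL)
  at5 <- which(abs(prof_c$cM - map$table$cM[5]) < 1e-8)[1]
  expect_gt(prof_c$lod[at5], 0.9 * prof_0$lod[at5])
})

test_that("permutation threshold: determinism and quantile boundaries", {
  set.seed(305)
  geno <- sim_bin_geno(60, n_bins = 6, r_step = 0.2)
  bg <- make_bg(geno)
  y <- rbinom(60, 1, 0.75)
  map <- build_genetic_map(bg)
  design <- encode_f2_covariates(bg)
  t1 <- permutation_threshold(map, design, y, n_perm = 100, seed = 42)
  t2 <- permutation_threshold(map, design, y, n_perm = 100, seed = 42)
  expect_identical(as.numeric(t1), as.numeric(t2))
  ml <- attr(t1, "max_lods")
  expect_equal(length(ml), 100L)
  # alpha = 1 gives the minimum of the null distribution
  tmin <- permutation_threshold(map, design, y, n_perm = 100, seed = 42,
                                alpha = 1)
  expect_equal(as.numeric(tmin), min(ml))
  # next-higher order statistic at alpha = 0.01, n = 100 -> the maximum
  expect_equal(as.numeric(t1), sort(ml)[100])
  expect_error(permutation_threshold(map, design, y, n_perm = 10),
               "at least 100")
})

test_that("support interval follows the LOD-drop definition", {
  mk_prof <- function(lod, cm = seq_along(lod) - 1) {
    structure(data.frame(lg = "LG_chr01", chrom = "chr01", cM = cm,
                         pos_bp = cm * 1e5 + 1, lod = lod, a = 0, d = 0,
                         pve = 0, n = 100),
              class = c("qtl_profile", "data.frame"))
  }
  # sharp peak of 30: interval where LOD >= 27
  prof <- mk_prof(c(5, 10, 26, 28, 30, 27.5, 26.5, 10))
  si <- support_interval(prof, drop = 3)
  expect_equal(si$peak$cM, 4)
  expect_equal(c(si$cM_lo, si$cM_hi), c(3, 5))
  expect_false(si$flat)
  # symmetric triangular profile gives a symmetric interval
  prof <- mk_prof(c(0, 2, 4, 6, 8, 6, 4, 2, 0))
  si <- support_interval(prof, drop = 3)
  expect_equal(si$peak$cM - si$cM_lo, si$cM_hi - si$peak$cM)
  # flat profile: whole group, flagged
  prof <- mk_prof(rep(5, 6))
  si <- support_interval(prof, drop = 3)
  expect_true(si$flat)
  expect_equal(c(si$cM_lo, si$cM_hi), c(0, 5))
  # ties broken leftmost
  prof <- mk_prof(c(1, 7, 3, 7, 1))
  expect_equal(support_interval(prof)$peak$cM, 1)
})

test_that("effects and PVE from genotype class means", {
  g <- c(rep(1L, 30), rep(2L, 60), rep(3L, 30))
  y <- c(rep(1, 30), rep(1, 60), rep(0, 30))  # complete dominance
  ef <- estimate_effects_pve(g, y)
  expect_equal(ef$a, 0.5)
  expect_equal(ef$d, 0.5)
  expect_equal(ef$pve, 100)  # zero residual within classes
  # phenotype independent of genotype: PVE near zero
  set.seed(9)
  y2 <- rnorm(120)
  expect_lt(estimate_effects_pve(g, y2)$pve, 10)
})
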