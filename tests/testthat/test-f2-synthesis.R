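test_that("simulated parent SNPs are informative and Poisson-dense", {
  counts <- vapply(1:4, function(s) {
    cfg <- sim_config(n_chrom = 1, chrom_len_bp = 10e6,
                      snp_spacing_bp = 2000, seed = s)
    nrow(simulate_parent_variants(cfg))
  }, 0)
  # each draw within 4 SD of the Poisson mean 5000, the mean within 3 SE
  expect_true(all(abs(counts - 5000) < 4 * sqrt(5000)))
  expect_lt(abs(mean(counts) - 5000), 3 * sqrt(5000 / 4))

  cfg <- sim_config(n_chrom = 2, chrom_len_bp = 1e6,
                    snp_spacing_bp = 5e4, seed = 1)
  skel <- simulate_parent_variants(cfg)
  expect_true(all(skel$p1_gt == "0/0" & skel$p2_gt == "1/1"))
  expect_true(all(skel$ref != skel$alt))
  expect_true(all(tapply(skel$pos, skel$chrom, function(p) all(diff(p) > 0))))

  # spacing larger than the chromosome still yields one SNP per chromosome
  cfg <- sim_config(n_chrom = 3, chrom_len_bp = 1e4,
                    snp_spacing_bp = 1e6, seed = 2)
  skel <- simulate_parent_variants(cfg)
  expect_true(all(table(skel$chrom) >= 1))

  expect_error(sim_config(chrom_len_bp = 0), "positive")
  expect_error(sim_config(n_lines = 0), "n_lines")
})

test_that("meiosis: crossover rate, Mendelian ratios, track consistency", {
  # 50 Mb at 3 cM/Mb = 150 cM -> 1.5 crossovers per gamete
  cfg <- sim_config(n_lines = 400, n_chrom = 1, chrom_len_bp = 50e6,
                    snp_spacing_bp = 5e5, recomb_rate_cM_per_Mb = 3,
                    seed = 9)
  skel <- simulate_parent_variants(cfg)
  truth <- simulate_f2_meiosis(cfg, skel)
  n_gam <- 2 * cfg$n_lines
  rate <- nrow(truth$crossovers) / n_gam
  expect_lt(abs(rate - 1.5), 3 * sqrt(1.5 / n_gam))

  # crossover positions strictly increasing per gamete
  by_gam <- split(truth$crossovers$pos,
                  paste(truth$crossovers$line, truth$crossovers$gamete))
  expect_true(all(vapply(by_gam, function(p) all(diff(p) > 0), TRUE)))

  # single-locus genotype frequencies consistent with 1:2:1
  mid <- which.min(abs(skel$pos - 25e6))
  tab <- tabulate(truth$geno[mid, ], 3)
  expect_gt(chi_square_gof(tab, c(1, 2, 1))$p_value, 0.01)

  # zero map distance means identical genotype vectors
  g1 <- true_genotype_at(truth, 1, 12345678)
  g2 <- true_genotype_at(truth, 1, 12345678.5)
  expect_identical(g1, g2)

  # recombinant fraction between two loci matches the Haldane r of
  # their map distance (10 cM -> r = 0.0906) within Monte-Carlo error
  ga <- true_genotype_at(truth, 1, 20e6)
  gb <- true_genotype_at(truth, 1, 20e6 + 10 / 3 * 1e6)
  r_hat <- estimate_recfrac_f2(ga, gb)
  r_true <- (1 - exp(-2 * 0.10)) / 2
  expect_lt(abs(r_hat - r_true), 3 * sqrt(r_true * (1 - r_true) / n_gam))
})

test_that("read observations follow the depth/error/missing model", {
  cfg <- sim_config(n_lines = 200, n_chrom = 1, chrom_len_bp = 2e6,
                    snp_spacing_bp = 2e3, depth_mean = 2.92,
                    error_rate = 0, missing_rate = 0, seed = 21)
  sim <- simulate_f2_population(cfg)
  depth <- sim$variants$ad_p1 + sim$variants$ad_p2
  # zero-depth fraction ~ exp(-2.92) = 0.0539
  p0 <- mean(depth == 0)
  expect_lt(abs(p0 - exp(-2.92)), 3 * sqrt(exp(-2.92) / length(depth)))
  # error 0: heterozygous lines read each allele with probability 1/2
  het <- sim$truth$geno == 2L
  n1 <- sum(sim$variants$ad_p1[het])
  ntot <- sum(depth[het])
  expect_lt(abs(n1 / ntot - 0.5), 3 * sqrt(0.25 / ntot))
  # error 0: homozygous lines never show the other parent's allele
  homA <- sim$truth$geno == 1L
  expect_equal(sum(sim$variants$ad_p2[homA]), 0L)

  # error 0.01: fraction of flipped reads in hom-A lines ~ 0.01
  cfg2 <- sim_config(n_lines = 200, n_chrom = 1, chrom_len_bp = 2e6,
                     snp_spacing_bp = 2e3, depth_mean = 3,
                     error_rate = 0.01, missing_rate = 0, seed = 22)
  sim2 <- simulate_f2_population(cfg2)
  homA <- sim2$truth$geno == 1L
  flips <- sum(sim2$variants$ad_p2[homA])
  reads <- sum((sim2$variants$ad_p1 + sim2$variants$ad_p2)[homA])
  expect_gt(reads, 1e5)
  expect_lt(abs(flips / reads - 0.01), 3 * sqrt(0.01 * 0.99 / reads))
})

test_that("trichome phenotype: dominance, penetrance, 3:1 segregation", {
  cfg <- sim_config(n_lines = 193, n_chrom = 2, chrom_len_bp = 5e6,
                    snp_spacing_bp = 2e4, qtl_chrom = 1,
                    penetrance = 1, seed = 31)
  sim <- simulate_f2_population(cfg)
  ph <- sim$phenotype
  # carriers always show the trait at penetrance 1; B never does
  expect_true(all(ph$phenotype[ph$qtl_geno %in% c("A", "H")] == 1))
  expect_true(all(ph$phenotype[ph$qtl_geno == "B"] == 0))
  # 3:1 segregation not rejected
  tab <- c(sum(ph$phenotype == 1), sum(ph$phenotype == 0))
  expect_gt(chi_square_gof(tab, c(3, 1))$p_value, 0.01)

  # penetrance 0.9: P(trait) = 0.75 * 0.9 = 0.675 in expectation
  hits <- vapply(1:6, function(s) {
    cfg <- sim_config(n_lines = 500, n_chrom = 1, chrom_len_bp = 5e6,
                      snp_spacing_bp = 5e4, qtl_chrom = 1,
                      penetrance = 0.9, seed = 100 + s)
    sim <- simulate_f2_population(cfg)
    mean(sim$phenotype$phenotype)
  }, 0)
  n <- 6 * 500
  expect_lt(abs(mean(hits) - 0.675), 3 * sqrt(0.675 * 0.325 / n))
})

test_that("population-level 1:2:1 holds across seeds and loci", {
  pvals <- unlist(lapply(1:10, function(s) {
    cfg <- sim_config(n_lines = 200, n_chrom = 1, chrom_len_bp = 2e6,
                      snp_spacing_bp = 2e5, seed = 200 + s)
    sim <- simulate_f2_population(cfg)
    apply(sim$truth$geno, 1, function(g)
      chi_square_gof(tabulate(g, 3), c(1, 2, 1))$p_value)
  }))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("fixture writing rejects an empty population", {
  cfg <- sim_config(n_lines = 5, n_chrom = 1, chrom_len_bp = 1e5,
                    snp_spacing_bp = 2e4, seed = 4)
  sim <- simulate_f2_population(cfg)
  sim$truth$lines <- character(0)
  expect_error(write_fixture(sim, withr::local_tempdir()), "empty")
})
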