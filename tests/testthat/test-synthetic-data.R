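test_that("configuration validation names the offending field", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(n_populations = 2,
                          families_per_population = c(5, 5, 5)),
               "families_per_population")
  expect_error(sim_config(families_per_population = 0, n_populations = 1),
               "families_per_population")
  expect_error(
    sim_config(variance_components = list(Na = c(sigma2_g = -1,
      sigma2_gs = 0, sigma2_b = 0, sigma2_r = 0, sigma2_c = 0,
      sigma2_e = 1))), "variance")
})

test_that("degenerate panel sizes work and dosages are valid", {
  f <- simulate_population_set(sim_config(n_populations = 1,
    families_per_population = 1, n_snps = 10, seed = 1))
  expect_equal(nrow(f$genotypes), 1L)
  expect_true(all(f$genotypes %in% 0:2))
})

test_that("default configuration mirrors the five-population 517-family panel", {
  cfg <- sim_config()
  expect_equal(sum(cfg$families_per_population), 517L)
  expect_equal(cfg$n_populations, 5L)
  f <- simulate_population_set(sim_config(n_snps = 500))
  expect_equal(nrow(f$genotypes), 517L)
  expect_equal(as.integer(table(f$population)), c(102L, 104L, 117L, 110L, 84L))
})

test_that("realized allele frequencies track the drawn targets", {
  cfg <- sim_config(n_populations = 1, families_per_population = 500,
                    n_snps = 2000, maf_range = c(0.05, 0.5), fst = 0,
                    seed = 7)
  f <- simulate_population_set(cfg)
  p_hat <- colMeans(f$genotypes) / 2
  p <- f$snp_info$p_anc
  se <- sqrt(p * (1 - p) / (2 * 500))
  # binomial sampling interval: ~99.99% of sites within 4 SE
  expect_gt(mean(abs(p_hat - p) <= 4 * se), 0.995)
})

test_that("population drift differentiates allele frequencies", {
  f <- simulate_population_set(sim_config(n_populations = 2,
    families_per_population = 300, n_snps = 800, fst = 0.1, seed = 9))
  p1 <- colMeans(f$genotypes[f$population == "Pop1", ]) / 2
  p2 <- colMeans(f$genotypes[f$population == "Pop2", ]) / 2
  # drift variance ~ fst * p(1-p) dominates binomial noise at n = 300
  expect_gt(sd(p1 - p2), 2 * sqrt(mean(p1 * (1 - p1)) / 300))
})

test_that("GBS reads: deep sequencing recovers true dosages exactly", {
  f <- simulate_population_set(small_config(n_fam = 20, n_snps = 100))
  r <- simulate_gbs_reads(f, mean_depth = 1e4, missing_rate = 0)
  x <- naive_calls(r)
  expect_equal(unname(x), unname(f$genotypes + 0), ignore_attr = TRUE)
})

test_that("heterozygote undercall follows 2^(1-d)", {
  # founder set that is heterozygous everywhere
  f <- simulate_population_set(small_config(n_fam = 60, n_snps = 400))
  f$genotypes[] <- 1L
  r <- simulate_gbs_reads(f, mean_depth = 3, missing_rate = 0, seed = 21)
  d <- r$ref + r$alt
  x <- naive_calls(r)
  hom1 <- mean(x[d == 1] != 1)
  hom3 <- mean(x[d == 3] != 1)
  expect_equal(hom1, 1)                      # depth 1 can never show both
  expect_equal(hom3, 2^(1 - 3), tolerance = 0.1)  # ~0.25, MC error
})

test_that("depth and missingness generator hits its targets", {
  f <- simulate_population_set(small_config(n_fam = 50, n_snps = 2000))
  r <- simulate_gbs_reads(f, mean_depth = 2.98, missing_rate = 0.23,
                          seed = 33)
  d <- r$ref + r$alt                          # 1e5 genotype draws
  expect_equal(mean(d == 0), 0.23, tolerance = 0.01)
  expect_equal(mean(d[d > 0]), 2.98, tolerance = 0.02)
})

test_that("read-level missingness is independent of true genotype", {
  f <- simulate_population_set(small_config(n_fam = 100, n_snps = 1000))
  r <- simulate_gbs_reads(f, mean_depth = 2, missing_rate = 0.25, seed = 5)
  d <- r$ref + r$alt
  miss_by_dosage <- vapply(0:2, function(g)
    mean(d[f$genotypes == g] == 0), numeric(1))
  expect_true(all(abs(miss_by_dosage - 0.25) < 0.01))
})

test_that("null variance components give exactly mean + fixed effects", {
  vc0 <- c(sigma2_g = 0, sigma2_gs = 0, sigma2_b = 0, sigma2_r = 0,
           sigma2_c = 0, sigma2_e = 0)
  cfg <- sim_config(n_populations = 2, families_per_population = 10,
                    n_snps = 50, variance_components = list(Na = vc0),
                    trait_means = c(Na = 3), seed = 2,
                    location_effects = c(-1, 1),
                    population_effects = c(0.5, -0.5))
  f <- simulate_population_set(cfg)
  tt <- simulate_trial(f)
  expected <- 3 + c(-1, 1)[as.integer(tt$location)] +
    c(0.5, -0.5)[as.integer(tt$population)]
  expect_equal(tt$Na, expected)
})

test_that("trial design is balanced: one plot per family x rep x location", {
  f <- simulate_population_set(small_config(n_fam = 15, n_pop = 2))
  tt <- simulate_trial(f)
  counts <- table(tt$family, tt$location, tt$replicate)
  expect_true(all(counts == 1))
  expect_equal(nrow(tt), 30 * 2 * 3)
})

test_that("fixed seed reproduces everything; SNP count does not perturb phenotypes", {
  cfg <- small_config(n_fam = 12, n_snps = 80, seed = 55)
  f1 <- simulate_population_set(cfg)
  f2 <- simulate_population_set(cfg)
  expect_identical(f1$genotypes, f2$genotypes)
  t1 <- simulate_trial(f1)
  t2 <- simulate_trial(f2)
  expect_identical(t1, t2)
  r1 <- simulate_gbs_reads(f1)
  r2 <- simulate_gbs_reads(f2)
  expect_identical(r1$alt, r2$alt)
  # same seed, more SNPs: phenotype columns unchanged up to BV rescaling of
  # the same stream -- the trial stage draws from its own stream
  cfg_big <- small_config(n_fam = 12, n_snps = 160, seed = 55)
  t3 <- simulate_trial(simulate_population_set(cfg_big))
  expect_identical(t1[, c("family", "location", "replicate", "row", "column")],
                   t3[, c("family", "location", "replicate", "row", "column")])
})

test_that("realized family-effect variance covers the configured sigma2_g", {
  vars <- vapply(1:100, function(i) {
    f <- simulate_population_set(small_config(n_fam = 200, n_snps = 60,
                                              seed = 1000 + i))
    tt <- simulate_trial(f)
    var(attr(tt, "family_effects")$Na)
  }, numeric(1))
  # mean realized variance within a few percent of the target
  expect_equal(mean(vars) / 2.32e-3, 1, tolerance = 0.05)
  # and the target sits inside the central mass of the realized distribution
  expect_gt(mean(vars > 2.32e-3), 0.2)
  expect_gt(mean(vars < 2.32e-3), 0.2)
})
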