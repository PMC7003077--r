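test_that("VanRaden closed forms: fully inbred-negative and duplicated individuals", {
  m <- 40
  # one individual heterozygous at every locus, p = 0.5: diagonal 0 (F = -1)
  X1 <- matrix(1, 1, m, dimnames = list("a", NULL))
  g1 <- vanraden_grm(X1, p = rep(0.5, m))
  expect_equal(unname(diag(g1$G)), 0)
  # two identical homozygous-alternate individuals, p = 0.5: all entries 2
  X2 <- matrix(2, 2, m, dimnames = list(c("a", "b"), NULL))
  g2 <- vanraden_grm(X2, p = rep(0.5, m))
  expect_true(all(abs(g2$G - 2) < 1e-12))
  # monomorphic everything is rejected
  expect_error(vanraden_grm(X2), "monomorphic")
})

test_that("VanRaden GRM is symmetric, PSD, and recovers half-sib relatedness", {
  hs <- halfsib_genotypes(n_fam = 60, sibs_per_fam = 4, m = 3000, seed = 11)
  g <- vanraden_grm(hs$kids + 0, p = hs$p)
  expect_lt(max(abs(g$G - t(g$G))), 1e-10)
  ev <- eigen(g$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  same <- outer(hs$family, hs$family, "==") & upper.tri(g$G)
  diff <- !outer(hs$family, hs$family, "==") & upper.tri(g$G)
  expect_equal(mean(g$G[same]), 0.25, tolerance = 0.035)
  expect_equal(mean(g$G[diff]), 0, tolerance = 0.02)
})

test_that("KGD equals VanRaden of the calls in the deep, complete limit", {
  f <- simulate_population_set(small_config(n_fam = 40, n_snps = 300,
                                            seed = 19))
  r <- simulate_gbs_reads(f, mean_depth = 1e4, missing_rate = 0)
  k <- kgd_grm(r)
  x <- naive_calls(r)
  poly <- attr(x, "p") > 0 & attr(x, "p") < 1
  v <- vanraden_grm(x[, poly, drop = FALSE])
  off <- upper.tri(k$G)
  expect_lt(max(abs(k$G[off] - v$G[off])), 1e-10)
  expect_lt(max(abs(diag(k$G) - diag(v$G))), 1e-8)  # 2^(1-d) correction ~ 0
})

test_that("KGD diagonal is unbiased at depth 2 while the naive diagonal inflates", {
  cfg <- sim_config(n_populations = 1, families_per_population = 200,
                    n_snps = 5000, mean_depth = 2, missing_rate = 0,
                    fst = 0, seed = 23)
  f <- simulate_population_set(cfg)
  r <- simulate_gbs_reads(f)
  k <- kgd_grm(r)
  truth <- vanraden_grm(f$genotypes + 0)     # deep-data reference, E[diag]=1+F
  expect_equal(mean(diag(k$G)), mean(diag(truth$G)), tolerance = 0.02)
  # uncorrected diagonal: centred call cross-product without the depth term
  x <- naive_calls(r)
  p <- attr(x, "p"); poly <- p > 0 & p < 1
  xc <- sweep(x[, poly], 2, 2 * p[poly]); xc[is.na(xc)] <- 0
  naive_diag <- rowSums(xc^2) / sum(2 * p[poly] * (1 - p[poly]))
  expect_gt(mean(naive_diag), mean(diag(truth$G)) + 0.3)
})

test_that("KGD off-diagonals are depth-invariant and recover half-sib pairs", {
  hs <- halfsib_genotypes(n_fam = 50, sibs_per_fam = 4, m = 4000, seed = 31)
  info <- data.frame(chrom = "chr1", pos = seq_len(4000) * 5L,
                     id = sprintf("s%05d", seq_len(4000)), ref = "A",
                     alt = "C", stringsAsFactors = FALSE)
  fset <- structure(list(
    genotypes = hs$kids, snp_info = info,
    config = sim_config(n_populations = 1, families_per_population = 200,
                        n_snps = 4000, seed = 1)),
    class = "founder_set")
  same <- outer(hs$family, hs$family, "==")
  for (dep in c(3, 8)) {
    r <- simulate_gbs_reads(fset, mean_depth = dep, missing_rate = 0.2,
                            seed = 40 + dep)
    k <- kgd_grm(r)
    sib <- same & upper.tri(k$G)
    # 0.02 absolute: Monte-Carlo error plus the small shrinkage from
    # estimating allele frequencies on the panel itself
    expect_lt(abs(mean(k$G[sib], na.rm = TRUE) - 0.25), 0.02)
  }
})

test_that("halving the SNP panel perturbs KGD entries only by sampling noise", {
  # needs true relatedness structure to correlate: a structured
  # multi-population panel gives the entries real between-pair variation
  f <- simulate_population_set(sim_config(n_populations = 3,
    families_per_population = 40, n_snps = 6000, fst = 0.2, seed = 47))
  r <- simulate_gbs_reads(f, mean_depth = 4, missing_rate = 0.1, seed = 48)
  idx <- seq_len(6000)
  k1 <- kgd_grm(forageGS:::subset_read_matrix(r, idx[idx %% 2 == 1]))
  k2 <- kgd_grm(forageGS:::subset_read_matrix(r, idx[idx %% 2 == 0]))
  off <- upper.tri(k1$G)
  expect_gt(cor(k1$G[off], k2$G[off], use = "complete.obs"), 0.9)
})

test_that("pairs with no shared SNPs are flagged, then zeroed on request", {
  ref <- rbind(c(2L, 3L, 0L, 0L), c(0L, 0L, 2L, 1L), c(1L, 2L, 2L, 0L))
  alt <- rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L), c(2L, 0L, 1L, 0L))
  r <- reads_from_counts(ref, alt)
  expect_warning(k <- kgd_grm(r), "no covered SNPs")
  expect_true(is.na(k$G[1, 2]))
  expect_warning(kc <- complete_grm(k), "replacing")
  expect_equal(kc$G[1, 2], 0)
})
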