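#!/usr/bin/env Rscript

# 01 — Simulate the synthetic study panel.
#
# Five breeding populations of maternal parents (counts proportional to the
# 102/104/117/110/84 layout, scaled to 154 families so the whole workflow
# runs in minutes), polycrossed half-sib families, GBS reads at mean depth
# 2.98 with 23% missing genotypes, and a two-location x three-replicate
# row-column trial for two nutritive traits on the sodium and NDF variance
# scales. Writes the VCF and the plot-level trial table that the later
# stages read back.

suppressPackageStartupMessages(library(forageGS))
dir.create("results", showWarnings = FALSE)

comp <- nutritive_trait_components()
vc_of <- function(ab) {
  r <- comp[comp$abbrev == ab, ]
  c(sigma2_g = r$sigma2_g, sigma2_gs = r$sigma2_gs,
    sigma2_b = 0.1 * r$sigma2_e, sigma2_r = 0.1 * r$sigma2_e,
    sigma2_c = 0.1 * r$sigma2_e, sigma2_e = r$sigma2_e)
}

cfg <- sim_config(
  n_populations = 5,
  families_per_population = c(30L, 31L, 35L, 33L, 25L),
  n_snps = 4000,
  variance_components = list(Na = vc_of("Na"), NDF = vc_of("NDF")),
  trait_means = c(Na = 0.4, NDF = 48),
  genetic_correlation = matrix(c(1, -0.3, -0.3, 1), 2),
  mean_depth = 2.98, missing_rate = 0.23, seed = 20190331)

founders <- simulate_population_set(cfg)
reads <- simulate_gbs_reads(founders)
trial <- simulate_trial(founders)

write_vcf_reads(reads, "results/panel_reads.vcf")
write_trial_table(trial, "results/trial.tsv")

d <- reads$ref + reads$alt
cat(sprintf("panel: %d families in %d populations, %d SNPs\n",
            nrow(founders$genotypes), nlevels(founders$population),
            ncol(founders$genotypes)))
cat(sprintf("reads: %.1f%% missing, mean nonzero depth %.2f\n",
            100 * mean(d == 0), mean(d[d > 0])))
cat(sprintf("trial: %d plots (%d locations x %d replicates)\n",
            nrow(trial), nlevels(trial$location),
            length(unique(trial$replicate))))
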