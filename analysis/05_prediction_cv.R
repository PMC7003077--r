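#!/usr/bin/env Rscript

# 05 — Stage two: genomic prediction and cross-validation.
#
# Two demonstrations, because predictive ability in this design is driven
# by two different things:
#
# (a) The generator panel from 01-03: maternal parents are unrelated
#     within populations and breeding values are centred per population.
#     There is then no relatedness signal for GBLUP to use, and held-out
#     GEBVs are dominated by a leave-one-out reflection: with family
#     BLUPs summing to ~0 within a population block of G, removing family
#     i makes its same-population training sum approximately -BLUP_i, so
#     predictions anti-correlate with the held-out values. Cross-validated
#     r is systematically negative — a real property of this regime, and
#     a caution against running GBLUP on panels with block structure but
#     no within-block relatedness.
#
# (b) A relatedness-structured panel (sib groups among the genotyped
#     parents, same sodium-scale variances), the regime that multi-
#     population breeding panels actually occupy. Here the three
#     prediction methods deliver similar, clearly positive predictive
#     ability, and the calibration slope of adjusted means on GEBVs sits
#     near 1.

suppressPackageStartupMessages(library(forageGS))

blups <- read.table("results/family_blups.tsv", header = TRUE, sep = "\t")
grm_vr <- read_grm("results/grm_vanraden.tsv", method = "vanraden")
grm_kgd <- read_grm("results/grm_kgd.tsv", method = "kgd")
reads <- read_vcf_reads("results/panel_reads.vcf")
dosages <- mean_impute(naive_calls(filter_snps(reads)))

## (a) generator panel: the no-relatedness regime
rows <- list()
preds_a <- list(gblup = gblup_predictor(grm_vr),
                `kgd-gblup` = gblup_predictor(grm_kgd),
                bayescpi = bayesc_predictor(dosages,
                                            bayes_spec(iterations = 2000,
                                                       burn_in = 500)))
for (m in names(preds_a)) {
  cv <- kfold_cv(blups, preds_a[[m]], k = 10, n_randomizations = 2,
                 seed = 11, value = "Na")
  rows[[m]] <- data.frame(panel = "generator", trait = "Na", method = m,
                          scheme = "kfold", mean_r = cv$mean, sd_r = cv$sd)
}

## (b) sib-structured panel: the relatedness-driven regime
make_sib_panel <- function(n_groups = 25, sibs = 10, m = 2000, seed = 77) {
  set.seed(seed)
  gam <- function(g) rbinom(length(g), 1, g / 2)
  X <- matrix(0L, n_groups * sibs, m)
  r <- 0L
  for (i in seq_len(n_groups)) {
    mo <- rbinom(m, 2, 0.3); fa <- rbinom(m, 2, 0.3)
    for (s in seq_len(sibs)) {
      r <- r + 1L
      X[r, ] <- gam(mo) + gam(fa)
    }
  }
  rownames(X) <- sprintf("K%04d", seq_len(nrow(X)))
  set.seed(seed + 50000)
  bv <- scale(as.numeric(X %*% rnorm(m)))[, 1] * sqrt(2 * 2.32e-3)
  n <- length(bv)
  y <- setNames(0.5 * bv + rnorm(n, 0, sqrt(2.32e-3 / 2)) +
                  rnorm(n, 0, sqrt(3.93e-3 / 6)), rownames(X))
  list(X = X, y = y)
}
sib <- make_sib_panel()
grm_sib <- vanraden_grm(sib$X + 0)
preds_b <- list(gblup = gblup_predictor(grm_sib),
                bayescpi = bayesc_predictor(sib$X + 0,
                                            bayes_spec(iterations = 2500,
                                                       burn_in = 800)))
slopes <- c()
for (m in names(preds_b)) {
  cv <- monte_carlo_cv(sib$y, preds_b[[m]], n_iterations = 15, seed = 19)
  rows[[paste0("sib.", m)]] <- data.frame(panel = "sib-structured",
                                          trait = "Na", method = m,
                                          scheme = "montecarlo",
                                          mean_r = cv$mean, sd_r = cv$sd)
}
# calibration slope on one 80/20 split of the sib panel
set.seed(23)
tr <- sample(length(sib$y), floor(0.8 * length(sib$y)))
gp <- gblup_predict(sib$y[tr], grm_sib, predict_ids = names(sib$y)[-tr])
cal <- prediction_bias(gp, sib$y[-tr], direction = "observed_on_gebv")

tab <- do.call(rbind, rows)
write.table(tab, "results/cv_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("cross-validated predictive ability:\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\ncalibration slope (adjusted means on GEBVs, sib panel): %.2f\n",
            cal))
cat("\nOn the generator panel predictive ability is negative (the\n")
cat("leave-one-out reflection described above); on the sib-structured\n")
cat("panel the methods agree at clearly positive values, as expected for\n")
cat("a polygenic trait where relationship capture does the work.\n")
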