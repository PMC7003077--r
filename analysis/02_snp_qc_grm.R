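#!/usr/bin/env Rscript

# 02 — SNP quality control and relationship matrices.
#
# Reads the simulated VCF back (exercising the AD/DP parser), summarizes
# per-SNP statistics, applies the GBS filter chain (call rate >= 50%,
# MAF > 0.05, mean depth > 1, HW disequilibrium > -0.05), and builds the
# two relationship matrices: VanRaden on mean-imputed naive calls and the
# depth-adjusted KGD matrix on raw allele reads.

suppressPackageStartupMessages(library(forageGS))

reads <- read_vcf_reads("results/panel_reads.vcf")
stats <- compute_snp_stats(reads)
filtered <- filter_snps(reads, stats)
report <- attr(filtered, "filter_report")

write.table(stats, "results/snp_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dosages <- mean_impute(naive_calls(filtered))
grm_vr <- vanraden_grm(dosages)
grm_kgd <- complete_grm(kgd_grm(filtered))
write_grm(grm_vr, "results/grm_vanraden.tsv")
write_grm(grm_kgd, "results/grm_kgd.tsv")

post <- compute_snp_stats(filtered)
cat(sprintf("filter chain: %d of %d SNPs retained (mean depth %.2f)\n",
            ncol(filtered$ref), ncol(reads$ref), mean(post$mean_depth)))
print(report, row.names = FALSE)
cat("\nVanRaden: "); print(grm_vr)
cat("KGD:      "); print(grm_kgd)
cat(sprintf("mean KGD diagonal %.3f (depth-corrected; the uncorrected\n",
            mean(diag(grm_kgd$G))))
cat("naive diagonal is inflated by heterozygote undercalling at low depth)\n")
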