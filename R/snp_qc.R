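#' Naive genotype calls from allele reads
#'
#' A genotype is called heterozygous iff both alleles were observed,
#' homozygous when only one allele was observed, and missing at depth zero.
#' At depth `d` a true heterozygote is miscalled homozygous with probability
#' `2^(1-d)`; this undercall model underlies both the Hardy-Weinberg
#' disequilibrium statistic and the KGD depth correction.
#'
#' @param reads A `read_matrix`.
#' @return Numeric matrix of alternate-allele dosages (0/1/2, `NA` when
#'   depth is zero) with the per-SNP allele frequency vector `p` (alternate
#'   frequency from the calls) as attribute.
#' @export
naive_calls <- function(reads) {
  stopifnot(inherits(reads, "read_matrix"))
  x <- matrix(NA_real_, nrow(reads$ref), ncol(reads$ref),
              dimnames = dimnames(reads$ref))
  x[reads$ref > 0 & reads$alt == 0] <- 0
  x[reads$ref > 0 & reads$alt > 0] <- 1
  x[reads$ref == 0 & reads$alt > 0] <- 2
  attr(x, "p") <- colMeans(x, na.rm = TRUE) / 2
  x
}

#' Per-SNP summary statistics from GBS reads
#'
#' Computes, from naive genotype calls, the minor allele frequency, call
#' rate, mean read depth over covered individuals, and the Hardy-Weinberg
#' disequilibrium statistic `D = f(hom-ref) - p_ref^2` (observed
#' homozygous-reference frequency minus its Hardy-Weinberg expectation).
#' Under low-coverage GBS, heterozygote undercalling inflates apparent
#' homozygosity, so `D > 0` is expected at honest biallelic sites; strongly
#' negative `D` (apparent heterozygote excess) flags artefacts such as
#' collapsed paralogs.
#'
#' @param reads A `read_matrix`.
#' @return `data.frame` with one row per SNP: `id`, `maf`, `call_rate`,
#'   `mean_depth`, `hw_diseq`, `n_called`. Sites with no calls get
#'   `maf = 0`, `hw_diseq = NA` and are flagged in `empty`.
#' @examples
#' f <- simulate_population_set(sim_config(n_populations = 1,
#'   families_per_population = 30, n_snps = 100, seed = 4))
#' r <- simulate_gbs_reads(f, mean_depth = 2, missing_rate = 0.1)
#' head(compute_snp_stats(r))
#' @export
compute_snp_stats <- function(reads) {
  stopifnot(inherits(reads, "read_matrix"))
  if (nrow(reads$ref) < 1) stop("need at least one individual")
  depth <- reads$ref + reads$alt
  x <- naive_calls(reads)
  n_called <- colSums(!is.na(x))
  p_alt <- ifelse(n_called > 0, colMeans(x, na.rm = TRUE) / 2, 0)
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0] <- 0
  call_rate <- n_called / nrow(x)
  mean_depth <- ifelse(n_called > 0,
                       colSums(depth) / pmax(n_called, 1L), 0)
  f_homref <- colMeans(x == 0, na.rm = TRUE)
  p_ref <- 1 - p_alt
  hw_diseq <- f_homref - p_ref^2
  hw_diseq[n_called == 0] <- NA_real_
  data.frame(id = reads$snp_info$id, maf = maf, call_rate = call_rate,
             mean_depth = mean_depth, hw_diseq = hw_diseq,
             n_called = n_called, empty = n_called == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter SNPs on call rate, MAF, mean depth and HW disequilibrium
#'
#' Retains exactly the SNPs with call rate `>= 1 - max_missing`, minor
#' allele frequency `> min_maf`, mean site depth `> min_mean_depth`
#' (strictly, as a per-site summary) and `hw_diseq > min_hwdiseq`. The
#' default thresholds are the standard low-coverage GBS chain: at most 50%
#' missing, MAF above 0.05, mean depth above 1, HW disequilibrium above
#' -0.05.
#'
#' @param reads A `read_matrix`.
#' @param stats Optional precomputed [compute_snp_stats()] output aligned
#'   with `reads`; recomputed when omitted.
#' @param max_missing,min_maf,min_mean_depth,min_hwdiseq Thresholds.
#' @return The surviving `read_matrix`, SNP order preserved, with a
#'   `filter_report` attribute: a `data.frame` of per-criterion removal
#'   counts (marginal; a SNP may fail several criteria) plus totals.
#' @export
filter_snps <- function(reads, stats = NULL, max_missing = 0.5,
                        min_maf = 0.05, min_mean_depth = 1,
                        min_hwdiseq = -0.05) {
  stopifnot(inherits(reads, "read_matrix"))
  if (is.null(stats)) stats <- compute_snp_stats(reads)
  if (nrow(stats) != ncol(reads$ref))
    stop("stats not aligned with reads (row count mismatch)")
  ok_call <- stats$call_rate >= 1 - max_missing
  ok_maf <- stats$maf > min_maf
  ok_dep <- stats$mean_depth > min_mean_depth
  ok_hw <- !is.na(stats$hw_diseq) & stats$hw_diseq > min_hwdiseq
  keep <- ok_call & ok_maf & ok_dep & ok_hw
  report <- data.frame(
    criterion = c("call_rate", "maf", "mean_depth", "hw_diseq", "total"),
    threshold = c(1 - max_missing, min_maf, min_mean_depth, min_hwdiseq, NA),
    n_removed = c(sum(!ok_call), sum(!ok_maf), sum(!ok_dep), sum(!ok_hw),
                  sum(!keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) warning("no SNPs survive the filter chain")
  out <- subset_read_matrix(reads, which(keep))
  attr(out, "filter_report") <- report
  out
}

subset_read_matrix <- function(reads, snp_idx, ind_idx = NULL) {
  if (is.null(ind_idx)) ind_idx <- seq_len(nrow(reads$ref))
  new_read_matrix(reads$ref[ind_idx, snp_idx, drop = FALSE],
                  reads$alt[ind_idx, snp_idx, drop = FALSE],
                  reads$snp_info[snp_idx, , drop = FALSE])
}

#' Dosage matrix from reads, and mean imputation
#'
#' `to_dosages()` converts naive calls to an analysis dosage matrix (still
#' holding `NA` at uncovered cells); `mean_impute()` replaces every missing
#' cell with the per-SNP observed mean, leaving observed cells untouched, so
#' per-SNP column means are unchanged.
#'
#' @param reads A `read_matrix`.
#' @return For both: numeric individuals x SNPs matrix with attribute `p`
#'   (per-SNP alternate allele frequency).
#' @export
to_dosages <- function(reads) naive_calls(reads)

#' @param calls Dosage matrix (individuals x SNPs) possibly holding `NA`.
#' @rdname to_dosages
#' @export
mean_impute <- function(calls) {
  stopifnot(is.matrix(calls))
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0))
    stop("all-missing SNP(s) at column(s) ",
         paste(head(which(n_obs == 0)), collapse = ", "),
         "; filter before imputing")
  mu <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(idx)) calls[idx] <- mu[idx[, 2]]
  attr(calls, "p") <- mu / 2
  calls
}
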