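#' Simulation configuration for a half-sib polycross panel
#'
#' Defines the study conditions for the synthetic panel: five advanced
#' breeding populations of maternal parents, a polycross producing one
#' half-sib family per parent, GBS genotyping at low depth, and a
#' two-location row-column trial with three replicates.
#'
#' @param n_populations Number of discrete breeding populations.
#' @param families_per_population Integer scalar or vector (one entry per
#'   population) of maternal-parent / half-sib family counts. The default
#'   (102, 104, 117, 110, 84) gives the 517-family panel evaluated by the
#'   default workflow.
#' @param n_snps Number of biallelic SNPs simulated.
#' @param maf_range Interval in (0, 0.5] from which target minor allele
#'   frequencies are drawn uniformly.
#' @param n_locations Number of trial locations (`s` in the family-mean
#'   heritability formula).
#' @param n_replicates Replicates per location (`b` in the same formula).
#' @param variance_components Named list, one entry per trait. Each entry is a
#'   named numeric vector with elements `sigma2_g` (family), `sigma2_gs`
#'   (family-by-location), `sigma2_b` (replicate), `sigma2_r` (row),
#'   `sigma2_c` (column) and `sigma2_e` (residual), all on the squared trait
#'   scale. Defaults to the sodium-like reference trait, see
#'   [nutritive_trait_components()].
#' @param trait_means Named numeric vector of grand means per trait (same
#'   names as `variance_components`); defaults to 0.
#' @param location_effects,population_effects Optional numeric vectors of
#'   fixed effects (recycled per trait); default small systematic shifts of
#'   one residual SD spread across levels.
#' @param genetic_correlation Optional trait-by-trait correlation matrix for
#'   family effects (QTL effects and family deviations share it). Identity by
#'   default.
#' @param n_qtl Number of causal markers per trait; default
#'   `min(200, n_snps)`.
#' @param effect_distribution `"normal"` (all QTL effects Gaussian) or
#'   `"mixture"` (point mass at zero with probability `pi_zero`).
#' @param pi_zero Proportion of zero-effect markers under
#'   `effect_distribution = "mixture"`.
#' @param mean_depth Mean of the nonzero read-depth distribution
#'   (zero-truncated Poisson), reads per genotype.
#' @param missing_rate Probability that a genotype receives zero reads.
#' @param fst Drift parameter of the Balding-Nichols perturbation that
#'   differentiates population allele frequencies from the shared ancestral
#'   frequencies.
#' @param seed Integer seed. One seed governs a hierarchical stream split per
#'   stage (founders / reads / trial), so adding SNPs does not perturb
#'   phenotypes.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_populations = 2, families_per_population = 20,
#'                   n_snps = 200, seed = 1)
#' @export
sim_config <- function(n_populations = 5,
                       families_per_population = c(102L, 104L, 117L, 110L, 84L),
                       n_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       n_locations = 2,
                       n_replicates = 3,
                       variance_components = list(
                         Na = c(sigma2_g = 2.32e-3, sigma2_gs = 0.25e-3,
                                sigma2_b = 0.4e-3, sigma2_r = 0.4e-3,
                                sigma2_c = 0.4e-3, sigma2_e = 3.93e-3)),
                       trait_means = NULL,
                       location_effects = NULL,
                       population_effects = NULL,
                       genetic_correlation = NULL,
                       n_qtl = NULL,
                       effect_distribution = c("normal", "mixture"),
                       pi_zero = 0.9,
                       mean_depth = 2.98,
                       missing_rate = 0.23,
                       fst = 0.05,
                       seed = 1L) {
  effect_distribution <- match.arg(effect_distribution)
  if (length(families_per_population) == 1L)
    families_per_population <- rep(families_per_population, n_populations)
  if (length(families_per_population) != n_populations)
    stop("families_per_population: length must be 1 or n_populations")
  if (any(families_per_population < 1))
    stop("families_per_population: every population needs at least one family")
  if (n_snps < 1) stop("n_snps: need at least one SNP")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range: must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate: must lie in [0, 1)")
  if (mean_depth <= 0) stop("mean_depth: must be positive")
  if (n_locations < 1) stop("n_locations: need at least one location")
  if (n_replicates < 1) stop("n_replicates: need at least one replicate")
  if (is.null(n_qtl)) n_qtl <- min(200L, n_snps)
  if (n_qtl < 1 || n_qtl > n_snps) stop("n_qtl: must lie in [1, n_snps]")
  if (pi_zero < 0 || pi_zero >= 1) stop("pi_zero: must lie in [0, 1)")
  comp_names <- c("sigma2_g", "sigma2_gs", "sigma2_b", "sigma2_r",
                  "sigma2_c", "sigma2_e")
  if (!is.list(variance_components) || is.null(names(variance_components)))
    stop("variance_components: must be a named list (one entry per trait)")
  for (tr in names(variance_components)) {
    vc <- variance_components[[tr]]
    if (!all(comp_names %in% names(vc)))
      stop("variance_components[['", tr, "']]: missing components ",
           paste(setdiff(comp_names, names(vc)), collapse = ", "))
    if (any(vc[comp_names] < 0))
      stop("variance_components[['", tr, "']]: all variances must be >= 0")
  }
  traits <- names(variance_components)
  if (is.null(trait_means)) trait_means <- setNames(rep(0, length(traits)), traits)
  if (!is.null(genetic_correlation)) {
    gc <- as.matrix(genetic_correlation)
    if (nrow(gc) != length(traits) || ncol(gc) != length(traits))
      stop("genetic_correlation: must be a square matrix over the traits")
  }
  if (!is.numeric(seed) || seed != round(seed)) stop("seed: must be an integer")
  structure(list(
    n_populations = as.integer(n_populations),
    families_per_population = as.integer(families_per_population),
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    n_locations = as.integer(n_locations),
    n_replicates = as.integer(n_replicates),
    variance_components = variance_components,
    trait_means = trait_means,
    location_effects = location_effects,
    population_effects = population_effects,
    genetic_correlation = genetic_correlation,
    n_qtl = as.integer(n_qtl),
    effect_distribution = effect_distribution,
    pi_zero = pi_zero,
    mean_depth = mean_depth,
    missing_rate = missing_rate,
    fst = fst,
    seed = as.integer(seed)),
    class = "sim_config")
}

# Hierarchical seed split: independent reproducible streams per stage so that
# e.g. enlarging the SNP panel leaves trial phenotypes untouched.
stage_seed <- function(seed, stage) {
  offs <- c(founders = 1L, reads = 2L, trial = 3L)
  as.integer((as.double(seed) * 48271 + offs[[stage]]) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  populations:", x$n_populations, "| families:",
      paste(x$families_per_population, collapse = "/"),
      "(total", sum(x$families_per_population), ")\n")
  cat("  SNPs:", x$n_snps, "| MAF in [", x$maf_range[1], ",", x$maf_range[2],
      "] | mean depth", x$mean_depth, "| missing", x$missing_rate, "\n")
  cat("  design:", x$n_locations, "location(s) x", x$n_replicates,
      "replicate(s); traits:", paste(names(x$variance_components),
                                     collapse = ", "), "\n")
  invisible(x)
}
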