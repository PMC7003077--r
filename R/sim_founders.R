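#' Simulate maternal-parent founder populations
#'
#' Draws ancestral allele frequencies from the configured MAF interval,
#' perturbs them per population with a Balding-Nichols drift model
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)` with drift `F = fst`), and samples
#' Hardy-Weinberg genotypes for one maternal parent per half-sib family.
#' Causal markers receive effects per trait; true breeding values are the
#' centred dosage-effect products, centred within population and scaled so
#' that the maternal half `0.5 * BV` carries half of the configured family
#' variance (the other half is the pollen-pool / Mendelian family deviation
#' drawn by [simulate_trial()]).
#'
#' @param config A [sim_config()].
#' @return An object of class `founder_set`: a list with `genotypes`
#'   (parents x SNPs dosage matrix, values 0/1/2), `population` (factor),
#'   `family` (identifiers, one per parent), `snp_info` (data frame with
#'   chrom, pos, id, ref, alt, ancestral frequency), `qtl` (per-trait list of
#'   marker indices and effects on the scaled BV) and `breeding_values`
#'   (parents x traits matrix).
#' @examples
#' f <- simulate_population_set(sim_config(n_populations = 1,
#'   families_per_population = 10, n_snps = 50, seed = 7))
#' dim(f$genotypes)
#' @export
simulate_population_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "founders"))
  m <- config$n_snps
  npop <- config$n_populations
  nfam <- config$families_per_population
  ntot <- sum(nfam)
  traits <- names(config$variance_components)

  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  # random orientation: the minor allele is ref or alt with equal probability
  p_anc <- ifelse(runif(m) < 0.5, maf, 1 - maf)

  fst <- config$fst
  pop_freq <- matrix(0, npop, m)
  for (k in seq_len(npop)) {
    if (fst > 0) {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      pk <- stats::rbeta(m, a, b)
      # keep sites segregating in every population
      pop_freq[k, ] <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
    } else {
      pop_freq[k, ] <- p_anc
    }
  }

  population <- factor(rep(paste0("Pop", seq_len(npop)), nfam),
                       levels = paste0("Pop", seq_len(npop)))
  family <- sprintf("F%03d", seq_len(ntot))
  geno <- matrix(0L, ntot, m, dimnames = list(family, NULL))
  row0 <- 0L
  for (k in seq_len(npop)) {
    idx <- row0 + seq_len(nfam[k])
    geno[idx, ] <- matrix(rbinom(nfam[k] * m, 2L, rep(pop_freq[k, ],
                                                      each = nfam[k])),
                          nfam[k], m)
    row0 <- row0 + nfam[k]
  }
  snp_id <- sprintf("chr%d:%d:A:C", 1L + (seq_len(m) - 1L) %% 7L,
                    1000L * seq_len(m))
  snp_info <- data.frame(
    chrom = paste0("chr", 1L + (seq_len(m) - 1L) %% 7L),
    pos = 1000L * seq_len(m), id = snp_id, ref = "A", alt = "C",
    p_anc = p_anc, stringsAsFactors = FALSE)
  colnames(geno) <- snp_id

  # QTL effects, optionally correlated across traits
  ntr <- length(traits)
  qtl_idx <- sort(sample.int(m, config$n_qtl))
  eff <- matrix(rnorm(config$n_qtl * ntr), config$n_qtl, ntr)
  if (!is.null(config$genetic_correlation)) {
    L <- chol(as.matrix(config$genetic_correlation))
    eff <- eff %*% L
  }
  if (config$effect_distribution == "mixture") {
    zero <- runif(config$n_qtl) < config$pi_zero
    if (all(zero)) zero[sample.int(config$n_qtl, 1L)] <- FALSE
    eff[zero, ] <- 0
  }
  colnames(eff) <- traits

  bv <- matrix(0, ntot, ntr, dimnames = list(family, traits))
  qtl <- vector("list", ntr)
  names(qtl) <- traits
  Xq <- geno[, qtl_idx, drop = FALSE]
  for (j in seq_len(ntr)) {
    raw <- as.numeric(Xq %*% eff[, j])
    raw <- raw - stats::ave(raw, population)      # centre per population
    s2g <- config$variance_components[[j]][["sigma2_g"]]
    v <- if (length(raw) > 1) stats::var(raw) else 0
    sc <- if (!is.na(v) && v > 0 && s2g > 0) sqrt(2 * s2g / v) else 0
    bv[, j] <- raw * sc
    qtl[[j]] <- list(index = qtl_idx, effect = eff[, j] * sc)
  }

  structure(list(genotypes = geno, population = population, family = family,
                 snp_info = snp_info, qtl = qtl, breeding_values = bv,
                 config = config),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("<founder_set>", nrow(x$genotypes), "maternal parents in",
      nlevels(x$population), "population(s),", ncol(x$genotypes), "SNPs,",
      ncol(x$breeding_values), "trait(s)\n")
  invisible(x)
}
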