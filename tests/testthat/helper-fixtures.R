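# Shared fixtures, built in code. Sizes are kept small: these exercise the
# statistical machinery, not the full 517-family study scale.

# Variance components used throughout: the sodium-like reference trait.
sodium_vc <- function(design = 0) {
  c(sigma2_g = 2.32e-3, sigma2_gs = 0.25e-3, sigma2_b = design,
    sigma2_r = design, sigma2_c = design, sigma2_e = 3.93e-3)
}

small_config <- function(n_fam = 60, n_pop = 1, n_snps = 300, seed = 101,
                         vc = sodium_vc(), mean_depth = 2.98,
                         missing_rate = 0.23, ...) {
  sim_config(n_populations = n_pop, families_per_population = n_fam,
             n_snps = n_snps, variance_components = list(Na = vc),
             mean_depth = mean_depth, missing_rate = missing_rate,
             seed = seed, ...)
}

# Read matrix built directly from a matrix of (ref, alt) count pairs.
reads_from_counts <- function(ref, alt) {
  info <- data.frame(chrom = "chr1", pos = seq_len(ncol(ref)) * 10L,
                     id = sprintf("s%03d", seq_len(ncol(ref))),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  rownames(ref) <- rownames(alt) <- sprintf("I%03d", seq_len(nrow(ref)))
  forageGS:::new_read_matrix(ref, alt, info)
}

# Explicit half-sib pedigree: mothers drawn from allele frequency p, each
# family's children get one maternal gamete plus a random-father gamete.
# Serves as the pedigree oracle for relationship estimates.
halfsib_genotypes <- function(n_fam, sibs_per_fam, m, p = 0.3, seed = 1) {
  set.seed(seed)
  gamete <- function(g) rbinom(length(g), 1, g / 2)
  mothers <- matrix(rbinom(n_fam * m, 2, p), n_fam, m)
  kids <- matrix(0L, n_fam * sibs_per_fam, m)
  fam <- integer(n_fam * sibs_per_fam)
  r <- 0L
  for (i in seq_len(n_fam)) {
    for (s in seq_len(sibs_per_fam)) {
      father <- rbinom(m, 2, p)
      r <- r + 1L
      kids[r, ] <- gamete(mothers[i, ]) + gamete(father)
      fam[r] <- i
    }
  }
  rownames(kids) <- sprintf("K%04d", seq_len(nrow(kids)))
  list(kids = kids, family = fam, p = rep(p, m))
}

# Balanced one-way expected-mean-squares ANOVA estimators (the closed-form
# REML oracle on balanced data).
ems_oneway <- function(y, fam) {
  fam <- factor(fam)
  nrep <- length(y) / nlevels(fam)
  a <- stats::anova(stats::lm(y ~ fam))
  ms_f <- a["fam", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
  c(sigma2_g = (ms_f - ms_e) / nrep, sigma2_e = ms_e)
}

# Family-mean panel with strong within-group relatedness: full-sib groups
# of genotyped parents, adjusted means y = 0.5*BV + family deviation +
# trial-mean noise on the sodium-like scale. This emulates the
# relatedness-driven prediction regime of a multi-population breeding
# panel, which the cross-validation schemes rely on.
fullsib_panel <- function(n_groups = 20, sibs = 16, m = 4000, seed = 1,
                          sigma2_g = 2.32e-3, sigma2_e = 3.93e-3) {
  set.seed(seed)
  gam <- function(g) rbinom(length(g), 1, g / 2)
  kids <- matrix(0L, n_groups * sibs, m)
  grp <- integer(n_groups * sibs)
  r <- 0L
  for (i in seq_len(n_groups)) {
    mo <- rbinom(m, 2, 0.3); fa <- rbinom(m, 2, 0.3)
    for (s in seq_len(sibs)) {
      r <- r + 1L
      kids[r, ] <- gam(mo) + gam(fa)
      grp[r] <- i
    }
  }
  rownames(kids) <- sprintf("K%04d", seq_len(nrow(kids)))
  set.seed(seed + 50000)   # effect draws decoupled from the genotype stream
  a <- rnorm(m)
  bv <- scale(as.numeric(kids %*% a))[, 1] * sqrt(2 * sigma2_g)
  n <- length(bv)
  y <- setNames(0.5 * bv + rnorm(n, 0, sqrt(sigma2_g / 2)) +
                  rnorm(n, 0, sqrt(sigma2_e / 6)), rownames(kids))
  list(X = kids, y = y, bv = bv, group = grp,
       populations = setNames(paste0("Pop", 1 + (grp - 1) %% 5),
                              rownames(kids)))
}

# Identity relationship matrix over the given identifiers.
identity_grm <- function(ids) {
  forageGS:::new_relationship_matrix(diag(length(ids)), ids, "identity",
                                     n_snps = NA_integer_)
}
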