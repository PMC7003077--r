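#' Simulate a multi-location row-column half-sib trial
#'
#' Builds a balanced design in which every half-sib family appears once per
#' replicate per location, families of each population blocked together and
#' laid out on a near-square row-column grid within each replicate block.
#' Plot values are
#' `grand mean + location + population + family + family-by-location +
#' replicate + row + column + residual`, each random term drawn with its
#' configured variance. The family effect is `0.5 * BV(mother) + d_i` with
#' `d_i ~ N(0, sigma2_g / 2)` (pollen pool plus Mendelian sampling), so the
#' family variance totals `sigma2_g` while maternal markers explain half of it.
#'
#' @param founders A [founder_set][simulate_population_set()].
#' @param config A [sim_config()]; defaults to the one stored in `founders`.
#' @param seed Integer seed; defaults to the trial-stage stream of the config.
#' @return A `data.frame` (trial table) with columns `family`, `population`,
#'   `location`, `replicate`, `row`, `column`, then one column per trait.
#'   Attributes `family_effects` (true family effects per trait, for
#'   simulation studies) and `trial_seed` are attached.
#' @examples
#' f <- simulate_population_set(sim_config(n_populations = 1,
#'   families_per_population = 8, n_snps = 40, seed = 3))
#' tt <- simulate_trial(f)
#' table(tt$location, tt$replicate)
#' @export
simulate_trial <- function(founders, config = founders$config, seed = NULL) {
  stopifnot(inherits(founders, "founder_set"), inherits(config, "sim_config"))
  if (is.null(seed)) seed <- stage_seed(config$seed, "trial")
  set.seed(seed)

  traits <- names(config$variance_components)
  nloc <- config$n_locations
  nrep <- config$n_replicates
  npop <- config$n_populations
  fam <- founders$family
  pop <- founders$population
  locs <- paste0("Loc", seq_len(nloc))

  # row-column layout per population block within a replicate
  layout <- lapply(split(seq_along(fam), pop), function(idx) {
    nf <- length(idx)
    nr <- ceiling(sqrt(nf))
    nc <- ceiling(nf / nr)
    if (nr * nc < nf) stop("row-column grid smaller than families per block")
    data.frame(idx = idx, row = rep(seq_len(nr), each = nc)[seq_len(nf)],
               column = rep(seq_len(nc), times = nr)[seq_len(nf)])
  })

  plots <- do.call(rbind, lapply(locs, function(lc) {
    do.call(rbind, lapply(seq_len(nrep), function(rp) {
      do.call(rbind, lapply(names(layout), function(pp) {
        ly <- layout[[pp]]
        # randomize family positions independently per replicate and location
        perm <- sample.int(nrow(ly))
        data.frame(family = fam[ly$idx], population = pp, location = lc,
                   replicate = rp, row = ly$row[perm], column = ly$column[perm],
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(plots) <- NULL
  plots$population <- factor(plots$population, levels = levels(pop))
  plots$location <- factor(plots$location, levels = locs)

  n <- nrow(plots)
  fidx <- match(plots$family, fam)
  lidx <- as.integer(plots$location)

  loc_fx <- config$location_effects
  pop_fx <- config$population_effects
  fam_eff_out <- list()

  # family deviations (pollen pool + Mendelian sampling) share the
  # configured trait correlation with the QTL-driven breeding values
  dev_mat <- matrix(rnorm(length(fam) * length(traits)), length(fam))
  if (!is.null(config$genetic_correlation))
    dev_mat <- dev_mat %*% chol(as.matrix(config$genetic_correlation))
  colnames(dev_mat) <- traits

  for (tr in traits) {
    vc <- config$variance_components[[tr]]
    mu <- config$trait_means[[tr]]
    if (is.null(mu) || is.na(mu)) mu <- 0
    sde <- sqrt(vc[["sigma2_e"]])
    lfx <- if (is.null(loc_fx)) seq(-0.5, 0.5, length.out = max(nloc, 2))[seq_len(nloc)] * sde
           else rep_len(loc_fx, nloc)
    pfx <- if (is.null(pop_fx)) seq(-0.25, 0.25, length.out = max(npop, 2))[seq_len(npop)] * sde
           else rep_len(pop_fx, npop)

    dev <- dev_mat[, tr] * sqrt(vc[["sigma2_g"]] / 2)
    fam_eff <- 0.5 * founders$breeding_values[, tr] + dev
    gl <- matrix(rnorm(length(fam) * nloc, 0, sqrt(vc[["sigma2_gs"]])),
                 length(fam), nloc)

    rep_key <- interaction(plots$location, plots$population, plots$replicate,
                           drop = TRUE)
    row_key <- interaction(rep_key, plots$row, drop = TRUE)
    col_key <- interaction(rep_key, plots$column, drop = TRUE)
    rep_eff <- rnorm(nlevels(rep_key), 0, sqrt(vc[["sigma2_b"]]))
    row_eff <- rnorm(nlevels(row_key), 0, sqrt(vc[["sigma2_r"]]))
    col_eff <- rnorm(nlevels(col_key), 0, sqrt(vc[["sigma2_c"]]))

    plots[[tr]] <- mu + lfx[lidx] + pfx[as.integer(plots$population)] +
      fam_eff[fidx] + gl[cbind(fidx, lidx)] +
      rep_eff[as.integer(rep_key)] + row_eff[as.integer(row_key)] +
      col_eff[as.integer(col_key)] + rnorm(n, 0, sde)

    fam_eff_out[[tr]] <- setNames(fam_eff, fam)
  }

  attr(plots, "family_effects") <- fam_eff_out
  attr(plots, "trial_seed") <- seed
  plots
}
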