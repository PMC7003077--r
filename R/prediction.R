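# Stage-two genomic prediction: GBLUP on a relationship matrix and
# BayesC-pi on marker dosages, operating on family adjusted means (BLUPs).

# Normalize the various accepted adjusted-mean inputs to data.frame(id, value).
as_blup_df <- function(blups, value = NULL) {
  if (is.numeric(blups) && !is.null(names(blups)))
    return(data.frame(id = names(blups), value = as.numeric(blups),
                      stringsAsFactors = FALSE))
  if (is.data.frame(blups)) {
    idcol <- intersect(c("id", "level", "family"), names(blups))[1]
    if (is.na(idcol)) stop("adjusted-mean table needs an id/level/family column")
    if (is.null(value)) {
      num <- setdiff(names(blups)[vapply(blups, is.numeric, TRUE)], idcol)
      if (length(num) != 1)
        stop("ambiguous value column; pass `value = <trait>`")
      value <- num
    }
    return(data.frame(id = as.character(blups[[idcol]]),
                      value = as.numeric(blups[[value]]),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported adjusted-mean input")
}

#' GBLUP prediction of genomic breeding values
#'
#' Fits `y = mu + g + e`, `g ~ N(0, sigma2_g G)`, to the training adjusted
#' means by exact REML (the variance ratio is profiled on the spectral
#' decomposition of the training block of `G`), then propagates GEBVs to
#' all requested identifiers through their relationship-matrix rows:
#' `g_hat = sigma2_g G[ids, train] V^{-1} (y - mu)`. An individual
#' unrelated to every training record therefore gets GEBV 0.
#'
#' @param train_blups Training adjusted means: named numeric vector or
#'   `data.frame` with an id column (`id`/`level`/`family`) and one value
#'   column.
#' @param grm A `relationship_matrix` covering training and prediction ids.
#' @param predict_ids Identifiers to predict; default all ids in `grm`.
#' @param value Value column name when `train_blups` has several.
#' @return `data.frame` (GEBV table): `id`, `gebv`, `method`; variance
#'   estimates are attached as attribute `varcomp`.
#' @export
gblup_predict <- function(train_blups, grm, predict_ids = NULL, value = NULL) {
  stopifnot(inherits(grm, "relationship_matrix"))
  tb <- as_blup_df(train_blups, value)
  grm <- complete_grm(grm)
  miss <- setdiff(tb$id, grm$ids)
  if (length(miss)) stop("training identifier(s) absent from G: ",
                         paste(head(miss), collapse = ", "))
  if (is.null(predict_ids)) predict_ids <- grm$ids
  miss <- setdiff(predict_ids, grm$ids)
  if (length(miss)) stop("prediction identifier(s) absent from G: ",
                         paste(head(miss), collapse = ", "))

  Gtt <- grm$G[tb$id, tb$id, drop = FALSE]
  y <- tb$value
  n <- length(y)
  eg <- eigen(Gtt, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  ys <- as.numeric(crossprod(U, y))
  xs <- as.numeric(crossprod(U, rep(1, n)))

  neg2ll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    sxx <- sum(w * xs^2)
    beta <- sum(w * xs * ys) / sxx
    rss <- sum(w * (ys - xs * beta)^2)
    s2e <- rss / (n - 1)
    (n - 1) * log(s2e) + sum(log(lam * d + 1)) + log(sxx)
  }
  opt <- optimize(neg2ll, c(-25, 25))
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  beta <- sum(w * xs * ys) / sum(w * xs^2)
  s2e <- sum(w * (ys - xs * beta)^2) / (n - 1)
  s2g <- lam * s2e

  # V^{-1} r in rotated coordinates (common sigma2_e factor cancels in g_hat)
  r <- y - beta
  vinv_r <- U %*% (w * as.numeric(crossprod(U, r)))
  ghat <- lam * as.numeric(grm$G[predict_ids, tb$id, drop = FALSE] %*% vinv_r)

  out <- data.frame(id = predict_ids, gebv = ghat,
                    method = paste0(grm$method, "-gblup"),
                    stringsAsFactors = FALSE)
  attr(out, "varcomp") <- c(sigma2_g = s2g, sigma2_e = s2e, lambda = lam,
                            mu = beta)
  out
}

#' Sampler settings for BayesC-pi
#'
#' Priors: marker effects are a point-mass mixture — zero with probability
#' `pi`, otherwise Gaussian with a shared variance carrying a scaled
#' inverse chi-squared prior; the residual variance has a scaled inverse
#' chi-squared prior; `pi` is uniform on (0, 1). Prior scales are set from
#' `r2`, the share of the phenotypic variance expected under the markers.
#'
#' @param iterations,burn_in,thin Gibbs chain length controls.
#' @param pi_init Starting proportion of zero-effect markers.
#' @param fix_pi Optional fixed value of `pi` (e.g. 0 forces all markers
#'   into the model, the ridge/GBLUP limit); `NULL` samples it.
#' @param nu_a,nu_e Prior degrees of freedom for the effect and residual
#'   variances.
#' @param r2 Prior expectation of the marker-explained variance share.
#' @return List of class `bayes_spec`.
#' @export
bayes_spec <- function(iterations = 10000L, burn_in = 2000L, thin = 10L,
                       pi_init = 0.5, fix_pi = NULL, nu_a = 4, nu_e = 4,
                       r2 = 0.5) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (!is.null(fix_pi) && (fix_pi < 0 || fix_pi >= 1))
    stop("fix_pi must lie in [0, 1)")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 pi_init = pi_init, fix_pi = fix_pi, nu_a = nu_a,
                 nu_e = nu_e, r2 = r2),
            class = "bayes_spec")
}

#' BayesC-pi genomic prediction
#'
#' Gibbs sampler over marker inclusion indicators, a shared effect
#' variance, the zero-effect proportion `pi` and the residual variance.
#' The GEBV of an individual is the posterior mean of its cumulative
#' marker effect `sum_k z_k alpha_k` over the post-burn-in chain.
#' Reproducible under `set.seed()` (the sampler draws from R's RNG).
#'
#' @param train_blups Training adjusted means (see [gblup_predict()]).
#' @param dosages Complete individuals x markers dosage matrix (mean
#'   imputed) with row names covering training and prediction ids.
#' @param predict_ids Identifiers to predict; default all rows of
#'   `dosages`.
#' @param spec A [bayes_spec()].
#' @param value Value column name when `train_blups` has several.
#' @return GEBV table `data.frame`: `id`, `gebv`, `sd` (posterior SD of
#'   the genetic value), `method`; posterior summaries (`pi`, variances,
#'   inclusion probabilities) attached as attribute `posterior`.
#' @export
bayes_c_pi_predict <- function(train_blups, dosages, predict_ids = NULL,
                               spec = bayes_spec(), value = NULL) {
  stopifnot(is.matrix(dosages), inherits(spec, "bayes_spec"))
  if (anyNA(dosages)) stop("dosages contain missing cells; mean-impute first")
  tb <- as_blup_df(train_blups, value)
  if (is.null(predict_ids)) predict_ids <- rownames(dosages)
  miss <- setdiff(c(tb$id, predict_ids), rownames(dosages))
  if (length(miss)) stop("identifier(s) absent from dosages: ",
                         paste(head(miss), collapse = ", "))
  Xc <- sweep(dosages, 2, colMeans(dosages))
  Xt <- Xc[tb$id, , drop = FALSE]
  Xp <- Xc[predict_ids, , drop = FALSE]
  y <- tb$value
  vary <- var(y)
  n <- length(y)
  sum_colvar <- sum(colSums(Xt^2)) / n
  pi0 <- if (!is.null(spec$fix_pi)) spec$fix_pi else spec$pi_init
  s_a <- spec$r2 * vary / max((1 - pi0) * sum_colvar, 1e-12) *
    (spec$nu_a - 2) / spec$nu_a
  s_e <- max((1 - spec$r2) * vary, 1e-12) * (spec$nu_e - 2) / spec$nu_e

  res <- bayesc_gibbs(y, Xt, Xp, spec$iterations, spec$burn_in, spec$thin,
                      spec$nu_a, s_a, spec$nu_e, s_e, spec$pi_init,
                      if (is.null(spec$fix_pi)) -1 else spec$fix_pi)

  out <- data.frame(id = predict_ids, gebv = res$gebv, sd = res$gebv_sd,
                    method = "bayescpi", stringsAsFactors = FALSE)
  attr(out, "posterior") <- list(pi = res$pi, sigma2_a = res$sigma2_a,
                                 sigma2_e = res$sigma2_e, mu = res$mu,
                                 inclusion_prob = res$pip,
                                 n_samples = res$n_samples)
  out
}

#' Prediction bias as a GEBV / adjusted-mean regression slope
#'
#' Two conventions exist. `"gebv_on_observed"` fits
#' `lm(gebv ~ observed)` and reads dispersion of the predictions against
#' the data (identical vectors give 1, doubled GEBVs give 2).
#' `"observed_on_gebv"` is the standard calibration check of genomic
#' evaluation: `lm(observed ~ gebv)` has expectation 1 for a correctly
#' shrunken (BLUP-type) predictor, so departures from 1 flag inflated or
#' deflated breeding values.
#'
#' @param gebv GEBV table (from [gblup_predict()] or
#'   [bayes_c_pi_predict()]) or named numeric vector.
#' @param observed Observed adjusted means (same accepted forms).
#' @param direction Which regression to fit (see above).
#' @return The slope (numeric scalar); `NA` with a warning when the
#'   regressor has zero variance.
#' @export
prediction_bias <- function(gebv, observed,
                            direction = c("gebv_on_observed",
                                          "observed_on_gebv")) {
  direction <- match.arg(direction)
  g <- if (is.data.frame(gebv))
    setNames(gebv$gebv, gebv$id) else gebv
  o <- as_blup_df(observed)
  common <- intersect(names(g), o$id)
  if (length(common) < 3) stop("need at least 3 paired values")
  x <- o$value[match(common, o$id)]
  gg <- unname(g[common])
  regressor <- if (direction == "gebv_on_observed") x else gg
  if (sd(regressor) == 0) {
    warning("regressor is constant; slope undefined")
    return(NA_real_)
  }
  if (direction == "gebv_on_observed")
    unname(coef(lm(gg ~ x))[2])
  else
    unname(coef(lm(x ~ gg))[2])
}
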