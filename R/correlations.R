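#' Genotypic correlation between two traits
#'
#' Estimates the family-level (genotypic) correlation from the
#' across-location trial model via the sum-trait variance identity:
#' the model is fitted to trait x, trait y and their sum, and
#' `Cov_g(x, y) = (sigma2_g(x+y) - sigma2_g(x) - sigma2_g(y)) / 2`,
#' `r_g = Cov_g / sqrt(sigma2_g(x) sigma2_g(y))`. On balanced data this is
#' identical to the MANOVA cross-products estimator; it stays well defined
#' under mild imbalance. Estimates with `|r_g| > 1` (possible because
#' components are estimated) are clamped with a warning.
#'
#' @param data Trial table holding both traits on the same plots.
#' @param trait_x,trait_y Trait column names.
#' @param terms Extra design terms, as in [fit_trial_model()].
#' @param ... Passed to [reml_fit()].
#' @return Object of class `genetic_correlation`: list with `r_g`,
#'   `cov_g`, the two family variances and the three fits' convergence.
#' @export
genotypic_correlation <- function(data, trait_x, trait_y,
                                  terms = c("rep"), ...) {
  stopifnot(all(c(trait_x, trait_y) %in% names(data)))
  ok <- complete.cases(data[, c(trait_x, trait_y)])
  data <- data[ok, , drop = FALSE]
  sum_col <- ".trait_sum"
  data[[sum_col]] <- data[[trait_x]] + data[[trait_y]]
  fx <- fit_trial_model(data, trait_x, model = "across", terms = terms, ...)
  fy <- fit_trial_model(data, trait_y, model = "across", terms = terms, ...)
  fs <- fit_trial_model(data, sum_col, model = "across", terms = terms, ...)
  vx <- as.numeric(vc(fx, "family"))
  vy <- as.numeric(vc(fy, "family"))
  vs <- as.numeric(vc(fs, "family"))
  cov_g <- (vs - vx - vy) / 2
  flagged <- FALSE
  if (vx <= 0 || vy <= 0) {
    warning("non-positive family variance; genotypic correlation undefined")
    r_g <- NA_real_
    flagged <- TRUE
  } else {
    r_g <- cov_g / sqrt(vx * vy)
    if (abs(r_g) > 1) {
      warning("estimated |r_g| > 1 (", format(r_g, digits = 3),
              "); clamped to the unit interval")
      r_g <- sign(r_g)
      flagged <- TRUE
    }
  }
  structure(list(trait_x = trait_x, trait_y = trait_y, r_g = r_g,
                 cov_g = cov_g, sigma2_g_x = vx, sigma2_g_y = vy,
                 flagged = flagged),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("<genetic_correlation> r_g(%s, %s) = %.3f (Cov_g = %.4g)\n",
              x$trait_x, x$trait_y, x$r_g, x$cov_g))
  invisible(x)
}

#' Phenotypic correlation matrix on family BLUPs
#'
#' Pearson correlations of per-family adjusted means (BLUPs) across traits.
#'
#' @param blups `data.frame` with a `level` (or `family`) identifier column
#'   and one numeric column per trait.
#' @return Symmetric correlation matrix with unit diagonal; entries against
#'   constant columns are `NA` with a warning.
#' @export
phenotypic_correlation <- function(blups) {
  idcol <- intersect(c("level", "family"), names(blups))[1]
  vals <- blups[, setdiff(names(blups), idcol), drop = FALSE]
  vals <- vals[, vapply(vals, is.numeric, TRUE), drop = FALSE]
  if (nrow(vals) < 3) stop("need at least 3 families")
  const <- vapply(vals, function(v) sd(v) == 0, TRUE)
  if (any(const))
    warning("constant trait column(s): ",
            paste(names(vals)[const], collapse = ", "),
            "; correlations flagged NA")
  suppressWarnings(cor(as.matrix(vals)))
}
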