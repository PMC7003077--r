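#' Family-mean repeatability / heritability from variance components
#'
#' Evaluates the family-mean formula
#' `h2 = sigma2_g / (sigma2_g + sigma2_gs / s + sigma2_e / (s b))`,
#' where `s` is the number of locations and `b` the number of replicates
#' per location. With the across-population family variance this is the
#' repeatability `R`; with the within-population additive variance it is
#' the narrow-sense family-mean heritability; with a marker-based family
#' variance it is the genomic heritability.
#'
#' @param sigma2_g Family variance.
#' @param sigma2_gs Family-by-location interaction variance.
#' @param sigma2_e Residual variance.
#' @param s Number of locations.
#' @param b Number of replicates per location.
#' @param kind Label: `"repeatability"`, `"narrow_sense"` or `"genomic"`.
#' @return Object of class `heritability_estimate`: list with `value`,
#'   `kind`, `s`, `b` and the components used.
#' @examples
#' # sodium-like components (x 1e-3): prints as 0.75
#' heritability_from_components(2.32e-3, 0.25e-3, 3.93e-3, s = 2, b = 3)
#' @export
heritability_from_components <- function(sigma2_g, sigma2_gs, sigma2_e,
                                         s, b,
                                         kind = c("repeatability",
                                                  "narrow_sense", "genomic")) {
  kind <- match.arg(kind)
  if (s < 1 || b < 1) stop("s and b must be >= 1")
  if (any(c(sigma2_g, sigma2_gs, sigma2_e) < 0))
    stop("variance components must be >= 0")
  denom <- sigma2_g + sigma2_gs / s + sigma2_e / (s * b)
  if (denom <= 0) stop("zero denominator: all components are zero")
  structure(list(value = sigma2_g / denom, kind = kind, s = s, b = b,
                 components = c(sigma2_g = sigma2_g, sigma2_gs = sigma2_gs,
                                sigma2_e = sigma2_e)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability_estimate> %s = %.2f (s = %d, b = %d)\n",
              x$kind, x$value, x$s, x$b))
  invisible(x)
}

#' Family-mean heritability from a fitted trial model
#'
#' Convenience wrapper reading `sigma2_g`, `sigma2_gs` (0 when the model
#' has no interaction term) and `sigma2_e` off an [reml_fit()] /
#' [fit_trial_model()] result.
#'
#' @param fit An `lmm_fit` with a `family` random term.
#' @param s,b Locations and replicates entering the family-mean formula.
#' @param kind Passed to [heritability_from_components()].
#' @return A `heritability_estimate`.
#' @export
heritability_from_fit <- function(fit, s, b, kind = "repeatability") {
  stopifnot(inherits(fit, "lmm_fit"))
  comps <- setNames(fit$components$estimate, fit$components$term)
  if (!"family" %in% names(comps)) stop("fit has no 'family' term")
  heritability_from_components(comps[["family"]],
                               if ("fam_loc" %in% names(comps))
                                 comps[["fam_loc"]] else 0,
                               comps[["residual"]], s = s, b = b, kind = kind)
}

#' Genomic heritability via a marker-based family covariance
#'
#' Refits the across-location trial model with the family random effect
#' distributed `N(0, G sigma2_g)` for a supplied genomic relationship
#' matrix `G` (the family-by-location term keeps an identity covariance),
#' then evaluates the family-mean formula on the resulting components.
#'
#' @param data Trial table.
#' @param grm `relationship_matrix` covering every family's maternal parent.
#' @param trait Response column.
#' @param terms Extra design terms, as in [fit_trial_model()].
#' @param ... Passed to [reml_fit()].
#' @return A `heritability_estimate` with the underlying fit attached as
#'   attribute `fit`.
#' @export
genomic_heritability <- function(data, grm, trait, terms = c("rep"), ...) {
  stopifnot(inherits(grm, "relationship_matrix"))
  data <- prepare_trial(data)
  fams <- levels(data$family)
  grm <- complete_grm(grm)
  grm <- grm_subset(grm, intersect(grm$ids, fams))
  miss <- setdiff(fams, grm$ids)
  if (length(miss))
    stop("relationship matrix lacks family identifier(s): ",
         paste(head(miss), collapse = ", "))
  fit <- fit_trial_model(data, trait, model = "across", grm = grm,
                         terms = terms, ...)
  s <- nlevels(data$location)
  b <- nlevels(data$replicate)
  out <- heritability_from_fit(fit, s = s, b = b, kind = "genomic")
  attr(out, "fit") <- fit
  out
}

#' Reference variance components for foliar nutritive traits
#'
#' Across-location family (`sigma2_g`), family-by-location (`sigma2_gs`)
#' and residual (`sigma2_e`) variance components, family-mean repeatability
#' and genomic heritability for 18 foliar nutritive traits of perennial
#' ryegrass evaluated as 517 half-sib families in a two-location,
#' three-replicate New Zealand trial series. Composition traits are on a
#' percent-of-dry-matter scale (squared for the variances; entries flagged
#' `scaled_1e3` are on a 1e-3 scale), Mn in mg/kg, metabolisable energy in
#' MJ/kg DM, tetany ratio dimensionless. These components parameterize the
#' default simulations and the desk checks of the family-mean heritability
#' formula.
#'
#' @return `data.frame` with columns `trait`, `abbrev`, `sigma2_g`,
#'   `sigma2_gs`, `sigma2_e`, `repeatability`, `h2_genomic`.
#' @examples
#' comp <- nutritive_trait_components()
#' na <- comp[comp$abbrev == "Na", ]
#' heritability_from_components(na$sigma2_g, na$sigma2_gs, na$sigma2_e,
#'                              s = 2, b = 3)
#' @export
nutritive_trait_components <- function() {
  sc <- 1e-3
  rows <- list(
    list("Acid detergent fiber",        "ADF",       0.16,      0.083,     1.11,      0.42, 0.32),
    list("Neutral detergent fiber",     "NDF",       0.50,      0.16,      1.36,      0.62, 0.48),
    list("Digestible organic matter",   "DOMD",      0.41,      0.22,      2.49,      0.44, 0.35),
    list("Crude fat",                   "CFAT",      4.99 * sc, 9.38 * sc, 30.0 * sc, 0.34, 0.29),
    list("Metabolisable energy",        "ME",        0.01,      0.005,     0.06,      0.45, 0.36),
    list("Crude protein",               "CP",        0.15,      0.148,     1.64,      0.31, 0.27),
    list("Calcium",                     "Ca",        0.57 * sc, 0.17 * sc, 1.48 * sc, 0.63, 0.60),
    list("Potassium",                   "K",         10.0 * sc, 5.19 * sc, 48.0 * sc, 0.49, 0.46),
    list("Magnesium",                   "Mg",        0.11 * sc, 0.03 * sc, 0.25 * sc, 0.65, 0.62),
    list("Manganese",                   "Mn",        64.6,      22.1,      240.5,     0.56, 0.55),
    list("Sodium",                      "Na",        2.32 * sc, 0.25 * sc, 3.93 * sc, 0.75, 0.74),
    list("Phosphorus",                  "P",         0.04 * sc, 0.04 * sc, 0.58 * sc, 0.26, 0.22),
    list("Sulfur",                      "S",         0.33 * sc, 0.15 * sc, 1.04 * sc, 0.57, 0.53),
    list("Nitrogen",                    "N",         3.08 * sc, 3.0 * sc,  40.0 * sc, 0.26, 0.22),
    list("Tetany ratio",                "Tetany",    0.01,      0.005,     0.04,      0.61, 0.63),
    list("Total water sol. carbs",      "TotalWSC",  51.7,      51.6,      325.2,     0.39, 0.31),
    list("Low MW carbohydrates",        "LMWWSC",    19.6,      19.3,      105.1,     0.42, 0.20),
    list("High MW carbohydrates",       "HMWWSC",    13.7,      11.9,      141.3,     0.32, 0.34))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(trait = r[[1]], abbrev = r[[2]], sigma2_g = r[[3]],
               sigma2_gs = r[[4]], sigma2_e = r[[5]], repeatability = r[[6]],
               h2_genomic = r[[7]], stringsAsFactors = FALSE)))
  out
}
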