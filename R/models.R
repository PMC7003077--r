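#' Derive nested design factors for the trial mixed models
#'
#' Adds the interaction columns the three standard models need:
#' `fam_loc` (family x location), `rep_id` (replicate within location x
#' population), `row_id` and `col_id` (row / column within replicate block).
#' Location collapses out of the nesting when the table holds a single
#' location.
#'
#' @param data Trial table.
#' @return The table with the derived factor columns appended.
#' @export
prepare_trial <- function(data) {
  req <- c("family", "population", "location", "replicate", "row", "column")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (col in req) data[[col]] <- factor(data[[col]])
  data$fam_loc <- interaction(data$family, data$location, drop = TRUE)
  data$rep_id <- interaction(data$location, data$population, data$replicate,
                             drop = TRUE)
  data$row_id <- interaction(data$rep_id, data$row, drop = TRUE)
  data$col_id <- interaction(data$rep_id, data$column, drop = TRUE)
  data
}

#' Fit the standard trial models
#'
#' Three conventional analyses of a multi-location half-sib row-column
#' trial: `"within_location"` (family variance in one location; fixed
#' population, random family / replicate / row / column), `"across"`
#' (family and family-by-location variance pooling all populations; fixed
#' location and population) and `"within_population"` (family and
#' family-by-location variance inside one population; fixed location — the
#' population term drops as it is constant). The family term takes an
#' optional relationship matrix, turning the across-location analysis into
#' the genomic (marker-based) variance model.
#'
#' @param data Trial table (passed through [prepare_trial()]).
#' @param trait Response column name.
#' @param model One of `"across"`, `"within_location"`,
#'   `"within_population"`.
#' @param grm Optional `relationship_matrix` for the family term, keyed by
#'   family identifiers.
#' @param terms Random design terms to include besides the family effect.
#' @param location,population Level selecting the subset for the
#'   within-location / within-population models.
#' @param ... Passed to [reml_fit()].
#' @return An `lmm_fit`.
#' @export
fit_trial_model <- function(data, trait,
                            model = c("across", "within_location",
                                      "within_population"),
                            grm = NULL,
                            terms = c("rep", "row", "col"),
                            location = NULL, population = NULL, ...) {
  model <- match.arg(model)
  data <- prepare_trial(data)
  fixed <- character()
  if (model == "within_location") {
    if (is.null(location)) location <- levels(data$location)[1]
    data <- droplevels(data[data$location == location, , drop = FALSE])
    fixed <- "population"
    random <- list(family = list(cov = grm))
  } else if (model == "within_population") {
    if (is.null(population)) population <- levels(data$population)[1]
    data <- droplevels(data[data$population == population, , drop = FALSE])
    fixed <- "location"
    random <- list(family = list(cov = grm), fam_loc = list())
  } else {
    fixed <- c("location", "population")
    random <- list(family = list(cov = grm), fam_loc = list())
  }
  if (nlevels(data$location) < 2) random$fam_loc <- NULL
  if ("rep" %in% terms) random$rep_id <- list()
  if ("row" %in% terms) random$row_id <- list()
  if ("col" %in% terms) random$col_id <- list()
  # recompute nesting on the possibly subset data
  data$fam_loc <- interaction(data$family, data$location, drop = TRUE)
  reml_fit(data, trait, fixed = fixed, random = random, ...)
}
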