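# The four evaluation schemes: predictive ability as the Pearson
# correlation between held-out adjusted means and GEBVs.

#' Predictor constructors for cross-validation
#'
#' A predictor couples a genomic prediction method to its marker data and
#' exposes one closure: `fit_predict(train, predict_ids)` taking a training
#' `data.frame(id, value)` and returning named GEBVs for `predict_ids`.
#'
#' @param grm A `relationship_matrix` (GBLUP / KGD-GBLUP depending on its
#'   method tag).
#' @return A `gs_predictor`.
#' @export
gblup_predictor <- function(grm) {
  grm <- complete_grm(grm)
  structure(list(
    label = paste0(grm$method, "-gblup"),
    fit_predict = function(train, predict_ids) {
      g <- gblup_predict(train, grm, predict_ids)
      setNames(g$gebv, g$id)
    }), class = "gs_predictor")
}

#' @param dosages Complete dosage matrix for [bayes_c_pi_predict()].
#' @param spec A [bayes_spec()].
#' @rdname gblup_predictor
#' @export
bayesc_predictor <- function(dosages, spec = bayes_spec()) {
  structure(list(
    label = "bayescpi",
    fit_predict = function(train, predict_ids) {
      g <- bayes_c_pi_predict(train, dosages, predict_ids, spec)
      setNames(g$gebv, g$id)
    }), class = "gs_predictor")
}

new_cv_report <- function(scheme, method, iterations, seed,
                          partitions = NULL, extra = list()) {
  out <- c(list(scheme = scheme, method = method, iterations = iterations,
                mean = mean(iterations$r, na.rm = TRUE),
                sd = sd(iterations$r, na.rm = TRUE),
                seed = seed, partitions = partitions), extra)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | %s | %d iteration(s): mean r = %.3f (SD %.3f)\n",
              x$scheme, x$method, nrow(x$iterations), x$mean, x$sd))
  invisible(x)
}

#' k-fold cross-validated predictive ability
#'
#' Per randomization, families are partitioned into `k` disjoint folds
#' covering the whole set; the model is trained on `k - 1` folds and
#' predictions for the held-out fold are pooled, giving one correlation
#' (and one bias slope) per randomization. The reported predictive ability
#' is the mean over randomizations.
#'
#' @param blups Family adjusted means (named vector or `data.frame`).
#' @param predictor A [gs_predictor][gblup_predictor()].
#' @param k Number of folds.
#' @param n_randomizations Complete re-partitions of the data.
#' @param seed Integer seed (governs all partitioning).
#' @param value Value column when `blups` has several.
#' @return A `cv_report`: per-randomization `r` and `slope`, their mean
#'   and SD, and the partition log.
#' @export
kfold_cv <- function(blups, predictor, k = 10, n_randomizations = 5,
                     seed = 1, value = NULL) {
  tb <- as_blup_df(blups, value)
  n <- nrow(tb)
  if (k > n) stop("k exceeds the number of families")
  if (k < 2) stop("k must be at least 2")
  set.seed(as.integer(seed))
  parts <- vector("list", n_randomizations)
  res <- data.frame(iteration = seq_len(n_randomizations), r = NA_real_,
                    slope = NA_real_)
  for (rz in seq_len(n_randomizations)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    parts[[rz]] <- setNames(fold, tb$id)
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      g <- predictor$fit_predict(tb[-test, , drop = FALSE], tb$id[test])
      pred[test] <- g[tb$id[test]]
    }
    res$r[rz] <- cor(pred, tb$value)
    res$slope[rz] <- unname(coef(lm(pred ~ tb$value))[2])
  }
  new_cv_report("kfold", predictor$label, res, seed, parts)
}

#' Monte-Carlo (repeated random split) cross-validation
#'
#' Independent random train/test splits; one correlation per iteration on
#' the held-out fraction.
#'
#' @inheritParams kfold_cv
#' @param train_fraction Fraction of families used for training.
#' @param n_iterations Number of random splits.
#' @return A `cv_report`.
#' @export
monte_carlo_cv <- function(blups, predictor, train_fraction = 0.8,
                           n_iterations = 500, seed = 1, value = NULL) {
  tb <- as_blup_df(blups, value)
  n <- nrow(tb)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  n_train <- floor(n * train_fraction)
  if (n - n_train < 3) stop("degenerate test set (< 3 families)")
  set.seed(as.integer(seed))
  res <- data.frame(iteration = seq_len(n_iterations), r = NA_real_,
                    slope = NA_real_)
  for (it in seq_len(n_iterations)) {
    tr <- sample.int(n, n_train)
    g <- predictor$fit_predict(tb[tr, , drop = FALSE], tb$id[-tr])
    obs <- tb$value[-tr]
    res$r[it] <- cor(g[tb$id[-tr]], obs)
    res$slope[it] <- unname(coef(lm(g[tb$id[-tr]] ~ obs))[2])
  }
  new_cv_report("montecarlo", predictor$label, res, seed)
}

#' Within-population cross-validation from a composite training set
#'
#' Per iteration, `floor(n_p / 2)` families are drawn from every
#' population so each is represented equally in the training set; the
#' model trained on that union predicts the held-out half of each focal
#' population, giving one correlation per population per iteration.
#'
#' @inheritParams kfold_cv
#' @param populations Named character/factor vector mapping family id to
#'   population, or a `data.frame` with `id`/`family` and `population`.
#' @param n_iterations Iterations.
#' @return A `cv_report` whose `iterations` table is long
#'   (iteration, population, r) and which carries a per-population summary
#'   in `$by_population`.
#' @export
within_population_cv <- function(blups, populations, predictor,
                                 n_iterations = 500, seed = 1, value = NULL) {
  tb <- as_blup_df(blups, value)
  if (is.data.frame(populations)) {
    idcol <- intersect(c("id", "level", "family"), names(populations))[1]
    populations <- setNames(as.character(populations$population),
                            populations[[idcol]])
  }
  miss <- setdiff(tb$id, names(populations))
  if (length(miss)) stop("population label missing for: ",
                         paste(head(miss), collapse = ", "))
  pop <- factor(populations[tb$id])
  if (any(table(pop) < 2)) stop("every population needs >= 2 families")
  set.seed(as.integer(seed))
  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    tr_idx <- unlist(lapply(levels(pop), function(pp) {
      idx <- which(pop == pp)
      sample(idx, floor(length(idx) / 2))
    }), use.names = FALSE)
    g <- predictor$fit_predict(tb[tr_idx, , drop = FALSE], tb$id[-tr_idx])
    held <- setdiff(seq_len(nrow(tb)), tr_idx)
    rows[[it]] <- do.call(rbind, lapply(levels(pop), function(pp) {
      te <- held[pop[held] == pp]
      data.frame(iteration = it, population = pp,
                 r = if (length(te) >= 3)
                   cor(g[tb$id[te]], tb$value[te]) else NA_real_)
    }))
  }
  iterations <- do.call(rbind, rows)
  by_pop <- aggregate(r ~ population, iterations, mean)
  by_pop$sd <- aggregate(r ~ population, iterations, sd)$r
  new_cv_report("within_population", predictor$label, iterations,
                seed, extra = list(by_population = by_pop))
}

#' Marker-density ladder
#'
#' For each marker fraction, a uniform random subset of SNPs is drawn, a
#' VanRaden relationship matrix rebuilt on the (mean-imputed) subset, and
#' Monte-Carlo cross-validation run with GBLUP; the result traces
#' predictive ability against marker number.
#'
#' @param blups Family adjusted means.
#' @param reads A `read_matrix` (naive-called and mean-imputed per subset)
#'   or a complete dosage matrix.
#' @param fractions Marker fractions in (0, 1]; the default ten-step
#'   ladder spans 100% down to 0.1%.
#' @param train_fraction,n_iterations,seed Passed to [monte_carlo_cv()].
#' @param value Value column when `blups` has several.
#' @return A `data.frame` ladder summary (fraction, n_markers, mean_r,
#'   sd_r) with the per-fraction `cv_report`s attached as attribute
#'   `reports`.
#' @export
marker_density_ladder <- function(blups, reads,
                                  fractions = c(1, 0.5, 0.25, 0.1, 0.05,
                                                0.02, 0.01, 0.005, 0.002,
                                                0.001),
                                  train_fraction = 0.8, n_iterations = 500,
                                  seed = 1, value = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (inherits(reads, "read_matrix")) {
    dos_full <- naive_calls(reads)
  } else {
    stopifnot(is.matrix(reads))
    dos_full <- reads
  }
  m <- ncol(dos_full)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, length(fractions))
  reports <- vector("list", length(fractions))
  rows <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    n_mark <- round(m * fractions[i])
    if (n_mark < 1) stop("fraction ", fractions[i], " yields 0 markers")
    idx <- sort(sample.int(m, n_mark))
    dos <- dos_full[, idx, drop = FALSE]
    observed <- colSums(!is.na(dos)) > 0
    dos <- mean_impute(dos[, observed, drop = FALSE])
    grm <- vanraden_grm(dos)
    rep_i <- monte_carlo_cv(blups, gblup_predictor(grm),
                            train_fraction = train_fraction,
                            n_iterations = n_iterations,
                            seed = sub_seeds[i], value = value)
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(fraction = fractions[i], n_markers = n_mark,
                            mean_r = rep_i$mean, sd_r = rep_i$sd)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
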