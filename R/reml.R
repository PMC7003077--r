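#' Multi-component REML for half-sib trial models
#'
#' Fits `y = X b + sum_k Z_k u_k + e` with `u_k ~ N(0, sigma2_k A_k)`
#' (`A_k = I` or a supplied relationship matrix) and `e ~ N(0, sigma2_e I)`
#' by restricted maximum likelihood. Updates are average-information (AI)
#' steps with step-halving, falling back to an EM update whenever an AI
#' proposal is non-finite, leaves the parameter space, or decreases the
#' restricted likelihood. Components are truncated at the boundary
#' `1e-10 * var(y)`. Convergence is declared when the largest relative
#' component change falls below `tol` (default `1e-8`).
#'
#' @param data Trial table (`data.frame`), one row per plot.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect factor columns (an
#'   intercept is always included). Factors with fewer than two observed
#'   levels are dropped with a message; any remaining rank deficiency is an
#'   error naming the offending columns.
#' @param random Named list of random terms. Names are grouping-factor
#'   columns of `data`; each element is either an empty `list()` (identity
#'   covariance) or `list(cov = <relationship_matrix or matrix>)` whose row
#'   names cover all levels of the factor.
#' @param maxit,tol Iteration cap and relative convergence tolerance.
#' @param verbose Print the component trace while iterating.
#' @return An object of class `lmm_fit` with elements `components`
#'   (`data.frame`: term, estimate, SE), `loglik` (REML log-likelihood),
#'   `beta` (fixed effects), `blups` (named list of per-level BLUPs),
#'   `converged`, `iterations`, `trace` and bookkeeping needed for
#'   likelihood-ratio refits.
#' @examples
#' f <- simulate_population_set(sim_config(n_populations = 1,
#'   families_per_population = 25, n_snps = 100, seed = 5))
#' tt <- simulate_trial(f)
#' fit <- reml_fit(tt, "Na", fixed = "location",
#'                 random = list(family = list()))
#' fit$components
#' @export
reml_fit <- function(data, response, fixed = character(), random,
                     maxit = 200L, tol = 1e-8, verbose = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- data[[response]]
  if (anyNA(y)) {
    keep <- !is.na(y)
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  if (length(unique(y)) < 2) return(degenerate_fit(data, response, fixed,
                                                   random, y))
  vary <- var(y)
  bound <- 1e-10 * vary

  X <- build_fixed_design(data, fixed)
  p <- ncol(X)

  terms <- names(random)
  if (is.null(terms) || any(terms == ""))
    stop("random terms must be a named list")
  K <- length(terms)
  Zs <- As <- Gs <- vector("list", K)
  qk <- integer(K)
  for (k in seq_len(K)) {
    col <- terms[k]
    if (!col %in% names(data)) stop("random term column not found: ", col)
    f <- factor(data[[col]])
    Z <- model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    A <- random[[k]]$cov
    if (!is.null(A)) {
      if (inherits(A, "relationship_matrix")) A <- A$G
      miss <- setdiff(levels(f), rownames(A))
      if (length(miss))
        stop("covariance for term '", col, "' lacks level(s): ",
             paste(head(miss), collapse = ", "))
      A <- A[levels(f), levels(f), drop = FALSE]
      if (anyNA(A)) stop("covariance for term '", col, "' holds NA entries; ",
                         "see complete_grm()")
      Gs[[k]] <- Z %*% A %*% t(Z)
    } else {
      Gs[[k]] <- tcrossprod(Z)
    }
    Zs[[k]] <- Z
    if (!is.null(A)) As[[k]] <- A   # NULL assignment would shrink the list
    qk[k] <- nlevels(f)
  }

  s2 <- rep(vary / (K + 1), K + 1)   # components, residual last
  trace <- matrix(NA_real_, 0, K + 1,
                  dimnames = list(NULL, c(terms, "residual")))
  ll_old <- -Inf
  converged <- FALSE
  state <- NULL

  for (it in seq_len(maxit)) {
    state <- reml_state(y, X, Gs, s2)
    ll <- state$loglik
    score <- numeric(K + 1)
    Fmat <- matrix(0, n, K + 1)
    for (k in seq_len(K)) {
      Fmat[, k] <- Gs[[k]] %*% state$Py
      score[k] <- -0.5 * (sum(state$P * Gs[[k]]) -
                            crossprod(state$Py, Fmat[, k]))
    }
    Fmat[, K + 1] <- state$Py
    score[K + 1] <- -0.5 * (sum(diag(state$P)) - crossprod(state$Py))
    AI <- 0.5 * crossprod(Fmat, state$P %*% Fmat)

    # active set: components parked at the boundary whose gradient points
    # outward stay pinned; the AI step updates the free components only
    pinned <- (s2 <= bound * 1.001) & (score < 0)
    free <- which(!pinned)
    s2_new <- NULL
    if (length(free)) {
      step <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        for (half in 0:4) {                   # step-halving on AI proposals
          cand <- s2
          cand[pinned] <- bound
          # negative proposals truncate to the boundary rather than
          # rejecting the whole step (components may legitimately vanish)
          cand[free] <- pmax(s2[free] + step / 2^half, bound)
          if (all(is.finite(cand))) {
            ll_cand <- reml_loglik_only(y, X, Gs, cand)
            if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) {
              s2_new <- cand
              break
            }
          }
        }
      }
    }
    if (is.null(s2_new)) {                      # EM fallback
      s2_new <- s2
      for (k in seq_len(K)) {
        yPGPy <- as.numeric(crossprod(state$Py, Fmat[, k]))
        trPG <- sum(state$P * Gs[[k]])
        s2_new[k] <- s2[k] + s2[k]^2 * (yPGPy - trPG) / qk[k]
      }
      s2_new[K + 1] <- s2[K + 1] + s2[K + 1]^2 *
        (as.numeric(crossprod(state$Py)) - sum(diag(state$P))) / n
      s2_new <- pmax(s2_new, bound)
    }

    trace <- rbind(trace, s2_new)
    rel <- max(abs(s2_new - s2)) / max(s2_new, bound)
    if (verbose)
      cat(sprintf("iter %3d  logLik %.6f  rel %.2e\n", it, ll, rel))
    s2 <- s2_new
    ll_old <- ll
    if (rel < tol) { converged <- TRUE; break }
  }

  state <- reml_state(y, X, Gs, s2)
  if (!converged) {
    cond <- structure(
      class = c("reml_convergence_error", "error", "condition"),
      list(message = paste0("REML did not converge in ", maxit,
                            " iterations for response '", response, "'"),
           call = sys.call(-1), trace = trace))
    stop(cond)
  }

  # asymptotic SEs from the inverse average-information matrix
  Fmat <- matrix(0, n, K + 1)
  for (k in seq_len(K)) Fmat[, k] <- Gs[[k]] %*% state$Py
  Fmat[, K + 1] <- state$Py
  AI <- 0.5 * crossprod(Fmat, state$P %*% Fmat)
  se <- rep(NA_real_, K + 1)
  Vi <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(Vi)) se <- sqrt(pmax(diag(Vi), 0))

  blups <- vector("list", K)
  names(blups) <- terms
  for (k in seq_len(K)) {
    u <- s2[k] * crossprod(Zs[[k]], state$Py)
    if (!is.null(As[[k]])) u <- As[[k]] %*% u
    blups[[k]] <- setNames(as.numeric(u), colnames(Zs[[k]]))
  }
  beta <- setNames(as.numeric(state$beta), colnames(X))

  structure(list(
    components = data.frame(term = c(terms, "residual"), estimate = s2,
                            se = se, stringsAsFactors = FALSE),
    loglik = state$loglik, beta = beta, blups = blups,
    converged = converged, iterations = nrow(trace), trace = trace,
    n = n, vary = vary,
    model = list(data = data, response = response, fixed = fixed,
                 random = random, maxit = maxit, tol = tol)),
    class = "lmm_fit")
}

# One REML evaluation: V, P, Py, beta, restricted log-likelihood.
reml_state <- function(y, X, Gs, s2) {
  n <- length(y)
  K <- length(Gs)
  V <- diag(s2[K + 1], n)
  for (k in seq_len(K)) V <- V + s2[k] * Gs[[k]]
  cv <- chol(V)
  Vinv <- chol2inv(cv)
  W <- Vinv %*% X
  XtVX <- crossprod(X, W)
  cx <- chol(XtVX)
  B <- chol2inv(cx)
  P <- Vinv - W %*% B %*% t(W)
  Py <- P %*% y
  beta <- B %*% crossprod(W, y)
  ll <- -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
                  as.numeric(crossprod(y, Py)) +
                  (n - ncol(X)) * log(2 * pi))
  list(P = P, Py = Py, beta = beta, loglik = ll)
}

reml_loglik_only <- function(y, X, Gs, s2) {
  out <- tryCatch(reml_state(y, X, Gs, s2)$loglik, error = function(e) -Inf)
  out
}

build_fixed_design <- function(data, fixed) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (col in fixed) {
    if (!col %in% names(data)) stop("fixed term column not found: ", col)
    f <- factor(data[[col]])
    if (nlevels(f) < 2) {
      message("fixed term '", col, "' has a single level; dropped")
      next
    }
    M <- model.matrix(~ 0 + f)[, -1, drop = FALSE]
    colnames(M) <- paste0(col, levels(f)[-1])
    X <- cbind(X, M)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

# Constant response: every component sits at the zero boundary.
degenerate_fit <- function(data, response, fixed, random, y) {
  terms <- names(random)
  K <- length(terms)
  blups <- lapply(terms, function(col)
    setNames(rep(0, nlevels(factor(data[[col]]))),
             levels(factor(data[[col]]))))
  names(blups) <- terms
  structure(list(
    components = data.frame(term = c(terms, "residual"),
                            estimate = rep(0, K + 1), se = rep(NA_real_, K + 1),
                            stringsAsFactors = FALSE),
    loglik = NA_real_, beta = c(`(Intercept)` = mean(y)), blups = blups,
    converged = TRUE, iterations = 0L, trace = NULL,
    n = length(y), vary = 0,
    model = list(data = data, response = response, fixed = fixed,
                 random = random)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> response:", x$model$response, "| n =", x$n,
      "| REML logLik =", format(x$loglik, digits = 8), "\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Extract a variance component estimate from a fit
#'
#' @param fit An `lmm_fit`.
#' @param term Term name as it appears in `fit$components$term`.
#' @return Named numeric of length one.
#' @export
vc <- function(fit, term) {
  i <- match(term, fit$components$term)
  if (is.na(i)) stop("no such variance component: ", term)
  setNames(fit$components$estimate[i], term)
}

#' Likelihood-ratio significance test of a variance component
#'
#' Refits the model without the given random term and compares restricted
#' likelihoods. Because the null value lies on the boundary of the parameter
#' space, the reference distribution is the equal mixture
#' `0.5 chi2_0 + 0.5 chi2_1`, giving `p = 0.5 * P(chi2_1 > LR)` (and
#' `p = 0.5` when `LR = 0`). A Wald z statistic from the AI standard error
#' is reported alongside.
#'
#' @param fit A converged [reml_fit()] result.
#' @param term Name of the random term to test.
#' @return List with `lr`, `p_value`, `wald_z`, `p_wald` and the reduced
#'   fit's log-likelihood.
#' @export
variance_significance <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("full model did not converge")
  m <- fit$model
  if (!term %in% names(m$random)) stop("no such random term: ", term)
  reduced <- m$random[setdiff(names(m$random), term)]
  if (length(reduced) == 0)
    stop("cannot drop the only random term; residual-only null unsupported")
  fit0 <- tryCatch(
    reml_fit(m$data, m$response, m$fixed, reduced,
             maxit = m$maxit %||% 200L, tol = m$tol %||% 1e-8),
    error = function(e)
      stop("reduced-model refit failed for term '", term, "': ",
           conditionMessage(e)))
  lr <- max(0, 2 * (fit$loglik - fit0$loglik))
  p <- 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  i <- match(term, fit$components$term)
  z <- fit$components$estimate[i] / fit$components$se[i]
  list(term = term, lr = lr, p_value = p, wald_z = z,
       p_wald = pnorm(z, lower.tail = FALSE), loglik_reduced = fit0$loglik)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Family BLUPs (adjusted means) from a fitted trial model
#'
#' Stage-one output of the two-stage genomic selection workflow: one
#' adjusted mean per family, the BLUP of the family effect optionally
#' shifted by the grand mean.
#'
#' @param fit An `lmm_fit`.
#' @param term Random term holding the family effect.
#' @param add_intercept Add the fixed intercept to each BLUP.
#' @return `data.frame` with columns `level` and `blup`.
#' @export
extract_blups <- function(fit, term = "family", add_intercept = FALSE) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!term %in% names(fit$blups)) stop("no such random term: ", term)
  b <- fit$blups[[term]]
  if (add_intercept) b <- b + fit$beta[["(Intercept)"]]
  data.frame(level = names(b), blup = as.numeric(b),
             stringsAsFactors = FALSE, row.names = NULL)
}
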