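# Family-mean panel with marker-driven genetics for exercising the schemes:
# adjusted means y = g + e over named families, G from the same markers.
cv_panel <- function(n = 120, m = 800, h2 = 0.6, seed = 1, n_pop = 1) {
  set.seed(seed)
  pops <- rep(paste0("Pop", seq_len(n_pop)), length.out = n)
  X <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("F%03d", 1:n), NULL))
  set.seed(seed + 90000)   # decouple effect draws from the genotype stream
  a <- rnorm(m, 0, 1 / sqrt(m))
  g <- as.numeric(scale(X %*% a))
  y <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
  list(X = X, g = g, y = setNames(y, rownames(X)),
       grm = vanraden_grm(X + 0),
       populations = setNames(pops, rownames(X)))
}

test_that("k-fold partitions are disjoint covers; k = n is leave-one-out", {
  pan <- cv_panel(n = 40, m = 200, seed = 211)
  pr <- gblup_predictor(pan$grm)
  rep1 <- kfold_cv(pan$y, pr, k = 40, n_randomizations = 1, seed = 3)
  expect_true(all(table(rep1$partitions[[1]]) == 1))
  rep2 <- kfold_cv(pan$y, pr, k = 8, n_randomizations = 2, seed = 3)
  for (part in rep2$partitions) {
    expect_setequal(names(part), names(pan$y))
    expect_true(all(table(part) == 5))
  }
  expect_error(kfold_cv(pan$y[1:5], pr, k = 10), "exceeds")
  # reproducibility and report self-consistency
  rep3 <- kfold_cv(pan$y, pr, k = 8, n_randomizations = 2, seed = 3)
  expect_identical(rep2$iterations, rep3$iterations)
  expect_equal(rep2$mean, mean(rep2$iterations$r), tolerance = 1e-12)
})

test_that("zero-heritability traits cross-validate to nothing", {
  # randomizations reuse one data set, so their r values are correlated;
  # average over independent null panels for a stable check
  means <- vapply(1:3, function(i) {
    pan <- cv_panel(n = 100, m = 500, h2 = 0.6, seed = 222 + i)
    set.seed(300 + i)
    y0 <- setNames(rnorm(100), names(pan$y))  # no genetic signal
    kfold_cv(y0, gblup_predictor(pan$grm), k = 10,
             n_randomizations = 5, seed = 5)$mean
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.1)
})

test_that("predictive ability rises with simulated heritability", {
  means <- vapply(c(0.1, 0.3, 0.6), function(h2) {
    pan <- cv_panel(n = 150, m = 800, h2 = h2, seed = 227)
    kfold_cv(pan$y, gblup_predictor(pan$grm), k = 10,
             n_randomizations = 3, seed = 7)$mean
  }, numeric(1))
  expect_gt(means[3], means[1] + 0.05)
  expect_gt(means[2], means[1] - 0.05)       # allow noise on the middle point
  expect_gt(means[3], means[2] - 0.05)
})

test_that("Monte-Carlo CV: guards, reproducibility, agreement with k-fold", {
  pan <- cv_panel(n = 120, m = 600, seed = 229)
  pr <- gblup_predictor(pan$grm)
  expect_error(monte_carlo_cv(pan$y, pr, train_fraction = 1), "train_fraction")
  expect_error(monte_carlo_cv(pan$y, pr, train_fraction = 0.99), "degenerate")
  mc1 <- monte_carlo_cv(pan$y, pr, n_iterations = 25, seed = 11)
  mc2 <- monte_carlo_cv(pan$y, pr, n_iterations = 25, seed = 11)
  expect_identical(mc1$iterations, mc2$iterations)
  kf <- kfold_cv(pan$y, pr, k = 10, n_randomizations = 5, seed = 11)
  expect_lt(abs(mc1$mean - kf$mean), 2 * (mc1$sd + 1e-9))
})

test_that("within-population scheme trains evenly and matches Monte-Carlo when unstructured", {
  pan <- cv_panel(n = 100, m = 600, seed = 233, n_pop = 1)
  pr <- gblup_predictor(pan$grm)
  wp <- within_population_cv(pan$y, pan$populations, pr,
                             n_iterations = 25, seed = 13)
  mc <- monte_carlo_cv(pan$y, pr, train_fraction = 0.5,
                       n_iterations = 25, seed = 13)
  expect_lt(abs(wp$mean - mc$mean), 2 * (wp$sd + mc$sd))
  expect_error(within_population_cv(pan$y, pan$populations[1:10], pr),
               "missing")
})

test_that("five exchangeable populations perform alike; a decoupled one ranks last", {
  pan <- fullsib_panel(n_groups = 40, sibs = 8, m = 1500, seed = 239)
  pr <- gblup_predictor(vanraden_grm(pan$X + 0))
  wp <- within_population_cv(pan$y, pan$populations, pr,
                             n_iterations = 30, seed = 17)
  spread <- diff(range(wp$by_population$r))
  expect_lt(spread, 4 * max(wp$by_population$sd))

  # decouple Pop5: its adjusted means carry no marker signal
  y2 <- pan$y
  set.seed(240)
  idx5 <- names(which(pan$populations == "Pop5"))
  y2[idx5] <- rnorm(length(idx5), 0, sd(pan$y))
  wp2 <- within_population_cv(y2, pan$populations, pr,
                              n_iterations = 30, seed = 19)
  r <- setNames(wp2$by_population$r, wp2$by_population$population)
  expect_equal(names(which.min(r)), "Pop5")
})

test_that("marker-density ladder: plateau at moderate density, collapse when starved", {
  pan <- fullsib_panel(seed = 241)
  lad <- marker_density_ladder(pan$y, pan$X + 0,
                               fractions = c(1, 0.05, 0.001),
                               n_iterations = 20, seed = 23)
  expect_equal(lad$n_markers, c(4000, 200, 4))
  expect_gt(lad$mean_r[2], lad$mean_r[1] - 0.12)  # 5% of markers holds up
  expect_lt(lad$mean_r[3], lad$mean_r[1] - 0.15)  # 4 markers collapse
  expect_error(marker_density_ladder(pan$y, pan$X + 0, fractions = 1e-5),
               "0 markers")
  # fraction 1 reproduces the baseline Monte-Carlo scheme up to noise
  base <- monte_carlo_cv(pan$y, gblup_predictor(vanraden_grm(pan$X + 0)),
                         n_iterations = 20, seed = 29)
  expect_lt(abs(lad$mean_r[1] - base$mean), 3 * (base$sd + 1e-9))
})
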