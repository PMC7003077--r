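test_that("REML equals closed-form EMS ANOVA on balanced one-way data", {
  set.seed(61)
  nf <- 40; nr <- 6
  fam <- rep(sprintf("F%02d", 1:nf), each = nr)
  y <- rep(rnorm(nf, 0, sqrt(2)), each = nr) + rnorm(nf * nr, 0, 1)
  d <- data.frame(family = fam, y = y)
  fit <- reml_fit(d, "y", random = list(family = list()))
  ems <- ems_oneway(y, fam)
  expect_equal(unname(vc(fit, "family")), unname(ems["sigma2_g"]),
               tolerance = 1e-8)
  expect_equal(unname(vc(fit, "residual")), unname(ems["sigma2_e"]),
               tolerance = 1e-8)
})

test_that("REML agrees with lme4 on a two-factor model (components and logLik)", {
  skip_if_not_installed("lme4")
  f <- simulate_population_set(small_config(n_fam = 40, n_pop = 2, seed = 67))
  tt <- simulate_trial(f)
  tt <- prepare_trial(tt)
  fit <- reml_fit(tt, "Na", fixed = c("location", "population"),
                  random = list(family = list(), fam_loc = list()))
  lf <- lme4::lmer(Na ~ location + population + (1 | family) + (1 | fam_loc),
                   tt, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vcl <- as.data.frame(lme4::VarCorr(lf))
  # 1e-4 relative: either optimizer may park a vanishing component at a
  # slightly different boundary epsilon
  expect_equal(unname(vc(fit, "family")),
               vcl$vcov[vcl$grp == "family"], tolerance = 1e-4)
  expect_lt(abs(unname(vc(fit, "fam_loc")) -
                  vcl$vcov[vcl$grp == "fam_loc"]), 1e-8)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("constant response puts every component at the zero boundary", {
  d <- data.frame(family = rep(letters[1:5], each = 3), y = 1)
  fit <- reml_fit(d, "y", random = list(family = list()))
  expect_true(all(fit$components$estimate == 0))
  expect_true(all(fit$blups$family == 0))
})

test_that("fits are invariant to row permutation of the trial table", {
  f <- simulate_population_set(small_config(n_fam = 25, seed = 71))
  tt <- simulate_trial(f)
  fit1 <- fit_trial_model(tt, "Na", model = "across", terms = "rep")
  set.seed(1)
  fit2 <- fit_trial_model(tt[sample(nrow(tt)), ], "Na", model = "across",
                          terms = "rep")
  expect_equal(fit1$components$estimate, fit2$components$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$blups$family, fit2$blups$family, tolerance = 1e-6)
})

test_that("singular fixed designs raise a named-column error", {
  d <- data.frame(family = rep(letters[1:6], each = 2),
                  loc2 = rep(c("A", "B"), 6),
                  dup = rep(c("A", "B"), 6),
                  y = rnorm(12))
  expect_error(
    reml_fit(d, "y", fixed = c("loc2", "dup"),
             random = list(family = list())),
    "aliased")
})

test_that("family BLUPs are shrunken family means with the closed-form factor", {
  set.seed(73)
  nf <- 60; nr <- 6
  fam <- rep(sprintf("F%02d", 1:nf), each = nr)
  y <- rep(rnorm(nf, 0, 1), each = nr) + rnorm(nf * nr, 0, 1.5)
  d <- data.frame(family = fam, y = y)
  fit <- reml_fit(d, "y", random = list(family = list()))
  s2g <- unname(vc(fit, "family")); s2e <- unname(vc(fit, "residual"))
  fmeans <- tapply(y, fam, mean)
  shrink <- s2g / (s2g + s2e / nr)
  expected <- as.numeric(shrink * (fmeans - mean(fmeans)))
  expect_equal(unname(fit$blups$family[names(fmeans)]), expected,
               tolerance = 1e-6)
  expect_lt(abs(sum(fit$blups$family)), 1e-6)
  # balanced data: BLUP ordering equals raw family-mean ordering
  expect_identical(order(fit$blups$family), order(unname(fmeans)))
})

test_that("boundary likelihood-ratio test: p = 0.5 at LR = 0, high power under signal", {
  set.seed(79)
  nf <- 30; nr <- 4
  fam <- rep(sprintf("F%02d", 1:nf), each = nr)
  d <- data.frame(family = fam,
                  rep_id = rep(rep(c("r1", "r2"), each = 2), nf))
  # under a pure-noise response the family component often hits the boundary
  found_boundary <- FALSE
  for (s in 1:20) {
    set.seed(100 + s)
    d$y <- rnorm(nrow(d))
    fit <- reml_fit(d, "y", random = list(family = list(),
                                          rep_id = list()))
    if (vc(fit, "family") < 1e-8) {
      vs <- variance_significance(fit, "family")
      expect_lt(vs$lr, 1e-4)
      expect_equal(vs$p_value, 0.5, tolerance = 1e-3)
      found_boundary <- TRUE
      break
    }
  }
  expect_true(found_boundary)
  # strong family signal: decisive rejection
  d$y <- rep(rnorm(nf, 0, 2), each = nr) + rnorm(nrow(d))
  fit <- reml_fit(d, "y", random = list(family = list(), rep_id = list()))
  vs <- variance_significance(fit, "family")
  expect_lt(vs$p_value, 1e-6)
})

test_that("Model 2 with an identity GRM reproduces the identity fit exactly", {
  f <- simulate_population_set(small_config(n_fam = 30, seed = 83))
  tt <- simulate_trial(f)
  fit_id <- fit_trial_model(tt, "Na", model = "across", terms = "rep")
  h_id <- heritability_from_fit(fit_id, s = 2, b = 3)
  h_g <- genomic_heritability(tt, identity_grm(f$family), "Na",
                              terms = "rep")
  expect_equal(h_g$value, h_id$value, tolerance = 1e-6)
})

test_that("marker-based family covariance: h2_g tracks the marker-explained share", {
  # maternal markers explain half of sigma2_g by construction, so the
  # genomic fit should attribute clearly less family variance than the
  # identity fit, but far more than none
  f <- simulate_population_set(small_config(n_fam = 120, n_snps = 1500,
                                            seed = 89))
  tt <- simulate_trial(f)
  g_true <- vanraden_grm(f$genotypes + 0)
  h_id <- heritability_from_fit(
    fit_trial_model(tt, "Na", model = "across", terms = "rep"), s = 2, b = 3)
  h_g <- genomic_heritability(tt, g_true, "Na", terms = "rep")
  expect_gt(h_g$value, 0.1 * h_id$value)
  expect_lt(h_g$value, 1.05 * h_id$value)
})

test_that("within-population model drops the constant population term", {
  f <- simulate_population_set(small_config(n_fam = 20, n_pop = 2, seed = 97))
  tt <- simulate_trial(f)
  fit <- fit_trial_model(tt, "Na", model = "within_population",
                         population = "Pop1", terms = "rep")
  expect_true(all(c("family", "fam_loc") %in% fit$components$term))
  expect_false(any(grepl("population", names(fit$beta))))
  expect_equal(fit$n, 20 * 6)
})
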