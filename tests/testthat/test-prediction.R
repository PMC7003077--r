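# Shared toy: markers, true effects, heritable phenotype on named ids.
marker_panel <- function(n, m, h2 = 0.5, seed = 1, p = 0.3) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, p), n, m,
              dimnames = list(sprintf("I%03d", 1:n), NULL))
  a <- rnorm(m, 0, 1 / sqrt(m))
  g <- as.numeric(scale(X %*% a))
  y <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
  list(X = X, g = g, y = setNames(y, rownames(X)))
}

test_that("GBLUP equals marker ridge regression on a 20 x 50 toy", {
  pan <- marker_panel(20, 50, h2 = 0.6, seed = 139)
  grm <- vanraden_grm(pan$X + 0)
  gp <- gblup_predict(pan$y, grm)
  vcp <- attr(gp, "varcomp")
  # ridge oracle via the normal equations at the same variance ratio
  p <- colMeans(pan$X) / 2
  Xc <- sweep(pan$X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  lam <- vcp[["lambda"]]
  alpha <- solve(crossprod(Xc) + diag(denom / lam, 50),
                 crossprod(Xc, pan$y - vcp[["mu"]]))
  expect_equal(gp$gebv, as.numeric(Xc %*% alpha), tolerance = 1e-8)
})

test_that("an individual unrelated to all training records predicts to zero", {
  G <- diag(10)
  G[1:9, 1:9] <- G[1:9, 1:9] + 0.3
  ids <- sprintf("I%03d", 1:10)
  grm <- forageGS:::new_relationship_matrix(G, ids, "vanraden", 100L)
  set.seed(149)
  y <- setNames(rnorm(9), ids[1:9])
  gp <- gblup_predict(y, grm, predict_ids = ids[10])
  expect_equal(gp$gebv, 0)
})

test_that("GBLUP: noiseless limit and training-shift invariance", {
  pan <- marker_panel(80, 400, h2 = 1, seed = 151)
  grm <- vanraden_grm(pan$X + 0)
  gp <- gblup_predict(pan$y, grm)
  expect_gt(cor(gp$gebv, pan$y), 0.99)
  gp2 <- gblup_predict(pan$y + 5, grm)
  expect_equal(gp$gebv, gp2$gebv, tolerance = 1e-8)
})

test_that("BayesC-pi: pure-noise response predicts near zero on held-out data", {
  rs <- vapply(1:20, function(i) {
    set.seed(160 + i)
    X <- matrix(rbinom(70 * 100, 2, 0.3), 70, 100,
                dimnames = list(sprintf("I%03d", 1:70), NULL))
    y <- setNames(rnorm(70), rownames(X))
    set.seed(260 + i)
    g <- bayes_c_pi_predict(y[1:50], X, predict_ids = rownames(X)[51:70],
                            spec = bayes_spec(iterations = 1200,
                                              burn_in = 400, thin = 5))
    suppressWarnings(cor(g$gebv, y[51:70]))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("BayesC-pi flags the simulated large-effect QTL", {
  set.seed(173)
  n <- 300; m <- 500
  X <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("I%03d", 1:n), NULL))
  qtl <- 250
  g <- as.numeric(scale(X[, qtl]))
  y <- setNames(g + rnorm(n), rownames(X))   # QTL explains ~50% of variance
  set.seed(174)
  b <- bayes_c_pi_predict(y, X, spec = bayes_spec(iterations = 2000,
                                                  burn_in = 500))
  post <- attr(b, "posterior")
  expect_equal(which.max(post$inclusion_prob), qtl)
  expect_gt(post$pi, 0.9)                     # most markers excluded
  expect_gt(cor(b$gebv, g), 0.9)
})

test_that("BayesC-pi with pi forced to zero approaches the GBLUP solution", {
  pan <- marker_panel(100, 150, h2 = 0.6, seed = 179)
  grm <- vanraden_grm(pan$X + 0)
  gp <- gblup_predict(pan$y, grm)
  set.seed(180)
  bp <- bayes_c_pi_predict(pan$y, pan$X,
                           spec = bayes_spec(iterations = 4000,
                                             burn_in = 1000, fix_pi = 0))
  expect_gt(cor(gp$gebv, bp$gebv), 0.95)
})

test_that("chain length: doubling iterations leaves GEBVs essentially unchanged", {
  pan <- marker_panel(80, 120, h2 = 0.5, seed = 181)
  set.seed(182)
  b1 <- bayes_c_pi_predict(pan$y, pan$X,
                           spec = bayes_spec(iterations = 3000,
                                             burn_in = 1000))
  set.seed(183)
  b2 <- bayes_c_pi_predict(pan$y, pan$X,
                           spec = bayes_spec(iterations = 6000,
                                             burn_in = 1000))
  expect_gt(cor(b1$gebv, b2$gebv), 0.98)
  # and identical seeds reproduce the chain exactly
  set.seed(182)
  b3 <- bayes_c_pi_predict(pan$y, pan$X,
                           spec = bayes_spec(iterations = 3000,
                                             burn_in = 1000))
  expect_identical(b1$gebv, b3$gebv)
})

test_that("prediction bias slope: exact closed forms and guards", {
  set.seed(191)
  obs <- data.frame(id = sprintf("F%02d", 1:20), value = rnorm(20))
  g1 <- data.frame(id = obs$id, gebv = obs$value, method = "x")
  expect_equal(prediction_bias(g1, obs), 1)
  g2 <- data.frame(id = obs$id, gebv = 2 * obs$value, method = "x")
  expect_equal(prediction_bias(g2, obs), 2)
  expect_equal(prediction_bias(g2, obs, direction = "observed_on_gebv"), 0.5)
  expect_error(prediction_bias(g1[1:2, ], obs[1:2, ]), "at least 3")
  const <- data.frame(id = obs$id, value = 1)
  expect_warning(s <- prediction_bias(g1, const), "constant")
  expect_true(is.na(s))
})
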