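test_that("Brownian covariance equals path-length arithmetic", {
  om <- brownian_covariance("((A:1,B:1):1,C:2);")
  expect_equal(om[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  # star tree with unit tip branches -> identity
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  expect_equal(unname(brownian_covariance(star)), diag(4))
  dup <- ape::read.tree(text = "((A:1,A:1):1,C:2);")
  expect_error(brownian_covariance(dup), "duplicate")
})

test_that("Brownian covariance is PSD on random trees", {
  for (s in 1:100) {
    set.seed(s)
    om <- brownian_covariance(ape::rtree(sample(4:20, 1)))
    expect_true(isSymmetric(om))
    expect_gte(min(eigen(om, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("GLS with identity covariance reduces to OLS", {
  f <- gls_fit(c(1, 2, 3), cbind(1, c(0, 1, 2)))
  expect_equal(unname(f$coefficients), c(1, 1))
  # zero-residual recovery to machine precision
  X <- cbind(1, 1:6)
  y <- as.numeric(X %*% c(2, -0.5))
  f0 <- gls_fit(y, X)
  expect_equal(unname(f0$coefficients), c(2, -0.5), tolerance = 1e-12)
  expect_lt(f0$sigma2, 1e-20)
  # 100 random problems vs lm.fit to 1e-8
  for (s in 1:100) {
    set.seed(s)
    n <- sample(10:40, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n))
    y <- rnorm(n)
    expect_equal(unname(gls_fit(y, X)$coefficients),
                 unname(stats::lm.fit(X, y)$coefficients),
                 tolerance = 1e-8)
  }
})

test_that("GLS matches the direct matrix-formula oracle on the 3-taxon tree", {
  om <- brownian_covariance("((A:1,B:1):1,C:2);")
  y <- c(1, 2, 3)
  X <- matrix(1, 3, 1)
  f <- gls_fit(y, X, om)
  beta_direct <- solve(t(X) %*% solve(om) %*% X,
                       t(X) %*% solve(om) %*% y)
  expect_equal(unname(f$coefficients), as.numeric(beta_direct))
})

test_that("GLS satisfies the generalized normal equations", {
  set.seed(3)
  tr <- ape::rtree(12)
  om <- brownian_covariance(tr)
  X <- cbind(1, rnorm(12))
  y <- rnorm(12)
  f <- gls_fit(y, X, om)
  resid <- y - f$fitted
  expect_lt(max(abs(t(X) %*% solve(om) %*% resid)), 1e-8)
})

test_that("GLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_no("nlme")
  set.seed(5)
  tr <- ape::rtree(20)
  om <- brownian_covariance(tr)
  dat <- data.frame(y = rnorm(20, 1), x = rnorm(20), spp = tr$tip.label)
  # nlme corStruct carries the correlation only (unit variances), so the
  # comparison runs on cov2cor(omega); on an ultrametric tree the two
  # parameterizations coincide
  f <- gls_fit(dat$y, cbind(1, x = dat$x), stats::cov2cor(om))
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(1, tr, form = ~spp),
                 method = "ML")
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the column", {
  X <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
  expect_error(gls_fit(c(1, 2, 3), X), "collinear.*c")
})

test_that("subset selection recovers a planted elevation effect", {
  set.seed(8)
  env <- simulate_strain_environment(40, seed = 8)
  tr <- ape::rtree(40)
  tr$tip.label <- env$strain
  om <- brownian_covariance(tr)
  env$mu_A <- 2 + 0.002 * env$elevation + rnorm(40, 0, 0.02)
  sel <- pgls_model_selection(env, "mu_A", om)
  expect_true("elevation" %in% sel$best_predictors)
  beta <- sel$best$coefficients["elevation"]
  se <- sel$best$se["elevation"]
  expect_lt(abs(beta - 0.002), 2 * se)
  # ranking is a permutation of all 127 subsets with ascending AIC
  expect_equal(nrow(sel$ranking), 127)
  expect_true(!is.unsorted(sel$ranking$AIC - 0))
  expect_true(!is.unsorted(sel$ranking$delta_AIC))
  # projected phenotype is X beta of the best model
  expect_equal(sel$projected$fitted, sel$best$fitted)
})

test_that("strain mismatches between table and covariance are dropped", {
  env <- simulate_strain_environment(12, seed = 2)
  tr <- ape::rtree(12)
  tr$tip.label <- c(env$strain[1:10], "ZZ1", "ZZ2")
  om <- brownian_covariance(tr)
  env$mu_A <- rnorm(12)
  expect_message(sel <- pgls_model_selection(env, "mu_A", om,
                                             predictors = "elevation"),
                 "unmatched")
  expect_setequal(sel$dropped, c("ZZ1", "ZZ2", env$strain[11:12]))
  expect_equal(sel$best$n, 10)
})

test_that("pre-specified PGLS tests are calibrated under Brownian noise", {
  p <- vapply(1:100, function(r) {
    set.seed(r)
    tr <- ape::rtree(40)
    om <- brownian_covariance(tr)
    y <- as.numeric(wormagg:::psd_sqrt(om) %*% rnorm(40))
    x <- rnorm(40)
    gls_fit(y, cbind(1, x), om)$p.value[2]
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.1)
})
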