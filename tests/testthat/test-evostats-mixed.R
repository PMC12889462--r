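test_that("pairwise distances match their closed forms", {
  tab <- tibble::tibble(strain = c("a", "b", "c"),
                        mu_A = c(1, 1, 3), elevation = c(0, 100, 200))
  pd <- pairwise_distances(tab, traits = c("mu_A", "elevation"))
  expect_equal(pd$matrices$mu_A["a", "b"], 0)       # identical means
  z <- as.numeric(scale(tab$elevation))
  expect_equal(pd$matrices$elevation["a", "c"], abs(z[1] - z[3]))
  # quarter great circle on the 6371-km sphere
  coords <- tibble::tibble(strain = c("a", "b", "c"),
                           latitude = c(0, 0, 10),
                           longitude = c(0, 90, 10))
  pd2 <- pairwise_distances(tab, traits = "mu_A", coords = coords)
  expect_true(all(pd2$matrices$geographic >= 0 &
                    pd2$matrices$geographic <= 1))
  expect_equal(max(pd2$matrices$geographic), 1)
  g <- simulate_genotypes(3, 4, seed = 1)
  g["S001", ] <- c(0, 0, 0, 0)
  g["S002", ] <- c(2, 0, 0, 0)
  rownames(g) <- c("a", "b", "c")
  pd3 <- pairwise_distances(tab, traits = "mu_A", genotypes = g)
  expect_equal(pd3$matrices$genetic["a", "b"], 0.25)
})

test_that("raw geodesic distances match the haversine closed form", {
  d <- geosphere::distHaversine(c(0, 0), c(90, 0), r = 6371000) / 1000
  expect_equal(d, pi * 6371 / 2, tolerance = 1e-6)
})

test_that("strains without coordinates are excluded with a message", {
  tab <- tibble::tibble(strain = c("a", "b", "c"), mu_A = 1:3)
  coords <- tibble::tibble(strain = c("a", "b", "c"),
                           latitude = c(0, NA, 10), longitude = c(0, 5, 10))
  expect_message(pd <- pairwise_distances(tab, "mu_A", coords), "without")
  expect_equal(pd$dropped, "b")
  expect_setequal(pd$populations, c("a", "c"))
})

test_that("MLPE with the population effect off reduces to OLS", {
  pp <- simulate_mlpe_pairs(12, seed = 1)
  f0 <- mlpe_fit(pp, lambda = 0)
  ols <- stats::lm(y ~ x, data = pp)
  expect_equal(unname(f0$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f0$se),
               unname(sqrt(diag(stats::vcov(ols)))), tolerance = 1e-8)
  expect_error(mlpe_fit(dplyr::mutate(pp, x2 = x), predictors = c("x", "x2")),
               "rank deficient")
})

test_that("the MLPE covariance structure couples pairs sharing a population", {
  pp <- simulate_mlpe_pairs(6, seed = 2)
  pops <- sort(unique(c(pp$pop1, pp$pop2)))
  Z <- matrix(0, nrow(pp), length(pops))
  Z[cbind(seq_len(nrow(pp)), match(pp$pop1, pops))] <- 1
  Z[cbind(seq_len(nrow(pp)), match(pp$pop2, pops))] <- 1
  S <- Z %*% t(Z)
  shared <- outer(seq_len(nrow(pp)), seq_len(nrow(pp)), Vectorize(function(i, j)
    length(intersect(c(pp$pop1[i], pp$pop2[i]),
                     c(pp$pop1[j], pp$pop2[j])))))
  diag(shared) <- diag(S)
  expect_equal(unname(S), unname(shared))
})

test_that("MLPE recovers slope and variance components", {
  f <- mlpe_fit(simulate_mlpe_pairs(40, beta = 0.5, sigma_u2 = 1,
                                    sigma_e2 = 0.5, seed = 7))
  expect_lt(abs(f$coefficients["x"] - 0.5), 2 * f$se["x"])
  expect_gt(f$sigma_u2, 0.5)
  expect_lt(f$sigma_u2, 1.5)
  expect_true(f$converged)
})

test_that("AICc selection penalizes parameters and ranks candidates", {
  fake <- function(ll, k, n) list(AIC = -2 * ll + 2 * k, logLik = ll,
                                  n_par = k, n = n)
  out <- aicc_model_selection(list(a = fake(-10, 2, 30)))
  expect_equal(out$best_name, "a")
  out2 <- aicc_model_selection(list(big = fake(-10, 5, 30),
                                    small = fake(-10, 2, 30)))
  expect_equal(out2$best_name, "small")
  expect_warning(
    out3 <- aicc_model_selection(list(ok = fake(-10, 2, 30),
                                      tiny = fake(-10, 29, 30))),
    "dropping")
  expect_equal(nrow(out3$table), 1)
})

test_that("AICc selection finds the generating predictor", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 30
    elev <- runif(n)
    geo <- runif(n)
    pops <- sprintf("P%02d", 1:n)
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    u <- rnorm(n, 0, 0.5)
    pairs <- tibble::tibble(
      pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
      elev_d = abs(elev[idx[, 1]] - elev[idx[, 2]]),
      geo_d = abs(geo[idx[, 1]] - geo[idx[, 2]]),
      y = 1.5 * abs(elev[idx[, 1]] - elev[idx[, 2]]) +
        u[idx[, 1]] + u[idx[, 2]] + rnorm(nrow(idx), 0, 0.3))
    fits <- list(elev = mlpe_fit(pairs, "y", "elev_d"),
                 geo = mlpe_fit(pairs, "y", "geo_d"),
                 both = mlpe_fit(pairs, "y", c("elev_d", "geo_d")))
    grepl("elev", aicc_model_selection(fits)$best_name)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
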