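test_that("VanRaden kinship matches the hand example and duplicates", {
  g <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), NULL))
  A <- vanraden_kinship(g)$A
  expect_equal(unname(A), matrix(c(2, -2, -2, 2), 2))
  g3 <- rbind(g, s3 = g[1, ])
  A3 <- suppressMessages(vanraden_kinship(g3)$A)
  expect_equal(A3["s1", "s3"], A3["s1", "s1"])   # identical genotypes
  expect_error(vanraden_kinship(matrix(2, 3, 4)), "monomorphic")
})

test_that("VanRaden kinship equals the direct formula on random matrices", {
  for (s in 1:50) {
    set.seed(s)
    g <- simulate_genotypes(sample(5:20, 1), sample(10:60, 1), seed = s)
    p <- colMeans(g) / 2
    keep <- p > 0 & p < 1
    g2 <- g[, keep, drop = FALSE]
    p <- p[keep]
    M <- sweep(g2, 2, 2 * p)
    A_direct <- (M %*% t(M)) / sum(2 * p * (1 - p))
    A <- suppressMessages(vanraden_kinship(g))$A
    expect_lt(max(abs(A - A_direct)), 1e-10)
  }
})

test_that("heritability hits its boundary cases", {
  # replicates identical within strains, strains differ -> H2 -> 1
  tab1 <- tibble::tibble(strain = rep(letters[1:6], each = 3),
                         value = rep(c(1, 4, 2, 8, 5, 7), each = 3))
  h1 <- reml_heritability(tab1, n_boot = 0)
  expect_gt(h1$estimate, 0.99)
  # equal strain means, noisy replicates -> H2 ~ 0
  set.seed(1)
  tab0 <- tibble::tibble(strain = rep(letters[1:10], each = 5),
                         value = rnorm(50))
  h0 <- reml_heritability(tab0, n_boot = 0)
  expect_lt(h0$estimate, 0.15)
})

test_that("REML matches lme4 on the identity-kinship model", {
  skip_if_no("lme4")
  tab <- simulate_traits(30, 4, 1.3, 0.7, seed = 5)
  h <- reml_heritability(tab, n_boot = 0)
  m <- lme4::lmer(value ~ 1 + (1 | strain), data = tab)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(h$sigma_u2, vc$vcov[1], tolerance = 1e-5)
  expect_equal(h$sigma_e2, vc$vcov[2], tolerance = 1e-5)
})

test_that("REML estimates are translation invariant and start-point stable", {
  tab <- simulate_traits(20, 4, 1, 1, seed = 9)
  h <- reml_heritability(tab, n_boot = 0)
  tab2 <- dplyr::mutate(tab, value = value + 1000)
  h2 <- reml_heritability(tab2, n_boot = 0)
  expect_equal(h$estimate, h2$estimate, tolerance = 1e-8)
  # profiled REML is a 1-D optimization; different search intervals
  # (start points) must agree
  y <- tab$value
  strains <- unique(tab$strain)
  Z <- outer(tab$strain, strains, "==") * 1
  K <- Z %*% t(Z)
  fits <- lapply(list(c(-15, 15), c(-8, 8), c(-15, 5)), function(iv)
    wormagg:::reml_one_component(y, matrix(1, length(y), 1), K,
                                 interval = iv))
  s <- vapply(fits, function(f) f$sigma_u2 / (f$sigma_u2 + f$sigma_e2),
              numeric(1))
  expect_lt(max(s) - min(s), 1e-5)
})

test_that("narrow-sense heritability under a genomic relationship matrix", {
  G <- simulate_genotypes(60, 400, seed = 3, n_founders = 8)
  kin <- vanraden_kinship(G)
  tab <- simulate_traits(60, 4, sigma_u2 = 1, sigma_e2 = 1,
                         kinship = kin$A, seed = 4)
  h <- reml_heritability(tab, kinship = kin, n_boot = 30, seed = 1)
  expect_equal(h$kind, "narrow")
  expect_gt(h$estimate, 0.2)
  expect_lt(h$estimate, 0.8)
  expect_true(h$ci[1] <= h$ci[2])
})

test_that("heritability estimate lands near truth across seeds", {
  h2 <- vapply(1:40, function(s)
    reml_heritability(simulate_traits(50, 5, 1, 1, seed = s),
                      n_boot = 0)$estimate, numeric(1))
  expect_gte(mean(h2 >= 0.35 & h2 <= 0.65), 0.95)
})

test_that("QTL variance partition finds null and planted fractions", {
  frac <- function(s, su) {
    Gq <- simulate_genotypes(100, 200, seed = 2000 + s, n_founders = 10)
    Gb <- simulate_genotypes(100, 1000, seed = 3000 + s, n_founders = 10)
    Aq <- suppressMessages(vanraden_kinship(Gq))
    Ab <- suppressMessages(vanraden_kinship(Gb))
    set.seed(4000 + s)
    u <- as.numeric(wormagg:::psd_sqrt(Aq$A) %*% rnorm(100)) * sqrt(su)
    v <- as.numeric(wormagg:::psd_sqrt(Ab$A) %*% rnorm(100))
    tab <- tibble::tibble(strain = rownames(Gq),
                          value = u + v + rnorm(100, 0, sqrt(2)))
    qtl_variance(tab, Aq, Ab)$fraction
  }
  null_frac <- vapply(1:10, frac, numeric(1), su = 0)
  expect_lt(median(null_frac), 0.1)
  planted <- vapply(11:25, frac, numeric(1), su = 1)
  expect_gt(median(planted), 0.1)
  expect_lt(median(planted), 0.45)
})

test_that("nearly collinear kinships raise a warning", {
  G <- simulate_genotypes(30, 500, seed = 1, n_founders = 5)
  A <- suppressMessages(vanraden_kinship(G))
  tab <- simulate_traits(30, 2, seed = 2)
  expect_warning(qtl_variance(tab, A, A), "collinear")
})
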