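test_that("the aggregation index matches its closed forms", {
  expect_equal(aggregation_index(rep(1, 40), 40), 1 / log(40))
  expect_equal(aggregation_index(c(20, 20), 40), 1 / log(2))
  # independent high-precision evaluation of -sum P log P for {39, 1}
  p <- c(39, 1) / 40
  expect_equal(aggregation_index(c(39, 1), 40), 1 / (-sum(p * log(p))))
  expect_equal(round(aggregation_index(c(39, 1), 40), 4), 8.5538)
  expect_error(aggregation_index(c(1, 2), 0), "positive")
  expect_error(aggregation_index(numeric(0), 40), "nonempty")
  # degenerate single-cluster frame hits the cap
  expect_equal(aggregation_index(40, 40), aggregation_cap(40))
})

test_that("A is scale consistent and minimized at equal sizes", {
  s <- c(3, 4, 5)
  expect_equal(aggregation_index(s, 12), aggregation_index(3 * s, 36))
  # over every 3-block partition of n = 12 the uniform one minimizes A
  parts <- list()
  for (a in 1:10) for (b in a:11) {
    cc <- 12 - a - b
    if (cc >= b) parts[[length(parts) + 1]] <- c(a, b, cc)
  }
  av <- vapply(parts, aggregation_index, numeric(1), n_worms = 12)
  uni <- vapply(parts, function(p) all(p == 4), logical(1))
  expect_equal(which.min(av), which(uni))
})

test_that("the aggregation series is per-frame, ordered, and capped", {
  fs <- list(c(1, 1, 2), c(2, 2), c(4))
  ser <- aggregation_series(fs, n_worms = 4, dt = 0.5)
  expect_equal(nrow(ser), 3)
  expect_equal(ser$time, c(0.5, 1, 1.5))
  expect_equal(ser$A[3], aggregation_cap(4))
  expect_equal(attr(ser, "cap_frames"), 3L)
  # monotone coarsening of equal clusters gives a non-decreasing series
  coarsen <- list(rep(1, 16), rep(2, 8), rep(4, 4), rep(8, 2), 16)
  a <- aggregation_series(coarsen, 16, dt = 1)$A
  expect_true(all(diff(a) >= 0))
})

test_that("QC-excluded recordings are refused with a marker", {
  est <- tibble::tibble(node = 1:2, frame = c(1, 1), blob_id = 1:2,
                        status = "resolved", size = c(10, 10),
                        min_size = c(10, 10), max_size = c(10, 10))
  fs <- per_frame_sizes(est, n_worms = 40)   # total 20, flagged
  expect_warning(ser <- aggregation_series(fs), "QC")
  expect_true(attr(ser, "qc_excluded"))
  expect_equal(nrow(ser), 0)
})

test_that("mean magnitude is the arithmetic time average", {
  expect_equal(mean_magnitude(c(2, 2, 2)), 2)
  expect_equal(mean_magnitude(c(1, 3)), 2)
  expect_error(mean_magnitude(numeric(0)), "empty")
})

test_that("the autocorrelation estimator matches hand evaluation", {
  ac <- autocorrelation(c(1, 2, 1, 2))
  expect_equal(ac$C[1], 1)             # C(0) = 1 exactly
  expect_equal(ac$C[2], -0.75)         # biased estimator, hand computed
  expect_true(all(abs(ac$C) <= 1 + 1e-12))
  expect_error(autocorrelation(rep(1, 10)), "variance")
})

test_that("the autocorrelation tracks the analytic AR(1) decay", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  ac <- autocorrelation(x, max_lag_fraction = 5e-4)
  k <- 0:10
  expect_true(all(abs(ac$C[k + 1] - 0.9^k) < 0.03))
})

test_that("temporal persistence is the max of the running integral", {
  expect_equal(temporal_persistence(c(1, 0, 0, 0), dt = 1), 1)
  # geometric decay sums to 1 / (1 - 0.9) = 10
  expect_equal(temporal_persistence(0.9^(0:300), dt = 1), 10,
               tolerance = 1e-10)
  # alternating-series acf: cumulative [1, .25, .75, .5] -> max 1
  expect_equal(temporal_persistence(c(1, -0.75, 0.5, -0.25), dt = 1), 1)
  # trapezoid variant stays close
  expect_lt(abs(temporal_persistence(0.9^(0:300), dt = 1,
                                     method = "trapezoid") - 9.5), 0.1)
})

test_that("iid noise shows no spurious persistence", {
  hits <- vapply(1:400, function(s) {
    set.seed(s)
    temporal_persistence(autocorrelation(rnorm(500)), dt = 1) < 3
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("stronger adhesion does not decrease the aggregation traits", {
  pairs <- vapply(1:6, function(s) {
    strong <- tiny_sim(n = 10, seconds = 45, seed = 600 + s,
                       leave_rate = 0.002)
    weak <- tiny_sim(n = 10, seconds = 45, seed = 600 + s,
                     leave_rate = 0.2)
    tr_s <- truth_frame_sizes(simulate_worms(strong))
    tr_w <- truth_frame_sizes(simulate_worms(weak))
    mu_s <- mean_magnitude(aggregation_series(tr_s$sizes, 10))
    mu_w <- mean_magnitude(aggregation_series(tr_w$sizes, 10))
    c(mu_s, mu_w)
  }, numeric(2))
  expect_gte(median(pairs[1, ]), median(pairs[2, ]))
})

test_that("bootstrap balances replicates to five per strain", {
  tab <- tibble::tibble(strain = c("a", rep("b", 7)),
                        replicate = c(1, 1:7),
                        mu_A = c(0.5, rnorm(7, 1)),
                        tau_A = c(10, rnorm(7, 20)))
  bt <- bootstrap_traits(tab, target_n = 5, seed = 1)
  expect_equal(unname(table(bt$strain)), array(c(5L, 5L)))
  expect_true(all(bt$mu_A[bt$strain == "a"] == 0.5))  # 1 replicate -> copies
  # joint resampling keeps trait pairs from the same replicate row
  rows_b <- bt[bt$strain == "b", c("mu_A", "tau_A")]
  orig_b <- tab[tab$strain == "b", c("mu_A", "tau_A")]
  expect_true(all(apply(rows_b, 1, function(r)
    any(abs(orig_b$mu_A - r[1]) < 1e-12 &
          abs(orig_b$tau_A - r[2]) < 1e-12))))
})

test_that("bootstrap means are consistent with the replicate mean", {
  tab <- tibble::tibble(strain = "s", replicate = 1:8,
                        mu_A = c(1, 4, 2, 6, 3, 5, 2, 4))
  m <- vapply(1:2000, function(b)
    mean(bootstrap_traits(tab, seed = b)$mu_A), numeric(1))
  se_mc <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - mean(tab$mu_A)), 3 * se_mc)
})
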