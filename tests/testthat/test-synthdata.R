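test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_worms = 0), "n_worms")
  expect_error(sim_config(patch_radius = 600, arena_radius = 500),
               "patch_radius")
  expect_error(sim_config(leave_rate = 1.5), "leave_rate")
  expect_error(sim_config(duration = 0), "positive")
  expect_error(sim_config(frame_rate = -1), "positive")
  expect_error(sim_config(speed_single = -1), "non-negative")
})

test_that("ground-truth partitions are exact set partitions every frame", {
  truth <- simulate_worms(tiny_sim(n = 10, seconds = 15, seed = 3))
  n <- 10
  for (f in unique(truth$frame)) {
    fr <- truth[truth$frame == f, ]
    expect_setequal(fr$worm_id, seq_len(n))
    expect_equal(sum(table(fr$cluster_id)), n)
  }
})

test_that("no interaction regime keeps every frame all-singletons", {
  cfg <- sim_config(n_worms = 6, arena_radius = 80, patch_radius = 40,
                    duration = 10, join_radius = 0, leave_rate = 1,
                    rng_seed = 2)
  truth <- simulate_worms(cfg)
  ts <- truth_frame_sizes(truth)
  expect_true(all(vapply(ts$sizes, function(s) all(s == 1), logical(1))))
})

test_that("strong adhesion reaches the single-cluster absorbing state", {
  cfg <- sim_config(n_worms = 6, arena_radius = 60, patch_radius = 30,
                    duration = 45, join_radius = 150, leave_rate = 0,
                    rng_seed = 4)
  truth <- simulate_worms(cfg)
  last <- truth_frame_sizes(truth)$sizes
  expect_equal(last[[length(last)]], 6)
})

test_that("identical seeds give identical simulations", {
  cfg <- tiny_sim(n = 6, seconds = 6, seed = 11)
  expect_identical(simulate_worms(cfg), simulate_worms(cfg))
})

test_that("rendering draws each ground-truth cluster as one component", {
  cfg <- tiny_sim(n = 8, seconds = 10, seed = 5)
  truth <- simulate_worms(cfg)
  frames <- sort(unique(truth$frame))
  check <- frames[seq(1, length(frames), by = 7)]
  imgs <- render_frames(truth, cfg, frames = check)
  ts <- truth_frame_sizes(truth)
  for (i in seq_along(check)) {
    lab <- cpp_label8(imgs[[i]], 1)
    expect_equal(length(lab$area),
                 length(ts$sizes[[match(check[i], ts$frame)]]),
                 info = paste("frame", check[i]))
  }
})

test_that("well-separated singles render with the nominal area", {
  cfg <- sim_config(n_worms = 5, arena_radius = 100, patch_radius = 90,
                    duration = 1, join_radius = 0, rng_seed = 6)
  truth <- simulate_worms(cfg)
  img <- render_frames(truth, cfg, frames = 1)[[1]]
  a1 <- single_worm_area(cfg)
  lab <- cpp_label8(img, 1)
  expect_length(lab$area, 5)
  expect_true(all(abs(lab$area - a1) / a1 < 0.2))
  # cross-check the component count with an independent labeller where
  # 4- and 8-connectivity agree (well-separated solid shapes)
  skip_if_no("EBImage")
  expect_equal(max(EBImage::bwlabel(img)), 5)
})

test_that("rendering refuses an image too small for the arena", {
  cfg <- tiny_sim(n = 2, seconds = 1)
  truth <- simulate_worms(cfg)
  expect_error(render_frames(truth, cfg, frames = 1, dim = c(20, 20)),
               "too small")
})

test_that("trait simulator honors its variance structure", {
  tab0 <- simulate_traits(6, 4, sigma_u2 = 1, sigma_e2 = 0, seed = 1)
  spread <- tapply(tab0$value, tab0$strain, function(v) diff(range(v)))
  expect_true(all(spread == 0))       # no residual variance
  expect_equal(attr(simulate_traits(5, 2, 1, 1), "true_H2"), 0.5)
  expect_error(simulate_traits(4, 2, kinship = matrix(c(1, 2, 2, 1), 2)),
               "n_strains")
  bad <- matrix(c(1, 2, 2, 1), 2)     # indefinite
  expect_error(simulate_traits(2, 2, kinship = bad), "semidefinite")
})

test_that("strain-mean variance shrinks to sigma_e2/reps when sigma_u2 = 0", {
  # Monte Carlo over seeds: Var(strain means) -> sigma_e2 / reps
  reps <- 4
  v <- vapply(1:300, function(s) {
    tab <- simulate_traits(8, reps, sigma_u2 = 0, sigma_e2 = 2, seed = s)
    var(tapply(tab$value, tab$strain, mean))
  }, numeric(1))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 2 / reps), 3 * se)
})

test_that("genotype simulator produces reproducible homozygous dosages", {
  g <- simulate_genotypes(12, 40, seed = 3)
  expect_true(all(g %in% c(0, 2)))
  expect_identical(g, simulate_genotypes(12, 40, seed = 3))
  expect_error(simulate_genotypes(5, 0), "n_snps")
  # law of large numbers at maf 0.5
  g2 <- simulate_genotypes(4000, 5, maf_range = c(0.5, 0.5), seed = 4)
  se <- sqrt(0.5 * 0.5 * 4) / sqrt(4000)
  expect_true(all(abs(colMeans(g2) - 1) < 3 * se))
})

test_that("trait simulator heritability converges across seeds", {
  # across many seeds, Var(u)/Var(total) approaches the nominal H2
  ratio <- vapply(1:400, function(s) {
    tab <- simulate_traits(10, 3, 1, 1, seed = 7000 + s)
    mu <- tapply(tab$value, tab$strain, mean)
    vu <- var(mu) - var(tab$value - mu[tab$strain]) / 3
    vu / var(tab$value)
  }, numeric(1))
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 0.5), 3 * se + 0.02)
})
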