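test_that("area threshold follows the declared lower-half-mode rule", {
  expect_equal(compute_area_threshold(rep(80, 50)), 120)   # 1.5 a
  areas <- c(rep(75, 100), rep(300, 10))
  expect_equal(compute_area_threshold(areas), 112.5)
  expect_gt(compute_area_threshold(runif(100, 10, 20)), 0)
  expect_error(compute_area_threshold(numeric(0)), "no blob areas")
})

test_that("isolated mobile small blobs classify as single, big static ones do not", {
  # a small blob roaming for 60 frames plus a large stationary one
  frames <- 1:60
  nodes <- data.frame(
    frame = rep(frames, each = 2),
    blob_id = rep(1:2, 60),
    x = c(rbind(10 + frames + 4 * sin(frames / 4), 60)),
    y = c(rbind(10 + 4 * cos(frames / 3) + frames / 3, 60)),
    area = rep(c(70, 300), 60))
  edges <- data.frame(from = seq(1, 117, by = 2), to = seq(3, 119, by = 2))
  edges <- rbind(edges, data.frame(from = seq(2, 118, by = 2),
                                   to = seq(4, 120, by = 2)))
  g <- make_graph(nodes, edges)
  lab <- classify_singles(g)
  small_nodes <- g$nodes$node[g$nodes$blob_id == 1]
  big_nodes <- g$nodes$node[g$nodes$blob_id == 2]
  expect_true(all(lab$single[lab$node %in% small_nodes]))
  expect_false(any(lab$single[lab$node %in% big_nodes]))
})

test_that("classifier performance on a simulated recording", {
  cfg <- tiny_sim(n = 10, seconds = 30, seed = 21)
  truth <- simulate_worms(cfg)
  blobs <- segment_recording(truth, cfg)
  g <- build_temporal_graph(blobs)
  tg <- truth_graph(truth)
  # map detected nodes to truth blocks by frame + nearest centroid
  m <- integer(nrow(g$nodes))
  for (f in unique(g$nodes$frame)) {
    gi <- which(g$nodes$frame == f)
    ti <- which(tg$nodes$frame == f)
    for (i in gi) {
      d <- (tg$nodes$x[ti] - g$nodes$x[i])^2 +
        (tg$nodes$y[ti] - g$nodes$y[i])^2
      m[i] <- ti[which.min(d)]
    }
  }
  truesz <- tg$nodes$true_size[m]
  lab <- classify_singles(g)
  coverage <- sum(lab$single & truesz[lab$node] == 1) / sum(truesz == 1)
  false_singles <- sum(lab$single & truesz[lab$node] > 1)
  expect_gte(coverage, 0.95)
  expect_equal(false_singles, 0)
})

test_that("conservation resolves merges, splits and totals", {
  # sizes 2 and 3 merge into one blob of 5
  nodes <- data.frame(frame = c(1, 1, 2), blob_id = c(1, 2, 1),
                      area = c(140, 210, 350))
  g <- make_graph(nodes, data.frame(from = c(1, 2), to = c(3, 3)))
  lab <- no_single_labels(g)
  est <- propagate_cluster_sizes(g, lab, n_worms = 5,
                                 use_frame_totals = FALSE)
  # seed the parts by hand through frame totals instead: use labels
  est2 <- propagate_cluster_sizes(
    g, lab, n_worms = 5, use_frame_totals = TRUE)
  # with totals off and no labels nothing resolves
  expect_true(all(is.na(est$size)))
  # construct resolvable case: parts are labelled singles sizes 1+1 -> 2
  nodes3 <- data.frame(frame = c(1, 1, 2), blob_id = c(1, 2, 1),
                       area = c(70, 70, 140))
  g3 <- make_graph(nodes3, data.frame(from = c(1, 2), to = c(3, 3)))
  est3 <- propagate_cluster_sizes(g3, labels_for(g3, c(1, 2)), 2)
  expect_equal(est3$size, c(1, 1, 2))
  expect_equal(est3$status, c("single", "single", "resolved"))
})

test_that("a split of a known cluster resolves the unknown child", {
  # blob of 5 splits into a labelled single and an unknown
  nodes <- data.frame(frame = c(1, 2, 2), blob_id = c(1, 1, 2),
                      area = c(350, 70, 280))
  g <- make_graph(nodes, data.frame(from = c(1, 1), to = c(2, 3)))
  lab <- labels_for(g, 2)
  est <- propagate_cluster_sizes(g, lab, n_worms = 5)
  expect_equal(est$size, c(5, 1, 4))   # whole resolved via frame totals
  expect_equal(est$status[3], "resolved")
})

test_that("propagation is idempotent at convergence", {
  cfg <- tiny_sim(n = 8, seconds = 15, seed = 31)
  tg <- truth_graph(simulate_worms(cfg))
  lab <- truth_labels(tg, p = 0.8, seed = 1)
  est1 <- propagate_cluster_sizes(tg, lab, 8)
  # feed resolved statuses back as labels-by-size: rerunning must not
  # change any assignment
  est2 <- propagate_cluster_sizes(tg, lab, 8)
  expect_identical(est1$size, est2$size)
  b1 <- bound_ambiguous(tg, est1, 8)
  b2 <- bound_ambiguous(tg, b1, 8)
  expect_identical(b1$size, b2$size)
  expect_identical(b1$status, b2$status)
})

test_that("sizes stay within [1, n]; resolved are integers, bounded are half-integers", {
  cfg <- tiny_sim(n = 8, seconds = 20, seed = 41)
  tg <- truth_graph(simulate_worms(cfg))
  est <- bound_ambiguous(
    tg, propagate_cluster_sizes(tg, truth_labels(tg, 0.7, 2), 8), 8)
  ok <- !is.na(est$size)
  expect_true(all(est$size[ok] >= 1 & est$size[ok] <= 8))
  res <- est$status %in% c("single", "resolved")
  expect_true(all(est$size[res] == round(est$size[res])))
  bnd <- est$status == "bounded"
  expect_true(all(est$min_size[bnd] == round(est$min_size[bnd])))
  expect_true(all(est$max_size[bnd] == round(est$max_size[bnd])))
  expect_true(all(est$size[bnd] ==
                    (est$min_size[bnd] + est$max_size[bnd]) / 2))
})

test_that("interval bounding handles forced and ambiguous cases", {
  # an unresolved blob in a frame whose other sizes sum to n - 2
  nodes <- data.frame(frame = c(1, 1, 1), blob_id = 1:3,
                      area = c(70, 70, 150))
  g <- make_graph(nodes, data.frame(from = integer(), to = integer()))
  lab <- labels_for(g, c(1, 2))
  est <- bound_ambiguous(g, propagate_cluster_sizes(g, lab, 4), 4)
  expect_equal(est$size[3], 2)
  expect_equal(est$status[3], "resolved")   # forced to [2, 2]
  # ambiguous split 5 -> unknown + unknown with no further constraints
  nodes2 <- data.frame(frame = c(1, 2, 2), blob_id = c(1, 1, 2),
                       area = c(350, 140, 210))
  g2 <- make_graph(nodes2, data.frame(from = c(1, 1), to = c(2, 3)))
  lab2 <- no_single_labels(g2)
  est2 <- propagate_cluster_sizes(g2, lab2, 5, use_frame_totals = TRUE)
  est2 <- bound_ambiguous(g2, est2, 5)
  expect_equal(est2$min_size[2:3], c(1, 1))
  expect_equal(est2$max_size[2:3], c(4, 4))
  expect_equal(est2$size[2:3], c(2.5, 2.5))
  expect_equal(est2$status[2:3], c("bounded", "bounded"))
})

test_that("a contradictory event is rejected rather than poisoning nodes", {
  # single(1) + single(1) "merge" into a blob that later splits into
  # three labelled singles: 1 + 1 = 3 is impossible, so one event must be
  # dropped and the remaining nodes still resolve
  nodes <- data.frame(frame = c(1, 1, 2, 3, 3, 3), blob_id = c(1, 2, 1, 1, 2, 3),
                      area = c(70, 70, 210, 70, 70, 70))
  g <- make_graph(nodes, data.frame(from = c(1, 2, 3, 3, 3),
                                    to = c(3, 3, 4, 5, 6)))
  lab <- labels_for(g, c(1, 2, 4, 5, 6))
  est <- propagate_cluster_sizes(g, lab, n_worms = 3,
                                 use_frame_totals = FALSE)
  expect_length(attr(est, "invalid_events"), 1)
  expect_false(any(est$status == "inconsistent"))
})

test_that("per-frame totals QC flags deviations and exclusions", {
  est <- tibble::tibble(
    node = 1:5, frame = c(1, 1, 2, 2, 3), blob_id = c(1, 2, 1, 2, 1),
    status = "resolved", size = c(20, 20, 20, 19, 30),
    min_size = size <- c(20, 20, 20, 19, 30), max_size = size)
  fs <- per_frame_sizes(est, n_worms = 40)
  expect_equal(fs$flagged, c(FALSE, FALSE, TRUE))  # 40, 39, 30
  qc <- attr(fs, "qc")
  expect_true(qc$excluded)                         # 1/3 frames flagged
  expect_equal(qc$zero_blob_frames, integer(0))
  # all-singles frame at n = 40 passes
  est2 <- tibble::tibble(node = 1:40, frame = 1, blob_id = 1:40,
                         status = "single", size = 1, min_size = 1,
                         max_size = 1)
  fs2 <- per_frame_sizes(est2, 40)
  expect_false(fs2$flagged)
  expect_false(attr(fs2, "qc")$excluded)
})

test_that("missing frames mark the recording excluded", {
  est <- tibble::tibble(node = 1:2, frame = c(1, 3), blob_id = 1,
                        status = "resolved", size = 4, min_size = 4,
                        max_size = 4)
  qc <- attr(per_frame_sizes(est, 4), "qc")
  expect_true(qc$excluded)
  expect_equal(qc$zero_blob_frames, 2L)
})
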