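# Shared fixture builders; everything is generated in code at test time.

# A small, quick simulation: n worms on a compact arena for `seconds` of
# recording at the standard effective frame rate.
tiny_sim <- function(n = 8, seconds = 12, seed = 1, leave_rate = 0.02, ...) {
  sim_config(n_worms = n, arena_radius = 40 + 10 * n,
             patch_radius = 20 + 5 * n, duration = seconds,
             leave_rate = leave_rate, rng_seed = seed, ...)
}

# Hand-built blob graph from a frame/blob/area table plus an explicit edge
# list; boundary sets are single points at the centroid so linking-based
# code is bypassed.
make_graph <- function(nodes_df, edges_df) {
  nodes <- tibble::tibble(
    node = seq_len(nrow(nodes_df)),
    frame = nodes_df$frame,
    blob_id = nodes_df$blob_id,
    x = nodes_df$x %||% 0, y = nodes_df$y %||% 0,
    area = nodes_df$area %||% NA_real_)
  edges <- tibble::tibble(from = edges_df$from, to = edges_df$to,
                          link_distance = 0)
  wormagg:::new_blob_graph(nodes, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

no_single_labels <- function(graph) {
  tibble::tibble(node = graph$nodes$node, single = FALSE)
}

labels_for <- function(graph, single_nodes) {
  tibble::tibble(node = graph$nodes$node,
                 single = graph$nodes$node %in% single_nodes)
}

# Ground-truth labels for a truth_graph: every true singleton node is
# single with probability p (seeded), mimicking classifier output.
truth_labels <- function(tg, p = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(node = tg$nodes$node,
                 single = tg$nodes$true_size == 1 &
                   stats::runif(nrow(tg$nodes)) <= p)
}

# Exact-multiset recovery of a cluster-size result against ground truth.
recovery_rate <- function(frame_sizes, truth) {
  ts <- truth_frame_sizes(truth)
  mean(vapply(seq_len(nrow(frame_sizes)), function(i) {
    identical(as.numeric(frame_sizes$sizes[[i]]),
              as.numeric(ts$sizes[[match(frame_sizes$frame[i], ts$frame)]]))
  }, logical(1)))
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
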