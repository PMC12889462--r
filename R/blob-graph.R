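new_blob_graph <- function(nodes, edges) {
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  nodes$in_degree <- tabulate(edges$to, nbins = nrow(nodes))
  nodes$out_degree <- tabulate(edges$from, nbins = nrow(nodes))
  structure(list(nodes = nodes, edges = edges), class = "blob_graph")
}

#' @export
print.blob_graph <- function(x, ...) {
  cat("<blob_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, frames ", min(x$nodes$frame), "-", max(x$nodes$frame),
      "\n", sep = "")
  invisible(x)
}

#' Build the temporal blob graph
#'
#' Links blobs of consecutive frames whenever the minimum distance between
#' their pixel sets is at most `max_link_distance`, forming a DAG ordered by
#' frame. Nodes with in-degree > 1 are merge events; nodes with
#' out-degree > 1 feed split events. Distances are computed between boundary
#' pixels only (identical minima for filled components) with a bounding-box
#' prefilter.
#'
#' A glancing pass between two separate worms can create a crossing edge
#' whose distance is far above both blobs' genuine (overlapping) links.
#' Such edges are pruned by link dominance: an edge is dropped when *both*
#' of its endpoints have another link closer by more than `prune_slack`
#' px. Genuine split and merge edges always survive, because the departing
#' or arriving blob has no closer alternative on its side.
#'
#' @param blobs Blob tibble from [segment_frames()] / [detect_blobs()]
#'   (columns `frame`, `blob_id`, `x`, `y`, `area`, `boundary`).
#' @param max_link_distance Maximum linking distance in px (default 15,
#'   one worm body length: wide enough to catch the displaced blob of a
#'   worm leaving or joining a cluster between consecutive analysed
#'   frames, while crossing links between unrelated blobs are removed by
#'   pruning).
#' @param prune_slack Dominance margin in px for crossing-edge pruning
#'   (default 4; `Inf` disables pruning).
#' @return A `blob_graph`: list with a `nodes` tibble (`node`, `frame`,
#'   `blob_id`, `x`, `y`, `area`, degrees) and an `edges` tibble (`from`,
#'   `to`, `link_distance`).
#' @export
build_temporal_graph <- function(blobs, max_link_distance = 15,
                                 prune_slack = 4) {
  if (max_link_distance <= 0)
    stop("max_link_distance must be positive", call. = FALSE)
  blobs <- dplyr::arrange(blobs, .data$frame, .data$blob_id)
  blobs$node <- seq_len(nrow(blobs))
  frames <- sort(unique(blobs$frame))
  if (length(frames) > 1 && any(diff(frames) != 1))
    warning("gaps in frame numbering; gap frames treated as missing")
  by_frame <- split(seq_len(nrow(blobs)), blobs$frame)
  edges <- vector("list", length(frames))
  for (i in seq_len(length(frames) - 1L)) {
    if (frames[i + 1L] - frames[i] != 1L) next
    ia <- by_frame[[as.character(frames[i])]]
    ib <- by_frame[[as.character(frames[i + 1L])]]
    if (length(ia) == 0 || length(ib) == 0) next
    e <- cpp_min_dist_edges(blobs$boundary[ia], blobs$boundary[ib],
                            max_link_distance)
    if (nrow(e) > 0) {
      edges[[i]] <- tibble::tibble(from = ia[e$from], to = ib[e$to],
                                   link_distance = e$dist)
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0)
    edges <- tibble::tibble(from = integer(), to = integer(),
                            link_distance = numeric())
  if (nrow(edges) > 0 && is.finite(prune_slack)) {
    min_out <- tapply(edges$link_distance, edges$from, min)
    min_in <- tapply(edges$link_distance, edges$to, min)
    dom <- edges$link_distance >
      min_out[as.character(edges$from)] + prune_slack &
      edges$link_distance > min_in[as.character(edges$to)] + prune_slack
    edges <- edges[!dom, , drop = FALSE]
  }
  nodes <- blobs %>%
    dplyr::select("node", "frame", "blob_id", "x", "y", "area",
                  dplyr::any_of(c("boundary", "true_size")))
  new_blob_graph(nodes, edges)
}

# Area of the convex hull around a set of points (shoelace on chull).
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  px <- pts[h, 1]; py <- pts[h, 2]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' Extract track segments from a temporal blob graph
#'
#' A track segment is a maximal chain of nodes connected by unambiguous
#' links (edges whose source has out-degree 1 and whose target has in-degree
#' 1), i.e. a stretch of a blob's life with no splits or merges. Each
#' segment's trajectory hull area (convex hull of its centroids) measures
#' spatial extent: single worms roam and accumulate large hulls, while
#' multi-worm clusters are nearly stationary.
#'
#' @param graph A `blob_graph`.
#' @return A tibble with one row per segment: `segment_id`, `nodes`
#'   (list-column of node ids in frame order), `n_frames`, `hull_area`,
#'   `extent` (bounding-box diagonal of the trajectory, px),
#'   `median_area`, `max_in_degree`, `max_out_degree` (plus the
#'   internal-node variants of the degree maxima).
#' @export
track_segments <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  n <- nrow(nodes)
  chain <- edges[nodes$out_degree[edges$from] == 1 &
                 nodes$in_degree[edges$to] == 1, , drop = FALSE]
  nxt <- rep(NA_integer_, n)
  prv <- rep(NA_integer_, n)
  nxt[chain$from] <- chain$to
  prv[chain$to] <- chain$from
  starts <- which(is.na(prv))
  seg_of <- rep(NA_integer_, n)
  seg_nodes <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    path <- integer(0)
    cur <- starts[s]
    while (!is.na(cur)) {
      path <- c(path, cur)
      seg_of[cur] <- s
      cur <- nxt[cur]
    }
    seg_nodes[[s]] <- path
  }
  hulls <- vapply(seg_nodes, function(p)
    hull_area(nodes$x[p], nodes$y[p]), numeric(1))
  extents <- vapply(seg_nodes, function(p)
    sqrt(diff(range(nodes$x[p]))^2 + diff(range(nodes$y[p]))^2), numeric(1))
  med_area <- vapply(seg_nodes, function(p)
    median(nodes$area[p]), numeric(1))
  max_in <- vapply(seg_nodes, function(p)
    max(nodes$in_degree[p]), numeric(1))
  max_out <- vapply(seg_nodes, function(p)
    max(nodes$out_degree[p]), numeric(1))
  internal <- function(p) if (length(p) > 2) p[-c(1, length(p))] else integer(0)
  max_in_int <- vapply(seg_nodes, function(p) {
    q <- internal(p)
    if (length(q) == 0) 0 else max(nodes$in_degree[q])
  }, numeric(1))
  max_out_int <- vapply(seg_nodes, function(p) {
    q <- internal(p)
    if (length(q) == 0) 0 else max(nodes$out_degree[q])
  }, numeric(1))
  tibble::tibble(
    segment_id = seq_along(seg_nodes),
    nodes = seg_nodes,
    n_frames = lengths(seg_nodes),
    hull_area = hulls,
    extent = extents,
    median_area = med_area,
    max_in_degree = max_in,
    max_out_degree = max_out,
    max_internal_in_degree = max_in_int,
    max_internal_out_degree = max_out_int)
}
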