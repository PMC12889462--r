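#' Dynamic single-worm area threshold
#'
#' Threshold separating single-worm blobs from multi-worm clusters,
#' computed as `factor` times the mode of the blob-area histogram restricted
#' to the lower half of the observed area range. Single worms dominate that
#' lower half, so its mode tracks the typical single-worm area without any
#' calibration input.
#'
#' @param areas Numeric vector of blob areas (px^2), or a blob tibble with
#'   an `area` column.
#' @param factor Multiplier on the modal area (default 1.5).
#' @param bins Number of histogram bins over the lower half (default 30).
#' @return A positive scalar threshold in px^2.
#' @export
compute_area_threshold <- function(areas, factor = 1.5, bins = 30) {
  if (is.data.frame(areas)) areas <- areas$area
  areas <- areas[is.finite(areas)]
  if (length(areas) == 0) stop("no blob areas supplied", call. = FALSE)
  rng <- range(areas)
  lower <- areas[areas <= rng[1] + diff(rng) / 2]
  if (diff(range(lower)) < sqrt(.Machine$double.eps)) {
    mode_area <- lower[1]
  } else {
    br <- seq(min(lower), max(lower), length.out = bins + 1)
    h <- graphics::hist(lower, breaks = br, plot = FALSE)
    mode_area <- h$mids[which.max(h$counts)]
  }
  factor * mode_area
}

# Split/merge conservation events of a temporal graph. Worms move only
# along temporal edges, so within every connected component of the
# edge graph between frames t and t+1 the worm counts are conserved:
# sum(sizes of the component's frame-t blobs) = sum(sizes of its
# frame-(t+1) blobs). A plain merge gives the classic "whole = sum of
# parts" equation; crossing events (e.g. a worm transferring between
# clusters in one step) still yield the valid component-sum constraint.
# 1-1 components are unambiguous links, handled as identity chains.
# Events are returned in deterministic (frame, blob_id) order with
# `left` = frame-t node ids and `right` = frame-(t+1) node ids.
graph_events <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  ev <- list()
  if (nrow(edges) == 0) return(ev)
  ef <- nodes$frame[edges$from]
  for (f in sort(unique(ef))) {
    sub <- edges[ef == f, , drop = FALSE]
    ids <- sort(unique(c(sub$from, sub$to)))
    parent <- seq_along(ids)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(sub))) {
      a <- find(match(sub$from[k], ids))
      b <- find(match(sub$to[k], ids))
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_along(ids), find, integer(1))
    for (cmp in split(ids, roots)) {
      if (length(cmp) < 3) next          # 1-1 links are identity chains
      ev[[length(ev) + 1L]] <- list(
        left = cmp[nodes$frame[cmp] == f],
        right = cmp[nodes$frame[cmp] == f + 1L])
    }
  }
  ev
}

# Union-find collapse of identity chains (out-degree-1 -> in-degree-1
# edges): all nodes of one chain hold the same worm count, so sizes are
# estimated per chain component. Components never contain two nodes of the
# same frame.
identity_components <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  n <- nrow(nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chain <- edges[nodes$out_degree[edges$from] == 1 &
                 nodes$in_degree[edges$to] == 1, , drop = FALSE]
  if (nrow(chain) > 0) {
    for (k in seq_len(nrow(chain))) {
      a <- find(chain$from[k]); b <- find(chain$to[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify single worms by iterative thresholding
#'
#' Labels a track segment as a single worm iff (a) more than a `majority`
#' fraction of its frames have blob area below the dynamic area threshold,
#' (b) every internal node of the segment has in- and out-degree at most
#' `degree_max` (a track may begin or end at a split/merge event -- a
#' single typically ends its track by joining a cluster -- but may not
#' contain one), and (c) its trajectory hull area is at least
#' `hull_min * min(1, n_frames / hull_ref_frames)` (the mobility
#' criterion: single worms roam and accrue hull one to two orders of
#' magnitude faster than near-stationary clusters, so the requirement
#' ramps linearly for tracks shorter than `hull_ref_frames` and is
#' absolute beyond it).
#' Classification iterates: after each pass the area threshold is
#' recomputed from the still-unlabelled blobs, until the label set is
#' stable or `max_iter` passes.
#'
#' @param graph A `blob_graph`.
#' @param threshold_factor Multiplier for [compute_area_threshold()].
#' @param hull_min Minimum trajectory hull area in px^2; default 1.5 x the
#'   modal single-worm area (even a few dozen frames of single-worm
#'   roaming exceed the body area, while a near-stationary cluster accrues
#'   hull far more slowly than it accrues blob area).
#' @param degree_max Maximum node degree for a single segment (default 1).
#' @param majority Fraction of below-threshold frames required (default 0.5,
#'   strict).
#' @param max_iter Iteration cap (default 10).
#' @param hull_ref_frames Track length (frames) beyond which the full
#'   `hull_min` is required (default 150, i.e. 18 s at 8.33 Hz).
#' @return A tibble `node`, `segment_id`, `single` (logical), with the
#'   final `threshold`, `hull_min` and iteration count as attributes.
#' @export
classify_singles <- function(graph, threshold_factor = 1.5, hull_min = NULL,
                             degree_max = 1, majority = 0.5, max_iter = 10,
                             hull_ref_frames = 150) {
  nodes <- graph$nodes
  segs <- track_segments(graph)
  if (is.null(hull_min))
    hull_min <- 1.5 * compute_area_threshold(nodes$area, 1) # 1.5 x modal area
  single_seg <- rep(FALSE, nrow(segs))
  # tracks of <= 5 frames carry no usable trajectory-extent signal (a hull
  # of a handful of 1-px steps is degenerate); for them the area-majority
  # and degree criteria decide alone, and the hull requirement ramps in
  # with track length
  hull_req <- hull_min *
    pmin(1, pmax(0, segs$n_frames - 5) / hull_ref_frames)
  # a near-straight run has a degenerate hull however fast the worm
  # travels, so short tracks may alternatively show mobility through
  # their trajectory extent (bounding-box diagonal), which grows with
  # single-worm speed but stays near zero for drifting clusters
  mobile <- segs$hull_area >= hull_req |
    (segs$n_frames <= hull_ref_frames &
       segs$extent >= 3 + 0.25 * segs$n_frames)
  eligible <- segs$max_internal_in_degree <= degree_max &
    segs$max_internal_out_degree <= degree_max & mobile
  thr <- compute_area_threshold(nodes$area, threshold_factor)
  it <- 0L
  repeat {
    it <- it + 1L
    unlab <- unlist(segs$nodes[!single_seg])
    # recompute from the still-unlabelled blobs, but never upward: once
    # most singles are labelled the unlabelled area mode drifts to the
    # two-worm cluster area, which must not re-target the threshold
    thr <- min(thr, compute_area_threshold(nodes$area[unlab],
                                           threshold_factor))
    # tracks of <= 5 frames carry no mobility evidence, so they face a
    # stricter area bar: the midpoint between the modal single area and
    # the standard threshold, keeping boundary-area cluster fragments out
    thr_seg <- ifelse(segs$n_frames <= 5, thr * 5 / 6, thr)
    below <- vapply(seq_len(nrow(segs)), function(i)
      mean(nodes$area[segs$nodes[[i]]] < thr_seg[i]), numeric(1))
    new_single <- eligible & below > majority
    if (all(new_single == single_seg) || it >= max_iter ||
        all(new_single)) {
      single_seg <- new_single
      break
    }
    single_seg <- new_single
  }
  lab <- tibble::tibble(
    node = unlist(segs$nodes),
    segment_id = rep(segs$segment_id, segs$n_frames))
  lab <- dplyr::arrange(lab, .data$node)
  lab$single <- single_seg[lab$segment_id]
  attr(lab, "threshold") <- thr
  attr(lab, "hull_min") <- hull_min
  attr(lab, "iterations") <- it
  lab
}

#' Propagate cluster sizes through split/merge conservation constraints
#'
#' Iteratively resolves worm counts on the temporal graph: labelled singles
#' start at size 1; sizes pass unchanged along unambiguous links; at every
#' split or merge event where all participating groups but one are
#' resolved, the remaining size follows from conservation (the worm count
#' of the whole equals the sum of its parts); optionally, within each frame
#' the totals constraint (sizes sum to `n_worms`) resolves a last unknown
#' blob. Iteration stops at a fixpoint or after `max_iter` sweeps.
#'
#' A conservation contradiction (an implied size below one, or resolved
#' sizes that violate an event equation) indicates a defective input.
#' When conservation implies a size other than one for a labelled single,
#' the classifier label is the weaker evidence and is revoked; otherwise
#' the offending event is discarded. Either way propagation restarts, and
#' the rejections are logged in the `"invalid_events"` and
#' `"revoked_singles"` attributes. Contradictions arising from the frame
#' totals flag the node itself as inconsistent and exclude it from
#' resolution.
#'
#' @param graph A `blob_graph`.
#' @param labels Output of [classify_singles()] (or any tibble with `node`
#'   and logical `single`).
#' @param n_worms Total worm count in the arena.
#' @param max_iter Sweep cap per propagation pass (default 100).
#' @param max_restarts Cap on constraint-rejection restarts (default 50).
#' @param use_frame_totals Use the per-frame totals constraint (default
#'   `TRUE`; disable to propagate from event conservation only).
#' @return A `size_estimates` tibble: `node`, `frame`, `blob_id`, `status`
#'   (`single`, `resolved`, `unknown` or `inconsistent`), `size`,
#'   `min_size`, `max_size`.
#' @export
propagate_cluster_sizes <- function(graph, labels, n_worms, max_iter = 100,
                                    max_restarts = 50,
                                    use_frame_totals = TRUE) {
  nodes <- graph$nodes
  comp <- identity_components(graph)
  nc <- max(comp)
  single_nodes <- labels$node[labels$single]
  single_comps <- unique(comp[single_nodes])

  events <- graph_events(graph)
  ev_left <- lapply(events, function(e) comp[e$left])
  ev_right <- lapply(events, function(e) comp[e$right])
  frame_comps <- lapply(split(comp, nodes$frame), unique)
  invalid <- rep(FALSE, length(events))

  restarts <- 0L
  revoked <- integer(0)
  repeat {
    csize <- rep(NA_real_, nc)
    cstat <- rep("unknown", nc)
    active_singles <- setdiff(single_comps, revoked)
    csize[active_singles] <- 1
    cstat[active_singles] <- "single"
    conflict <- NA_integer_
    revoke <- NA_integer_
    it <- 0L
    repeat {
      it <- it + 1L
      changed <- FALSE
      for (k in seq_along(events)) {
        if (invalid[k]) next
        lc <- ev_left[[k]]; rc <- ev_right[[k]]
        ids <- c(lc, rc)
        if (any(cstat[ids] == "inconsistent")) next
        vals <- csize[ids]
        nas <- which(is.na(vals))
        if (length(nas) == 1) {
          # conservation: sum(left) = sum(right); signed gap solves the
          # one remaining unknown on either side
          sgn <- c(rep(1, length(lc)), rep(-1, length(rc)))
          v <- -sgn[nas] * sum(sgn[-nas] * vals[-nas])
          cc <- ids[nas]
          if (cstat[cc] == "single" && v != 1 && v >= 1 &&
              v == round(v)) {
            # conservation and a single label disagree: the label is the
            # softer evidence
            revoke <- cc
            break
          }
          if (v < 1 || v != round(v)) {
            conflict <- k
            break
          }
          csize[cc] <- v
          if (cstat[cc] != "single") cstat[cc] <- "resolved"
          changed <- TRUE
        } else if (length(nas) == 0) {
          if (sum(csize[lc]) != sum(csize[rc])) {
            conflict <- k
            break
          }
        }
      }
      if (!is.na(conflict) || !is.na(revoke)) break
      if (use_frame_totals) {
        for (f in seq_along(frame_comps)) {
          ids <- frame_comps[[f]]
          if (any(cstat[ids] == "inconsistent")) next
          vals <- csize[ids]
          nas <- which(is.na(vals))
          if (length(nas) == 1) {
            v <- n_worms - sum(vals, na.rm = TRUE)
            cc <- ids[nas]
            if (cstat[cc] == "single" && v != 1 && v >= 1) {
              revoke <- cc
              break
            }
            if (v < 1) {
              cstat[cc] <- "inconsistent"
              csize[cc] <- NA_real_
            } else {
              csize[cc] <- v
              if (cstat[cc] != "single") cstat[cc] <- "resolved"
            }
            changed <- TRUE
          }
        }
        if (!is.na(revoke)) break
      }
      if (!changed || it >= max_iter) break
    }
    if (!is.na(revoke) && restarts < max_restarts) {
      revoked <- c(revoked, revoke)
      restarts <- restarts + 1L
      next
    }
    if (!is.na(conflict) && restarts < max_restarts) {
      invalid[conflict] <- TRUE
      restarts <- restarts + 1L
      next
    }
    if (!is.na(conflict)) {
      # restart budget exhausted: flag the event's nodes instead
      cc <- c(ev_left[[conflict]], ev_right[[conflict]])
      cstat[cc] <- "inconsistent"
      csize[cc] <- NA_real_
    }
    break
  }

  status <- cstat[comp]
  size <- csize[comp]
  out <- tibble::tibble(
    node = nodes$node, frame = nodes$frame, blob_id = nodes$blob_id,
    status = status, size = size,
    min_size = ifelse(is.na(size), NA_real_, size),
    max_size = ifelse(is.na(size), NA_real_, size))
  attr(out, "component") <- comp
  attr(out, "invalid_events") <- which(invalid)
  attr(out, "revoked_singles") <- revoked
  attr(out, "restarts") <- restarts
  attr(out, "n_worms") <- n_worms
  attr(out, "use_frame_totals") <- use_frame_totals
  class(out) <- c("size_estimates", class(out))
  out
}

#' Bound and assign sizes for ambiguous clusters
#'
#' For nodes still unresolved after [propagate_cluster_sizes()], propagates
#' interval bounds `[min, max]` through the same conservation constraints
#' (event sums, unambiguous links, optional frame totals) until a fixpoint,
#' then assigns the mean of the interval endpoints. Half-integer sizes are
#' therefore possible for ambiguous clusters; averaging the extremes may
#' bias large frequently-splitting clusters upwards, a caveat recorded in
#' the `"bias_note"` attribute. Events rejected during propagation stay
#' rejected here; an event constraint that empties an interval is likewise
#' rejected and bounding restarts, while an empty interval under the frame
#' totals flags the node inconsistent.
#'
#' @param graph A `blob_graph`.
#' @param estimates Output of [propagate_cluster_sizes()].
#' @param n_worms Total worm count.
#' @param min_unresolved Lower bound assumed for an unresolved,
#'   unlabelled node (default 1; set 2 to assume the single classifier
#'   catches every true single).
#' @param max_iter Tightening sweep cap (default 1000).
#' @param max_restarts Cap on constraint-rejection restarts (default 50).
#' @param area_floor If `TRUE`, an unresolved node whose blob areas lie
#'   above the dataset's single-worm area threshold in a majority of its
#'   frames starts at a lower bound of 2 (it looks like a multi-worm
#'   cluster). Default `FALSE`: pure conservation bounds; the pipeline
#'   driver enables it.
#' @return A completed `size_estimates` tibble (no `unknown` rows except
#'   nodes flagged inconsistent).
#' @export
bound_ambiguous <- function(graph, estimates, n_worms, min_unresolved = 1,
                            max_iter = 1000, max_restarts = 50,
                            area_floor = FALSE) {
  nodes <- graph$nodes
  comp <- attr(estimates, "component")
  if (is.null(comp)) comp <- identity_components(graph)
  use_frame_totals <- isTRUE(attr(estimates, "use_frame_totals"))
  nc <- max(comp)
  cc_node <- comp[estimates$node]

  events <- graph_events(graph)
  ev_left <- lapply(events, function(e) comp[e$left])
  ev_right <- lapply(events, function(e) comp[e$right])
  frame_comps <- lapply(split(comp, nodes$frame), unique)
  invalid <- rep(FALSE, length(events))
  invalid[attr(estimates, "invalid_events")] <- TRUE

  cluster_like <- rep(FALSE, nc)
  single_like <- rep(FALSE, nc)
  if (isTRUE(area_floor) && any(is.finite(nodes$area))) {
    thr <- compute_area_threshold(nodes$area)
    above <- tapply(nodes$area >= thr, comp, mean, na.rm = TRUE)
    cluster_like[as.integer(names(above))] <- !is.na(above) & above > 0.5
    # the symmetric ceiling uses a stricter bar (midpoint between the
    # modal single area and the threshold): a blob persistently below it
    # cannot hold two worms
    tiny <- tapply(nodes$area < thr * 5 / 6, comp, mean, na.rm = TRUE)
    single_like[as.integer(names(tiny))] <- !is.na(tiny) & tiny > 0.5
  }

  restarts <- 0L
  repeat {
    cstat <- rep("unknown", nc)
    lo <- rep(NA_real_, nc)
    hi <- rep(NA_real_, nc)
    cstat[cc_node] <- estimates$status
    known <- !is.na(estimates$size)
    lo[cc_node[known]] <- estimates$size[known]
    hi[cc_node[known]] <- estimates$size[known]
    unres <- cstat == "unknown"
    lo[unres] <- min_unresolved
    lo[unres & cluster_like] <- pmax(min_unresolved, 2)
    hi[unres] <- max(n_worms - 1, min_unresolved)
    hi[unres & single_like] <- pmax(1, min_unresolved)

    conflict <- NA_integer_
    changed <- FALSE
    # returns FALSE when the interval empties
    set_interval <- function(cc, nlo, nhi) {
      nlo <- max(nlo, 0)
      nhi <- min(nhi, n_worms)
      if (nlo > nhi) return(FALSE)
      if (nlo != lo[cc] || nhi != hi[cc]) {
        lo[cc] <<- nlo
        hi[cc] <<- nhi
        changed <<- TRUE
      }
      TRUE
    }
    it <- 0L
    repeat {
      it <- it + 1L
      changed <- FALSE
      for (k in seq_along(events)) {
        if (invalid[k]) next
        lc <- ev_left[[k]]; rc <- ev_right[[k]]
        ids <- c(lc, rc)
        if (any(cstat[ids] == "inconsistent") || any(is.na(lo[ids]))) next
        # sum(left) = sum(right): each side's interval bounds the other
        llo <- sum(lo[lc]); lhi <- sum(hi[lc])
        rlo <- sum(lo[rc]); rhi <- sum(hi[rc])
        ok <- TRUE
        for (cc in lc) {
          ok <- set_interval(cc, max(lo[cc], rlo - (lhi - hi[cc])),
                             min(hi[cc], rhi - (llo - lo[cc])))
          if (!ok) break
        }
        if (ok) {
          for (cc in rc) {
            ok <- set_interval(cc, max(lo[cc], llo - (rhi - hi[cc])),
                               min(hi[cc], lhi - (rlo - lo[cc])))
            if (!ok) break
          }
        }
        if (!ok) {
          conflict <- k
          break
        }
      }
      if (!is.na(conflict)) break
      if (use_frame_totals) {
        for (f in seq_along(frame_comps)) {
          ids <- frame_comps[[f]]
          if (any(cstat[ids] == "inconsistent") || any(is.na(lo[ids]))) next
          slo <- sum(lo[ids]); shi <- sum(hi[ids])
          for (cc in ids) {
            if (!set_interval(cc, max(lo[cc], n_worms - (shi - hi[cc])),
                              min(hi[cc], n_worms - (slo - lo[cc])))) {
              cstat[cc] <- "inconsistent"
              lo[cc] <- NA_real_
              hi[cc] <- NA_real_
              changed <- TRUE
              break
            }
          }
        }
      }
      if (!changed || it >= max_iter) break
    }
    if (!is.na(conflict) && restarts < max_restarts) {
      invalid[conflict] <- TRUE
      restarts <- restarts + 1L
      next
    }
    if (!is.na(conflict)) {
      cc <- c(ev_left[[conflict]], ev_right[[conflict]])
      cstat[cc] <- "inconsistent"
      lo[cc] <- NA_real_
      hi[cc] <- NA_real_
    }
    break
  }

  out <- estimates
  bad <- cstat[cc_node] == "inconsistent"
  unk <- out$status == "unknown" & !bad
  out$status[bad] <- "inconsistent"
  out$size[bad] <- NA_real_
  out$min_size[bad] <- NA_real_
  out$max_size[bad] <- NA_real_
  out$min_size[unk] <- lo[cc_node[unk]]
  out$max_size[unk] <- hi[cc_node[unk]]
  out$size[unk] <- (lo[cc_node[unk]] + hi[cc_node[unk]]) / 2
  out$status[unk] <- ifelse(lo[cc_node[unk]] == hi[cc_node[unk]],
                            "resolved", "bounded")
  attr(out, "invalid_events") <- which(invalid)
  attr(out, "bias_note") <-
    "interval-midpoint sizes may be biased upward for large, frequently splitting/merging clusters"
  out
}

#' Per-frame size multisets and quality control
#'
#' Collects estimated sizes per frame and flags frames whose size total
#' deviates from `n_worms` by more than `tol` (relative) or that contain
#' unresolved/inconsistent nodes. The recording is marked excluded if any
#' analysed frame has zero blobs or the flagged fraction exceeds
#' `flag_cap`, mirroring the exclusion of recordings with non-continuous
#' tracking.
#'
#' @param estimates Completed `size_estimates` (after [bound_ambiguous()]).
#' @param n_worms Total worm count.
#' @param tol Relative tolerance on the per-frame size total (default 0.1).
#' @param flag_cap Maximum tolerated fraction of flagged frames (default
#'   0.05).
#' @return A `frame_sizes` tibble: `frame`, `sizes` (list-column), `total`,
#'   `n_blobs`, `flagged`; QC verdict in `attr(, "qc")`.
#' @export
per_frame_sizes <- function(estimates, n_worms, tol = 0.1, flag_cap = 0.05) {
  by_frame <- split(estimates$size, estimates$frame)
  frames_present <- as.integer(names(by_frame))
  all_frames <- seq(min(frames_present), max(frames_present))
  zero_frames <- setdiff(all_frames, frames_present)
  out <- tibble::tibble(
    frame = frames_present,
    sizes = unname(lapply(by_frame, function(s) sort(s[!is.na(s)]))),
    total = unname(vapply(by_frame, sum, numeric(1))),
    n_blobs = unname(lengths(by_frame)))
  out$flagged <- is.na(out$total) | abs(out$total - n_worms) > tol * n_worms
  flagged_fraction <- mean(out$flagged)
  excluded <- length(zero_frames) > 0 || flagged_fraction > flag_cap
  attr(out, "qc") <- list(
    excluded = excluded,
    zero_blob_frames = zero_frames,
    flagged_fraction = flagged_fraction,
    n_worms = n_worms, tol = tol, flag_cap = flag_cap)
  class(out) <- c("frame_sizes", class(out))
  out
}

#' Full cluster-size estimation from a blob table
#'
#' Convenience driver chaining [build_temporal_graph()],
#' [classify_singles()], [propagate_cluster_sizes()], [bound_ambiguous()]
#' and [per_frame_sizes()].
#'
#' @param blobs Blob tibble (from [segment_frames()] or
#'   [segment_recording()]).
#' @param n_worms Total worm count.
#' @param max_link_distance Linking radius, px (see
#'   [build_temporal_graph()]).
#' @param ... Passed to [classify_singles()].
#' @param tol,flag_cap See [per_frame_sizes()].
#' @param use_frame_totals See [propagate_cluster_sizes()].
#' @return A list of class `cluster_size_result` with elements `graph`,
#'   `labels`, `estimates`, `frame_sizes`.
#' @export
estimate_cluster_sizes <- function(blobs, n_worms, max_link_distance = 15,
                                   ..., use_frame_totals = TRUE, tol = 0.1,
                                   flag_cap = 0.05) {
  graph <- build_temporal_graph(blobs, max_link_distance)
  labels <- classify_singles(graph, ...)
  est <- propagate_cluster_sizes(graph, labels, n_worms,
                                 use_frame_totals = use_frame_totals)
  est <- bound_ambiguous(graph, est, n_worms, area_floor = TRUE)
  fs <- per_frame_sizes(est, n_worms, tol = tol, flag_cap = flag_cap)
  structure(list(graph = graph, labels = labels, estimates = est,
                 frame_sizes = fs),
            class = "cluster_size_result")
}

#' @export
print.cluster_size_result <- function(x, ...) {
  st <- table(x$estimates$status)
  qc <- attr(x$frame_sizes, "qc")
  cat("<cluster_size_result> ", nrow(x$estimates), " blobs: ",
      paste(names(st), st, sep = "=", collapse = ", "), "\n",
      "QC: ", if (qc$excluded) "EXCLUDED" else "pass",
      sprintf(" (%.1f%% frames flagged)\n", 100 * qc$flagged_fraction),
      sep = "")
  invisible(x)
}
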