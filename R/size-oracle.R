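# All compositions of `total` into `m` parts in [1, maxv]; matrix m x count.
compositions_m <- function(total, m, maxv) {
  if (m == 1) {
    if (total >= 1 && total <= maxv) return(matrix(total, 1, 1))
    return(matrix(numeric(0), 1, 0))
  }
  out <- list()
  for (v in seq_len(min(maxv, total - (m - 1)))) {
    sub <- compositions_m(total - v, m - 1, maxv)
    if (ncol(sub) > 0) out[[length(out) + 1L]] <- rbind(v, sub)
  }
  if (length(out) == 0) return(matrix(numeric(0), m, 0))
  do.call(cbind, out)
}

#' Brute-force enumeration of feasible cluster-size assignments
#'
#' Exhaustively enumerates every integer size assignment that satisfies the
#' single labels, all split/merge conservation constraints, size equality
#' along unambiguous links, and the per-frame totals constraint
#' (sizes sum to `n_worms` in every frame). Used as an independent test
#' oracle for [propagate_cluster_sizes()] and [bound_ambiguous()]; the
#' enumeration proceeds frame by frame (constraints only couple consecutive
#' frames) so small multi-frame instances stay tractable, with explicit
#' size guards.
#'
#' @param graph A `blob_graph`.
#' @param labels Tibble with `node` and logical `single` (as from
#'   [classify_singles()]).
#' @param n_worms Total worm count.
#' @param max_states Refuse if any frame admits more than this many
#'   candidate size vectors (default 20000).
#' @param max_enumerate Return explicit assignments only if their total
#'   count is at most this (default 10000); ranges and counts are always
#'   returned.
#' @return A list with `n_assignments`, `feasible` (logical), `ranges` (a
#'   tibble `node`, `min_size`, `max_size`), and `assignments` (a
#'   `n_assignments x n_nodes` matrix, or `NULL` if over
#'   `max_enumerate`).
#' @export
brute_force_size_oracle <- function(graph, labels, n_worms,
                                    max_states = 20000,
                                    max_enumerate = 10000) {
  nodes <- graph$nodes
  edges <- graph$edges
  n_nodes <- nrow(nodes)
  if (n_worms > 15) stop("instance too large for the oracle (n_worms > 15)",
                         call. = FALSE)
  frames <- sort(unique(nodes$frame))
  if (length(frames) > 300) stop("instance too large for the oracle (> 300 frames)",
                                 call. = FALSE)
  single <- rep(FALSE, n_nodes)
  single[labels$node[labels$single]] <- TRUE
  by_frame <- split(seq_len(n_nodes), nodes$frame)

  # candidate size vectors per frame (singles pinned to 1, totals = n)
  states <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    idx <- by_frame[[as.character(frames[i])]]
    m <- length(idx)
    free <- idx[!single[idx]]
    fixed_sum <- sum(single[idx])
    if (length(free) == 0) {
      states[[i]] <- if (fixed_sum == n_worms) matrix(1, m, 1) else
        matrix(numeric(0), m, 0)
      next
    }
    comp <- compositions_m(n_worms - fixed_sum, length(free), n_worms)
    if (ncol(comp) > max_states)
      stop("instance too large for the oracle (state explosion)", call. = FALSE)
    st <- matrix(1, m, ncol(comp))
    st[match(free, idx), ] <- comp
    states[[i]] <- st
  }

  # cross-frame conservation constraints: connected components of the
  # edge graph between consecutive frames conserve their worm totals
  # (local indices within each frame)
  events <- graph_events(graph)
  pair_constraints <- vector("list", max(length(frames) - 1L, 0L))
  if (length(frames) > 1) {
    for (i in seq_len(length(frames) - 1L)) pair_constraints[[i]] <- list()
    loc <- function(v) match(v, by_frame[[as.character(nodes$frame[v[1]])]])
    chain <- edges[nodes$out_degree[edges$from] == 1 &
                   nodes$in_degree[edges$to] == 1, , drop = FALSE]
    if (nrow(chain) > 0) {
      for (k in seq_len(nrow(chain))) {
        fi <- match(nodes$frame[chain$from[k]], frames)
        if (match(nodes$frame[chain$to[k]], frames) == fi + 1L)
          pair_constraints[[fi]][[length(pair_constraints[[fi]]) + 1L]] <-
            list(left = loc(chain$from[k]), right = loc(chain$to[k]))
      }
    }
    for (e in events) {
      fi <- match(nodes$frame[e$left[1]], frames)
      pair_constraints[[fi]][[length(pair_constraints[[fi]]) + 1L]] <-
        list(left = loc(e$left), right = loc(e$right))
    }
  }

  ok_transition <- function(i, sa, sb) {
    for (con in pair_constraints[[i]]) {
      if (sum(sa[con$left]) != sum(sb[con$right])) return(FALSE)
    }
    TRUE
  }

  nf <- length(frames)
  ns <- vapply(states, ncol, integer(1))
  if (any(ns == 0)) {
    return(list(n_assignments = 0, feasible = FALSE,
                ranges = tibble::tibble(node = nodes$node,
                                        min_size = NA_real_,
                                        max_size = NA_real_),
                assignments = NULL))
  }
  # forward/backward path counts over the layered transition graph
  fwd <- vector("list", nf)
  bwd <- vector("list", nf)
  trans <- vector("list", max(nf - 1L, 0L))
  fwd[[1]] <- rep(1, ns[1])
  if (nf > 1) {
    for (i in seq_len(nf - 1L)) {
      tm <- matrix(FALSE, ns[i], ns[i + 1L])
      for (a in seq_len(ns[i])) {
        sa <- states[[i]][, a]
        for (b in seq_len(ns[i + 1L])) {
          tm[a, b] <- ok_transition(i, sa, states[[i + 1L]][, b])
        }
      }
      trans[[i]] <- tm
      fwd[[i + 1L]] <- as.numeric(crossprod(tm, fwd[[i]]))
    }
  }
  bwd[[nf]] <- rep(1, ns[nf])
  if (nf > 1) {
    for (i in rev(seq_len(nf - 1L))) {
      bwd[[i]] <- as.numeric(trans[[i]] %*% bwd[[i + 1L]])
    }
  }
  n_assign <- sum(fwd[[nf]] * bwd[[nf]])
  feasible_states <- lapply(seq_len(nf), function(i)
    which(fwd[[i]] > 0 & bwd[[i]] > 0))
  if (n_assign == 0) {
    return(list(n_assignments = 0, feasible = FALSE,
                ranges = tibble::tibble(node = nodes$node,
                                        min_size = NA_real_,
                                        max_size = NA_real_),
                assignments = NULL))
  }

  min_size <- rep(NA_real_, n_nodes)
  max_size <- rep(NA_real_, n_nodes)
  for (i in seq_len(nf)) {
    idx <- by_frame[[as.character(frames[i])]]
    st <- states[[i]][, feasible_states[[i]], drop = FALSE]
    min_size[idx] <- apply(st, 1, min)
    max_size[idx] <- apply(st, 1, max)
  }

  assignments <- NULL
  if (n_assign <= max_enumerate) {
    paths <- lapply(feasible_states[[1]], function(a) a)
    if (nf > 1) {
      for (i in seq_len(nf - 1L)) {
        nxt <- list()
        for (p in paths) {
          a <- p[length(p)]
          for (b in feasible_states[[i + 1L]]) {
            if (trans[[i]][a, b] && bwd[[i + 1L]][b] > 0)
              nxt[[length(nxt) + 1L]] <- c(p, b)
          }
        }
        paths <- nxt
      }
    }
    assignments <- matrix(NA_real_, length(paths), n_nodes)
    for (r in seq_along(paths)) {
      for (i in seq_len(nf)) {
        idx <- by_frame[[as.character(frames[i])]]
        assignments[r, idx] <- states[[i]][, paths[[r]][i]]
      }
    }
    colnames(assignments) <- as.character(nodes$node)
  }

  list(n_assignments = n_assign, feasible = TRUE,
       ranges = tibble::tibble(node = nodes$node, min_size = min_size,
                               max_size = max_size),
       assignments = assignments)
}
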