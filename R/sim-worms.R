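#' Simulation configuration for an aggregating-worm recording
#'
#' Parameters of the agent-based simulation used to generate synthetic
#' recordings with known ground truth. Defaults reproduce the assay
#' conditions the pipeline was designed for: 40 age-matched worms in a
#' circular arena recorded at an effective rate of 8.33 Hz for 45 minutes,
#' with worms feeding on a central bacterial patch where they can aggregate
#' into clusters.
#'
#' Worms are modelled as persistent random walkers. A free ("single") worm
#' moves at `speed_single` pixels per frame with Gaussian heading noise and
#' is weakly attracted to the food patch. Worms join a cluster on body
#' contact: whenever the gap between two worms' capsule outlines falls to
#' `join_radius` or less they belong to one cluster (this is the same
#' geometry that makes their rendered blobs touch, so ground-truth
#' partitions and rendered connected components stay consistent). Clusters
#' move as slow rigid units at `speed_in_cluster` and each member leaves
#' independently with probability `leave_rate` per frame (one leaver per
#' cluster per frame, so splits are binary, unless `multiway_splits` is
#' set). Cluster members are packed on a hexagonal lattice with ~3.5 px
#' spacing, keeping their slots across joins, so each cluster renders as
#' one stable connected component.
#'
#' @param n_worms Number of worms (default 40).
#' @param arena_radius Arena radius in pixels (default 500, i.e. a
#'   1000-px-wide arena).
#' @param patch_radius Radius of the food patch in pixels; singles outside it
#'   steer back towards the centre.
#' @param frame_rate Effective analysis frame rate in Hz (default 8.33).
#' @param duration Recording duration in seconds (default 2700 s = 45 min).
#' @param speed_single Speed of a free worm, px/frame.
#' @param speed_in_cluster Speed of a cluster centroid, px/frame. Kept well
#'   below `speed_single` so that single worms have visibly larger
#'   trajectory extents, the property the single-worm classifier exploits.
#' @param heading_noise Heading noise, rad/frame.
#' @param join_radius Contact gap in px between worm body outlines at which
#'   worms join a cluster (default 5, a third of a body length).
#' @param leave_rate Per-member probability of leaving a cluster per frame.
#' @param rng_seed Integer seed; identical seeds give identical simulations.
#' @param worm_length,worm_width Rendered worm capsule dimensions in px
#'   (defaults 15 and 5, single-worm area about 70 px^2).
#' @param margin Blank border around the arena in the rendered image, px.
#' @param multiway_splits If `TRUE`, allow several members to leave one
#'   cluster in the same frame (stress-testing only).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_worms = 40, arena_radius = 500, patch_radius = 250,
                       frame_rate = 8.33, duration = 2700,
                       speed_single = 1.0, speed_in_cluster = 0.1,
                       heading_noise = 0.3, join_radius = 5,
                       leave_rate = 0.005, rng_seed = 1,
                       worm_length = 15, worm_width = 5, margin = 10,
                       multiway_splits = FALSE) {
  cfg <- list(n_worms = as.integer(n_worms), arena_radius = arena_radius,
              patch_radius = patch_radius, frame_rate = frame_rate,
              duration = duration, speed_single = speed_single,
              speed_in_cluster = speed_in_cluster,
              heading_noise = heading_noise, join_radius = join_radius,
              leave_rate = leave_rate, rng_seed = as.integer(rng_seed),
              worm_length = worm_length, worm_width = worm_width,
              margin = margin, multiway_splits = isTRUE(multiway_splits))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_worms < 1) stop("n_worms must be >= 1", call. = FALSE)
  if (cfg$patch_radius > cfg$arena_radius)
    stop("patch_radius must not exceed arena_radius", call. = FALSE)
  if (cfg$leave_rate < 0 || cfg$leave_rate > 1)
    stop("leave_rate must be a probability in [0, 1]", call. = FALSE)
  if (cfg$duration <= 0 || cfg$frame_rate <= 0)
    stop("duration and frame_rate must be positive", call. = FALSE)
  rates <- c(cfg$speed_single, cfg$speed_in_cluster, cfg$heading_noise,
             cfg$join_radius, cfg$arena_radius, cfg$patch_radius)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and radii must be finite and non-negative", call. = FALSE)
  invisible(cfg)
}

#' Nominal pixel area of one rendered worm
#'
#' Area of the capsule (thick segment with round caps) used to draw a worm.
#'
#' @param config A [sim_config()].
#' @return Area in px^2.
#' @export
single_worm_area <- function(config) {
  w <- config$worm_width
  (config$worm_length - w) * w + pi * (w / 2)^2
}

#' Rendered image dimension for a configuration
#' @param config A [sim_config()].
#' @return Integer vector `c(nrow, ncol)`.
#' @export
frame_dim <- function(config) {
  d <- as.integer(ceiling(2 * (config$arena_radius + config$margin)))
  c(d, d)
}

# Evaluate `code` with a locally seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# Hexagonal-spiral slot positions for cluster members. The first k points
# of a unit hex lattice ordered by distance from the origin: every added
# slot has an already-placed neighbour at exactly unit distance, so with a
# spacing below the capsule half-length (worm centres lie on the body
# axes, hence capsule distance <= centre distance) each member is
# guaranteed to overlap a neighbour regardless of body orientation, and
# clusters always render as one connected component. The 3.5-px spacing
# leaves a >=1.5-px-wide overlap strip, wide enough that rasterization
# cannot miss it (a 4-px spacing occasionally produced pixel-free
# overlap strips between near-parallel neighbours, fragmenting blobs).
.hex_cache <- new.env(parent = emptyenv())
hex_slots <- function(k) {
  key <- as.character(k)
  if (!is.null(.hex_cache[[key]])) return(.hex_cache[[key]])
  R <- ceiling(sqrt(k)) + 2L
  ij <- expand.grid(i = -R:R, j = -R:R)
  x <- ij$i + ij$j / 2
  y <- ij$j * sqrt(3) / 2
  r <- sqrt(x^2 + y^2)
  ord <- order(r, atan2(y, x))
  pts <- cbind(x[ord], y[ord])[seq_len(k), , drop = FALSE]
  .hex_cache[[key]] <- pts
  pts
}

# Offsets for k members (x, y columns), rotated by `phase`; attribute
# "tangent" carries the per-slot tangential body orientation (members lie
# curled around the cluster, keeping small-cluster union areas clearly
# above the single-worm area).
cluster_offsets <- function(k, phase = 0, spacing = 3.5) {
  pts <- spacing * hex_slots(k)
  rot <- cbind(c(cos(phase), sin(phase)), c(-sin(phase), cos(phase)))
  out <- pts %*% rot
  attr(out, "tangent") <- atan2(out[, 2], out[, 1]) + pi / 2
  out
}

cluster_radius <- function(k, spacing = 3.5) {
  if (k <= 1) return(0)
  spacing * max(sqrt(rowSums(hex_slots(k)^2)))
}

#' Simulate aggregating worms with ground-truth cluster partitions
#'
#' Agent-based simulation of `n_worms` worms in a circular arena that form,
#' exchange members with, and leave multi-worm clusters. The returned table
#' is the ground truth used to validate every downstream stage: per frame it
#' records each worm's position and the exact partition of worms into
#' clusters. Cluster membership changes only through join (merge) and leave
#' (split) events between consecutive frames.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `frame` (1-based), `worm_id`, `x`, `y`
#'   (pixel coordinates in the rendered image frame, x = column, y = row),
#'   `heading` (rad) and `cluster_id`. Singles carry `cluster_id = -worm_id`;
#'   multi-worm clusters carry stable positive ids. The generating
#'   `sim_config` is attached as attribute `"config"`.
#' @export
simulate_worms <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$rng_seed, simulate_worms_impl(config))
}

# Minimum distance between 2-D segments p1-q1 and p2-q2.
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a == 0 && e == 0) return(sqrt(sum(r * r)))
  if (a == 0) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e == 0) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom != 0) min(max((b * f - cc * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  c1 <- p1 + s * d1; c2 <- p2 + t * d2
  sqrt(sum((c1 - c2)^2))
}

simulate_worms_impl <- function(cfg) {
  n <- cfg$n_worms
  n_frames <- max(1L, as.integer(round(cfg$duration * cfg$frame_rate)))
  centre <- cfg$arena_radius + cfg$margin
  jr <- cfg$join_radius
  half <- (cfg$worm_length - cfg$worm_width) / 2 # capsule axis half-length

  # gap between the capsule outlines of worms i and j given pos/heading
  gap_between <- function(pi_, hi_, pj_, hj_) {
    di <- c(cos(hi_), sin(hi_)); dj <- c(cos(hj_), sin(hj_))
    seg_seg_dist(pi_ - half * di, pi_ + half * di,
                 pj_ - half * dj, pj_ + half * dj) - cfg$worm_width
  }

  # initial positions: uniform in the patch, capsule gaps well above the
  # contact threshold so frame 1 is unambiguously all singletons
  min_sep <- cfg$worm_length + cfg$worm_width + jr + 2
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  r_init <- max(cfg$patch_radius * 0.9, min_sep * sqrt(n) / 1.5)
  r_init <- min(r_init, cfg$arena_radius - cfg$worm_length)
  tries <- 0L
  while (placed < n) {
    u <- sqrt(runif(1)) * r_init
    a <- runif(1, 0, 2 * pi)
    p <- c(u * cos(a), u * sin(a))
    ok <- placed == 0L ||
      min(sqrt((pos[seq_len(placed), 1] - p[1])^2 +
               (pos[seq_len(placed), 2] - p[2])^2)) >= min_sep
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
    } else {
      tries <- tries + 1L
      if (tries > 200L * n) {
        # separation infeasible at this density (e.g. a huge contact
        # radius): relax it and keep going
        min_sep <- min_sep * 0.8
        tries <- 0L
      }
    }
  }
  heading <- runif(n, 0, 2 * pi)
  cl <- integer(n)                 # 0 = single, else cluster id
  clusters <- list()               # id -> list(centroid, heading, phase, members)
  next_id <- 1L

  X <- matrix(NA_real_, n_frames, n)
  Y <- matrix(NA_real_, n_frames, n)
  H <- matrix(NA_real_, n_frames, n)
  CL <- matrix(NA_integer_, n_frames, n)

  place_members <- function(cid) {
    k <- length(clusters[[cid]]$members)
    off <- cluster_offsets(k, clusters[[cid]]$phase)
    idx <- clusters[[cid]]$members
    pos[idx, 1] <<- clusters[[cid]]$centroid[1] + off[, 1]
    pos[idx, 2] <<- clusters[[cid]]$centroid[2] + off[, 2]
    heading[idx] <<- attr(off, "tangent") + clusters[[cid]]$wiggle[seq_len(k)]
  }

  # After a membership change, match members to lattice slots greedily by
  # current position so that nobody teleports across the cluster: every
  # member's displacement stays small and the rendered blob deforms
  # continuously through join/leave/merge events (keeping consecutive-frame
  # blob distances within the temporal-graph linking radius).
  reorder_slots <- function(cid) {
    mem <- clusters[[cid]]$members
    k <- length(mem)
    if (k < 2) return(invisible())
    off <- cluster_offsets(k, clusters[[cid]]$phase)
    tx <- clusters[[cid]]$centroid[1] + off[, 1]
    ty <- clusters[[cid]]$centroid[2] + off[, 2]
    D <- outer(pos[mem, 1], tx, "-")^2 + outer(pos[mem, 2], ty, "-")^2
    slot_of <- integer(k)
    for (s in seq_len(k)) {
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      slot_of[ij[2]] <- ij[1]
      D[ij[1], ] <- Inf
      D[, ij[2]] <- Inf
    }
    clusters[[cid]]$members <<- mem[slot_of]
    clusters[[cid]]$wiggle <<- clusters[[cid]]$wiggle[slot_of]
  }

  record <- function(t) {
    X[t, ] <<- pos[, 1] + centre
    Y[t, ] <<- pos[, 2] + centre
    H[t, ] <<- heading
    CL[t, ] <<- ifelse(cl == 0L, -seq_len(n), cl)
  }

  record(1L)

  for (t in seq_len(n_frames - 1L)) {
    ## --- leave events (binary splits unless multiway) ---
    for (cid in names(clusters)) {
      mem <- clusters[[cid]]$members
      k <- length(mem)
      if (k < 2) next
      leavers <- mem[runif(k) < cfg$leave_rate]
      if (length(leavers) == 0) next
      if (!cfg$multiway_splits) leavers <- leavers[1]
      for (w in leavers) {
        keep <- clusters[[cid]]$members != w
        old_wiggle <- clusters[[cid]]$wiggle[!keep]
        clusters[[cid]]$members <- clusters[[cid]]$members[keep]
        clusters[[cid]]$wiggle <- clusters[[cid]]$wiggle[keep]
        mem <- clusters[[cid]]$members
        if (length(mem) >= 2) {
          reorder_slots(cid)
          mem <- clusters[[cid]]$members
          place_members(cid)
        }
        cen <- clusters[[cid]]$centroid
        rk <- cluster_radius(length(mem))
        ang <- runif(1, 0, 2 * pi)
        if (sqrt(sum(cen^2)) > cfg$arena_radius - rk - 40)
          ang <- atan2(-cen[2], -cen[1]) + runif(1, -0.8, 0.8)
        # place the leaver just outside contact range but inside the
        # temporal-graph linking radius, by refining the capsule gap
        # (the leaver then steps outward, so the split-frame gap stays
        # about 1 px above this)
        target <- jr + 0.5
        others <- setdiff(seq_len(n), c(mem, w))
        clear <- FALSE
        for (try_ang in 1:16) {
          d_out <- rk + half + cfg$worm_width + target
          for (adj in 1:4) {
            cand <- cen + d_out * c(cos(ang), sin(ang))
            g <- min(vapply(mem, function(m)
              gap_between(cand, ang, pos[m, ], heading[m]), numeric(1)))
            if (abs(g - target) < 0.5) break
            d_out <- d_out + (target - g)
          }
          # keep the leaver at least a body length clear of every other
          # worm: a leaver surfacing near a second group either joins it
          # in the same step (a crossing event with no conservation
          # constraint) or draws a spurious proximity link to it
          clearance <- cfg$worm_length + 6
          near <- others[sqrt((pos[others, 1] - cand[1])^2 +
                              (pos[others, 2] - cand[2])^2) <
                           2 * cfg$worm_length + clearance + 2]
          clear <- length(near) == 0 ||
            min(vapply(near, function(m) gap_between(cand, ang,
              pos[m, ], heading[m]), numeric(1))) > clearance
          if (clear && sqrt(sum(cand^2)) < cfg$arena_radius - 8)
            break
          ang <- ang + 2 * pi / 16 + runif(1, 0, 0.3)
        }
        if (!clear) {
          # too crowded to exit cleanly: defer the leave and restore
          clusters[[cid]]$members <- c(mem, w)
          clusters[[cid]]$wiggle <- c(clusters[[cid]]$wiggle, old_wiggle)
          reorder_slots(cid)
          place_members(cid)
          next
        }
        pos[w, ] <- cand
        heading[w] <- ang
        cl[w] <- 0L
      }
      if (length(clusters[[cid]]$members) == 1L) {
        w <- clusters[[cid]]$members
        cl[w] <- 0L
        clusters[[cid]] <- NULL
      }
    }

    ## --- motion ---
    singles <- which(cl == 0L)
    if (length(singles) > 0) {
      heading[singles] <- heading[singles] +
        rnorm(length(singles), 0, cfg$heading_noise)
      rad <- sqrt(rowSums(pos[singles, , drop = FALSE]^2))
      out <- rad > cfg$patch_radius
      if (any(out)) {
        s_out <- singles[out]
        to_centre <- atan2(-pos[s_out, 2], -pos[s_out, 1])
        heading[s_out] <- heading[s_out] +
          0.2 * wrap_angle(to_centre - heading[s_out])
      }
      pos[singles, 1] <- pos[singles, 1] +
        cfg$speed_single * cos(heading[singles])
      pos[singles, 2] <- pos[singles, 2] +
        cfg$speed_single * sin(heading[singles])
      rad <- sqrt(rowSums(pos[singles, , drop = FALSE]^2))
      hit <- rad > cfg$arena_radius - 8
      if (any(hit)) {
        s_hit <- singles[hit]
        scl <- (cfg$arena_radius - 8) / rad[hit]
        pos[s_hit, ] <- pos[s_hit, ] * scl
        heading[s_hit] <- atan2(-pos[s_hit, 2], -pos[s_hit, 1]) +
          runif(length(s_hit), -0.5, 0.5)
      }
    }
    for (cid in names(clusters)) {
      k <- length(clusters[[cid]]$members)
      # clusters drift slowly but persistently (low heading noise, weak
      # patch attraction), so no region of the plate stays occupied long
      # enough to contaminate the temporal-median background
      h_cl <- clusters[[cid]]$heading + rnorm(1, 0, cfg$heading_noise * 0.15)
      cen0 <- clusters[[cid]]$centroid
      if (sqrt(sum(cen0^2)) > cfg$patch_radius)
        h_cl <- h_cl + 0.1 * wrap_angle(atan2(-cen0[2], -cen0[1]) - h_cl)
      clusters[[cid]]$heading <- h_cl
      clusters[[cid]]$phase <- clusters[[cid]]$phase + 0.02
      cen <- cen0 + cfg$speed_in_cluster * c(cos(h_cl), sin(h_cl))
      rmax <- cfg$arena_radius - cluster_radius(k) - 9
      if (sqrt(sum(cen^2)) > rmax) cen <- cen * rmax / sqrt(sum(cen^2))
      clusters[[cid]]$centroid <- cen
      w <- clusters[[cid]]$wiggle
      clusters[[cid]]$wiggle <- 0.9 * w + rnorm(length(w), 0, 0.1)
      place_members(cid)
    }

    ## --- contact detection: union-find over body contacts ---
    if (jr > 0 && n > 1) {
      parent <- seq_len(n)
      findw <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      unionw <- function(i, j) {
        a <- findw(i); b <- findw(j)
        if (a != b) parent[b] <<- a
      }
      for (cid in names(clusters)) {
        mem <- clusters[[cid]]$members
        for (m in mem[-1]) unionw(mem[1], m)
      }
      D <- as.matrix(dist(pos))
      reach <- cfg$worm_length + cfg$worm_width + jr
      cand <- which(upper.tri(D) & D <= reach, arr.ind = TRUE)
      cp_i <- integer(0); cp_j <- integer(0)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (cl[i] != 0L && cl[i] == cl[j]) next
        if (gap_between(pos[i, ], heading[i], pos[j, ], heading[j]) <= jr) {
          unionw(i, j)
          cp_i <- c(cp_i, i); cp_j <- c(cp_j, j)
        }
      }
      roots <- vapply(seq_len(n), findw, integer(1))
      comps <- split(seq_len(n), roots)
      comps <- comps[lengths(comps) >= 2]
      absorb <- function(comp) {
        # merge/absorb the worms of `comp` (a contact-connected set that
        # contains at least one existing cluster) into the largest
        # constituent cluster
        ids_chr <- as.character(unique(cl[comp][cl[comp] != 0L]))
        sizes <- vapply(ids_chr, function(i)
          length(clusters[[i]]$members), integer(1))
        primary <- ids_chr[which.max(sizes)]
        old <- clusters[[primary]]$members
        newcomers <- sort(setdiff(comp, old))
        if (length(newcomers) == 0) return(invisible())
        clusters[[primary]]$members <<- c(old, newcomers)
        clusters[[primary]]$wiggle <<-
          c(clusters[[primary]]$wiggle[seq_along(old)],
            rnorm(length(newcomers), 0, 0.3))
        # recentre only when whole clusters coalesce (the merged blob
        # must cover both old bodies); on single accretion the body of
        # the existing cluster must stay put so that its outline, and
        # with it the merge-event link to the joining worm's previous
        # blob, does not recede
        if (length(ids_chr) > 1)
          clusters[[primary]]$centroid <<-
            colMeans(pos[clusters[[primary]]$members, , drop = FALSE])
        for (i in setdiff(ids_chr, primary)) clusters[[i]] <<- NULL
        cl[comp] <<- as.integer(primary)
        reorder_slots(primary)
        place_members(primary)
      }
      for (comp in comps) {
        comp <- sort(comp)
        ids <- unique(cl[comp])
        ids <- ids[ids != 0L]
        ids_chr <- as.character(ids)
        if (length(ids) == 1 &&
            length(clusters[[ids_chr]]$members) == length(comp)) next
        if (length(ids) > 0) {
          # only worms in direct body contact with an existing cluster
          # join this frame; a worm whose contact runs through another
          # single would otherwise be repositioned from far outside the
          # linking radius, severing the merge link from its old blob.
          # Deferred worms simply join on a later frame. After the
          # filtering the remaining worms may fall apart into several
          # connected pieces, each absorbed separately.
          body <- unlist(lapply(ids_chr, function(i) clusters[[i]]$members))
          direct <- unique(c(cp_i[cp_j %in% body], cp_j[cp_i %in% body]))
          allowed <- sort(intersect(comp, c(body, direct)))
          lp <- seq_along(allowed)
          lfind <- function(i) {
            while (lp[i] != i) {
              lp[i] <<- lp[lp[i]]
              i <- lp[i]
            }
            i
          }
          lunion <- function(i, j) {
            a <- lfind(i); b <- lfind(j)
            if (a != b) lp[b] <<- a
          }
          for (i in ids_chr) {
            mem <- intersect(clusters[[i]]$members, allowed)
            for (mm in mem[-1]) lunion(match(mem[1], allowed),
                                       match(mm, allowed))
          }
          keep_cp <- cp_i %in% allowed & cp_j %in% allowed
          for (r in which(keep_cp)) lunion(match(cp_i[r], allowed),
                                           match(cp_j[r], allowed))
          lroots <- vapply(lp, lfind, integer(1))
          for (sub in split(allowed, lroots)) {
            if (length(sub) >= 2 && any(cl[sub] != 0L)) absorb(sort(sub))
          }
        } else {
          cid <- as.character(next_id)
          next_id <- next_id + 1L
          clusters[[cid]] <- list(
            centroid = colMeans(pos[comp, , drop = FALSE]),
            heading = runif(1, 0, 2 * pi),
            phase = runif(1, 0, 2 * pi),
            members = comp,
            wiggle = rnorm(length(comp), 0, 0.3))
          cl[comp] <- as.integer(cid)
          reorder_slots(cid)
          place_members(cid)
        }
      }
    }

    record(t + 1L)
  }

  out <- tibble::tibble(
    frame = rep(seq_len(n_frames), each = n),
    worm_id = rep(seq_len(n), n_frames),
    x = as.vector(t(X)), y = as.vector(t(Y)),
    heading = as.vector(t(H)), cluster_id = as.vector(t(CL)))
  attr(out, "config") <- cfg
  out
}

#' Ground-truth cluster-size multisets per frame
#'
#' @param truth Output of [simulate_worms()].
#' @return A tibble `frame`, `sizes` (list-column of sorted integer block
#'   sizes of the ground-truth partition).
#' @export
truth_frame_sizes <- function(truth) {
  truth %>%
    dplyr::group_by(.data$frame, .data$cluster_id) %>%
    dplyr::summarise(size = dplyr::n(), .groups = "drop") %>%
    dplyr::group_by(.data$frame) %>%
    dplyr::summarise(sizes = list(sort(.data$size)), .groups = "drop")
}

#' Abstract temporal graph from ground truth
#'
#' Builds the idealized temporal blob graph implied by the ground-truth
#' partitions: one node per partition block per frame, one edge between
#' blocks of consecutive frames that share at least one worm. Used as a
#' fixture generator for the size-propagation algorithm and its
#' brute-force oracle, bypassing rendering and segmentation.
#'
#' @param truth Output of [simulate_worms()].
#' @return A `blob_graph` (see [build_temporal_graph()]) whose node table
#'   carries the extra column `true_size`.
#' @export
truth_graph <- function(truth) {
  blocks <- truth %>%
    dplyr::group_by(.data$frame, .data$cluster_id) %>%
    dplyr::summarise(members = list(sort(.data$worm_id)),
                     x = mean(.data$x), y = mean(.data$y),
                     .groups = "drop") %>%
    dplyr::arrange(.data$frame, .data$cluster_id) %>%
    dplyr::group_by(.data$frame) %>%
    dplyr::mutate(blob_id = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(node = dplyr::row_number(),
                  true_size = lengths(.data$members),
                  area = NA_real_)
  frames <- sort(unique(blocks$frame))
  edges <- list()
  for (i in seq_len(length(frames) - 1L)) {
    a <- blocks[blocks$frame == frames[i], ]
    b <- blocks[blocks$frame == frames[i + 1L], ]
    for (p in seq_len(nrow(a))) {
      for (q in seq_len(nrow(b))) {
        if (length(intersect(a$members[[p]], b$members[[q]])) > 0) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = a$node[p], to = b$node[q], link_distance = 0)
        }
      }
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    data.frame(from = integer(), to = integer(), link_distance = numeric())
  nodes <- blocks %>%
    dplyr::select("node", "frame", "blob_id", "x", "y", "area", "true_size")
  new_blob_graph(nodes, tibble::as_tibble(edges))
}

#' Render simulated worms into binary frames
#'
#' Draws every worm as a filled capsule of length `worm_length` and width
#' `worm_width` along its heading. Members of one ground-truth cluster are
#' packed within overlap distance by the simulator, so each cluster renders
#' as a single connected component on a zero background.
#'
#' @param truth Output of [simulate_worms()].
#' @param config The [sim_config()] used (defaults to the one attached to
#'   `truth`).
#' @param frames Integer vector of frame indices to render (default all).
#' @param dim Image dimensions `c(nrow, ncol)`; must contain the arena.
#' @return A named list of 0/1 integer matrices, one per requested frame.
#' @export
render_frames <- function(truth, config = attr(truth, "config"),
                          frames = NULL, dim = NULL) {
  if (is.null(config)) stop("no sim_config supplied or attached", call. = FALSE)
  if (is.null(dim)) dim <- frame_dim(config)
  need <- 2 * (config$arena_radius + config$margin)
  if (dim[1] < need || dim[2] < need)
    stop("image dimensions too small to contain the arena", call. = FALSE)
  if (is.null(frames)) frames <- sort(unique(truth$frame))
  out <- lapply(frames, function(f) {
    fr <- truth[truth$frame == f, ]
    cpp_render_worms(fr$x, fr$y, fr$heading, config$worm_length,
                     config$worm_width, dim[1], dim[2])
  })
  names(out) <- as.character(frames)
  out
}
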