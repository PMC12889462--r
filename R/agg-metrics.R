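#' Cap value for degenerate single-cluster frames
#'
#' When every worm sits in one cluster the cluster-size entropy is zero and
#' the inverse-entropy aggregation index diverges. Such frames are capped at
#' the largest finite index reachable with `n` worms, `1 / H({n-1, 1})`,
#' i.e. the index of the most aggregated two-cluster state.
#'
#' @param n_worms Total worm count (>= 2).
#' @return The cap value.
#' @export
aggregation_cap <- function(n_worms) {
  if (n_worms < 2) stop("n_worms must be >= 2 for the cap", call. = FALSE)
  p <- c(n_worms - 1, 1) / n_worms
  1 / (-sum(p * log(p)))
}

#' Aggregation magnitude of one frame (inverse spatial entropy)
#'
#' Treats clusters as discrete bins with probabilities
#' `P_i = size_i / n_worms` and returns `A = 1 / (-sum P_i log P_i)`
#' (natural log). Worms spread as singletons give the minimum `1 / log n`;
#' concentration into few clusters lowers the entropy and raises `A`.
#' Probabilities are normalised by the nominal `n_worms` even if the frame's
#' sizes do not sum exactly to it (set `strict = TRUE` to renormalise by the
#' actual total). A single-cluster frame (zero entropy) returns
#' [aggregation_cap()].
#'
#' @param sizes Numeric vector of cluster sizes for one frame (each > 0;
#'   half-integers from bounded estimates are accepted).
#' @param n_worms Total worm count.
#' @param strict Renormalise probabilities to sum to one (default `FALSE`).
#' @return The scalar aggregation index `A` (dimensionless).
#' @export
aggregation_index <- function(sizes, n_worms, strict = FALSE) {
  if (n_worms <= 0) stop("n_worms must be positive", call. = FALSE)
  if (length(sizes) == 0 || any(!is.finite(sizes)) || any(sizes <= 0))
    stop("sizes must be nonempty, finite and positive", call. = FALSE)
  p <- if (strict) sizes / sum(sizes) else sizes / n_worms
  h <- -sum(p * log(p))
  if (h <= 0) return(aggregation_cap(n_worms))
  1 / h
}

#' Aggregation time series A(t) of a recording
#'
#' One aggregation index per analysed frame, in frame order. Refuses
#' QC-excluded recordings (returns an empty series flagged
#' `qc_excluded`).
#'
#' @param frame_sizes A `frame_sizes` object from [per_frame_sizes()], or a
#'   list of per-frame size vectors.
#' @param n_worms Total worm count (default taken from the QC metadata).
#' @param dt Time step between analysed frames in seconds (default 0.12 s,
#'   i.e. 8.33 Hz).
#' @param strict See [aggregation_index()].
#' @return An `agg_series` tibble with columns `time` (s) and `A`;
#'   attributes `dt`, `n_worms`, `cap_frames` (indices of capped degenerate
#'   frames) and `qc_excluded`.
#' @export
aggregation_series <- function(frame_sizes, n_worms = NULL, dt = 0.12,
                               strict = FALSE) {
  qc <- attr(frame_sizes, "qc")
  if (is.null(n_worms)) {
    if (is.null(qc)) stop("n_worms must be supplied", call. = FALSE)
    n_worms <- qc$n_worms
  }
  if (!is.null(qc) && isTRUE(qc$excluded)) {
    warning("recording failed tracking QC; returning excluded marker")
    out <- tibble::tibble(time = numeric(0), A = numeric(0))
    attr(out, "qc_excluded") <- TRUE
    class(out) <- c("agg_series", class(out))
    return(out)
  }
  sizes <- if (is.data.frame(frame_sizes)) frame_sizes$sizes else frame_sizes
  a <- vapply(sizes, aggregation_index, numeric(1), n_worms = n_worms,
              strict = strict)
  cap <- aggregation_cap(max(n_worms, 2))
  out <- tibble::tibble(time = seq_along(a) * dt, A = a)
  attr(out, "dt") <- dt
  attr(out, "n_worms") <- n_worms
  attr(out, "cap_frames") <- which(a >= cap)
  attr(out, "qc_excluded") <- FALSE
  class(out) <- c("agg_series", class(out))
  out
}

#' Mean aggregation magnitude of a recording
#'
#' The time average `mu_A` of the aggregation series (discrete realisation
#' of `(1/T) integral A(t) dt`).
#'
#' @param series An `agg_series` or numeric vector.
#' @return Scalar `mu_A`.
#' @export
mean_magnitude <- function(series) {
  x <- if (is.data.frame(series)) series$A else series
  if (length(x) == 0) stop("empty aggregation series", call. = FALSE)
  mean(x)
}

#' Normalized autocorrelation of an aggregation series
#'
#' The biased (divide-by-total) estimator
#' `C(k dt) = sum_t dev(t) dev(t+k) / sum_t dev(t)^2` with
#' `dev(t) = A(t) - mu_A`, so `C(0) = 1` exactly.
#'
#' @param series An `agg_series` or numeric vector.
#' @param max_lag_fraction Largest lag as a fraction of the series length
#'   (default 1, i.e. lags up to T-1).
#' @return An `acf_result` tibble with columns `lag` (s) and `C`;
#'   attribute `dt`.
#' @export
autocorrelation <- function(series, max_lag_fraction = 1) {
  x <- if (is.data.frame(series)) series$A else series
  dt <- attr(series, "dt") %||% 1
  if (length(x) < 2 || var(x) == 0)
    stop("series variance is zero; autocorrelation undefined", call. = FALSE)
  lag_max <- max(1L, min(length(x) - 1L,
                         floor(max_lag_fraction * length(x))))
  cc <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)
  out <- tibble::tibble(lag = (seq_along(cc) - 1) * dt, C = cc)
  attr(out, "dt") <- dt
  class(out) <- c("acf_result", class(out))
  out
}

#' Temporal persistence tau_A (integral timescale)
#'
#' The maximum of the running integral of the autocorrelation function,
#' `tau_A = max_t integral_0^t C(tau) dtau`, discretised as a
#' left-rectangle sum including lag 0 (so `tau_A >= dt` always). Analogous
#' to the integral timescale of turbulence studies; robust to
#' autocorrelations that deviate from simple exponential decay.
#'
#' @param acf_result An `acf_result` from [autocorrelation()], or a numeric
#'   vector of correlation values starting at lag 0.
#' @param dt Lag step in seconds (default from the object).
#' @param method `"rectangle"` (default, left-rectangle) or `"trapezoid"`.
#' @return Scalar `tau_A` in seconds.
#' @export
temporal_persistence <- function(acf_result, dt = NULL,
                                 method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  cc <- if (is.data.frame(acf_result)) acf_result$C else acf_result
  if (is.null(dt)) dt <- attr(acf_result, "dt") %||% 1
  if (method == "rectangle") {
    max(cumsum(cc)) * dt
  } else {
    max(c(0, cumsum((cc[-1] + cc[-length(cc)]) / 2))) * dt
  }
}

#' Summarise one recording into trait values
#'
#' @param frame_sizes A `frame_sizes` object.
#' @param n_worms,dt,strict See [aggregation_series()].
#' @param max_lag_fraction See [autocorrelation()].
#' @return A list with `mu_A`, `tau_A`, `series` and `acf`.
#' @export
aggregation_traits <- function(frame_sizes, n_worms = NULL, dt = 0.12,
                               strict = FALSE, max_lag_fraction = 1) {
  series <- aggregation_series(frame_sizes, n_worms, dt, strict)
  if (isTRUE(attr(series, "qc_excluded")))
    return(list(mu_A = NA_real_, tau_A = NA_real_, series = series,
                acf = NULL))
  ac <- autocorrelation(series, max_lag_fraction)
  list(mu_A = mean_magnitude(series),
       tau_A = temporal_persistence(ac),
       series = series, acf = ac)
}

#' Bootstrap traits to a fixed number of replicates per strain
#'
#' Resamples whole replicate rows (all traits jointly) with replacement
#' within each strain until every strain carries exactly `target_n`
#' samples, balancing unequal replicate counts across strains before the
#' evolutionary analyses.
#'
#' @param table Trait tibble with a `strain` column; remaining columns are
#'   carried along row-wise.
#' @param target_n Samples per strain after resampling (default 5).
#' @param seed Integer seed.
#' @return A tibble with `target_n` rows per strain; `replicate` renumbered
#'   1..`target_n`.
#' @export
bootstrap_traits <- function(table, target_n = 5, seed = 1) {
  if (!"strain" %in% names(table)) stop("table needs a 'strain' column",
                                        call. = FALSE)
  with_local_seed(seed, {
    table %>%
      dplyr::group_by(.data$strain) %>%
      dplyr::group_modify(function(d, key) {
        if (nrow(d) == 0)
          stop("strain with zero replicates: ", key$strain, call. = FALSE)
        d[sample.int(nrow(d), target_n, replace = TRUE), , drop = FALSE]
      }) %>%
      dplyr::mutate(replicate = dplyr::row_number()) %>%
      dplyr::ungroup()
  })
}
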