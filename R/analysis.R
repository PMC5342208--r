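# Coerce the objects the analysis functions accept into a
# (time, value, K) series: an fp_trajectory (global human density, K from
# its parameters) or a two-column time/value object with K supplied.
global_series <- function(x, K = NULL) {
  if (inherits(x, "fp_trajectory")) {
    list(time = x$time, value = x$global_a,
         K = if (is.null(K)) x$params$K_total else K)
  } else if (is.data.frame(x) || is.list(x)) {
    tm <- x$time; va <- x$value
    if (is.null(tm) || is.null(va)) {
      if (is.data.frame(x) && ncol(x) >= 2L) { tm <- x[[1L]]; va <- x[[2L]] }
      else stop("cannot interpret input as a time series", call. = FALSE)
    }
    if (is.null(K)) K <- attr(x, "K_ref")
    if (is.null(K)) stop("`K` must be supplied for a raw series", call. = FALSE)
    list(time = as.numeric(tm), value = as.numeric(va), K = as.numeric(K))
  } else stop("unsupported input type", call. = FALSE)
}

window_series <- function(s, window = NULL, transient = 0.05) {
  if (is.null(window)) {
    t0 <- min(s$time) + transient * (max(s$time) - min(s$time))
    window <- c(t0, max(s$time))
  }
  keep <- s$time >= window[1L] & s$time <= window[2L]
  if (!any(keep)) stop("empty analysis window", call. = FALSE)
  list(time = s$time[keep], value = s$value[keep], K = s$K)
}

#' Oscillation interval relative to the carrying capacity
#'
#' Computes the extremes of the global human-density series over the
#' analysis window, expressed as ratios to the carrying capacity `K`; the
#' quantities used to compare model runs with demographic reconstructions.
#' The initial transient (default: first 5% of the horizon) is excluded so
#' that the statistics describe the established oscillatory regime.
#'
#' @param x An `fp_trajectory`, or a two-column (time, value) data frame /
#'   list with `K` supplied.
#' @param window Optional numeric `c(t_min, t_max)` analysis window;
#'   overrides `transient`.
#' @param transient Fraction of the horizon dropped from the start when no
#'   explicit window is given.
#' @param K Carrying capacity override (required for raw series).
#' @return List with `min_ratio`, `max_ratio`, `std_ratio` (sd of
#'   value/K over the window), `K`, and the `window` used.
#' @examples
#' s <- data.frame(time = seq(0, 10, 0.01),
#'                 value = 0.5 * (1 + 0.2 * sin(seq(0, 10, 0.01))))
#' oscillation_interval(s, K = 0.5, transient = 0)
#' @export
oscillation_interval <- function(x, window = NULL, transient = 0.05,
                                 K = NULL) {
  s <- window_series(global_series(x, K), window, transient)
  r <- s$value / s$K
  list(min_ratio = min(r), max_ratio = max(r),
       std_ratio = stats::sd(r), K = s$K,
       window = range(s$time))
}

#' Count major peaks and valleys of the global density series
#'
#' Detects local extremes with a minimum-separation rule and keeps only the
#' "major" ones: peaks whose height is within `closeness` of the window
#' maximum (relative to the full min-max range), and symmetrically for
#' valleys. Small ripples riding on the main oscillation are thereby
#' excluded. Counts are invariant under shifting or rescaling the series.
#'
#' @inheritParams oscillation_interval
#' @param closeness Fraction of the min-max range within which an extremum
#'   must approach the interval limit to count as major (default `0.10`).
#' @param min_separation Minimum distance between counted extremes, as a
#'   fraction of the window length (default `0.02`).
#' @return Named integer vector `c(n_major_peaks, n_major_valleys)`.
#' @export
count_extremes <- function(x, closeness = 0.10, min_separation = 0.02,
                           window = NULL, transient = 0.05, K = NULL) {
  stopifnot(closeness > 0, closeness < 1)
  s <- window_series(global_series(x, K), window, transient)
  v <- s$value
  rng <- max(v) - min(v)
  if (rng == 0)
    return(c(n_major_peaks = 0L, n_major_valleys = 0L))
  mind <- max(1L, floor(min_separation * length(v)))
  # a "major" extremum is a contiguous excursion of the series into the
  # closeness band at the interval limit; excursions separated by less
  # than the minimum separation are merged into one
  count_side <- function(above) {
    if (!any(above)) return(0L)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ks <- which(r$values)
    n <- 1L
    for (i in seq_along(ks)[-1L])
      if (starts[ks[i]] - ends[ks[i - 1L]] >= mind) n <- n + 1L
    n
  }
  n_peaks <- count_side(v >= max(v) - closeness * rng)
  n_valleys <- count_side(v <= min(v) + closeness * rng)
  c(n_major_peaks = as.integer(n_peaks), n_major_valleys = as.integer(n_valleys))
}

#' Smoothing of the global density with the number of cells
#'
#' In the no-migration scenario the cells oscillate out of phase and their
#' fluctuations average out, so the global density curve becomes smoother
#' as more cells are included. This metric tabulates the standard deviation
#' of the global density / K for a set of no-migration runs with different
#' cell counts.
#'
#' @param trajs List of `fp_trajectory` objects, all from no-migration
#'   runs (`p = 0`) with comparable parameters.
#' @inheritParams oscillation_interval
#' @return Data frame with columns `n_cells`, `std_ratio`, sorted by
#'   increasing cell count.
#' @export
smoothing_metric <- function(trajs, window = NULL, transient = 0.05) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  rows <- lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "fp_trajectory"))
    if (tr$params$p != 0 &&
        !(identical(tr$scenario, "no_migration")))
      stop("smoothing_metric expects no-migration runs only", call. = FALSE)
    osc <- oscillation_interval(tr, window = window, transient = transient)
    data.frame(n_cells = ncol(tr$n_a), std_ratio = osc$std_ratio)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$n_cells), , drop = FALSE]
}

#' Compare a model trajectory with a reference demographic curve
#'
#' Computes the oscillation interval and major-extreme counts for both the
#' model's global human-density series and a reference curve (each relative
#' to its own carrying capacity), and reports the absolute differences.
#'
#' @param traj An `fp_trajectory`.
#' @param reference Two-column (time, value) data frame or list, e.g. read
#'   with [read_reference()] or generated with [make_reference_fixture()].
#' @param K_ref Carrying capacity of the reference curve (taken from the
#'   `K_ref` attribute if present).
#' @param closeness,min_separation Passed to [count_extremes()].
#' @param transient Transient fraction for the model trajectory (the
#'   reference curve is used in full).
#' @return List with per-curve summaries (`model`, `reference`) and the
#'   absolute differences `interval_diff` (length 2: lower, upper) and
#'   `peak_count_diff`, `valley_count_diff`.
#' @export
compare_reference <- function(traj, reference, K_ref = NULL,
                              closeness = 0.10, min_separation = 0.02,
                              transient = 0.05) {
  sref <- global_series(reference, K_ref)
  if (length(sref$time) < 2L)
    stop("reference curve must have at least 2 points", call. = FALSE)
  mo <- oscillation_interval(traj, transient = transient)
  me <- count_extremes(traj, closeness = closeness,
                       min_separation = min_separation,
                       transient = transient)
  ro <- oscillation_interval(reference, K = sref$K, transient = 0)
  re <- count_extremes(reference, closeness = closeness,
                       min_separation = min_separation, transient = 0,
                       K = sref$K)
  list(
    model = c(mo, as.list(me)),
    reference = c(ro, as.list(re)),
    interval_diff = c(lower = abs(mo$min_ratio - ro$min_ratio),
                      upper = abs(mo$max_ratio - ro$max_ratio)),
    peak_count_diff = abs(me[["n_major_peaks"]] - re[["n_major_peaks"]]),
    valley_count_diff = abs(me[["n_major_valleys"]] - re[["n_major_valleys"]]))
}
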