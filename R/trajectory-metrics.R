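# Single-cell motility statistics computed on one track: a data frame with
# strictly increasing t_hours and complete x_um/y_um columns.

check_track <- function(traj) {
  need <- c("t_hours", "x_um", "y_um")
  if (!is.data.frame(traj) || !all(need %in% names(traj)))
    stop_param("a track needs columns t_hours, x_um, y_um")
  if (nrow(traj) < 2L)
    stop_param("a track needs at least 2 time points")
  if (anyNA(traj[need]))
    stop_param("tracks must not contain missing positions or times")
  dt <- diff(traj$t_hours)
  if (any(dt <= 0))
    stop_param("track times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    warning("non-uniform frame interval; lag-based statistics assume uniform sampling",
            call. = FALSE)
  invisible(traj)
}

step_lengths <- function(traj) {
  sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
}

#' Total travelled distance of one track
#'
#' Sum of the Euclidean distances covered between consecutive frames, in um.
#' Always at least the net displacement (triangle inequality).
#'
#' @param traj single-track data frame with columns `t_hours`, `x_um`, `y_um`.
#' @return travelled distance in um.
#' @examples
#' trk <- data.frame(t_hours = 0:3 / 6,
#'                   x_um = c(0, 3, 3, 6), y_um = c(0, 4, 4, 8))
#' travelled_distance(trk)  # 5 + 0 + 5 = 10
#' @export
travelled_distance <- function(traj) {
  check_track(traj)
  sum(step_lengths(traj))
}

#' Net (start-to-end) displacement of one track, in um
#' @inheritParams travelled_distance
#' @export
net_displacement <- function(traj) {
  check_track(traj)
  n <- nrow(traj)
  sqrt((traj$x_um[n] - traj$x_um[1])^2 + (traj$y_um[n] - traj$y_um[1])^2)
}

#' Per-step instantaneous speed series
#'
#' Step length divided by step duration for each consecutive frame pair;
#' the series has one entry fewer than the track has points. For uniform
#' sampling, `mean(speed) * total time` equals the travelled distance.
#'
#' @inheritParams travelled_distance
#' @return numeric vector of speeds, um/h.
#' @export
instantaneous_speed <- function(traj) {
  check_track(traj)
  step_lengths(traj) / diff(traj$t_hours)
}

#' Track straightness (confinement ratio)
#'
#' Net displacement divided by travelled distance: 1 for a straight
#' constant-heading track, near 0 for a track that returns to its origin.
#' Undefined (NA with a warning) for a track that never moves.
#'
#' @inheritParams travelled_distance
#' @return dimensionless value in \[0, 1\], or NA for a stationary track.
#' @export
straightness <- function(traj) {
  check_track(traj)
  path <- sum(step_lengths(traj))
  if (path == 0) {
    warning("zero travelled distance: straightness undefined", call. = FALSE)
    return(NA_real_)
  }
  net_displacement(traj) / path
}

#' Time-averaged mean-squared displacement of one track
#'
#' For each lag \eqn{\tau = k \Delta t}, averages the squared displacement
#' over all overlapping frame pairs `(i, i + k)` of the track, up to
#' `max_lag_fraction` of the track duration. Time-averaging over overlapping
#' pairs is the standard spreadsheet-macro behaviour and uses every
#' available displacement pair.
#'
#' @inheritParams travelled_distance
#' @param max_lag_fraction largest lag as a fraction of track duration,
#'   in (0, 1].
#' @return an `msd_curve`: data frame with columns `lag_h`, `msd_um2`,
#'   `n_pairs`.
#' @examples
#' trk <- data.frame(t_hours = 0:10, x_um = 2 * (0:10), y_um = 0)
#' msd <- compute_msd(trk, max_lag_fraction = 0.5)
#' msd$msd_um2[3]  # ballistic: (v * tau)^2 = (2 * 3)^2 = 36
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.5) {
  check_track(traj)
  if (!is.numeric(max_lag_fraction) || length(max_lag_fraction) != 1L ||
      is.na(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop_param("'max_lag_fraction' must lie in (0, 1]")
  n <- nrow(traj)
  dt <- mean(diff(traj$t_hours))
  k_max <- max(1L, floor(max_lag_fraction * (n - 1L)))
  x <- traj$x_um
  y <- traj$y_um
  msd <- numeric(k_max)
  for (k in seq_len(k_max)) {
    i <- seq_len(n - k)
    msd[k] <- mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }
  out <- data.frame(lag_h = seq_len(k_max) * dt, msd_um2 = msd,
                    n_pairs = n - seq_len(k_max))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Pool MSD curves across cells
#'
#' Pair-count-weighted mean of per-track MSD curves sharing one lag grid,
#' giving the ensemble MSD used for diffusion estimation.
#'
#' @param curves list of `msd_curve` objects on a common lag grid (curves
#'   are truncated to the shortest shared grid).
#' @return an `msd_curve` with summed `n_pairs`.
#' @export
ensemble_msd <- function(curves) {
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  if (!is.list(curves) || length(curves) == 0L)
    stop_param("'curves' must be a non-empty list of msd_curve objects")
  k <- min(vapply(curves, nrow, 1L))
  if (k < 1L) stop_param("empty MSD curve supplied")
  lag <- curves[[1L]]$lag_h[seq_len(k)]
  for (cv in curves)
    if (max(abs(cv$lag_h[seq_len(k)] - lag)) > 1e-8 * max(lag))
      stop_param("MSD curves do not share a lag grid")
  w <- vapply(curves, function(cv) cv$n_pairs[seq_len(k)], numeric(k))
  m <- vapply(curves, function(cv) cv$msd_um2[seq_len(k)], numeric(k))
  w <- matrix(w, nrow = k)
  m <- matrix(m, nrow = k)
  out <- data.frame(lag_h = lag,
                    msd_um2 = rowSums(m * w) / rowSums(w),
                    n_pairs = as.integer(rowSums(w)))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Estimate the diffusion coefficient from an MSD curve
#'
#' Fits a through-origin least-squares line to MSD versus lag over the first
#' `fit_fraction` of available lags and reports \eqn{D} = slope / 4, the 2D
#' diffusion relation \eqn{MSD = 4 D \tau}. Short-lag fitting is the default
#' because MSD estimator variance grows with lag. A negative fitted slope is
#' clamped to \eqn{D = 0} and flagged; goodness is the uncentred
#' \eqn{R^2} of the through-origin fit.
#'
#' @param msd an `msd_curve`.
#' @param fit_fraction fraction of lags used for the fit, in (0, 1].
#' @return a `diffusion_estimate` list: `D` (um^2/h), `slope`, `fit_lags`
#'   (lag window, h), `r_squared`, `clamped`.
#' @examples
#' msd <- data.frame(lag_h = 1:8, msd_um2 = 4 * (1:8), n_pairs = 8:1)
#' estimate_diffusion(msd)$D  # 1
#' @export
estimate_diffusion <- function(msd, fit_fraction = 0.25) {
  if (!all(c("lag_h", "msd_um2") %in% names(msd)))
    stop_param("'msd' must have columns lag_h and msd_um2")
  if (!is.numeric(fit_fraction) || length(fit_fraction) != 1L ||
      is.na(fit_fraction) || fit_fraction <= 0 || fit_fraction > 1)
    stop_param("'fit_fraction' must lie in (0, 1]")
  k <- max(2L, ceiling(fit_fraction * nrow(msd)))
  if (nrow(msd) < 2L) stop_param("need at least 2 lags to fit")
  k <- min(k, nrow(msd))
  lag <- msd$lag_h[seq_len(k)]
  y <- msd$msd_um2[seq_len(k)]
  if (all(y == 0)) {
    est <- list(D = 0, slope = 0, fit_lags = range(lag), r_squared = NA_real_,
                clamped = FALSE)
    class(est) <- "diffusion_estimate"
    return(est)
  }
  slope <- sum(y * lag) / sum(lag^2)
  r2 <- 1 - sum((y - slope * lag)^2) / sum(y^2)
  clamped <- slope < 0
  est <- list(D = max(slope, 0) / 4, slope = slope, fit_lags = range(lag),
              r_squared = r2, clamped = clamped)
  class(est) <- "diffusion_estimate"
  est
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate: D = %.4g um^2/h (MSD = 4 D t)\n", x$D))
  cat(sprintf("  fit window: %.3g-%.3g h, R^2 = %.4f%s\n",
              x$fit_lags[1], x$fit_lags[2],
              if (is.na(x$r_squared)) NA else x$r_squared,
              if (isTRUE(x$clamped)) " [negative slope clamped to 0]" else ""))
  invisible(x)
}

#' Per-track motility metrics table
#'
#' Applies the single-cell statistics to every track of a trajectory table:
#' travelled distance, net displacement, straightness, and a per-track
#' diffusion estimate from the time-averaged MSD.
#'
#' @param tracks a `trajectory_set` data frame.
#' @param fit_fraction passed to [estimate_diffusion()].
#' @param max_lag_fraction passed to [compute_msd()].
#' @return data frame with one row per track: `track_id`, `travelled_um`,
#'   `net_um`, `straightness`, `D_um2_per_h`, `fit_r2`.
#' @export
track_metrics <- function(tracks, fit_fraction = 0.25, max_lag_fraction = 0.5) {
  per <- split_tracks(tracks)
  rows <- lapply(names(per), function(id) {
    tr <- per[[id]]
    fit <- estimate_diffusion(compute_msd(tr, max_lag_fraction), fit_fraction)
    path <- travelled_distance(tr)
    data.frame(track_id = id,
               travelled_um = path,
               net_um = net_displacement(tr),
               straightness = if (path > 0) net_displacement(tr) / path else NA_real_,
               D_um2_per_h = fit$D,
               fit_r2 = fit$r_squared)
  })
  do.call(rbind, rows)
}
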