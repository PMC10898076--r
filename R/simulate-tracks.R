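#' Simulate Brownian cell trajectories
#'
#' Generates 2D trajectories whose per-axis displacements between consecutive
#' frames are independent zero-mean Gaussian steps with variance
#' \eqn{2 D \Delta t}, the discrete sampling of an isotropic diffusion with
#' coefficient \eqn{D}. The ensemble mean-squared displacement of such tracks
#' grows as \eqn{MSD(\tau) = 4 D \tau}, which is the relation used by
#' [estimate_diffusion()] to recover \eqn{D}.
#'
#' Defaults reproduce a 24 h time-lapse imaged every 10 minutes
#' (145 frames at 1/6 h), with frame 0 at \eqn{t = 0}.
#'
#' @param n_tracks number of cells to simulate.
#' @param n_frames frames per track (>= 2).
#' @param frame_interval time between frames, hours.
#' @param diffusion diffusion coefficient \eqn{D}, um^2/h (>= 0).
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return A `trajectory_set`: a data frame with columns `track_id`, `frame`,
#'   `t_hours`, `x_um`, `y_um`, one row per (track, frame).
#' @examples
#' trk <- simulate_brownian(n_tracks = 5, n_frames = 20, diffusion = 1, seed = 1)
#' head(trk)
#' @seealso [simulate_prw()] for persistent/biased walks.
#' @export
simulate_brownian <- function(n_tracks, n_frames = 145L, frame_interval = 1 / 6,
                              diffusion = 1, seed = NULL) {
  n_tracks <- check_count(n_tracks, "n_tracks")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  frame_interval <- check_positive(frame_interval, "frame_interval")
  diffusion <- check_positive(diffusion, "diffusion", strict = FALSE)

  with_seed(seed, {
    sd_step <- sqrt(2 * diffusion * frame_interval)
    n_steps <- n_frames - 1L
    dx <- matrix(stats::rnorm(n_tracks * n_steps, sd = sd_step), n_steps, n_tracks)
    dy <- matrix(stats::rnorm(n_tracks * n_steps, sd = sd_step), n_steps, n_tracks)
    x <- rbind(0, apply(dx, 2L, cumsum))
    y <- rbind(0, apply(dy, 2L, cumsum))
    new_trajectory_set(x, y, frame_interval)
  })
}

#' Simulate persistent, optionally biased, random-walk trajectories
#'
#' A constant-speed walk whose heading decorrelates over `persistence_time`
#' (wrapped-Gaussian heading increments with variance
#' \eqn{2 \Delta t / P}) and is pulled toward a fixed `bias_direction` with
#' weight `bias_strength`: at each step the heading first relaxes a fraction
#' `bias_strength` of the angular gap to the bias direction, then receives
#' the stochastic increment. `bias_strength = 1` with infinite persistence
#' gives perfectly straight tracks along the bias direction;
#' `bias_strength = 0` with `persistence_time = 0` is an uncorrelated
#' fixed-step walk whose long-lag MSD scales linearly with lag.
#'
#' @inheritParams simulate_brownian
#' @param speed cell speed, um/h; the step length is `speed * frame_interval`.
#' @param persistence_time heading decorrelation time, hours (>= 0; `Inf`
#'   freezes the heading). `0` redraws the heading uniformly each frame.
#' @param bias_strength pull toward `bias_direction`, in \[0, 1\].
#' @param bias_direction bias heading, radians.
#' @return A `trajectory_set` data frame (see [simulate_brownian()]).
#' @export
simulate_prw <- function(n_tracks, n_frames = 145L, frame_interval = 1 / 6,
                         speed = 20, persistence_time = 1,
                         bias_strength = 0, bias_direction = 0, seed = NULL) {
  n_tracks <- check_count(n_tracks, "n_tracks")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  frame_interval <- check_positive(frame_interval, "frame_interval")
  speed <- check_positive(speed, "speed", strict = FALSE)
  if (!is.numeric(persistence_time) || length(persistence_time) != 1L ||
      is.na(persistence_time) || persistence_time < 0)
    stop_param("'persistence_time' must be a single number >= 0 (Inf allowed)")
  if (!is.numeric(bias_strength) || length(bias_strength) != 1L ||
      is.na(bias_strength) || bias_strength < 0 || bias_strength > 1)
    stop_param("'bias_strength' must lie in [0, 1]")

  with_seed(seed, {
    n_steps <- n_frames - 1L
    step <- speed * frame_interval
    sigma <- if (is.infinite(persistence_time)) 0
             else if (persistence_time == 0) Inf
             else sqrt(2 * frame_interval / persistence_time)

    theta <- stats::runif(n_tracks, -pi, pi)
    dx <- matrix(0, n_steps, n_tracks)
    dy <- matrix(0, n_steps, n_tracks)
    for (i in seq_len(n_steps)) {
      theta <- theta + bias_strength * wrap_angle(bias_direction - theta)
      if (is.infinite(sigma)) {
        theta <- theta + stats::runif(n_tracks, -pi, pi)
      } else if (sigma > 0) {
        theta <- theta + stats::rnorm(n_tracks, sd = sigma)
      }
      theta <- wrap_angle(theta)
      dx[i, ] <- step * cos(theta)
      dy[i, ] <- step * sin(theta)
    }
    x <- rbind(0, apply(dx, 2L, cumsum))
    y <- rbind(0, apply(dy, 2L, cumsum))
    new_trajectory_set(x, y, frame_interval)
  })
}

# x, y: n_frames x n_tracks position matrices starting at the origin.
new_trajectory_set <- function(x, y, frame_interval) {
  n_frames <- nrow(x)
  n_tracks <- ncol(x)
  out <- data.frame(
    track_id = rep(seq_len(n_tracks), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_tracks),
    t_hours = rep((seq_len(n_frames) - 1L) * frame_interval, n_tracks),
    x_um = as.vector(x),
    y_um = as.vector(y)
  )
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' Split a trajectory table into single tracks
#'
#' @param tracks a `trajectory_set` or any data frame with columns
#'   `track_id`, `t_hours`, `x_um`, `y_um`.
#' @return named list of single-track data frames ordered by time.
#' @keywords internal
#' @export
split_tracks <- function(tracks) {
  need <- c("track_id", "t_hours", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop_param("trajectory table needs columns: ", paste(need, collapse = ", "))
  out <- split(tracks[setdiff(names(tracks), "track_id")], tracks$track_id)
  lapply(out, function(d) d[order(d$t_hours), , drop = FALSE])
}
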