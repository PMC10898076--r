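#' Simulate a gap-closure (wound-healing) movie with known ground truth
#'
#' Builds a binary mask stack of two cell fronts closing a vertical gap.
#' The gap is a band in the middle of the image; fronts advance horizontally
#' at `front_speed` each, so the gap narrows by `2 * front_speed *
#' frame_interval` per frame. On every frame after the first, each image row
#' ("column" of the wound) receives an independent Gaussian front offset
#' with variance `roughness_variance`, redrawn per frame (memoryless
#' roughness). Frame 0 is the straight barrier edge, so the distance between
#' a later front and the initial edge has variance exactly
#' `roughness_variance` per row — the planted truth recovered by
#' [edge_regularity()].
#'
#' @param width_px,height_px image size in pixels; fronts advance along the
#'   width (x) axis, rows index positions along the wound.
#' @param initial_gap starting gap width, um (> 0).
#' @param front_speed advance speed of each front, um/h.
#' @param roughness_variance per-row Gaussian offset variance, um^2 (>= 0).
#' @param pixel_size pixel edge, um.
#' @param n_frames,frame_interval movie length and sampling (default 6 h at
#'   10-min intervals, the evaluation window of the regularity statistic).
#' @param seed integer seed.
#' @return list of class `wound_sim` with elements
#'   \describe{
#'     \item{stack}{a [mask_stack()] of binary frames}
#'     \item{truth}{list with `t_h`, `gap_area_um2` (from the emitted masks),
#'       `left_um` and `right_um` (H x T matrices of continuous front
#'       positions, um)}
#'   }
#' @export
simulate_wound <- function(width_px = 400L, height_px = 400L,
                           initial_gap = 300, front_speed = 10,
                           roughness_variance = 25, pixel_size = 2,
                           n_frames = 37L, frame_interval = 1 / 6,
                           seed = NULL) {
  width_px <- check_count(width_px, "width_px", min = 2L)
  height_px <- check_count(height_px, "height_px")
  initial_gap <- check_positive(initial_gap, "initial_gap")
  front_speed <- check_positive(front_speed, "front_speed", strict = FALSE)
  roughness_variance <- check_positive(roughness_variance, "roughness_variance",
                                       strict = FALSE)
  pixel_size <- check_positive(pixel_size, "pixel_size")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  frame_interval <- check_positive(frame_interval, "frame_interval")

  width_um <- width_px * pixel_size
  if (initial_gap >= width_um)
    stop_param("'initial_gap' must be smaller than the image width")
  if (2 * front_speed * frame_interval >= initial_gap)
    stop_param("gap would close before frame 1; reduce front_speed or frame_interval")

  with_seed(seed, {
    sd_off <- sqrt(roughness_variance)
    left0 <- (width_um - initial_gap) / 2
    right0 <- left0 + initial_gap
    t_h <- (seq_len(n_frames) - 1L) * frame_interval
    centers <- (seq_len(width_px) - 0.5) * pixel_size

    frames <- array(0L, dim = c(height_px, width_px, n_frames))
    left_um <- matrix(0, height_px, n_frames)
    right_um <- matrix(0, height_px, n_frames)
    for (n in seq_len(n_frames)) {
      l <- rep(left0 + front_speed * t_h[n], height_px)
      r <- rep(right0 - front_speed * t_h[n], height_px)
      if (n > 1L && sd_off > 0) {
        l <- l + stats::rnorm(height_px, sd = sd_off)
        r <- r + stats::rnorm(height_px, sd = sd_off)
      }
      # once the fronts meet in a row, the row is closed
      mask <- outer(l, centers, function(L, x) x < L) |
        outer(r, centers, function(R, x) x > R)
      mask[l >= r, ] <- TRUE
      frames[, , n] <- mask * 1L
      left_um[, n] <- l
      right_um[, n] <- r
    }
    stack <- mask_stack(frames, pixel_size = pixel_size,
                        frame_interval = frame_interval)
    gap_area <- apply(frames, 3L, function(f) sum(f == 0L)) * pixel_size^2
    structure(list(stack = stack,
                   truth = list(t_h = t_h, gap_area_um2 = gap_area,
                                left_um = left_um, right_um = right_um)),
              class = "wound_sim")
  })
}

#' Binary mask stack container
#'
#' @param frames H x W x T array (or H x W matrix for a single frame) of
#'   binary values (0/1 or logical); background 0 is the open gap.
#' @param pixel_size pixel edge, um.
#' @param frame_interval time between frames, hours.
#' @param gap_axis `"x"` if the fronts advance along image columns (gap is a
#'   vertical band, the default), `"y"` if along rows.
#' @return list of class `mask_stack`.
#' @export
mask_stack <- function(frames, pixel_size, frame_interval,
                       gap_axis = c("x", "y")) {
  gap_axis <- match.arg(gap_axis)
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_param("'frames' must be an H x W x T array")
  v <- unique(as.vector(frames))
  if (!all(v %in% c(0, 1)))
    stop_param("mask values must be binary (0/1)")
  pixel_size <- check_positive(pixel_size, "pixel_size")
  frame_interval <- check_positive(frame_interval, "frame_interval")
  structure(list(frames = frames != 0, pixel_size = pixel_size,
                 frame_interval = frame_interval, gap_axis = gap_axis),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("mask_stack: %d frames of %d x %d px (%.3g um/px, %.3g h/frame), gap axis %s\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval, x$gap_axis))
  invisible(x)
}

#' @export
print.wound_sim <- function(x, ...) {
  print(x$stack)
  cat(sprintf("  truth: initial gap area %.4g um^2, %d frames\n",
              x$truth$gap_area_um2[1], length(x$truth$gap_area_um2)))
  invisible(x)
}
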