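# Collective gap-closure statistics from binary mask stacks.

get_frame <- function(stack, frame) {
  if (!inherits(stack, "mask_stack")) stop_param("expected a mask_stack")
  n <- dim(stack$frames)[3]
  frame <- check_count(frame, "frame")
  if (frame > n) stop_param("frame index out of range")
  m <- stack$frames[, , frame]
  if (stack$gap_axis == "y") m <- t(m)
  m
}

#' Open-gap area of one binary frame
#'
#' Counts background (gap) pixels and converts to um^2. A fully closed
#' frame returns 0.
#'
#' @param frame binary matrix (foreground = cells, background = gap).
#' @param pixel_size pixel edge, um.
#' @return gap area, um^2.
#' @export
gap_area <- function(frame, pixel_size) {
  pixel_size <- check_positive(pixel_size, "pixel_size")
  v <- unique(as.vector(frame))
  if (!all(v %in% c(0, 1, FALSE, TRUE)))
    stop_param("'frame' must be binary")
  sum(frame == 0) * pixel_size^2
}

#' Wound closure rate
#'
#' The printed closure statistic \eqn{(A_0 - A_n)/A_0 \times 100}: 0% for no
#' closure, 100% for a fully closed wound. `An > A0` (monolayer retraction)
#' is allowed and yields a negative percentage with a warning.
#'
#' @param A0 initial gap area, um^2 (> 0).
#' @param An gap area at the evaluated time, um^2 (>= 0).
#' @return closure percentage.
#' @export
closure_rate <- function(A0, An) {
  if (!is.numeric(A0) || any(A0 <= 0)) stop_param("'A0' must be > 0")
  if (!is.numeric(An) || any(An < 0)) stop_param("'An' must be >= 0")
  if (any(An > A0))
    warning("An > A0: negative closure (retraction) reported", call. = FALSE)
  (A0 - An) / A0 * 100
}

#' Gap area and closure percentage over time
#'
#' @param stack a [mask_stack()].
#' @return a `closure_series` data frame: `t_h`, `area_um2`, `closed_pct`.
#' @export
closure_series <- function(stack) {
  if (!inherits(stack, "mask_stack")) stop_param("expected a mask_stack")
  n <- dim(stack$frames)[3]
  area <- vapply(seq_len(n), function(i)
    gap_area(get_frame(stack, i), stack$pixel_size), numeric(1))
  if (area[1] <= 0) stop_param("initial frame has no open gap (A0 = 0)")
  out <- data.frame(t_h = (seq_len(n) - 1L) * stack$frame_interval,
                    area_um2 = area,
                    closed_pct = closure_rate(area[1], area))
  class(out) <- c("closure_series", "data.frame")
  out
}

#' Time to reach a fractional closure
#'
#' First time the closure percentage crosses `fraction`, linearly
#' interpolated between the bracketing frames. Returns NA with a warning if
#' the series never reaches the fraction.
#'
#' @param series a `closure_series` (or data frame with `t_h`, `closed_pct`).
#' @param fraction target closure, percent, in (0, 100].
#' @return time in hours, or NA if never reached.
#' @examples
#' s <- data.frame(t_h = c(0, 4, 6), closed_pct = c(0, 40, 60))
#' time_to_fraction(s, 50)  # 5
#' @export
time_to_fraction <- function(series, fraction = 50) {
  if (!all(c("t_h", "closed_pct") %in% names(series)) || nrow(series) == 0L)
    stop_param("'series' must be a non-empty closure series")
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 100)
    stop_param("'fraction' must lie in (0, 100]")
  pct <- series$closed_pct
  t_h <- series$t_h
  hit <- which(pct >= fraction)
  if (length(hit) == 0L) {
    warning(sprintf("closure never reaches %.3g%%", fraction), call. = FALSE)
    return(NA_real_)
  }
  i <- hit[1L]
  if (i == 1L) return(t_h[1L])
  # linear interpolation between the bracketing frames
  t_h[i - 1L] + (fraction - pct[i - 1L]) / (pct[i] - pct[i - 1L]) *
    (t_h[i] - t_h[i - 1L])
}

#' Gap-closure velocity over time
#'
#' Finite-difference rate of the closed area, and the equivalent mean edge
#' advance (area rate divided by twice the wound length, two fronts).
#' `align = "center"` uses a centred difference over `window` frames with
#' one-sided differences at the ends; `align = "trailing"` uses trailing
#' differences, whose sum times the frame interval telescopes exactly to the
#' total closed area.
#'
#' @param series a `closure_series`.
#' @param wound_length extent of the wound along the fronts, um (the length
#'   over which the gap is measured).
#' @param window half-width (frames) of the difference stencil, >= 1.
#' @param align `"center"` or `"trailing"`.
#' @return data frame: `t_h`, `area_rate_um2_per_h`, `edge_speed_um_per_h`
#'   (`NA` where a trailing difference is undefined).
#' @export
front_velocity <- function(series, wound_length, window = 1L,
                           align = c("center", "trailing")) {
  align <- match.arg(align)
  if (!all(c("t_h", "area_um2") %in% names(series)))
    stop_param("'series' must be a closure series")
  window <- check_count(window, "window")
  n <- nrow(series)
  if (window >= n) stop_param("'window' larger than the series")
  wound_length <- check_positive(wound_length, "wound_length")
  closed <- series$area_um2[1L] - series$area_um2
  t_h <- series$t_h
  rate <- rep(NA_real_, n)
  if (align == "center") {
    for (i in seq_len(n)) {
      lo <- max(1L, i - window)
      hi <- min(n, i + window)
      rate[i] <- (closed[hi] - closed[lo]) / (t_h[hi] - t_h[lo])
    }
  } else {
    for (i in (window + 1L):n)
      rate[i] <- (closed[i] - closed[i - window]) / (t_h[i] - t_h[i - window])
  }
  data.frame(t_h = t_h, area_rate_um2_per_h = rate,
             edge_speed_um_per_h = rate / (2 * wound_length))
}

#' Extract the leading-edge profile of a frame
#'
#' For each row along the wound, reports the gap-facing boundary of the
#' foreground on each side: the boundary between the last foreground pixel
#' and the first gap pixel, converted to um (a front flush after pixel `k`
#' sits at `k * pixel_size`). Rows where the gap is locally closed are
#' flagged and carry NA positions.
#'
#' @param frame binary matrix, fronts advancing along columns.
#' @param pixel_size pixel edge, um.
#' @param t_h frame time, hours (stored as attribute).
#' @return a `front_profile` data frame: `line`, `left_um`, `right_um`,
#'   `closed`.
#' @export
extract_front <- function(frame, pixel_size, t_h = NA_real_) {
  pixel_size <- check_positive(pixel_size, "pixel_size")
  m <- frame != 0
  H <- nrow(m); W <- ncol(m)
  first_gap <- apply(m, 1L, function(r) {
    i <- which(!r)
    if (length(i)) i[1L] else NA_integer_
  })
  last_gap <- apply(m, 1L, function(r) {
    i <- which(!r)
    if (length(i)) i[length(i)] else NA_integer_
  })
  closed <- is.na(first_gap)
  left_um <- (first_gap - 1L) * pixel_size
  right_um <- last_gap * pixel_size
  left_um[closed] <- NA_real_
  right_um[closed] <- NA_real_
  out <- data.frame(line = seq_len(H), left_um = left_um,
                    right_um = right_um, closed = closed)
  attr(out, "t_h") <- t_h
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("front_profile", "data.frame")
  out
}

#' Leading-edge regularity (dispersion of edge travel)
#'
#' Sample variance (n - 1 denominator), across rows along the wound, of the
#' unsigned distance between a front's position at the evaluated time and
#' its initial position. Low values mean a coordinated, even front; high
#' values an irregular one. Computed per side and averaged over the two
#' fronts; rows closed at either time are excluded.
#'
#' @param front_t,front_0 `front_profile`s of the evaluated and initial
#'   frames, on the same rows.
#' @param sides `"both"` (average of per-side variances), `"left"` or
#'   `"right"`.
#' @return variance in um^2, with attribute `per_side`.
#' @export
edge_regularity <- function(front_t, front_0, sides = c("both", "left", "right")) {
  sides <- match.arg(sides)
  if (nrow(front_t) != nrow(front_0))
    stop_param("front profiles must share their rows")
  ok <- !front_t$closed & !front_0$closed
  per_side <- c(left = NA_real_, right = NA_real_)
  if (sides %in% c("both", "left")) {
    d <- abs(front_t$left_um[ok] - front_0$left_um[ok])
    if (length(d) < 2L) stop_param("fewer than 2 open rows for the left front")
    per_side["left"] <- stats::var(d)
  }
  if (sides %in% c("both", "right")) {
    d <- abs(front_t$right_um[ok] - front_0$right_um[ok])
    if (length(d) < 2L) stop_param("fewer than 2 open rows for the right front")
    per_side["right"] <- stats::var(d)
  }
  out <- mean(per_side, na.rm = TRUE)
  attr(out, "per_side") <- per_side
  out
}

#' Edge regularity of a mask stack at a given time
#'
#' Convenience wrapper: extracts the initial and evaluated front profiles
#' from a stack and applies [edge_regularity()]. The default evaluation time
#' of 6 h matches the usual reporting point for gap-closure movies.
#'
#' @param stack a [mask_stack()].
#' @param at_time evaluation time, hours (nearest frame is used).
#' @inheritParams edge_regularity
#' @return variance in um^2 with attributes `per_side` and `t_h`.
#' @export
wound_regularity <- function(stack, at_time = 6, sides = "both") {
  if (!inherits(stack, "mask_stack")) stop_param("expected a mask_stack")
  n <- dim(stack$frames)[3]
  idx <- round(at_time / stack$frame_interval) + 1L
  if (idx < 1L || idx > n) stop_param("'at_time' outside the movie")
  f0 <- extract_front(get_frame(stack, 1L), stack$pixel_size, t_h = 0)
  ft <- extract_front(get_frame(stack, idx), stack$pixel_size,
                      t_h = (idx - 1L) * stack$frame_interval)
  out <- edge_regularity(ft, f0, sides = sides)
  attr(out, "t_h") <- (idx - 1L) * stack$frame_interval
  out
}
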