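#' Worm centroid track
#'
#' Time-stamped 2-D centroid positions for a single animal at a known frame
#' rate, the raw material for all locomotion metrics.
#'
#' @param worm_id animal label.
#' @param t strictly increasing timestamps (seconds).
#' @param x,y centroid coordinates (mm).
#' @param fps frames per second (informational).
#' @return Object of class `"worm_track"`.
#' @export
worm_track <- function(worm_id, t, x, y, fps = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y)) {
    stop("t, x and y must have equal length", call. = FALSE)
  }
  if (length(t) < 2) stop("a track needs at least 2 samples", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(worm_id = as.character(worm_id), t = t, x = x, y = y,
                 fps = fps %||% 1 / stats::median(diff(t))),
            class = "worm_track")
}

#' Instantaneous speeds along a track
#'
#' Euclidean displacement between consecutive samples divided by the
#' elapsed time. Tracker jitter can inflate apparent slow-speed fractions,
#' so an optional window-3 rolling-median smoother is available (off by
#' default; when used, record the choice alongside results).
#'
#' @param track a [worm_track()].
#' @param smooth apply a window-3 rolling median to the speed series.
#' @return Numeric vector of per-interval speeds (mm/s), length
#'   `length(track$t) - 1`.
#' @examples
#' tr <- worm_track("w1", 0:3, c(0, 0.03, 0.06, 0.09), c(0, 0.04, 0.08, 0.12))
#' instantaneous_speeds(tr)  # 0.05 0.05 0.05
#' @export
instantaneous_speeds <- function(track, smooth = FALSE) {
  stopifnot(inherits(track, "worm_track"))
  dt <- diff(track$t)
  if (any(dt <= 0)) stop("duplicate or decreasing timestamps", call. = FALSE)
  sp <- sqrt(diff(track$x)^2 + diff(track$y)^2) / dt
  if (smooth && length(sp) >= 3) sp <- stats::runmed(sp, 3)
  sp
}

#' Count directional shifts along a track
#'
#' A directional shift is a transition where the angle between successive
#' above-noise displacement vectors exceeds `angle_threshold`. Steps
#' shorter than `min_step` are treated as tracker noise: they are skipped
#' and do not define a heading, so a stationary worm scores zero. The
#' default 90 degree threshold targets reversals, the locomotory feature
#' that increases with age and neurodegeneration.
#'
#' @param track a [worm_track()] with at least 3 samples.
#' @param angle_threshold heading-change threshold in degrees (strict `>`).
#' @param min_step noise floor for a displacement to define a heading (mm).
#' @return Integer count of shifts.
#' @examples
#' # 1-D path stepping +1, +1, -1, +1 mm: two reversals
#' tr <- worm_track("w1", 0:4, cumsum(c(0, 1, 1, -1, 1)), rep(0, 5))
#' count_directional_shifts(tr, min_step = 0.5)  # 2
#' @export
count_directional_shifts <- function(track, angle_threshold = 90,
                                     min_step = 0.005) {
  stopifnot(inherits(track, "worm_track"))
  if (length(track$t) < 3) stop("need at least 3 samples", call. = FALSE)
  dx <- diff(track$x); dy <- diff(track$y)
  len <- sqrt(dx^2 + dy^2)
  keep <- len >= min_step
  if (sum(keep) < 2) return(0L)
  heading <- atan2(dy[keep], dx[keep])
  dtheta <- diff(heading) * 180 / pi
  # wrap to (-180, 180]
  dtheta <- dtheta - 360 * round(dtheta / 360)
  sum(abs(dtheta) > angle_threshold)
}

#' Paralysis decision rule
#'
#' An animal is called paralyzed when more than 80% of its instantaneous
#' speeds fall below 0.015 mm/s (defaults). The comparison on the slow
#' fraction is strict by default ("more than"), so a worm with exactly 80%
#' slow frames is still motile.
#'
#' @param speed_threshold speed below which a frame counts as slow (mm/s).
#' @param slow_fraction_threshold fraction of slow frames above which the
#'   worm is paralyzed; in (0, 1).
#' @param strict use strict `>` on the slow fraction.
#' @return Object of class `"paralysis_rule"`.
#' @export
paralysis_rule <- function(speed_threshold = 0.015,
                           slow_fraction_threshold = 0.80,
                           strict = TRUE) {
  if (speed_threshold <= 0) stop("speed_threshold must be positive", call. = FALSE)
  if (slow_fraction_threshold <= 0 || slow_fraction_threshold >= 1) {
    stop("slow_fraction_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(speed_threshold = speed_threshold,
                 slow_fraction_threshold = slow_fraction_threshold,
                 strict = isTRUE(strict)),
            class = "paralysis_rule")
}

#' Classify a worm as paralyzed from its speed series
#'
#' @param speeds numeric vector of instantaneous speeds (mm/s).
#' @param rule a [paralysis_rule()].
#' @return List with `paralyzed` (logical) and `frac_slow` (fraction of
#'   speeds below the rule's speed threshold).
#' @examples
#' classify_paralysis(c(rep(0.01, 85), rep(0.1, 15)))  # paralyzed
#' @export
classify_paralysis <- function(speeds, rule = paralysis_rule()) {
  if (length(speeds) == 0) stop("empty speed series", call. = FALSE)
  stopifnot(inherits(rule, "paralysis_rule"))
  frac_slow <- mean(speeds < rule$speed_threshold)
  paralyzed <- if (rule$strict) {
    frac_slow > rule$slow_fraction_threshold
  } else {
    frac_slow >= rule$slow_fraction_threshold
  }
  list(paralyzed = paralyzed, frac_slow = frac_slow)
}

#' Per-worm locomotion metrics
#'
#' Convenience wrapper computing the full metric row for one track.
#'
#' @param track a [worm_track()].
#' @param rule a [paralysis_rule()].
#' @param angle_threshold,min_step passed to [count_directional_shifts()].
#' @param smooth passed to [instantaneous_speeds()].
#' @return One-row data.frame: `worm_id`, `mean_speed`, `n_direction_shifts`,
#'   `paralyzed`, `frac_slow`, `smoothed`.
#' @export
track_metrics <- function(track, rule = paralysis_rule(),
                          angle_threshold = 90, min_step = 0.005,
                          smooth = FALSE) {
  sp <- instantaneous_speeds(track, smooth = smooth)
  cls <- classify_paralysis(sp, rule)
  data.frame(
    worm_id = track$worm_id,
    mean_speed = mean(sp),
    n_direction_shifts = count_directional_shifts(track, angle_threshold,
                                                  min_step),
    paralyzed = cls$paralyzed,
    frac_slow = cls$frac_slow,
    smoothed = smooth,
    stringsAsFactors = FALSE
  )
}

#' Direction rescue index
#'
#' Normalizes a treatment group's directional-shift counts against the
#' untreated control group: the index is the fraction of treated animals
#' whose shift count falls strictly below the control group's mean. Because
#' shift counts rise with frailty, a higher index means stronger rescue of
#' the locomotory deficit.
#'
#' @param treated_shifts integer vector of per-worm shift counts in the
#'   treatment group.
#' @param control_shifts integer vector of per-worm shift counts in the
#'   untreated control group.
#' @return Object of class `"rescue_index"`: list with `control_mean`,
#'   `n_below`, `n_total` and `index` (= n_below / n_total, in \[0, 1\]).
#' @examples
#' direction_rescue_index(c(5, 10, 15, 20), c(12, 12))$index  # 0.5
#' @export
direction_rescue_index <- function(treated_shifts, control_shifts) {
  if (length(treated_shifts) == 0) stop("empty treated group", call. = FALSE)
  if (length(control_shifts) == 0) stop("empty control group", call. = FALSE)
  control_mean <- mean(control_shifts)
  n_below <- sum(treated_shifts < control_mean)
  structure(list(control_mean = control_mean,
                 n_below = n_below,
                 n_total = length(treated_shifts),
                 index = n_below / length(treated_shifts)),
            class = "rescue_index")
}

#' @export
print.rescue_index <- function(x, ...) {
  cat(sprintf("Direction rescue index = %.3f (%d of %d below control mean %.2f)\n",
              x$index, x$n_below, x$n_total, x$control_mean))
  invisible(x)
}

#' Fraction of animals not paralyzed
#'
#' @param metrics data.frame with a logical `paralyzed` column, e.g. rows
#'   from [track_metrics()].
#' @return `1 - (paralyzed count / total)`.
#' @export
fraction_not_paralyzed <- function(metrics) {
  if (!"paralyzed" %in% names(metrics) || nrow(metrics) == 0) {
    stop("metrics must have >= 1 row and a 'paralyzed' column", call. = FALSE)
  }
  1 - mean(as.logical(metrics$paralyzed))
}
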