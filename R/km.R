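#' Kaplan-Meier survival curve for one experimental group
#'
#' Product-limit estimate of the survival function. Ties between deaths and
#' censorings at the same time are resolved deaths-first (the standard
#' product-limit convention). The fitted curve records whether survival
#' actually reaches zero within follow-up (`fully_observed`), which decides
#' how far [curve_auc()] integrates.
#'
#' @param events an [event_table()]; must contain a single group unless
#'   `group` selects one.
#' @param group optional group label to restrict `events` to.
#' @return An object of class `"surv_curve"`: a list with elements
#'   `times` (event times at which S drops), `surv` (survival probability
#'   just after each event time), `n_at_risk`, `n_event`, `t_end` (last
#'   observed time, event or censoring), `fully_observed`, `n` and `unit`.
#' @examples
#' et <- event_table(paste0("w", 1:4), "g", c(1, 2, 3, 4), 1)
#' km <- km_estimate(et)
#' km$surv  # 0.75 0.50 0.25 0.00
#' @seealso [curve_auc()], [s_over_l()]
#' @export
km_estimate <- function(events, group = NULL) {
  validate_event_table(events)
  if (!is.null(group)) events <- subset_group(events, group)
  groups <- unique(events$group)
  if (length(groups) > 1) {
    stop("events contains ", length(groups),
         " groups; pass `group =` to select one", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(events))
  keep <- fit$n.event > 0
  structure(
    list(
      times = fit$time[keep],
      surv = fit$surv[keep],
      n_at_risk = fit$n.risk[keep],
      n_event = fit$n.event[keep],
      t_end = max(fit$time),
      fully_observed = sum(keep) > 0 && fit$surv[max(which(keep))] == 0,
      n = nrow(events),
      group = groups,
      unit = attr(events, "unit")
    ),
    class = "surv_curve"
  )
}

validate_surv_curve <- function(curve) {
  if (!inherits(curve, "surv_curve")) stop("not a surv_curve", call. = FALSE)
  s <- curve$surv
  if (length(s) > 0) {
    if (any(s < 0 | s > 1)) stop("survival probabilities outside [0, 1]", call. = FALSE)
    if (any(diff(s) > 0)) stop("survival curve is non-monotone", call. = FALSE)
    if (is.unsorted(curve$times, strictly = TRUE)) {
      stop("curve times must be strictly increasing", call. = FALSE)
    }
  }
  invisible(curve)
}

#' Area under a Kaplan-Meier step function
#'
#' Exact rectangle integration of the right-continuous survival step
#' function from time zero. When the curve reaches zero the integral is
#' complete and equals mean survival; when censoring leaves survival
#' positive, integration stops at the last observed time (the restricted
#' mean convention) and the curve's `fully_observed` flag is `FALSE`.
#'
#' @param curve a `"surv_curve"` from [km_estimate()].
#' @param t_max optional nonnegative upper integration bound; the integral
#'   is truncated at `min(t_max, effective end)`.
#' @return The area, in the curve's time unit.
#' @examples
#' et <- event_table(paste0("w", 1:4), "g", c(1, 2, 3, 4), 1)
#' curve_auc(km_estimate(et))  # 2.5 = mean death time
#' @export
curve_auc <- function(curve, t_max = NULL) {
  validate_surv_curve(curve)
  if (!is.null(t_max)) {
    if (!is.numeric(t_max) || length(t_max) != 1 || t_max < 0) {
      stop("t_max must be a single nonnegative number", call. = FALSE)
    }
  }
  end_eff <- if (curve$fully_observed) {
    curve$times[match(TRUE, curve$surv == 0)]
  } else {
    curve$t_end
  }
  upper <- if (is.null(t_max)) end_eff else min(t_max, end_eff)
  if (upper <= 0) return(0)
  inside <- curve$times < upper
  bounds <- c(0, curve$times[inside], upper)
  heights <- c(1, curve$surv[inside])
  sum(heights * diff(bounds))
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: group '%s', n = %d, %d event time(s)\n",
              x$group, x$n, length(x$times)))
  cat(sprintf("  t_end = %g %s, fully observed: %s\n",
              x$t_end, x$unit %||% "", x$fully_observed))
  invisible(x)
}
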