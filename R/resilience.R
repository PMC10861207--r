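#' Survival resilience: the S/L ratio
#'
#' The resilience of a population to a lethal stressor is summarised as the
#' ratio of its cumulative survival under stress to the unstressed
#' population's cumulative survival over life: S/L = AUC(stress span) /
#' AUC(life span), each AUC taken under the Kaplan-Meier curve. A ratio
#' below 1 (a left-shifted stress curve) is a loss of resilience; above 1,
#' a gain. For a treated, stress-exposed population the same ratio with the
#' treatment curve in the numerator measures treatment benefit.
#'
#' An optional subject-level bootstrap (resampling animals with replacement
#' within each group) yields a percentile confidence interval for the
#' ratio; it requires the source event tables and an explicit seed.
#'
#' @param stress `"surv_curve"` for the stress-exposed (or treated) group.
#' @param control_lifespan `"surv_curve"` for the unstressed life-span group.
#' @param n_boot number of bootstrap replicates (default 1000); used only
#'   when `source_events` is supplied.
#' @param seed integer RNG seed, mandatory when bootstrapping.
#' @param source_events optional list with elements `stress` and `control`,
#'   the [event_table()]s the two curves were estimated from.
#' @param conf_level bootstrap interval coverage (default 0.95).
#' @param tie_tol half-width of the neutral band around 1 used to classify
#'   the ratio as loss/neutral/gain (default `1e-9`).
#' @return An object of class `"resilience_result"`: list with
#'   `auc_stress`, `auc_life`, `s_over_l`, `classification`
#'   (`"loss"`, `"neutral"` or `"gain"`), `ci_low`, `ci_high`, `n_boot`,
#'   `seed`.
#' @examples
#' ctl <- event_table(paste0("c", 1:6), "control", c(10, 12, 14, 16, 18, 20), 1)
#' str <- event_table(paste0("s", 1:6), "paraquat", c(3, 4, 5, 6, 7, 8), 1)
#' s_over_l(km_estimate(str), km_estimate(ctl))
#' @export
s_over_l <- function(stress, control_lifespan, n_boot = 1000, seed = NULL,
                     source_events = NULL, conf_level = 0.95,
                     tie_tol = 1e-9) {
  validate_surv_curve(stress)
  validate_surv_curve(control_lifespan)
  u1 <- stress$unit
  u2 <- control_lifespan$unit
  if (!is.null(u1) && !is.null(u2) && !identical(u1, u2)) {
    stop("time unit mismatch: stress curve in ", u1,
         ", control curve in ", u2, call. = FALSE)
  }
  auc_s <- curve_auc(stress)
  auc_l <- curve_auc(control_lifespan)
  if (auc_l == 0) stop("control life-span AUC is zero", call. = FALSE)
  ratio <- auc_s / auc_l

  ci <- c(NA_real_, NA_real_)
  used_boot <- 0L
  if (!is.null(source_events)) {
    if (!all(c("stress", "control") %in% names(source_events))) {
      stop("source_events must be a list with elements 'stress' and 'control'",
           call. = FALSE)
    }
    if (is.null(seed)) stop("bootstrap requires an explicit seed", call. = FALSE)
    ci <- with_seed(seed, {
      reps <- replicate(n_boot, boot_ratio(source_events$stress,
                                           source_events$control))
      stats::quantile(reps, probs = c((1 - conf_level) / 2,
                                      1 - (1 - conf_level) / 2),
                      na.rm = TRUE, names = FALSE)
    })
    used_boot <- as.integer(n_boot)
  }

  structure(
    list(
      auc_stress = auc_s,
      auc_life = auc_l,
      s_over_l = ratio,
      classification = classify_ratio(ratio, tie_tol),
      ci_low = ci[1], ci_high = ci[2],
      n_boot = used_boot,
      seed = seed
    ),
    class = "resilience_result"
  )
}

classify_ratio <- function(ratio, tie_tol = 1e-9) {
  if (ratio < 1 - tie_tol) "loss" else if (ratio > 1 + tie_tol) "gain" else "neutral"
}

boot_ratio <- function(stress_events, control_events) {
  rs <- stress_events[sample.int(nrow(stress_events), replace = TRUE), , drop = FALSE]
  rc <- control_events[sample.int(nrow(control_events), replace = TRUE), , drop = FALSE]
  attr(rs, "unit") <- attr(stress_events, "unit")
  attr(rc, "unit") <- attr(control_events, "unit")
  class(rs) <- class(rc) <- c("event_table", "data.frame")
  al <- curve_auc(km_estimate(rc))
  if (al == 0) return(NA_real_)
  curve_auc(km_estimate(rs)) / al
}

#' @export
print.resilience_result <- function(x, ...) {
  cat(sprintf("Survival resilience S/L = %.4f (%s)\n", x$s_over_l,
              x$classification))
  cat(sprintf("  AUC stress span = %.4g, AUC life span = %.4g\n",
              x$auc_stress, x$auc_life))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f] (%d replicates, seed %d)\n",
                x$ci_low, x$ci_high, x$n_boot, x$seed))
  }
  invisible(x)
}

#' Relative survival gain in percent (delta AUC %)
#'
#' Percent change of the treated survival AUC relative to the control
#' survival AUC: `100 * (AUC_treated - AUC_control) / AUC_control`.
#' Accepts either fitted curves or, as a shortcut, scalar AUC values —
#' including S/L ratios, whose shared life-span denominator cancels in the
#' percent change.
#'
#' @param treated a `"surv_curve"` or a single nonnegative AUC value.
#' @param control a `"surv_curve"` or a single positive AUC value.
#' @return Percent change (a bare number; 45 means +45%).
#' @examples
#' delta_auc_pct(0.45, 0.31)  # ~ +45%
#' @export
delta_auc_pct <- function(treated, control) {
  a_t <- if (inherits(treated, "surv_curve")) curve_auc(treated) else as_auc_scalar(treated)
  a_c <- if (inherits(control, "surv_curve")) curve_auc(control) else as_auc_scalar(control)
  if (a_c == 0) stop("control AUC is zero", call. = FALSE)
  100 * (a_t - a_c) / a_c
}

as_auc_scalar <- function(x) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    stop("AUC value must be a single finite nonnegative number", call. = FALSE)
  }
  as.numeric(x)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Observed-minus-expected chi-square over the pooled risk sets, 1 degree
#' of freedom, no continuity correction.
#'
#' @param g1,g2 [event_table()]s for the two groups (each may carry any
#'   group label; the split used is g1 vs g2).
#' @return A list with `statistic` (chi-square) and `p_value`.
#' @examples
#' g1 <- event_table(paste0("a", 1:2), "a", c(1, 2), 1)
#' g2 <- event_table(paste0("b", 1:2), "b", c(3, 4), 1)
#' logrank_test(g1, g2)
#' @export
logrank_test <- function(g1, g2) {
  validate_event_table(g1)
  validate_event_table(g2)
  if (sum(g1$event) + sum(g2$event) == 0) {
    stop("log-rank test requires at least one event", call. = FALSE)
  }
  df <- data.frame(
    time = c(g1$time, g2$time),
    event = c(g1$event, g2$event),
    arm = rep(c("g1", "g2"), c(nrow(g1), nrow(g2)))
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = df, rho = 0)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Dose-resilience profile over literature records
#'
#' Aggregates published life-span / stress-survival pairs into per-dose-bin
#' summaries of the S/L ratio. When only mean spans are reported (rather
#' than full curves), S/L is the ratio of mean stress span to mean life
#' span — valid because the AUC of a fully observed survival curve equals
#' mean survival. Each record is classified as a loss of resilience
#' (S/L < 1) or as maintaining/promoting it (S/L >= 1).
#'
#' @param records data.frame with columns `study_id`, `dose` (stressor
#'   concentration, mM), `stress_mean_span` and `control_mean_lifespan`
#'   (same time unit). Records with a nonpositive control life span are
#'   dropped with a warning.
#' @param dose_bins numeric vector of bin edges covering all observed doses.
#' @return A data.frame with one row per bin: `bin`, `dose_lo`, `dose_hi`,
#'   `n`, `median_sl`, `q25`, `q75`, `n_loss`, `n_gain`.
#' @export
dose_resilience_profile <- function(records, dose_bins) {
  required <- c("study_id", "dose", "stress_mean_span", "control_mean_lifespan")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  if (any(records$dose < 0)) stop("doses must be nonnegative", call. = FALSE)
  bad <- records$control_mean_lifespan <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: nonpositive control mean lifespan (",
            paste(records$study_id[bad], collapse = ", "), ")", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    if (nrow(records) == 0) stop("all records rejected", call. = FALSE)
  }
  sl <- records$stress_mean_span / records$control_mean_lifespan
  bins <- cut(records$dose, breaks = dose_bins, include.lowest = TRUE)
  if (anyNA(bins)) {
    stop("dose_bins do not cover all observed doses", call. = FALSE)
  }
  out <- do.call(rbind, lapply(levels(bins), function(lv) {
    v <- sl[bins == lv]
    if (length(v) == 0) return(NULL)
    q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE)
    edges <- bin_edges(lv)
    data.frame(bin = lv, dose_lo = edges[1], dose_hi = edges[2],
               n = length(v), median_sl = q[2], q25 = q[1], q75 = q[3],
               n_loss = sum(v < 1), n_gain = sum(v >= 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

bin_edges <- function(label) {
  as.numeric(strsplit(gsub("[][()]", "", label), ",")[[1]])
}
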