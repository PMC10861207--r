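#' The five healthspan fitness metrics, in canonical order
#' @export
FITNESS_METRICS <- c("body_size", "crawl_speed", "direction_index",
                     "swim_speed", "thrash_freq")

#' Group-level fitness panel
#'
#' Holds the five locomotory/size health metrics for one experimental
#' group: normalized body size, crawling speed (mm/s), a direction score
#' oriented so that higher = fitter (typically the direction rescue index,
#' or an inverse shift ratio when no index is available), swimming speed
#' (mm/s) and thrashing frequency (body bends/s). Thrashing frequency
#' cannot be derived from centroid tracks and is accepted as a
#' pre-computed scalar.
#'
#' @param group group label.
#' @param body_size,crawl_speed,direction_index,swim_speed,thrash_freq
#'   positive scalars.
#' @param n_worms optional named vector of per-metric sample sizes.
#' @param direction_basis how the direction score was derived:
#'   `"rescue_index"` or `"inverse_shift_ratio"`; carried as metadata.
#' @return Object of class `"fitness_panel"`.
#' @export
fitness_panel <- function(group, body_size, crawl_speed, direction_index,
                          swim_speed, thrash_freq, n_worms = NULL,
                          direction_basis = c("rescue_index",
                                              "inverse_shift_ratio")) {
  metrics <- c(body_size = body_size, crawl_speed = crawl_speed,
               direction_index = direction_index, swim_speed = swim_speed,
               thrash_freq = thrash_freq)
  if (any(!is.finite(metrics))) stop("all metrics must be finite", call. = FALSE)
  structure(list(group = as.character(group), metrics = metrics,
                 n_worms = n_worms,
                 direction_basis = match.arg(direction_basis)),
            class = "fitness_panel")
}

#' Normalize a fitness panel against its control
#'
#' Elementwise treated/control ratios in the canonical metric order.
#'
#' @param treated,control [fitness_panel()]s.
#' @return Named numeric vector of five ratios.
#' @examples
#' ctl <- fitness_panel("control", 1, 1, 1, 1, 1)
#' trt <- fitness_panel("peptide", 1.2, 1.4, 1.6, 1.0, 0.8)
#' normalize_metrics(trt, ctl)
#' @export
normalize_metrics <- function(treated, control) {
  stopifnot(inherits(treated, "fitness_panel"),
            inherits(control, "fitness_panel"))
  bad <- FITNESS_METRICS[control$metrics[FITNESS_METRICS] <= 0]
  if (length(bad) > 0) {
    stop("control metric(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  treated$metrics[FITNESS_METRICS] / control$metrics[FITNESS_METRICS]
}

#' Total fitness: mean of the five treated/control ratios
#'
#' Integrates the fitness landscape into one score, the average of the
#' five metric ratios. A control measured against itself scores exactly
#' 1.0, the baseline.
#'
#' @param ratios numeric vector of exactly five treated/control ratios.
#' @return Scalar total fitness.
#' @examples
#' total_fitness(c(1.2, 1.4, 1.6, 1.0, 0.8))  # 1.2
#' @export
total_fitness <- function(ratios) {
  if (!is.numeric(ratios) || length(ratios) != length(FITNESS_METRICS)) {
    stop("total fitness requires exactly ", length(FITNESS_METRICS),
         " metric ratios", call. = FALSE)
  }
  mean(ratios)
}

#' Long-format ratio table for radar charts
#'
#' @param panels list of treated [fitness_panel()]s.
#' @param control the control [fitness_panel()].
#' @return data.frame with columns `group`, `metric`, `ratio` (one row per
#'   panel and metric, metrics in canonical order), ready for radar
#'   plotting.
#' @export
radar_export <- function(panels, control) {
  if (inherits(panels, "fitness_panel")) panels <- list(panels)
  do.call(rbind, lapply(panels, function(p) {
    data.frame(group = p$group, metric = FITNESS_METRICS,
               ratio = unname(normalize_metrics(p, control)),
               stringsAsFactors = FALSE)
  }))
}
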