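#' Subject-level survival event table
#'
#' Constructs and validates the tabular input to all survival computations:
#' one row per animal, with its group label, its observed time, and whether
#' death was observed (`event = 1`) or the animal was censored (`event = 0`).
#'
#' @param subject_id character vector of subject labels.
#' @param group character vector of condition labels (e.g. `"control"`,
#'   `"paraquat"`, `"paraquat+peptide"`).
#' @param time nonnegative numeric vector of observed times.
#' @param event integer vector with values in `{0, 1}`; 1 = death observed.
#' @param unit time unit shared by all rows (e.g. `"hours"`, `"days"`).
#'   Recorded as an attribute and checked when two tables are compared.
#' @return A `data.frame` of class `"event_table"` with columns
#'   `subject_id`, `group`, `time`, `event` and a `"unit"` attribute.
#' @examples
#' et <- event_table(paste0("w", 1:4), "control", c(1, 2, 3, 4), 1)
#' km_estimate(et)
#' @export
event_table <- function(subject_id, group, time, event, unit = "days") {
  df <- data.frame(
    subject_id = as.character(subject_id),
    group = as.character(group),
    time = as.numeric(time),
    event = as.integer(event),
    stringsAsFactors = FALSE
  )
  validate_event_table(df)
  attr(df, "unit") <- unit
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  required <- c("subject_id", "group", "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("event table has no rows", call. = FALSE)
  if (any(!is.finite(df$time))) stop("non-finite time values", call. = FALSE)
  if (any(df$time < 0)) stop("negative time values are not allowed", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d subjects, %d group(s) [unit: %s]\n",
              nrow(x), length(unique(x$group)),
              attr(x, "unit") %||% "unspecified"))
  tab <- table(x$group, factor(x$event, levels = 0:1,
                               labels = c("censored", "death")))
  print(tab)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restrict an event table to one group, keeping the unit attribute
subset_group <- function(events, group) {
  validate_event_table(events)
  out <- events[events$group == group, , drop = FALSE]
  if (nrow(out) == 0) stop("no subjects in group '", group, "'", call. = FALSE)
  attr(out, "unit") <- attr(events, "unit")
  class(out) <- c("event_table", "data.frame")
  out
}
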