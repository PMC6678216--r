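#' Define a morphological state space
#'
#' The state space fixes the set and the order of the discrete phenotypic
#' states. The order is load-bearing: it defines row/column indexing of every
#' transition matrix and the tie-break order used when ranking fluxes. The
#' canonical three-state space for EGF-induced EMT morphodynamics is
#' cobblestone ("cobble", polygonal, in contact), "spindle" (elongated,
#' scattered) and "circular" (rounded, scattered).
#'
#' @param labels character vector of distinct, non-empty state names, at least
#'   two. Defaults to the canonical three morphological states.
#' @return A `state_space` object (a classed character vector).
#' @examples
#' state_space()
#' state_space(c("epithelial", "hybrid", "mesenchymal"))
#' @export
state_space <- function(labels = c("cobble", "spindle", "circular")) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stopf("a state space needs at least 2 states, got %d", length(labels))
  if (anyNA(labels) || any(!nzchar(labels)))
    stopf("state labels must be non-empty strings")
  if (anyDuplicated(labels))
    stopf("state labels must be distinct")
  structure(labels, class = "state_space")
}

as_state_space <- function(x) {
  if (inherits(x, "state_space")) x else state_space(x)
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", paste(unclass(x), collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Aggregate population observation at one time point
#'
#' A snapshot records, for one time point, the fraction of live cells in each
#' state, the live-cell count relative to time 0 (`total_fold`) and optionally
#' the cumulative dead-cell fraction. Fractions must lie on the probability
#' simplex within 1e-9.
#'
#' @param time observation time in hours, >= 0.
#' @param fractions numeric vector over the state space; must sum to 1.
#' @param total_fold live cells relative to t = 0 (> 0); must be 1 at time 0.
#' @param dead_fraction cumulative dead cells / (dead + live), in [0, 1], or
#'   `NA` when not measured.
#' @param sd optional per-state standard deviations across replicates
#'   (metadata used to weight inference residuals).
#' @param states a [state_space()] or character vector naming `fractions`.
#' @return A `population_snapshot` object.
#' @export
population_snapshot <- function(time, fractions, total_fold = NA_real_,
                                dead_fraction = NA_real_, sd = NULL,
                                states = state_space()) {
  states <- as_state_space(states)
  m <- length(states)
  if (!is_number(time) || time < 0) stopf("time must be a single number >= 0")
  fractions <- as.numeric(fractions)
  if (length(fractions) != m)
    stopf("fractions must have length %d (one per state)", m)
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12))
    stopf("fractions must lie in [0, 1] at time %g", time)
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions at time %g sum to %.12g, not 1", time, sum(fractions))
  names(fractions) <- unclass(states)
  if (!is.na(total_fold)) {
    if (!is_number(total_fold) || total_fold <= 0)
      stopf("total_fold must be > 0 at time %g", time)
    if (time == 0 && abs(total_fold - 1) > 1e-9)
      stopf("total_fold at time 0 must equal 1, got %g", total_fold)
  }
  if (!is.na(dead_fraction) &&
      (dead_fraction < 0 || dead_fraction > 1))
    stopf("dead_fraction must lie in [0, 1] at time %g", time)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != m) stopf("sd must have length %d", m)
    names(sd) <- unclass(states)
  }
  structure(list(time = as.numeric(time), fractions = fractions,
                 total_fold = as.numeric(total_fold),
                 dead_fraction = as.numeric(dead_fraction),
                 sd = sd, states = states),
            class = "population_snapshot")
}

#' Time series of aggregate population snapshots under one condition
#'
#' @param snapshots list of [population_snapshot()] with strictly increasing
#'   times, the first at time 0; at least two.
#' @param condition list describing the dosing schedule: `label` (free text),
#'   `dose` (ng/mL), `pulses` (pulse times, hours), `inhibitor_time` (hours or
#'   `NULL`). Partial lists are completed with defaults.
#' @param replicate_table optional tidy data frame of per-replicate rows
#'   retained for serialization; the snapshots themselves are replicate means.
#' @return A `timeseries_dataset` object.
#' @export
timeseries_dataset <- function(snapshots, condition = list(label = "unspecified"),
                               replicate_table = NULL) {
  if (length(snapshots) < 2L) stopf("need at least 2 snapshots")
  if (!all(vapply(snapshots, inherits, TRUE, "population_snapshot")))
    stopf("snapshots must be population_snapshot objects")
  states <- snapshots[[1L]]$states
  same <- vapply(snapshots, function(s) identical(unclass(s$states), unclass(states)), TRUE)
  if (!all(same)) stopf("all snapshots must share one state space")
  times <- vapply(snapshots, `[[`, 0, "time")
  if (any(diff(times) <= 0)) stopf("snapshot times must be strictly increasing")
  if (times[1L] != 0) stopf("the first snapshot must be at time 0")
  defaults <- list(label = "unspecified", dose = NA_real_, pulses = NULL,
                   inhibitor_time = NULL)
  condition <- utils::modifyList(defaults, as.list(condition))
  structure(list(snapshots = snapshots, states = states, condition = condition,
                 replicate_table = replicate_table),
            class = "timeseries_dataset")
}

#' @export
print.timeseries_dataset <- function(x, ...) {
  cat(sprintf("<timeseries_dataset> '%s': %d snapshots over %g-%g h, states: %s\n",
              x$condition$label, length(x$snapshots),
              x$snapshots[[1L]]$time, x$snapshots[[length(x$snapshots)]]$time,
              paste(unclass(x$states), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.timeseries_dataset <- function(x, ...) {
  rows <- lapply(x$snapshots, function(s) {
    data.frame(condition = x$condition$label, time_h = s$time,
               state = unclass(x$states), fraction = as.numeric(s$fractions),
               total_fold = s$total_fold, dead_fraction = s$dead_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

snapshot_times <- function(dataset) {
  vapply(dataset$snapshots, `[[`, 0, "time")
}
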