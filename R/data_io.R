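#' Read a tidy time series of population snapshots
#'
#' Expects a long-format CSV with one row per condition/time/state (and
#' optionally replicate): required columns `condition`, `time_h`, `state`,
#' `fraction`; optional `total_fold`, `dead_fraction`, `replicate`. Replicate
#' rows are averaged into mean snapshots, with per-state standard deviations
#' retained as snapshot metadata for residual weighting.
#'
#' @param path CSV file path (UTF-8, header row, "." decimal).
#' @param validation `"strict"` rejects any fraction vector off the simplex
#'   (tolerance 1e-9); `"renormalize"` rescales vectors off by at most 0.02 to
#'   sum 1 (with a warning) and rejects larger deviations.
#' @param condition when the file holds several conditions, the label to
#'   extract; by default the file must contain exactly one.
#' @param states optional [state_space()] fixing state order; defaults to the
#'   canonical order when all canonical labels are present, else the order of
#'   first appearance in the file.
#' @return A [timeseries_dataset()].
#' @export
read_timeseries <- function(path, validation = c("strict", "renormalize"),
                            condition = NULL, states = NULL) {
  validation <- match.arg(validation)
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "time_h", "state", "fraction")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  conds <- unique(df$condition)
  if (is.null(condition)) {
    if (length(conds) > 1L)
      stopf("file holds %d conditions (%s); pick one via `condition`",
            length(conds), paste(conds, collapse = ", "))
    condition <- conds
  }
  df <- df[df$condition == condition, , drop = FALSE]
  if (!nrow(df)) stopf("condition '%s' not found", condition)
  if (is.null(states)) {
    seen <- unique(df$state)
    canonical <- c("cobble", "spindle", "circular")
    states <- if (setequal(seen, canonical)) state_space(canonical)
              else state_space(seen)
  }
  states <- as_state_space(states)
  if (!all(df$state %in% unclass(states)))
    stopf("unknown state label(s): %s",
          paste(setdiff(df$state, unclass(states)), collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"total_fold" %in% names(df)) df$total_fold <- NA_real_
  if (!"dead_fraction" %in% names(df)) df$dead_fraction <- NA_real_

  times <- sort(unique(df$time_h))
  snaps <- vector("list", length(times))
  for (k in seq_along(times)) {
    dk <- df[df$time_h == times[k], , drop = FALSE]
    reps <- unique(dk$replicate)
    per_rep <- matrix(NA_real_, nrow = length(reps), ncol = length(states),
                      dimnames = list(NULL, unclass(states)))
    for (r in seq_along(reps)) {
      dr <- dk[dk$replicate == reps[r], , drop = FALSE]
      if (anyDuplicated(dr$state))
        stopf("duplicate state rows at time %g, replicate %s", times[k], reps[r])
      if (!setequal(dr$state, unclass(states)))
        stopf("time %g, replicate %s: need one row per state", times[k], reps[r])
      f <- dr$fraction[match(unclass(states), dr$state)]
      s <- sum(f)
      if (abs(s - 1) > 1e-9) {
        if (validation == "strict")
          stopf("fractions at time %g (replicate %s) sum to %.6g; strict validation failed",
                times[k], reps[r], s)
        if (abs(s - 1) > 0.02)
          stopf("fractions at time %g (replicate %s) off the simplex by %.3g (> 0.02)",
                times[k], reps[r], abs(s - 1))
        warnf("renormalizing fractions at time %g (replicate %s), sum was %.6g",
              times[k], reps[r], s)
        f <- f / s
      }
      per_rep[r, ] <- f
    }
    mean_f <- colMeans(per_rep)
    mean_f <- mean_f / sum(mean_f)  # guard means off by < 1e-12
    sd_f <- if (length(reps) > 1L) apply(per_rep, 2L, stats::sd) else NULL
    fold <- mean(dk$total_fold[match(reps, dk$replicate)], na.rm = TRUE)
    dead <- mean(dk$dead_fraction[match(reps, dk$replicate)], na.rm = TRUE)
    snaps[[k]] <- population_snapshot(
      time = times[k], fractions = mean_f,
      total_fold = if (is.finite(fold)) fold else NA_real_,
      dead_fraction = if (is.finite(dead)) dead else NA_real_,
      sd = sd_f, states = states)
  }
  timeseries_dataset(snaps, condition = list(label = condition),
                     replicate_table = df)
}

#' Write a dataset back to tidy CSV
#'
#' Writes the replicate-level table when one is attached, else the mean
#' snapshots, in the same long format [read_timeseries()] accepts.
#'
#' @param dataset a [timeseries_dataset()].
#' @param path output CSV path.
#' @export
write_timeseries <- function(dataset, path) {
  stopifnot(inherits(dataset, "timeseries_dataset"))
  df <- if (!is.null(dataset$replicate_table)) dataset$replicate_table
        else as.data.frame(dataset)
  write_csv_full(df, path)
}

# full-precision CSV writer so numeric round-trips hold to 1e-12
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write to %s", path)
  invisible(path)
}

#' Serialize analysis results to self-describing text files
#'
#' Schedules and flux tables go to tidy CSV; Hill fits and potential diagrams
#' to key-value JSON. Reading back with the matching `read_*` function
#' reproduces the object to within 1e-12 on floats.
#'
#' @param x a [transition_schedule()], `flux_table`, `hill_fit` or
#'   `potential_diagram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) UseMethod("write_result")

#' @export
write_result.transition_schedule <- function(x, path) {
  write_csv_full(as.data.frame(x), path)
}

#' @export
write_result.flux_table <- function(x, path) {
  write_csv_full(as.data.frame(x), path)
}

#' @export
write_result.hill_fit <- function(x, path) {
  obj <- x[c("y_min", "y_max", "K", "h", "rss", "n_points",
             "response_definition")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_result.potential_diagram <- function(x, path) {
  obj <- list(states = as.list(x$states_by_potential),
              fractions = as.list(x$fractions),
              potentials = as.list(x$potentials))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transition schedule written by [write_result()]
#' @param path CSV path.
#' @param states optional [state_space()] fixing state order.
#' @return A [transition_schedule()].
#' @export
read_schedule <- function(path, states = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start", "t_end", "kind", "from_state", "to_state", "value")
  if (length(setdiff(need, names(df))))
    stopf("not a schedule file: missing %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(states)) {
    seen <- unique(df$from_state)
    canonical <- c("cobble", "spindle", "circular")
    states <- if (setequal(seen, canonical)) canonical else seen
  }
  states <- as_state_space(states)
  m <- length(states)
  key <- paste(df$t_start, df$t_end)
  ivs <- lapply(unique(key), function(k) {
    dk <- df[key == k, , drop = FALSE]
    P <- matrix(0, m, m, dimnames = list(unclass(states), unclass(states)))
    tr <- dk[dk$kind == "transition", , drop = FALSE]
    P[cbind(match(tr$from_state, unclass(states)),
            match(tr$to_state, unclass(states)))] <- tr$value
    de <- dk[dk$kind == "death", , drop = FALSE]
    bi <- dk[dk$kind == "birth", , drop = FALSE]
    interval_params(dk$t_start[1L], dk$t_end[1L], P,
                    d = de$value[match(unclass(states), de$from_state)],
                    b = bi$value[match(unclass(states), bi$from_state)],
                    states = states)
  })
  ord <- order(vapply(ivs, `[[`, 0, "t_start"))
  transition_schedule(ivs[ord])
}

#' Read a flux table written by [write_result()]
#' @param path CSV path.
#' @return A `flux_table`.
#' @export
read_flux <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start", "t_end", "from_state", "to_state", "flux")
  if (length(setdiff(need, names(df))))
    stopf("not a flux file")
  seen <- unique(df$from_state)
  canonical <- c("cobble", "spindle", "circular")
  states <- as_state_space(if (setequal(seen, canonical)) canonical else seen)
  m <- length(states)
  key <- paste(df$t_start, df$t_end)
  intervals <- lapply(unique(key), function(k) {
    dk <- df[key == k, , drop = FALSE]
    F <- matrix(NA_real_, m, m, dimnames = list(unclass(states), unclass(states)))
    F[cbind(match(dk$from_state, unclass(states)),
            match(dk$to_state, unclass(states)))] <- dk$flux
    list(t_start = dk$t_start[1L], t_end = dk$t_end[1L], F = F)
  })
  ord <- order(vapply(intervals, `[[`, 0, "t_start"))
  structure(list(intervals = intervals[ord], states = states,
                 include_self = !anyNA(vapply(intervals, function(x) diag(x$F)[1L], 0))),
            class = "flux_table")
}

#' Read a Hill fit written by [write_result()]
#' @param path JSON path.
#' @return A `hill_fit`.
#' @export
read_hill_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(y_min = obj$y_min, y_max = obj$y_max, K = obj$K, h = obj$h,
                 rss = obj$rss, n_points = obj$n_points,
                 response_definition = obj$response_definition),
            class = "hill_fit")
}

#' Read a potential diagram written by [write_result()]
#' @param path JSON path.
#' @return A `potential_diagram`.
#' @export
read_potential_diagram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- unlist(obj$fractions)
  potentials(f)
}

#' Export a state-transition diagram in DOT format
#'
#' One node per state and one directed edge per path per interval, annotated
#' with its normalized flux. Edges with flux above the upper threshold are
#' styled as dominant (bold black), between the thresholds as secondary
#' (blue), below as faint gray — mirroring how time-resolved transition
#' diagrams distinguish the dominant and next-dominant paths.
#'
#' @param flux a `flux_table` from [normalized_flux()].
#' @param emphasis_thresholds decreasing pair `(upper, lower)` of flux
#'   cutoffs in (0, 1].
#' @param exclude_self drop self-retention edges from the drawing (the
#'   normalization is unchanged).
#' @param path optional file to write; the DOT text is also returned.
#' @return Character vector of DOT lines, invisibly when `path` is given.
#' @export
export_diagram <- function(flux, emphasis_thresholds = c(0.3, 0.1),
                           exclude_self = TRUE, path = NULL) {
  stopifnot(inherits(flux, "flux_table"))
  th <- as.numeric(emphasis_thresholds)
  if (length(th) != 2L || any(!is.finite(th)) || any(th <= 0) || any(th > 1) ||
      th[1L] <= th[2L])
    stopf("emphasis_thresholds must be a decreasing pair in (0, 1]")
  states <- unclass(flux$states)
  lines <- c("digraph state_transitions {",
             "  rankdir=LR;",
             sprintf("  %s [shape=ellipse];", states))
  for (iv in flux$intervals) {
    for (j in seq_along(states)) for (i in seq_along(states)) {
      if (exclude_self && i == j) next
      f <- iv$F[j, i]
      if (is.na(f) || f <= 0) next  # zero-flux paths are not drawn
      style <- if (f > th[1L]) "color=black penwidth=2.5"
               else if (f > th[2L]) "color=blue penwidth=1.5"
               else "color=gray70 penwidth=0.5"
      lines <- c(lines, sprintf(
        '  %s -> %s [label="%.3f (%g-%g h)" %s];',
        states[j], states[i], f, iv$t_start, iv$t_end, style))
    }
  }
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Load a run configuration from YAML or JSON
#'
#' Convenience loader for the generator/estimation settings used by scripts.
#' YAML support requires the optional \pkg{yaml} package; JSON always works.
#'
#' @param path configuration file ending in .yaml/.yml or .json.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML config needs the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
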