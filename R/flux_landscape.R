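#' Normalized live-cell flux through every state-transition path
#'
#' For each interval, the raw path traffic `n_j (1 - d_j) P[j, i]` (from
#' [path_counts_expectation()], with counts implied by the dataset at the
#' interval start) is normalized by the total number of surviving live cells
#' in that interval. Normalized flux is therefore the fraction of live cells
#' moving through a particular path in a particular time interval and sums to
#' 1 per interval. With `include_self = FALSE` the self-retention paths are
#' removed from the reported table but the denominator is unchanged, so
#' cross-path values are comparable between the two conventions.
#'
#' @param schedule a [transition_schedule()] (estimated or ground truth).
#' @param dataset the [timeseries_dataset()] it was estimated from; snapshot
#'   times must align with the interval endpoints.
#' @param include_self keep self-retention paths in the table (default TRUE).
#' @return A `flux_table`: per interval an m x m flux matrix (self paths `NA`
#'   when excluded), plus interval times.
#' @export
normalized_flux <- function(schedule, dataset, include_self = TRUE) {
  stopifnot(inherits(schedule, "transition_schedule"),
            inherits(dataset, "timeseries_dataset"))
  times <- snapshot_times(dataset)
  intervals <- lapply(schedule$intervals, function(iv) {
    k <- which(abs(times - iv$t_start) < 1e-6)
    if (!length(k))
      stopf("no snapshot at interval start %g h; grids misaligned", iv$t_start)
    snap <- dataset$snapshots[[k]]
    fold <- if (is.na(snap$total_fold)) 1 else snap$total_fold
    n <- as.numeric(snap$fractions) * fold
    M <- path_counts_expectation(n, iv)
    F <- M / sum(M)
    if (!include_self) diag(F) <- NA_real_
    list(t_start = iv$t_start, t_end = iv$t_end, F = F)
  })
  structure(list(intervals = intervals, states = schedule$states,
                 include_self = include_self),
            class = "flux_table")
}

#' @export
as.data.frame.flux_table <- function(x, ...) {
  states <- unclass(x$states)
  rows <- lapply(x$intervals, function(iv) {
    g <- expand.grid(from_state = states, to_state = states,
                     stringsAsFactors = FALSE)
    f <- iv$F[cbind(match(g$from_state, states), match(g$to_state, states))]
    keep <- !is.na(f)
    data.frame(t_start = iv$t_start, t_end = iv$t_end,
               g[keep, , drop = FALSE], flux = f[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("<flux_table> %d intervals, states: %s, self paths %s\n",
              length(x$intervals), paste(unclass(x$states), collapse = ", "),
              if (x$include_self) "included" else "excluded"))
  invisible(x)
}

#' Rank the dominant transition paths per interval
#'
#' Returns, for each interval, the `k` largest cross-state fluxes (self
#' paths optionally excluded), ranked descending. Ties are broken by the
#' deterministic lexicographic (from, to) order of the canonical state
#' ordering and flagged in the `tied` column rather than silently resolved.
#'
#' @param flux a `flux_table`.
#' @param k number of top paths per interval (>= 1).
#' @param exclude_self rank only cross-state paths (default TRUE).
#' @return data frame with columns `t_start`, `t_end`, `rank`, `from_state`,
#'   `to_state`, `flux`, `tied`.
#' @export
dominant_paths <- function(flux, k = 2L, exclude_self = TRUE) {
  stopifnot(inherits(flux, "flux_table"))
  if (!is_number(k) || k < 1) stopf("k must be >= 1")
  states <- unclass(flux$states)
  m <- length(states)
  rows <- lapply(flux$intervals, function(iv) {
    g <- expand.grid(from = seq_len(m), to = seq_len(m))
    if (exclude_self) g <- g[g$from != g$to, , drop = FALSE]
    f <- iv$F[cbind(g$from, g$to)]
    keep <- !is.na(f)
    g <- g[keep, , drop = FALSE]; f <- f[keep]
    ord <- order(-f, g$from, g$to)
    top <- utils::head(ord, k)
    tied <- duplicated(signif(f[ord], 12)) | rev(duplicated(rev(signif(f[ord], 12))))
    data.frame(t_start = iv$t_start, t_end = iv$t_end,
               rank = seq_along(top),
               from_state = states[g$from[top]], to_state = states[g$to[top]],
               flux = f[top], tied = tied[seq_along(top)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize the dominant state-transition trajectory
#'
#' Walks the rank-1 cross-state path of each interval in time order and
#' reports the distinct paths in order of first appearance, e.g.
#' `cobble -> circular -> spindle -> cobble` for a reversible excursion.
#' Intervals whose largest cross-state flux falls below `min_flux` are
#' skipped: a near-stationary interval carries no directional information and
#' its top path is estimation noise.
#'
#' @param flux a `flux_table`.
#' @param min_flux smallest cross-flux considered directional (default 0.05, above the replicate-noise scale of the default generator).
#' @return list with `paths` (data frame of the distinct rank-1 paths in
#'   order), `label` (arrow string chaining the path sequence) and
#'   `per_interval` (the rank-1 table with the skipped intervals flagged).
#' @export
path_trajectory <- function(flux, min_flux = 0.05) {
  top <- dominant_paths(flux, k = 1L, exclude_self = TRUE)
  top$informative <- top$flux >= min_flux
  inf <- top[top$informative, , drop = FALSE]
  key <- paste(inf$from_state, inf$to_state)
  first <- !duplicated(key)
  paths <- inf[first, c("t_start", "t_end", "from_state", "to_state", "flux")]
  label <- if (!nrow(paths)) "" else {
    seq_states <- paths$from_state[1L]
    for (i in seq_len(nrow(paths))) {
      seq_states <- c(seq_states,
                      if (paths$from_state[i] == utils::tail(seq_states, 1L))
                        paths$to_state[i]
                      else c(paths$from_state[i], paths$to_state[i]))
    }
    paste(seq_states, collapse = " -> ")
  }
  list(paths = paths, label = label, per_interval = top)
}

#' Discretized energy-level (quasi-potential) diagram
#'
#' Assigns each state a dimensionless potential `U_i = -ln(f_i)` from its
#' steady-state occupancy `f_i`, so rarer states sit higher — a discrete
#' ladder of levels analogous to a Jablonski diagram, with the ground state
#' at the lowest potential. `exp(-U)` recovers the input occupancies.
#'
#' @param steady_fractions occupancy vector on the simplex, all entries > 0
#'   (zero occupancy would put a state at infinite potential; supply a
#'   regularized estimate instead).
#' @return A `potential_diagram`: `fractions`, `potentials` (named, same
#'   order as input) and `states_by_potential` (lowest first).
#' @examples
#' potentials(c(cobble = 0.79, spindle = 0.13, circular = 0.08))
#' @export
potentials <- function(steady_fractions) {
  f <- as.numeric(steady_fractions)
  nm <- names(steady_fractions)
  if (is.null(nm)) nm <- unclass(state_space())[seq_along(f)]
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("all occupancies must be > 0 (a zero would sit at infinite potential)")
  if (abs(sum(f) - 1) > 1e-9)
    stopf("occupancies must sum to 1 (got %.12g)", sum(f))
  U <- -log(f)
  names(U) <- names(f) <- nm
  structure(list(fractions = f, potentials = U,
                 states_by_potential = nm[order(U)]),
            class = "potential_diagram")
}

#' @export
print.potential_diagram <- function(x, ...) {
  cat("<potential_diagram> U = -ln(f):\n")
  for (s in x$states_by_potential)
    cat(sprintf("  %-10s f = %.4g  U = %.4f\n", s, x$fractions[[s]],
                x$potentials[[s]]))
  invisible(x)
}

#' Check dominant paths against the excitation/relaxation rule
#'
#' The energy-level picture predicts which dominant path is allowed in each
#' interval: while the signal switch is ON (mean phospho-EGFR at or above the
#' Hill midpoint), cells are excited from the lowest-potential state straight
#' to the highest (ground -> excited); while it is OFF, relaxation descends
#' one level at a time (highest -> second, or second -> lowest), never
#' skipping the intermediate state. Each interval's rank-1 path is checked
#' against the allowed set; intervals skipped as non-directional by
#' [path_trajectory()] are exempt.
#'
#' @param flux a `flux_table`.
#' @param diagram a [potentials()] diagram sharing the state space.
#' @param signal the driving [signal_trajectory()].
#' @param hill_mid the switch midpoint K on the normalized signal scale.
#' @param min_flux directionality floor passed to [path_trajectory()].
#' @return A `path_rule_report` data frame: per interval the switch state,
#'   dominant path, `consistent` flag; attribute `"violations"` lists the
#'   inconsistent intervals and attribute `"rule_consistent"` summarizes.
#' @export
check_path_rule <- function(flux, diagram, signal, hill_mid = 0.35,
                            min_flux = 0.05) {
  stopifnot(inherits(flux, "flux_table"),
            inherits(diagram, "potential_diagram"),
            inherits(signal, "signal_trajectory"))
  states <- unclass(flux$states)
  if (!setequal(states, names(diagram$potentials)))
    stopf("flux table and potential diagram use different state spaces")
  ladder <- diagram$states_by_potential      # lowest U first
  ground <- ladder[1L]
  mid <- ladder[2L]
  excited <- ladder[length(ladder)]
  top <- path_trajectory(flux, min_flux = min_flux)$per_interval
  switch_on <- vapply(seq_len(nrow(top)), function(i)
    mean_signal(signal, top$t_start[i], top$t_end[i]) >= hill_mid, TRUE)
  allowed <- function(on) {
    if (on) list(c(ground, excited))
    else list(c(excited, mid), c(mid, ground))
  }
  consistent <- vapply(seq_len(nrow(top)), function(i) {
    if (!top$informative[i]) return(NA)
    any(vapply(allowed(switch_on[i]), function(a)
      identical(a, c(top$from_state[i], top$to_state[i])), TRUE))
  }, TRUE)
  rep <- data.frame(t_start = top$t_start, t_end = top$t_end,
                    switch = ifelse(switch_on, "ON", "OFF"),
                    from_state = top$from_state, to_state = top$to_state,
                    flux = top$flux, informative = top$informative,
                    consistent = consistent, stringsAsFactors = FALSE)
  attr(rep, "violations") <- rep[!is.na(consistent) & !consistent, , drop = FALSE]
  attr(rep, "rule_consistent") <- all(consistent[!is.na(consistent)])
  class(rep) <- c("path_rule_report", class(rep))
  rep
}
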