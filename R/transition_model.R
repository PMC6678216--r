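#' Per-interval transition, death and birth parameters
#'
#' The elementary unit of the discrete-time population model. Over one
#' observation interval, a cell in state j first survives with probability
#' `1 - d[j]`, then lands in state i with probability `P[j, i]` (rows of `P`
#' lie on the simplex and include self-retention), and each surviving cell
#' finally produces `b[i]` expected offspring in its post-transition state
#' (at most one division per interval in the stochastic simulator).
#'
#' @param t_start,t_end interval endpoints in hours, `t_end > t_start`.
#' @param P m x m row-stochastic matrix; `P[j, i]` is the probability that a
#'   surviving state-j cell is found in state i at `t_end`.
#' @param d per-state death probability over the interval, in [0, 1).
#' @param b per-state expected offspring per surviving cell, in [0, 1] for the
#'   stochastic simulator (>= 0 is accepted in expectation mode).
#' @param states a [state_space()].
#' @return An `interval_params` object.
#' @export
interval_params <- function(t_start, t_end, P, d = 0, b = 0,
                            states = state_space()) {
  states <- as_state_space(states)
  m <- length(states)
  if (!is_number(t_start) || !is_number(t_end) || t_end <= t_start)
    stopf("need t_end > t_start")
  P <- as.matrix(P)
  if (!all(dim(P) == c(m, m))) stopf("P must be %d x %d", m, m)
  if (any(!is.finite(P)) || any(P < -1e-12) || any(P > 1 + 1e-12))
    stopf("P entries must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stopf("P rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  d <- rep_len(as.numeric(d), m)
  b <- rep_len(as.numeric(b), m)
  if (any(d < 0) || any(d >= 1)) stopf("d must lie in [0, 1)")
  if (any(b < 0)) stopf("b must be >= 0")
  dimnames(P) <- list(unclass(states), unclass(states))
  names(d) <- names(b) <- unclass(states)
  structure(list(t_start = t_start, t_end = t_end, P = P, d = d, b = b,
                 states = states),
            class = "interval_params")
}

#' Contiguous schedule of interval parameters
#'
#' @param intervals list of [interval_params()] whose intervals abut exactly
#'   and share one state space.
#' @return A `transition_schedule` object.
#' @export
transition_schedule <- function(intervals) {
  if (!length(intervals)) stopf("empty schedule")
  if (!all(vapply(intervals, inherits, TRUE, "interval_params")))
    stopf("intervals must be interval_params objects")
  states <- intervals[[1L]]$states
  for (k in seq_along(intervals)) {
    if (!identical(unclass(intervals[[k]]$states), unclass(states)))
      stopf("interval %d uses a different state space", k)
    if (k > 1L &&
        abs(intervals[[k]]$t_start - intervals[[k - 1L]]$t_end) > 1e-9)
      stopf("intervals must abut: gap between %g and %g h",
            intervals[[k - 1L]]$t_end, intervals[[k]]$t_start)
  }
  structure(list(intervals = intervals, states = states),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  ts <- vapply(x$intervals, `[[`, 0, "t_start")
  te <- vapply(x$intervals, `[[`, 0, "t_end")
  cat(sprintf("<transition_schedule> %d intervals over %g-%g h, states: %s\n",
              length(x$intervals), min(ts), max(te),
              paste(unclass(x$states), collapse = ", ")))
  invisible(x)
}

schedule_times <- function(schedule) {
  c(schedule$intervals[[1L]]$t_start,
    vapply(schedule$intervals, `[[`, 0, "t_end"))
}

# expectation step without class overhead (hot path for the optimizer)
step_expectation_raw <- function(n, P, d, b) {
  survivors <- n * (1 - d)
  moved <- as.numeric(crossprod(P, survivors))
  list(n_next = moved * (1 + b), deaths = sum(n * d),
       survivors = survivors, moved = moved)
}

#' One expectation step of the population model
#'
#' Applies the death -> transition -> birth event order in expectation:
#' `survivors_j = n_j (1 - d_j)`, `moved_i = sum_j P[j, i] survivors_j`,
#' `n_next_i = moved_i (1 + b_i)`. Counts stay real-valued; no rounding.
#'
#' @param n non-negative live counts per state at `t_start`.
#' @param params an [interval_params()].
#' @return list with `n_next` (expected counts at `t_end`), `deaths`
#'   (expected deaths over the interval), `survivors` and `moved`.
#' @examples
#' p <- interval_params(0, 12, diag(3), d = c(0.1, 0, 0), b = c(0.2, 0, 0))
#' step_expectation(c(100, 0, 0), p)$n_next  # 100 * 0.9 * 1.2 = 108
#' @export
step_expectation <- function(n, params) {
  stopifnot(inherits(params, "interval_params"))
  n <- as.numeric(n)
  if (length(n) != length(params$states) || any(n < 0) || any(!is.finite(n)))
    stopf("n must be %d non-negative counts", length(params$states))
  out <- step_expectation_raw(n, params$P, params$d, params$b)
  names(out$n_next) <- names(out$survivors) <- names(out$moved) <-
    unclass(params$states)
  out
}

# one stochastic step: Binomial deaths, Multinomial transitions among
# survivors, Binomial (at most one division) births in the landing state
step_stochastic <- function(n, params) {
  m <- length(n)
  deaths <- stats::rbinom(m, size = n, prob = params$d)
  survivors <- n - deaths
  moved <- integer(m)
  for (j in seq_len(m)) {
    if (survivors[j] > 0L)
      moved <- moved + as.integer(stats::rmultinom(1L, survivors[j], params$P[j, ]))
  }
  births <- stats::rbinom(m, size = moved, prob = pmin(params$b, 1))
  list(n_next = moved + births, deaths = sum(deaths))
}

#' Simulate the population model along a schedule
#'
#' Chains the per-interval model over a [transition_schedule()], either in
#' expectation (real-valued counts, deterministic) or as a stochastic
#' branching simulation (integer counts; Binomial deaths, Multinomial
#' transitions, Binomial single-division births). Emits one
#' [population_snapshot()] per grid time: live-state fractions, total live
#' fold change relative to t = 0, and the cumulative dead fraction
#' dead / (dead + live).
#'
#' @param schedule a [transition_schedule()].
#' @param n0 initial live counts per state (positive total). Integer-rounded
#'   in stochastic mode.
#' @param mode `"expectation"` or `"stochastic"`.
#' @param seed RNG seed (stochastic mode); the run is reproducible given the
#'   seed and leaves the caller's RNG stream untouched.
#' @param condition passed to [timeseries_dataset()].
#' @return A [timeseries_dataset()]; attribute `"deaths"` holds per-interval
#'   death counts and attribute `"counts"` the trajectory of live counts. If
#'   the population goes extinct in stochastic mode the trajectory is
#'   truncated at the last positive total and flagged with attribute
#'   `"extinct" = TRUE`.
#' @export
simulate_schedule <- function(schedule, n0, mode = c("expectation", "stochastic"),
                              seed = 1L, condition = list(label = "simulated")) {
  stopifnot(inherits(schedule, "transition_schedule"))
  mode <- match.arg(mode)
  states <- schedule$states
  m <- length(states)
  n0 <- as.numeric(n0)
  if (length(n0) != m || any(n0 < 0) || sum(n0) <= 0)
    stopf("n0 must be %d non-negative counts with positive total", m)
  run <- function() {
    n <- if (mode == "stochastic") as.integer(round(n0)) else n0
    total0 <- sum(n)
    cum_dead <- 0
    counts <- list(n)
    deaths <- numeric(0)
    extinct <- FALSE
    for (iv in schedule$intervals) {
      st <- if (mode == "stochastic") step_stochastic(n, iv)
            else step_expectation_raw(n, iv$P, iv$d, iv$b)
      n <- st$n_next
      cum_dead <- cum_dead + st$deaths
      deaths <- c(deaths, st$deaths)
      if (sum(n) <= 0) { extinct <- TRUE; break }
      counts <- c(counts, list(n))
    }
    times <- schedule_times(schedule)[seq_along(counts)]
    cum <- cumsum(c(0, deaths))[seq_along(counts)]
    snaps <- vector("list", length(counts))
    for (k in seq_along(counts)) {
      nk <- counts[[k]]
      snaps[[k]] <- population_snapshot(
        time = times[k], fractions = nk / sum(nk),
        total_fold = sum(nk) / total0,
        dead_fraction = cum[k] / (cum[k] + sum(nk)),
        states = states)
    }
    ds <- timeseries_dataset(snaps, condition = condition)
    attr(ds, "deaths") <- deaths
    attr(ds, "counts") <- do.call(rbind, counts)
    attr(ds, "extinct") <- extinct
    ds
  }
  if (mode == "stochastic") with_seed(seed, run()) else run()
}

#' Expected live-cell traffic through every state-transition path
#'
#' Entry (j, i) is the expected number of surviving cells moving from state j
#' to state i over the interval: `n_j (1 - d_j) P[j, i]`. Row sums equal the
#' per-state survivor counts; the matrix total equals all survivors. This is
#' the raw quantity behind normalized flux.
#'
#' @inheritParams step_expectation
#' @return m x m numeric matrix with state dimnames.
#' @export
path_counts_expectation <- function(n, params) {
  stopifnot(inherits(params, "interval_params"))
  n <- as.numeric(n)
  survivors <- n * (1 - params$d)
  M <- survivors * params$P  # recycles survivors down rows
  dimnames(M) <- dimnames(params$P)
  M
}

#' @export
as.data.frame.transition_schedule <- function(x, ...) {
  states <- unclass(x$states)
  rows <- lapply(x$intervals, function(iv) {
    tr <- expand.grid(from_state = states, to_state = states,
                      stringsAsFactors = FALSE)
    tr <- data.frame(t_start = iv$t_start, t_end = iv$t_end,
                     kind = "transition", tr,
                     value = as.numeric(iv$P[cbind(match(tr$from_state, states),
                                                   match(tr$to_state, states))]),
                     stringsAsFactors = FALSE)
    db <- data.frame(t_start = iv$t_start, t_end = iv$t_end,
                     kind = rep(c("death", "birth"), each = length(states)),
                     from_state = rep(states, 2L), to_state = NA_character_,
                     value = c(as.numeric(iv$d), as.numeric(iv$b)),
                     stringsAsFactors = FALSE)
    rbind(tr, db)
  })
  do.call(rbind, rows)
}
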