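#' Coupling between the phospho-EGFR signal and state-transition rates
#'
#' Encodes the switch logic linking receptor signaling to morphological state
#' transitions in the canonical three-state space (cobble, spindle, circular):
#'
#' * Excitation: the per-interval cobble -> circular probability follows a
#'   Hill function of the mean signal level over the interval, running from a
#'   `floor_rate` leak (signal at baseline) to a `ceiling_rate` (signal
#'   saturating), with midpoint `hill_k` and steepness `hill_h`. Cells move to
#'   the circular state only when phospho-EGFR is high.
#' * Relaxation: circular -> spindle and spindle -> cobble proceed at fixed
#'   per-hour rates, but only while the mean signal is below the switch
#'   midpoint (the decay phase); while the switch is ON they are suppressed
#'   to the leak level.
#' * Leak: all remaining cross paths carry a small background rate.
#'
#' Rates are per hour and converted to per-interval probabilities linearly
#' (`rate * dt`, capped at 0.95), so a schedule built on a fine grid composes
#' consistently with one built on a coarse grid. The defaults balance the
#' untreated relaxation cycle so its stationary distribution is the observed
#' untreated occupancy 0.79/0.13/0.08 (cobble/spindle/circular):
#' `0.79 * floor_rate = 0.08 * relax_circ_spindle = 0.13 * relax_spindle_cobble`.
#' The first relaxation step is faster than the second, so after a transient
#' excitation the decay separates into a circular -> spindle phase followed by
#' a spindle -> cobble phase with a pronounced spindle peak near 24-36 h.
#'
#' @param hill_h,hill_k Hill steepness and midpoint (on normalized signal).
#' @param floor_rate,ceiling_rate excitation rate per hour at zero/full signal.
#' @param relax_circ_spindle,relax_spindle_cobble relaxation rates per hour.
#' @param leak background cross-path rate per hour.
#' @param birth,death per-state birth and death probabilities per hour
#'   (scalar or length-3, order cobble/spindle/circular).
#' @param states the three-state [state_space()]; position 1 is the ground
#'   state, position 2 the intermediate, position 3 the excited state.
#' @return A `coupling_params` object.
#' @export
coupling_params <- function(hill_h = 8.6, hill_k = 0.35,
                            floor_rate = 0.06 * 0.08 / 0.79,
                            ceiling_rate = 0.07,
                            relax_circ_spindle = 0.06,
                            relax_spindle_cobble = 0.06 * 0.08 / 0.13,
                            leak = 2e-4,
                            birth = 0.004, death = 0.001,
                            states = state_space()) {
  states <- as_state_space(states)
  if (length(states) != 3L)
    stopf("signal coupling is defined for the three-state space")
  stopifnot(is_number(hill_h), hill_h > 0, is_number(hill_k), hill_k > 0,
            is_number(floor_rate), floor_rate >= 0,
            is_number(ceiling_rate), ceiling_rate >= floor_rate,
            is_number(relax_circ_spindle), relax_circ_spindle >= 0,
            is_number(relax_spindle_cobble), relax_spindle_cobble >= 0,
            is_number(leak), leak >= 0)
  birth <- rep_len(as.numeric(birth), 3L)
  death <- rep_len(as.numeric(death), 3L)
  if (any(birth < 0) || any(death < 0)) stopf("birth/death rates must be >= 0")
  structure(list(hill_h = hill_h, hill_k = hill_k, floor_rate = floor_rate,
                 ceiling_rate = ceiling_rate,
                 relax_circ_spindle = relax_circ_spindle,
                 relax_spindle_cobble = relax_spindle_cobble,
                 leak = leak, birth = birth, death = death, states = states),
            class = "coupling_params")
}

#' Build a ground-truth transition schedule from a signal trajectory
#'
#' For each interval of `grid`, computes the mean signal level (trapezoidal),
#' sets the cobble -> circular probability by the Hill excitation switch,
#' activates the relaxation paths when the mean level is below the switch
#' midpoint, adds leak paths, closes each row to the simplex by
#' self-retention, and copies per-interval death/birth from the coupling.
#'
#' @param signal a [signal_trajectory()].
#' @param coupling a [coupling_params()].
#' @param grid interval endpoints (hours) within the signal time range.
#' @return A [transition_schedule()]; attribute `"mean_signal"` records the
#'   per-interval mean levels and attribute `"switch_on"` the gate state.
#' @export
schedule_from_signal <- function(signal, coupling, grid = seq(0, 60, by = 12)) {
  stopifnot(inherits(signal, "signal_trajectory"),
            inherits(coupling, "coupling_params"))
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stopf("grid must be strictly increasing interval endpoints")
  states <- coupling$states
  n_iv <- length(grid) - 1L
  ivs <- vector("list", n_iv)
  meanE <- numeric(n_iv)
  on <- logical(n_iv)
  p_of <- function(rate, dt) min(rate * dt, 0.95)
  for (k in seq_len(n_iv)) {
    t0 <- grid[k]; t1 <- grid[k + 1L]
    dt <- t1 - t0
    E <- mean_signal(signal, t0, t1)
    meanE[k] <- E
    on[k] <- E >= coupling$hill_k
    hill_frac <- E^coupling$hill_h /
      (coupling$hill_k^coupling$hill_h + E^coupling$hill_h)
    exc_rate <- coupling$floor_rate +
      (coupling$ceiling_rate - coupling$floor_rate) * hill_frac
    relax_cs <- if (on[k]) coupling$leak else coupling$relax_circ_spindle
    relax_sc <- if (on[k]) coupling$leak else coupling$relax_spindle_cobble
    P <- diag(3)
    # row order: ground (cobble), intermediate (spindle), excited (circular)
    P[1L, 3L] <- p_of(exc_rate, dt)
    P[1L, 2L] <- p_of(coupling$leak, dt)
    P[2L, 1L] <- p_of(relax_sc, dt)
    P[2L, 3L] <- p_of(coupling$leak, dt)
    P[3L, 2L] <- p_of(relax_cs, dt)
    P[3L, 1L] <- p_of(coupling$leak, dt)
    for (j in 1:3) {
      off <- sum(P[j, -j])
      if (off > 1)
        stopf("interval %d (%g-%g h): outgoing probabilities sum to %.3f > 1",
              k, t0, t1, off)
      P[j, j] <- 1 - off
    }
    ivs[[k]] <- interval_params(t0, t1, P,
                                d = pmin(coupling$death * dt, 0.95),
                                b = coupling$birth * dt, states = states)
  }
  out <- transition_schedule(ivs)
  attr(out, "mean_signal") <- meanE
  attr(out, "switch_on") <- on
  out
}

#' Sample replicated aggregate observations from a schedule
#'
#' Runs the population model once per replicate (stochastic branching with
#' distinct sub-seeds, or the deterministic expectation), applies
#' multiplicative lognormal noise with coefficient of variation `noise_cv` to
#' the live counts and cumulative death counts at every time point after 0,
#' and converts to fractions, total fold change and cumulative dead fraction.
#' Replicates are then averaged into mean snapshots with per-state standard
#' deviations kept as metadata; the replicate-level rows are retained in the
#' dataset's `replicate_table`. Fully reproducible given `seed`.
#'
#' @param schedule a [transition_schedule()].
#' @param n0 initial live counts per state (positive total).
#' @param replicates number of replicates, >= 1.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables it).
#' @param seed master RNG seed; every replicate derives its own sub-seed.
#' @param mode `"stochastic"` or `"expectation"` (the latter gives the exact
#'   forward expectation, useful as an infinite-population limit).
#' @param condition condition descriptor for the returned dataset.
#' @return A [timeseries_dataset()] of replicate-mean snapshots.
#' @export
sample_observations <- function(schedule, n0, replicates = 3, noise_cv = 0.05,
                                seed = 1L, mode = c("stochastic", "expectation"),
                                condition = list(label = "synthetic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "transition_schedule"))
  if (replicates < 1L) stopf("replicates must be >= 1")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  n0 <- as.numeric(n0)
  if (sum(n0) <= 0 || any(n0 < 0)) stopf("n0 must be non-negative with positive total")
  states <- schedule$states
  m <- length(states)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rep_tables <- vector("list", replicates)
  frac_arr <- array(NA_real_, c(replicates, length(schedule$intervals) + 1L, m))
  fold_mat <- dead_mat <- matrix(NA_real_, replicates, length(schedule$intervals) + 1L)
  times <- schedule_times(schedule)
  for (r in seq_len(replicates)) {
    sim <- simulate_schedule(schedule, n0, mode = mode,
                             seed = sub_seed(seed, 2L * r))
    counts <- attr(sim, "counts")
    cum_dead <- cumsum(c(0, attr(sim, "deaths")))
    if (nrow(counts) < length(times))
      stopf("replicate %d went extinct; use a larger n0", r)
    if (noise_cv > 0) {
      with_seed(sub_seed(seed, 2L * r + 1L), {
        tpos <- 2:nrow(counts)
        noise <- matrix(stats::rlnorm(length(tpos) * m,
                                      meanlog = -sdlog^2 / 2, sdlog = sdlog),
                        nrow = length(tpos))
        counts[tpos, ] <- counts[tpos, , drop = FALSE] * noise
        cum_dead[tpos] <- cum_dead[tpos] *
          stats::rlnorm(length(tpos), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      })
    }
    totals <- rowSums(counts)
    frac_arr[r, , ] <- counts / totals
    fold_mat[r, ] <- totals / totals[1L]
    dead_mat[r, ] <- cum_dead / (cum_dead + totals)
    rep_tables[[r]] <- data.frame(
      condition = condition$label %||% "synthetic",
      time_h = rep(times, each = m),
      state = rep(unclass(states), length(times)),
      fraction = as.numeric(t(counts / totals)),
      total_fold = rep(totals / totals[1L], each = m),
      dead_fraction = rep(cum_dead / (cum_dead + totals), each = m),
      replicate = r, stringsAsFactors = FALSE)
  }
  snaps <- vector("list", length(times))
  for (k in seq_along(times)) {
    f <- colMeans(matrix(frac_arr[, k, ], nrow = replicates))
    f <- f / sum(f)
    sds <- if (replicates > 1L) apply(frac_arr[, k, ], 2L, stats::sd) else NULL
    snaps[[k]] <- population_snapshot(
      time = times[k], fractions = f,
      total_fold = if (k == 1L) 1 else mean(fold_mat[, k]),
      dead_fraction = mean(dead_mat[, k]),
      sd = sds, states = states)
  }
  timeseries_dataset(snaps, condition = condition,
                     replicate_table = do.call(rbind, rep_tables))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call synthetic experiment for a dosing condition
#'
#' Builds the phospho-EGFR trajectory for the dosing schedule, couples it into
#' a ground-truth transition schedule, and simulates the population — the
#' generator pipeline behind every downstream test. The defaults emulate the
#' canonical experimental arms: dose 0 reproduces the untreated stationary
#' distribution, a moderate dose (10 ng/mL) a transient circular excursion
#' that relaxes through spindle back to cobble, and a high dose (25 ng/mL) a
#' sustained circular population.
#'
#' @param dose EGF dose, ng/mL.
#' @param pulses pulse times, hours.
#' @param inhibitor_time inhibitor addition time, hours, or `NULL`.
#' @param grid observation interval endpoints, hours.
#' @param signal a [signal_params()].
#' @param coupling a [coupling_params()].
#' @param n0 initial counts (default 10^4 cells at the untreated stationary
#'   distribution).
#' @param mode,replicates,noise_cv,seed observation sampling controls; with
#'   `mode = "expectation"`, `replicates = 1` and `noise_cv = 0` the dataset
#'   is the exact forward expectation.
#' @param signal_step signal grid resolution, hours.
#' @return list with `signal` ([signal_trajectory()]), `schedule`
#'   (ground-truth [transition_schedule()]) and `dataset`
#'   ([timeseries_dataset()]).
#' @examples
#' run <- simulate_condition(dose = 10, mode = "expectation",
#'                           replicates = 1, noise_cv = 0)
#' sapply(run$dataset$snapshots, function(s) s$fractions["circular"])
#' @export
simulate_condition <- function(dose, pulses = 0, inhibitor_time = NULL,
                               grid = seq(0, 60, by = 12),
                               signal = signal_params(),
                               coupling = coupling_params(),
                               n0 = round(1e4 * c(0.79, 0.13, 0.08)),
                               mode = c("stochastic", "expectation"),
                               replicates = 3, noise_cv = 0.05, seed = 1L,
                               signal_step = 0.5) {
  mode <- match.arg(mode)
  sig <- signal_trajectory(signal, dose = dose, pulses = pulses,
                           inhibitor_time = inhibitor_time,
                           grid = seq(0, max(grid), by = signal_step))
  sched <- schedule_from_signal(sig, coupling, grid = grid)
  label <- sprintf("EGF %g ng/mL%s%s", dose,
                   if (length(pulses) > 1L)
                     sprintf(" x%d pulses", length(pulses)) else "",
                   if (is.null(inhibitor_time)) ""
                   else sprintf(" + inhibitor at %g h", inhibitor_time))
  ds <- sample_observations(sched, n0, replicates = replicates,
                            noise_cv = noise_cv, seed = seed, mode = mode,
                            condition = list(label = label, dose = dose,
                                             pulses = pulses,
                                             inhibitor_time = inhibitor_time))
  list(signal = sig, schedule = sched, dataset = ds)
}

#' Untreated stationary occupancy of the three morphological states
#'
#' The observed steady-state distribution in the absence of EGF:
#' 79\% cobble, 13\% spindle, 8\% circular. Used as the generator's
#' stationary target and as the reference occupancy for the energy-level
#' diagram.
#'
#' @return Named numeric vector on the simplex.
#' @export
untreated_fractions <- function() {
  c(cobble = 0.79, spindle = 0.13, circular = 0.08)
}
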