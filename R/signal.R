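#' Parameters of the phenomenological phospho-EGFR signal model
#'
#' EGF stimulation produces a transient phospho-EGFR response: a very fast
#' rise followed by a gradual, dose-dependent decline. Each EGF pulse at time
#' t_p contributes `A(dose) (1 - exp(-(t - t_p)/rise_time)) exp(-(t - t_p)/
#' decay_time(dose))` on top of a constitutive baseline; pulse contributions
#' superpose additively and the total is clipped to [0, 1]. The amplitude
#' saturates with dose, `A(dose) = amp_scale * dose / (amp_half_dose + dose)`,
#' so `A(0) = 0`. The decay time *lengthens* with dose (prolonged receptor
#' activation at high dose) through a saturating Hill dependence:
#' `decay_time(dose) = decay_base + decay_scale * dose^q / (decay_half_dose^q
#' + dose^q)` with exponent `q = decay_hill`. An EGFR inhibitor added at some
#' time collapses the stimulus component to zero with time constant
#' `inhibitor_decay`.
#'
#' @param baseline constitutive normalized phospho-EGFR level in [0, 1).
#' @param amp_scale,amp_half_dose amplitude saturation parameters
#'   (dimensionless; half-dose in ng/mL).
#' @param rise_time activation time constant, hours.
#' @param decay_base,decay_scale,decay_half_dose,decay_hill decay-time
#'   dose dependence (hours, hours, ng/mL, dimensionless).
#' @param inhibitor_decay stimulus shut-off time constant after inhibitor
#'   addition, hours.
#' @return A `signal_params` object.
#' @export
signal_params <- function(baseline = 0.05, amp_scale = 1, amp_half_dose = 5,
                          rise_time = 0.5, decay_base = 2, decay_scale = 88,
                          decay_half_dose = 15, decay_hill = 4,
                          inhibitor_decay = 1) {
  stopifnot(is_number(baseline), baseline >= 0, baseline < 1,
            is_number(rise_time), rise_time > 0,
            is_number(decay_base), decay_base > 0,
            is_number(decay_scale), decay_scale >= 0,
            is_number(decay_half_dose), decay_half_dose > 0,
            is_number(inhibitor_decay), inhibitor_decay > 0,
            is_number(amp_scale), amp_scale >= 0,
            is_number(amp_half_dose), amp_half_dose > 0)
  structure(list(baseline = baseline, amp_scale = amp_scale,
                 amp_half_dose = amp_half_dose, rise_time = rise_time,
                 decay_base = decay_base, decay_scale = decay_scale,
                 decay_half_dose = decay_half_dose, decay_hill = decay_hill,
                 inhibitor_decay = inhibitor_decay),
            class = "signal_params")
}

signal_amplitude <- function(params, dose) {
  params$amp_scale * dose / (params$amp_half_dose + dose)
}

signal_decay_time <- function(params, dose) {
  q <- params$decay_hill
  params$decay_base +
    params$decay_scale * dose^q / (params$decay_half_dose^q + dose^q)
}

#' Generate a normalized phospho-EGFR trajectory
#'
#' Evaluates the signal model of [signal_params()] on a time grid for a given
#' dosing schedule: EGF dose, pulse times, and an optional inhibitor addition
#' time after which the stimulus component relaxes to zero with time constant
#' `inhibitor_decay` (the baseline persists).
#'
#' @param params a [signal_params()].
#' @param dose EGF dose, ng/mL (>= 0).
#' @param pulses pulse times in hours (default a single pulse at 0).
#' @param inhibitor_time inhibitor addition time in hours, or `NULL`.
#' @param grid strictly increasing time grid starting at 0, hours.
#' @return A `signal_trajectory`: list with `times`, `level` (in [0, 1]),
#'   `dose`, `pulses`, `inhibitor_time`, `params`.
#' @examples
#' s <- signal_trajectory(signal_params(), dose = 10, grid = seq(0, 60, 0.5))
#' range(s$level)
#' @export
signal_trajectory <- function(params, dose, pulses = 0, inhibitor_time = NULL,
                              grid = seq(0, 60, by = 0.5)) {
  stopifnot(inherits(params, "signal_params"))
  if (!is_number(dose) || dose < 0) stopf("dose must be a number >= 0")
  pulses <- as.numeric(pulses)
  if (any(pulses < 0)) stopf("pulse times must be >= 0")
  if (!is.null(inhibitor_time) && (!is_number(inhibitor_time) || inhibitor_time < 0))
    stopf("inhibitor_time must be >= 0")
  grid <- as.numeric(grid)
  if (grid[1L] != 0 || any(diff(grid) <= 0))
    stopf("grid must be strictly increasing and start at 0")
  stim <- stimulus_component(params, dose, pulses, grid)
  if (!is.null(inhibitor_time)) {
    after <- grid > inhibitor_time
    if (any(after)) {
      s_at <- stimulus_component(params, dose, pulses, inhibitor_time)
      stim[after] <- s_at * exp(-(grid[after] - inhibitor_time) / params$inhibitor_decay)
    }
  }
  level <- pmin(pmax(params$baseline + stim, 0), 1)
  structure(list(times = grid, level = level, dose = dose, pulses = pulses,
                 inhibitor_time = inhibitor_time, params = params),
            class = "signal_trajectory")
}

# raw superposed stimulus (no baseline, no clipping) at times t
stimulus_component <- function(params, dose, pulses, t) {
  A <- signal_amplitude(params, dose)
  tau <- signal_decay_time(params, dose)
  out <- numeric(length(t))
  for (tp in pulses) {
    dt <- t - tp
    on <- dt >= 0
    out[on] <- out[on] +
      A * (1 - exp(-dt[on] / params$rise_time)) * exp(-dt[on] / tau)
  }
  out
}

# trapezoidal mean signal level over [t0, t1]; endpoints are interpolated so
# interval grids need not coincide with the signal grid nodes
mean_signal <- function(signal, t0, t1) {
  tt <- signal$times
  if (t0 < tt[1L] - 1e-9 || t1 > tt[length(tt)] + 1e-9)
    stopf("interval [%g, %g] outside the signal grid", t0, t1)
  inside <- tt > t0 & tt < t1
  ts <- c(t0, tt[inside], t1)
  ys <- stats::approx(tt, signal$level, xout = ts)$y
  trapz_mean(ts, ys)
}

#' @export
print.signal_trajectory <- function(x, ...) {
  cat(sprintf("<signal_trajectory> dose %g ng/mL, %d pulse(s)%s, %g-%g h, peak %.3f\n",
              x$dose, length(x$pulses),
              if (is.null(x$inhibitor_time)) ""
              else sprintf(", inhibitor at %g h", x$inhibitor_time),
              min(x$times), max(x$times), max(x$level)))
  invisible(x)
}
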