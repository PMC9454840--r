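# Biphasic rectangular pulse waveform and per-well dose metrics.
# The stimulator delivers symmetric biphasic rectangular pulses: within
# each period 1/f the voltage is +A for tau/2, -A for tau/2, and zero
# for the rest. tau is the TOTAL biphasic duration (both half-pulses).

#' Biphasic rectangular pulse waveform
#'
#' @param amplitude Peak voltage A (V, applied as +/- A).
#' @param frequency Pulse repetition frequency f (Hz).
#' @param pulse_duration Total biphasic pulse duration tau (s), covering
#'   both the positive and the negative half-pulse; each polarity lasts
#'   tau/2. Must satisfy `0 < tau <= 1/f`.
#' @return An object of class `pulse_waveform`.
#' @export
#' @examples
#' pulse_waveform(5, 7.9, 10e-3)   # the 5 V / 7.9 Hz / 10 ms setting
pulse_waveform <- function(amplitude, frequency, pulse_duration) {
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("invalid waveform: amplitude must be >= 0", call. = FALSE)
  }
  if (!is.finite(frequency) || frequency <= 0) {
    stop("invalid waveform: frequency must be positive", call. = FALSE)
  }
  if (!is.finite(pulse_duration) || pulse_duration <= 0 ||
      frequency * pulse_duration > 1 + 1e-12) {
    stop("invalid waveform: pulse_duration must satisfy 0 < tau <= 1/f",
         call. = FALSE)
  }
  structure(list(amplitude = amplitude, frequency = frequency,
                 pulse_duration = pulse_duration),
            class = "pulse_waveform")
}

#' The four stimulation settings of the characterized protocol
#'
#' 1 or 5 V combined with 20 Hz (3.6 ms biphasic pulse) or 7.9 Hz
#' (10 ms biphasic pulse), named by the conventional setting codes.
#'
#' @return A named list of [pulse_waveform()] objects.
#' @export
default_settings <- function() {
  list(
    "1V_20Hz"  = pulse_waveform(1, 20, 3.6e-3),
    "1V_7.9Hz" = pulse_waveform(1, 7.9, 10e-3),
    "5V_20Hz"  = pulse_waveform(5, 20, 3.6e-3),
    "5V_7.9Hz" = pulse_waveform(5, 7.9, 10e-3)
  )
}

#' Duty cycle of a biphasic pulse train
#'
#' Fraction of each period during which the stimulus is nonzero,
#' `f * tau`.
#'
#' @param waveform A [pulse_waveform()].
#' @return A fraction in (0, 1].
#' @export
duty_cycle <- function(waveform) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  d <- waveform$frequency * waveform$pulse_duration
  if (d > 1 + 1e-12) {
    stop("invalid waveform: duty cycle exceeds 1", call. = FALSE)
  }
  min(d, 1)
}

#' Sample the ideal stimulus voltage over time
#'
#' @param waveform A [pulse_waveform()].
#' @param sample_rate Sampling rate (Hz); must exceed `10 / tau` so each
#'   half-pulse is resolved.
#' @param n_periods Number of pulse periods to generate.
#' @return data.frame with `time` (s) and `voltage` (V).
#' @export
sample_waveform <- function(waveform, sample_rate, n_periods = 1) {
  stopifnot(inherits(waveform, "pulse_waveform"), n_periods >= 1)
  if (sample_rate <= 10 / waveform$pulse_duration) {
    stop("sample_rate too low to resolve the pulse (need > 10 / tau)",
         call. = FALSE)
  }
  n <- round(sample_rate * n_periods / waveform$frequency)
  t <- (seq_len(n) - 1) / sample_rate
  phase <- t %% (1 / waveform$frequency)
  tau <- waveform$pulse_duration
  v <- ifelse(phase < tau / 2, waveform$amplitude,
              ifelse(phase < tau, -waveform$amplitude, 0))
  data.frame(time = t, voltage = v)
}

#' Average electrical power delivered to one well
#'
#' For rectangular pulses the instantaneous power is constant
#' (`amplitude * peak_current`) while the pulse is on, so the time
#' average is that product times the duty cycle.
#'
#' @param waveform A [pulse_waveform()].
#' @param peak_current Pulse-top current magnitude (A).
#' @return Average power in W.
#' @export
average_power <- function(waveform, peak_current) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  if (!is.finite(peak_current) || peak_current < 0) {
    stop("peak_current must be >= 0", call. = FALSE)
  }
  waveform$amplitude * peak_current * duty_cycle(waveform)
}

#' Energy deposited into one well over a stimulation run
#'
#' @param waveform A [pulse_waveform()].
#' @param peak_current Pulse-top current magnitude (A).
#' @param duration Stimulation duration (s, >= 0).
#' @return Energy in J.
#' @export
deposited_energy <- function(waveform, peak_current, duration) {
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be >= 0", call. = FALSE)
  }
  average_power(waveform, peak_current) * duration
}

#' Adiabatic temperature-rise bound
#'
#' Upper bound on the liquid temperature rise if all deposited energy
#' heated the liquid with no losses to the environment:
#' `energy / (volume * density * heat_capacity)`.
#'
#' @param energy Deposited energy (J).
#' @param liquid_volume Liquid volume (m^3).
#' @param density Liquid density (kg/m^3), default water.
#' @param heat_capacity Specific heat (J/(kg K)), default water.
#' @return Temperature rise bound in K.
#' @export
adiabatic_temp_rise <- function(energy, liquid_volume,
                                density = 1000, heat_capacity = 4184) {
  stopifnot(energy >= 0, liquid_volume > 0, density > 0, heat_capacity > 0)
  energy / (liquid_volume * density * heat_capacity)
}

#' Per-setting dose summary table
#'
#' One row per stimulation setting (plus an unstimulated control row)
#' with the scaled midpoint field strength, the theoretical current at
#' the chamber's conductivity, the duty cycle, average power, energy
#' deposited over the stated duration, and the adiabatic
#' temperature-rise bound. Measured peak currents are merged by setting
#' code when supplied; unknown codes are reported with a warning, not an
#' error.
#'
#' @param geometry A [chamber_geometry()] (supplies conductivity, fill
#'   level and liquid volume).
#' @param settings Named list of [pulse_waveform()] objects; names are
#'   the setting codes.
#' @param field A [solve_potential()] result for `geometry` (any solve
#'   voltage; scaled internally per setting).
#' @param measurements Optional data.frame with columns `code` and
#'   `I_measured_A`.
#' @param duration Stimulation duration in s (default 600, the 10 min
#'   protocol).
#' @param density,heat_capacity Medium thermal properties (water
#'   defaults).
#' @return Class `dose_summary` data.frame with columns `code`,
#'   `voltage_V`, `frequency_Hz`, `pulse_ms`, `field_V_per_m`,
#'   `I_theory_A`, `I_measured_A`, `duty`, `P_avg_W`, `E_J`, `dT_max_K`.
#' @export
dose_table <- function(geometry, settings, field, measurements = NULL,
                       duration = 600, density = 1000, heat_capacity = 4184) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(field, "potential_field"))
  if (length(settings) > 0 && is.null(names(settings))) {
    stop("settings must be a named list of pulse_waveform objects",
         call. = FALSE)
  }
  base <- scale_to_voltage(field, 1)
  mid_e1 <- field_at(base, cbind(0, 0))$e_mag
  i2d1 <- electrode_current_per_depth(base, geometry$conductivity)
  i_total1 <- total_current(i2d1, geometry$fill_level)
  vol <- if (!is.null(geometry$liquid_volume)) geometry$liquid_volume else
    geometry$effective_liquid_area * geometry$fill_level
  rows <- lapply(names(settings), function(code) {
    wf <- settings[[code]]
    i_theory <- i_total1 * wf$amplitude
    p <- average_power(wf, i_theory)
    e <- p * duration
    data.frame(code = code, voltage_V = wf$amplitude,
               frequency_Hz = wf$frequency,
               pulse_ms = wf$pulse_duration * 1e3,
               field_V_per_m = mid_e1 * wf$amplitude,
               I_theory_A = i_theory, I_measured_A = NA_real_,
               duty = duty_cycle(wf), P_avg_W = p, E_J = e,
               dT_max_K = adiabatic_temp_rise(e, vol, density, heat_capacity),
               stringsAsFactors = FALSE)
  })
  control <- data.frame(code = "Control", voltage_V = 0, frequency_Hz = NA,
                        pulse_ms = NA, field_V_per_m = 0, I_theory_A = 0,
                        I_measured_A = NA_real_, duty = NA, P_avg_W = 0,
                        E_J = 0, dT_max_K = 0, stringsAsFactors = FALSE)
  tab <- if (length(rows) > 0) {
    rbind(control, do.call(rbind, c(rows, list(make.row.names = FALSE))))
  } else {
    control
  }
  if (!is.null(measurements)) {
    unknown <- setdiff(measurements$code, tab$code)
    if (length(unknown) > 0) {
      warning("unknown setting code(s) in measurements: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(tab$code, measurements$code)
    tab$I_measured_A <- measurements$I_measured_A[idx]
  }
  attr(tab, "duration_s") <- duration
  attr(tab, "conductivity_S_per_m") <- geometry$conductivity
  attr(tab, "density_kg_per_m3") <- density
  attr(tab, "heat_capacity_J_per_kgK") <- heat_capacity
  class(tab) <- c("dose_summary", "data.frame")
  tab
}
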