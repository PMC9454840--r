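# Synthetic inputs with the structure the analysis assumes: noisy
# shunt-resistor current traces (the 1 Ohm shunt makes the recorded
# voltage numerically equal to the current) and randomly perturbed
# chamber geometries for sensitivity checks. Everything is reproducible
# from an explicit seed.

#' Synthesize a shunt-resistor current trace
#'
#' Generates a biphasic rectangular current at the waveform's timing
#' with a given pulse-top amplitude, plus independent zero-mean Gaussian
#' noise (an instrumentation-amplifier noise model). An optional mains
#' interference component can be added.
#'
#' @param waveform A [pulse_waveform()] giving the pulse timing (its
#'   voltage amplitude is ignored; the current amplitude is
#'   `peak_current`).
#' @param peak_current Pulse-top current (A).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (A, >= 0).
#' @param sample_rate Sampling rate (Hz), must exceed `10 / tau`.
#' @param n_periods Number of pulse periods.
#' @param seed Integer RNG seed; the trace is reproducible per seed.
#' @param mains_amplitude Amplitude of an optional 50 Hz sinusoidal
#'   interference component (A, default 0).
#' @return Class `current_trace`: list with `time` (s), `current` (A),
#'   `sample_rate`, `true_peak`, `seed`.
#' @export
synth_current_trace <- function(waveform, peak_current, noise_sd,
                                sample_rate, n_periods, seed,
                                mains_amplitude = 0) {
  stopifnot(inherits(waveform, "pulse_waveform"),
            peak_current >= 0, noise_sd >= 0)
  shape <- sample_waveform(
    pulse_waveform(1, waveform$frequency, waveform$pulse_duration),
    sample_rate, n_periods
  )
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  current <- shape$voltage * peak_current +
    stats::rnorm(nrow(shape), 0, noise_sd) +
    mains_amplitude * sin(2 * pi * 50 * shape$time)
  structure(
    list(time = shape$time, current = current, sample_rate = sample_rate,
         true_peak = peak_current, seed = seed),
    class = "current_trace"
  )
}

#' Robust pulse-top peak current estimate
#'
#' Estimates the pulse-top current of a biphasic trace as the mean of
#' the absolute current over the samples above 80% of the 99.9th
#' percentile of |current| — a noise-robust plateau average rather than
#' the single maximum sample.
#'
#' @param trace A [synth_current_trace()] result, or any list with a
#'   numeric `current` element.
#' @return Estimated peak current in A (0 for an all-zero trace).
#' @export
detect_peak_current <- function(trace) {
  cur <- abs(trace$current)
  if (length(cur) == 0) stop("empty trace", call. = FALSE)
  if (all(cur == 0)) return(0)
  q <- stats::quantile(cur, 0.999, names = FALSE)
  top <- cur[cur >= 0.8 * q]
  mean(top)
}

#' Randomly perturbed chamber geometries
#'
#' Jitters the electrode gap, electrode width and fill level of a base
#' chamber by independent Gaussian relative perturbations, resampling
#' any draw that violates the geometry invariants. Used for sensitivity
#' analysis of the unprinted chamber dimensions.
#'
#' @param base A [chamber_geometry()].
#' @param rel_sd Relative standard deviation of the perturbations
#'   (< 0.2).
#' @param n Number of geometries.
#' @param seed Integer RNG seed.
#' @return List of `n` `chamber_geometry` objects.
#' @export
perturbed_geometries <- function(base, rel_sd, n, seed) {
  stopifnot(inherits(base, "chamber_geometry"), rel_sd >= 0, rel_sd < 0.2,
            n >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    repeat {
      g <- tryCatch(
        chamber_geometry(
          well_diameter = base$well_diameter,
          electrode_gap = base$electrode_gap * (1 + stats::rnorm(1, 0, rel_sd)),
          electrode_width = base$electrode_width * (1 + stats::rnorm(1, 0, rel_sd)),
          electrode_thickness = base$electrode_thickness,
          fill_level = base$fill_level * (1 + stats::rnorm(1, 0, rel_sd)),
          conductivity = base$conductivity
        ),
        error = function(e) NULL
      )
      if (!is.null(g)) break
    }
    out[[k]] <- g
  }
  out
}

#' Write / read a current trace as CSV
#'
#' Two-column CSV (`t_s`, `I_A`); generator parameters are echoed in a
#' sidecar `<path>.meta.txt` file.
#'
#' @param trace A `current_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$time, I_A = trace$current),
                   path, row.names = FALSE)
  meta <- c(sprintf("sample_rate_Hz: %g", trace$sample_rate),
            sprintf("true_peak_A: %g", trace$true_peak),
            sprintf("seed: %s", format(trace$seed)))
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}
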