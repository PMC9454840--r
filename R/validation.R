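# Comparison of model-predicted electrode currents with measured
# shunt-resistor peak currents, including the linearity diagnostics:
# the measured current ratio between voltage levels vs the ideal
# voltage ratio, and the measured/predicted prediction ratio.

#' Measured peak currents for the characterized chamber
#'
#' Reads the packaged measurement fixture: pulse-top peak currents
#' recorded through a 1 Ohm shunt resistor for each stimulation setting
#' in DMEM with 10% FCS.
#'
#' @param path Optional path to a measurement CSV with columns `code`,
#'   `voltage_V`, `frequency_Hz`, `pulse_ms`, `I_measured_A`; defaults
#'   to the packaged table.
#' @return data.frame of measurement records.
#' @export
measured_currents <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "measured_currents.csv",
                        package = "stimwell", mustWork = TRUE)
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("code", "voltage_V", "frequency_Hz", "pulse_ms",
              "I_measured_A")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop("measurement CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(rec$I_measured_A) | rec$I_measured_A < 0)
  if (length(bad) > 0) {
    stop("malformed measurement row at line ", bad[1] + 1L,
         ": I_measured_A must be a non-negative number", call. = FALSE)
  }
  if (anyDuplicated(rec$code)) {
    stop("duplicate setting code in measurement records", call. = FALSE)
  }
  rec
}

#' Measured current scaling between two voltage levels
#'
#' Ratio of the measured currents at `v_high` and `v_low` at a matched
#' frequency. For a perfectly linear (ohmic) system this equals
#' `v_high / v_low`.
#'
#' @param records Measurement data.frame (see [measured_currents()]).
#' @param v_low,v_high The two voltage levels (V).
#' @param frequency Pulse frequency (Hz) at which to match records.
#' @return The current ratio `I(v_high) / I(v_low)`.
#' @export
voltage_scaling_factor <- function(records, v_low, v_high, frequency) {
  pick <- function(v) {
    i <- which(abs(records$voltage_V - v) < 1e-9 &
                 abs(records$frequency_Hz - frequency) < 1e-9)
    if (length(i) == 0) {
      stop("incomplete data: no record at ", v, " V, ", frequency, " Hz",
           call. = FALSE)
    }
    records$I_measured_A[i[1]]
  }
  pick(v_high) / pick(v_low)
}

#' Measured-to-predicted current ratio
#'
#' @param measured Measured peak current (A).
#' @param predicted Model-predicted current (A, > 0).
#' @return The ratio `measured / predicted`.
#' @export
prediction_ratio <- function(measured, predicted) {
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("division error: predicted current must be positive", call. = FALSE)
  }
  measured / predicted
}

#' Model-vs-measurement validation report
#'
#' Assembles per-setting predicted currents from the field solution
#' (scaled linearly to each setting's voltage, at the chamber
#' conductivity), merges measured peak currents, and computes the two
#' diagnostics: measured voltage-scaling factor per frequency (flagged
#' when it deviates by more than `linearity_tol` from the ideal voltage
#' ratio) and the per-setting measured/predicted ratio.
#'
#' @param geometry A [chamber_geometry()].
#' @param field A [solve_potential()] result for `geometry`.
#' @param settings Named list of [pulse_waveform()] objects.
#' @param records Optional measurement data.frame; `NULL` gives a
#'   predictions-only report.
#' @param linearity_tol Relative deviation of the measured scaling
#'   factor from the voltage ratio above which the linearity flag is
#'   raised (default 0.05).
#' @return Class `validation_report`: list with `table` (per-setting
#'   data.frame), `scaling` (per-frequency data.frame with `frequency`,
#'   `factor`, `ideal`, `flag`), `linearity_flag`.
#' @export
build_validation_report <- function(geometry, field, settings,
                                    records = NULL,
                                    linearity_tol = 0.05) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(field, "potential_field"))
  base <- scale_to_voltage(field, 1)
  i1 <- total_current(
    electrode_current_per_depth(base, geometry$conductivity),
    geometry$fill_level
  )
  tab <- do.call(rbind, lapply(names(settings), function(code) {
    wf <- settings[[code]]
    data.frame(code = code, voltage_V = wf$amplitude,
               frequency_Hz = wf$frequency,
               I_predicted_A = i1 * wf$amplitude,
               I_measured_A = NA_real_, ratio = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(records) && nrow(records) > 0) {
    idx <- match(tab$code, records$code)
    tab$I_measured_A <- records$I_measured_A[idx]
    has <- !is.na(tab$I_measured_A)
    tab$ratio[has] <- prediction_ratio(tab$I_measured_A[has],
                                       tab$I_predicted_A[has])
  }
  scaling <- NULL
  if (!is.null(records) && nrow(records) > 0) {
    volts <- sort(unique(tab$voltage_V))
    if (length(volts) >= 2) {
      v_low <- volts[1]; v_high <- volts[length(volts)]
      freqs <- sort(unique(tab$frequency_Hz))
      ideal <- v_high / v_low
      rows <- lapply(freqs, function(fq) {
        fac <- tryCatch(
          voltage_scaling_factor(records, v_low, v_high, fq),
          error = function(e) NA_real_
        )
        data.frame(frequency = fq, factor = fac, ideal = ideal,
                   flag = is.finite(fac) &&
                     abs(fac - ideal) / ideal > linearity_tol)
      })
      scaling <- do.call(rbind, rows)
    }
  }
  structure(
    list(table = tab, scaling = scaling,
         linearity_flag = !is.null(scaling) && any(scaling$flag, na.rm = TRUE),
         linearity_tol = linearity_tol),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model-vs-measurement validation\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$scaling)) {
    cat("\nMeasured voltage-scaling factors (ideal = voltage ratio):\n")
    print(x$scaling, row.names = FALSE)
    if (x$linearity_flag) {
      cat(sprintf("\nNote: measured scaling deviates from the voltage ratio by > %.0f%%;\n",
                  100 * x$linearity_tol))
      cat("the response is approximately, but not perfectly, linear.\n")
    } else {
      cat("\nMeasured scaling is consistent with a linear response.\n")
    }
  } else {
    cat("\n(no measurements supplied: predictions only)\n")
  }
  invisible(x)
}
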