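#' Periodic waveform
#'
#' One cardiac period of a flow (m^3/s) or pressure (Pa) signal, sampled at
#' strictly increasing times starting in [0, period). The signal is treated as
#' periodic: the sample at `period` wraps back to the first value.
#'
#' @param times sample times, s, strictly increasing, all in [0, period)
#' @param values sampled values (SI units)
#' @param period cardiac period, s; defaults to the implied sample spacing
#'   past the last sample (uniform grids) or `max(times) + first spacing`
#' @return an object of class `waveform`
#' @export
waveform <- function(times, values, period = NULL) {
  if (length(times) != length(values) || length(times) < 2L) {
    cf_stop("cf_invalid_waveform", "times and values must match, length >= 2")
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    cf_stop("cf_invalid_waveform", "waveform samples must be finite")
  }
  if (any(diff(times) <= 0)) {
    cf_stop("cf_invalid_waveform", "times must be strictly increasing")
  }
  if (is.null(period)) period <- times[length(times)] + (times[2] - times[1])
  if (!is.finite(period) || period <= times[length(times)]) {
    cf_stop("cf_invalid_waveform", "period must exceed the last sample time")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = period),
            class = "waveform")
}

#' Evaluate a waveform at arbitrary times (periodic linear interpolation)
#'
#' @param w a [waveform()]
#' @param t times, s (any real values; wrapped into the period)
#' @return interpolated values
#' @export
wave_at <- function(w, t) {
  tt <- t %% w$period
  # periodic extension: append the wrap point
  xs <- c(w$times, w$times[1] + w$period)
  ys <- c(w$values, w$values[1])
  # samples may not start at 0; wrap queries before the first sample
  below <- tt < xs[1]
  tt[below] <- tt[below] + w$period
  stats::approx(xs, ys, xout = tt, rule = 2)$y
}

#' Time-average of a periodic waveform
#'
#' Trapezoidal quadrature over one full period including the wrap-around
#' segment back to the first sample.
#'
#' @param w a [waveform()]
#' @return mean value over one period
#' @export
waveform_mean <- function(w) {
  xs <- c(w$times, w$times[1] + w$period)
  ys <- c(w$values, w$values[1])
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) / w$period
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples, period %.4g s, mean %.4g, range [%.4g, %.4g]\n",
              length(x$times), x$period, waveform_mean(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a waveform from a 2-column CSV
#'
#' The header declares units: first column `time_s`, second one of
#' `flow_m3s`, `flow_mls`, `pressure_pa`, `pressure_mmhg`. Values are
#' converted to SI. The period is inferred from the sample spacing past the
#' last time unless a `# period_s=<x>` comment line is present.
#'
#' @param path CSV path
#' @return a [waveform()] in SI units
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  period <- NULL
  meta <- grep("^#", lines, value = TRUE)
  pm <- regmatches(meta, regexec("period_s=([0-9.eE+-]+)", meta))
  pm <- Filter(length, pm)
  if (length(pm)) period <- as.numeric(pm[[1]][2])
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (ncol(df) < 2L) cf_stop("cf_format", "waveform CSV needs 2 columns: %s", path)
  unit <- tolower(names(df)[2])
  vals <- switch(unit,
    flow_m3s = df[[2]],
    flow_mls = mls_to_m3s(df[[2]]),
    pressure_pa = df[[2]],
    pressure_mmhg = mmHg_to_Pa(df[[2]]),
    cf_stop("cf_format", "unknown unit column '%s' in %s", names(df)[2], path))
  if (any(diff(df[[1]]) <= 0)) {
    cf_stop("cf_format", "non-monotone time column in %s", path)
  }
  waveform(df[[1]], vals, period = period)
}

#' Write a waveform to CSV
#'
#' @param w a [waveform()] (SI units)
#' @param path output path
#' @param unit one of "flow_mls", "flow_m3s", "pressure_mmhg", "pressure_pa"
#' @export
write_waveform_csv <- function(w, path, unit = "flow_mls") {
  vals <- switch(unit,
    flow_m3s = w$values,
    flow_mls = m3s_to_mls(w$values),
    pressure_pa = w$values,
    pressure_mmhg = Pa_to_mmHg(w$values),
    cf_stop("cf_format", "unknown unit '%s'", unit))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g", w$period), con)
  df <- data.frame(time_s = w$times, v = vals)
  names(df)[2] <- unit
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
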