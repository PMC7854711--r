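# Hydrophone / transducer trace handling: calibration against a
# frequency-dependent sensitivity curve, pulse metrics, spectra, CSV IO.

#' Time-pressure (or time-voltage) waveform
#'
#' A uniformly sampled trace. Raw hydrophone traces are in volts
#' (`calibrated = FALSE`); after [calibrate()] the values are in MPa.
#'
#' @param time_ns Sample times in ns, uniformly spaced (relative jitter
#'   below 1e-9), length >= 16.
#' @param value Sample values (V raw, MPa calibrated).
#' @param calibrated Logical; whether `value` is in MPa.
#' @return An object of class `waveform` with element `sample_interval_ns`.
#' @export
waveform <- function(time_ns, value, calibrated = FALSE) {
  if (length(time_ns) != length(value)) {
    stop("'time_ns' and 'value' must share length", call. = FALSE)
  }
  if (length(time_ns) < 16) {
    stop("waveform must have at least 16 samples", call. = FALSE)
  }
  dt <- diff(time_ns)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * abs(mean(dt)) + 1e-300) {
    stop("sampling error: 'time_ns' must be uniformly increasing", call. = FALSE)
  }
  structure(
    list(time_ns = as.numeric(time_ns), value = as.numeric(value),
         calibrated = isTRUE(calibrated), sample_interval_ns = mean(dt)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %.4g ns, %s, range [%.4g, %.4g] %s\n",
              length(x$value), x$sample_interval_ns,
              if (x$calibrated) "calibrated" else "raw",
              min(x$value), max(x$value),
              if (x$calibrated) "MPa" else "V"))
  invisible(x)
}

#' Hydrophone sensitivity curve
#'
#' Frequency-dependent sensitivity (V/MPa) supplied by the hydrophone
#' manufacturer, valid over a stated frequency band. Outside `valid_band_MHz`
#' the sensitivity is held at its band-edge value during calibration (flat
#' extrapolation: conservative when out-of-band spectral content exists).
#'
#' @param frequency_MHz Strictly increasing frequencies in MHz.
#' @param sensitivity_V_per_MPa Positive sensitivities in V/MPa.
#' @param valid_band_MHz Length-2 band `(lo, hi)` within the frequency range;
#'   defaults to the full range of `frequency_MHz`.
#' @return An object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(frequency_MHz, sensitivity_V_per_MPa,
                              valid_band_MHz = range(frequency_MHz)) {
  if (any(diff(frequency_MHz) <= 0)) {
    stop("'frequency_MHz' must be strictly increasing", call. = FALSE)
  }
  if (any(sensitivity_V_per_MPa <= 0)) {
    stop("invalid calibration: sensitivities must be positive", call. = FALSE)
  }
  if (valid_band_MHz[1] < min(frequency_MHz) ||
      valid_band_MHz[2] > max(frequency_MHz)) {
    stop("'valid_band_MHz' must lie within the tabulated frequency range",
         call. = FALSE)
  }
  structure(
    list(frequency_MHz = as.numeric(frequency_MHz),
         sensitivity_V_per_MPa = as.numeric(sensitivity_V_per_MPa),
         valid_band_MHz = as.numeric(valid_band_MHz)),
    class = "sensitivity_curve"
  )
}

# sensitivity evaluated at arbitrary |f| with flat band-edge extrapolation
eval_sensitivity <- function(sens, f_MHz) {
  f_cl <- pmin(pmax(f_MHz, sens$valid_band_MHz[1]), sens$valid_band_MHz[2])
  approx(sens$frequency_MHz, sens$sensitivity_V_per_MPa, xout = f_cl,
         rule = 2)$y
}

#' Calibrate a raw hydrophone trace to pressure
#'
#' Frequency-domain deconvolution: the FFT of the voltage trace is divided
#' by the sensitivity evaluated at each bin frequency (flat band-edge
#' extrapolation outside the valid band) and inverse-transformed. The output
#' is marked calibrated, in MPa.
#'
#' @param raw An uncalibrated [waveform()] in volts.
#' @param sens A [sensitivity_curve()].
#' @return A calibrated [waveform()] in MPa.
#' @export
calibrate <- function(raw, sens) {
  stopifnot(inherits(raw, "waveform"), inherits(sens, "sensitivity_curve"))
  if (raw$calibrated) {
    stop("waveform is already calibrated", call. = FALSE)
  }
  n <- length(raw$value)
  dt_s <- raw$sample_interval_ns * 1e-9
  f_MHz <- abs(signed_freq(n)) / (n * dt_s) / 1e6
  s <- eval_sensitivity(sens, f_MHz)
  V <- stats::fft(raw$value)
  p <- Re(stats::fft(V / s, inverse = TRUE)) / n
  waveform(raw$time_ns, p, calibrated = TRUE)
}

#' Peak, width and spectral metrics of a calibrated waveform
#'
#' After subtracting the baseline (median of the first 10% of samples), the
#' metrics are: peak compressive pressure (global maximum), peak rarefaction
#' pressure (magnitude of the minimum in the window from the compressive
#' peak to the end of the trace, where the trailing rarefaction tail of a
#' photoacoustic pulse lies), temporal FWHM of the compressive peak (linear
#' interpolation at half maximum), centre frequency (spectral centroid of
#' the one-sided magnitude spectrum), and the compression/rarefaction ratio.
#'
#' @param w A calibrated [waveform()].
#' @return An object of class `waveform_metrics`: a list with
#'   `p_max_compressive_MPa`, `p_rarefaction_MPa`, `temporal_fwhm_ns`,
#'   `centre_frequency_MHz`, `compression_rarefaction_ratio`.
#' @export
waveform_metrics <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (!w$calibrated) {
    stop("metrics are defined on calibrated waveforms; run calibrate() first",
         call. = FALSE)
  }
  v <- w$value - median(w$value[seq_len(max(2, ceiling(0.1 * length(w$value))))])
  t <- w$time_ns
  ipk <- which.max(v)
  p_max <- v[ipk]
  if (p_max <= 0) {
    stop("no-compressive-peak: trace has no positive maximum after baseline removal",
         call. = FALSE)
  }
  tail_v <- v[ipk:length(v)]
  p_rar <- if (min(tail_v) < 0) abs(min(tail_v)) else 0

  half <- p_max / 2
  left <- NA_real_
  for (j in seq(ipk, 2)) {
    if (v[j - 1] <= half && v[j] >= half) {
      left <- t[j - 1] + (half - v[j - 1]) / (v[j] - v[j - 1]) * (t[j] - t[j - 1])
      break
    }
  }
  right <- NA_real_
  if (ipk < length(v)) {
    for (j in ipk:(length(v) - 1)) {
      if (v[j] >= half && v[j + 1] <= half) {
        right <- t[j] + (v[j] - half) / (v[j] - v[j + 1]) * (t[j + 1] - t[j])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("unbounded peak: no half-maximum crossing on one side", call. = FALSE)
  }

  sp <- waveform_spectrum(waveform(w$time_ns, v, calibrated = TRUE))
  centroid <- sum(sp$frequency_MHz * sp$magnitude) / sum(sp$magnitude)

  structure(
    list(p_max_compressive_MPa = p_max,
         p_rarefaction_MPa = p_rar,
         temporal_fwhm_ns = right - left,
         centre_frequency_MHz = centroid,
         compression_rarefaction_ratio = if (p_rar > 0) p_max / p_rar else Inf),
    class = "waveform_metrics"
  )
}

#' @export
print.waveform_metrics <- function(x, ...) {
  cat(sprintf(paste0("<waveform_metrics> p_max %.3g MPa, rarefaction %.3g MPa ",
                     "(ratio %.3g), FWHM %.3g ns, centre %.3g MHz\n"),
              x$p_max_compressive_MPa, x$p_rarefaction_MPa,
              x$compression_rarefaction_ratio, x$temporal_fwhm_ns,
              x$centre_frequency_MHz))
  invisible(x)
}

#' One-sided magnitude spectrum of a waveform
#'
#' Raw FFT magnitudes for the non-negative frequency bins (no doubling), so
#' Parseval's identity holds with weight 1 on the DC and Nyquist bins and 2
#' elsewhere: \eqn{\sum x^2 = (\sum_k w_k |X_k|^2)/N}.
#'
#' @param w A [waveform()] (raw or calibrated).
#' @return A data.frame with `frequency_MHz` and `magnitude`, with attribute
#'   `n` (trace length).
#' @export
waveform_spectrum <- function(w) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$value)
  dt_s <- w$sample_interval_ns * 1e-9
  X <- stats::fft(w$value)
  k <- 0:(n %/% 2)
  out <- data.frame(frequency_MHz = k / (n * dt_s) / 1e6,
                    magnitude = Mod(X[k + 1]))
  attr(out, "n") <- n
  out
}

#' Read / write waveform CSV
#'
#' Two columns `time_ns,value`, comma-separated, decimal point, with header.
#'
#' @param path CSV path.
#' @param calibrated Whether the stored values are MPa.
#' @return [read_waveform_csv()] returns a [waveform()];
#'   [write_waveform_csv()] returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, calibrated = FALSE) {
  d <- read.csv(path)
  if (!all(c("time_ns", "value") %in% names(d))) {
    stop("waveform CSV must have columns 'time_ns' and 'value'", call. = FALSE)
  }
  waveform(d$time_ns, d$value, calibrated = calibrated)
}

#' @rdname read_waveform_csv
#' @param w A [waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  write.csv(data.frame(time_ns = w$time_ns, value = w$value), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a sensitivity curve CSV
#'
#' Columns `frequency_MHz,sensitivity_V_per_MPa`.
#'
#' @param path CSV path.
#' @param valid_band_MHz Optional band; defaults to the tabulated range.
#' @return A [sensitivity_curve()].
#' @export
read_sensitivity_csv <- function(path, valid_band_MHz = NULL) {
  d <- read.csv(path)
  if (!all(c("frequency_MHz", "sensitivity_V_per_MPa") %in% names(d))) {
    stop("sensitivity CSV must have columns 'frequency_MHz' and 'sensitivity_V_per_MPa'",
         call. = FALSE)
  }
  sensitivity_curve(d$frequency_MHz, d$sensitivity_V_per_MPa,
                    valid_band_MHz %||% range(d$frequency_MHz))
}
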