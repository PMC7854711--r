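# Fourier fringe demodulation: interferogram pair -> phase -> refractive
# index -> density -> pressure (Tait), plus profile extraction.
#
# The demodulation follows the standard 2D Fourier-transform method: locate
# the carrier sideband in the image spectrum, apodize it with a radial Hann
# window, shift it to DC, inverse-transform, and take the unwrapped argument.

# signed spectral coordinate (cycles/image) for FFT bin indices 0..n-1
signed_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k)
}

# circular distance between FFT bin indices (0-based), in bins
circ_dist <- function(i, p, n) {
  d <- abs(i - p)
  pmin(d, n - d)
}

unwrap_vec <- function(x) {
  d <- diff(x)
  x[1] + c(0, cumsum(d - 2 * pi * round(d / (2 * pi))))
}

# Itoh sequential 2D unwrapping: each column along rows, then align columns
# using the (assumed quiet) first row. Adequate for smooth, low-noise phase.
unwrap_matrix <- function(m) {
  m2 <- apply(m, 2, unwrap_vec)
  r1 <- m2[1, ]
  r1u <- unwrap_vec(r1)
  sweep(m2, 2, r1u - r1, "+")
}

# least-squares plane (offset + tilt) fitted over an ROI, evaluated everywhere
fit_plane <- function(grid, roi = NULL) {
  nr <- nrow(grid); nc <- ncol(grid)
  if (is.null(roi)) roi <- c(1, nr, 1, nc)
  check_roi(roi, nr, nc)
  rows <- roi[1]:roi[2]; cols <- roi[3]:roi[4]
  sub <- grid[rows, cols, drop = FALSE]
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  fit <- stats::lm.fit(cbind(1, rr, cc), as.vector(sub))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  outer(seq_len(nr) * b[2], rep(1, nc)) +
    outer(rep(1, nr), seq_len(nc) * b[3]) + b[1]
}

check_roi <- function(roi, nr, nc) {
  if (length(roi) != 4) {
    stop("roi must be c(row_min, row_max, col_min, col_max)", call. = FALSE)
  }
  if (roi[1] < 1 || roi[2] > nr || roi[3] < 1 || roi[4] > nc ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("bounds error: roi outside field", call. = FALSE)
  }
  invisible(roi)
}

#' Demodulate the fringe phase of an interferogram
#'
#' Converts a carrier-fringe intensity image into an unwrapped phase map by
#' the 2D Fourier-transform method: the carrier sideband is located as the
#' largest spectral peak outside a DC exclusion disc (restricted to the
#' half-plane of positive column frequency so the sign of the recovered
#' phase is deterministic), apodized with a radial Hann window, shifted to
#' DC, and inverse-transformed; the phase is the unwrapped argument of the
#' analytic image.
#'
#' @param image A `scalar_field` of quantity `"intensity"` (or a plain
#'   matrix).
#' @param carrier Optional known carrier frequency in cycles/pixel: a scalar
#'   (column direction) or length-2 vector (rows, cols). Auto-detected when
#'   `NULL`.
#' @param dc_exclusion_cycles Radius (cycles/image) of the disc around DC
#'   excluded from carrier detection.
#' @param window_radius_cycles Radius (cycles/image) of the Hann apodization
#'   window; defaults to half the carrier-to-DC distance.
#' @param min_peak_ratio Carrier detection threshold: the sideband magnitude
#'   must exceed this fraction of the DC magnitude.
#' @return A `scalar_field` of quantity `"phase_rad"`, with attribute
#'   `carrier_cycles_px` recording the demodulated carrier.
#' @export
extract_phase <- function(image, carrier = NULL, dc_exclusion_cycles = 3,
                          window_radius_cycles = NULL, min_peak_ratio = 0.1) {
  image <- as_field(image, "intensity")
  g <- image$grid
  nr <- nrow(g); nc <- ncol(g)
  Fm <- stats::fft(g)
  mag <- Mod(Fm)

  kr <- signed_freq(nr)
  kc <- signed_freq(nc)
  if (is.null(carrier)) {
    dist <- sqrt(outer(kr^2, kc^2, "+"))
    # positive-column-frequency half-plane; kc == 0 column allowed for kr > 0
    half <- outer(kr, kc, function(a, b) b > 0 | (b == 0 & a > 0))
    cand <- mag
    cand[dist <= dc_exclusion_cycles | !half] <- -Inf
    pk <- arrayInd(which.max(cand), dim(cand))
    if (mag[pk] < min_peak_ratio * mag[1, 1]) {
      stop("no-carrier: no spectral sideband above ", min_peak_ratio,
           " x DC magnitude", call. = FALSE)
    }
    p0 <- as.vector(pk) - 1L # 0-based bin indices
  } else {
    if (length(carrier) == 1) carrier <- c(0, carrier)
    p0 <- c(round(carrier[1] * nr), round(carrier[2] * nc)) %% c(nr, nc)
  }

  carrier_dist <- sqrt(min(p0[1], nr - p0[1])^2 + min(p0[2], nc - p0[2])^2)
  if (carrier_dist <= 0) {
    stop("no-carrier: carrier coincides with DC", call. = FALSE)
  }
  R <- window_radius_cycles %||% (carrier_dist / 2)

  dr <- circ_dist(0:(nr - 1), p0[1], nr)
  dc <- circ_dist(0:(nc - 1), p0[2], nc)
  dd <- sqrt(outer(dr^2, dc^2, "+"))
  W <- ifelse(dd < R, 0.5 * (1 + cos(pi * dd / R)), 0)

  # shift the windowed sideband to DC and inverse-transform
  ridx <- ((0:(nr - 1) + p0[1]) %% nr) + 1
  cidx <- ((0:(nc - 1) + p0[2]) %% nc) + 1
  Fs <- (Fm * W)[ridx, cidx]
  analytic <- stats::fft(Fs, inverse = TRUE) / (nr * nc)
  ph <- unwrap_matrix(Arg(analytic))

  out <- scalar_field(ph, "phase_rad", image$pixel_size_um, origin = image$origin)
  attr(out, "carrier_cycles_px") <- c(p0[1] / nr, p0[2] / nc)
  out
}

#' Phase change between pumped and reference interferograms
#'
#' Subtracts the reference phase map from the pumped one and removes the
#' residual instrumental plane (offset + tilt) fitted over a quiet region
#' where no acoustic signal is expected.
#'
#' @param pumped_phase,reference_phase `scalar_field`s of quantity
#'   `"phase_rad"` with identical shape.
#' @param quiet_roi Region used for plane fitting, as
#'   `c(row_min, row_max, col_min, col_max)` (1-based, inclusive). Defaults
#'   to the first 10% of rows (the margin farthest from the acoustic
#'   source in the package's conventions).
#' @param detrend If `FALSE`, skip plane removal.
#' @return A `scalar_field` of quantity `"phase_rad"` holding the acoustic
#'   phase change.
#' @export
phase_difference <- function(pumped_phase, reference_phase, quiet_roi = NULL,
                             detrend = TRUE) {
  pumped_phase <- as_field(pumped_phase, "phase_rad")
  reference_phase <- as_field(reference_phase, "phase_rad")
  if (!identical(dim(pumped_phase$grid), dim(reference_phase$grid))) {
    stop("incompatible fields: shapes differ", call. = FALSE)
  }
  d <- pumped_phase$grid - reference_phase$grid
  if (detrend) {
    nr <- nrow(d)
    if (is.null(quiet_roi)) quiet_roi <- c(1, max(2, ceiling(0.1 * nr)), 1, ncol(d))
    d <- d - fit_plane(d, quiet_roi)
  }
  scalar_field(d, "phase_rad", pumped_phase$pixel_size_um,
               origin = pumped_phase$origin)
}

#' Convert a phase-change map to a refractive-index change map
#'
#' \eqn{\Delta n = (\Delta\phi / 2\pi)(\lambda / l)} for probe wavelength
#' \eqn{\lambda} and probed liquid thickness \eqn{l}.
#'
#' @param dphi `scalar_field` of quantity `"phase_rad"`.
#' @param wavelength_nm Probe wavelength in nm (> 0).
#' @param path_mm Optical path through the liquid in mm (> 0).
#' @return A `scalar_field` of quantity `"delta_n"`.
#' @export
phase_to_index <- function(dphi, wavelength_nm, path_mm) {
  dphi <- as_field(dphi, "phase_rad")
  if (wavelength_nm <= 0 || path_mm <= 0) {
    stop("invalid parameter: wavelength and path must be positive", call. = FALSE)
  }
  dn <- dphi$grid / (2 * pi) * (wavelength_nm * 1e-9) / (path_mm * 1e-3)
  scalar_field(dn, "delta_n", dphi$pixel_size_um, origin = dphi$origin)
}

#' Convert a refractive-index change map to a density change map
#'
#' Uses the empirical proportionality for water,
#' \eqn{\Delta\rho = \Delta n / 0.322} g/cm^3.
#'
#' @param dn `scalar_field` of quantity `"delta_n"`.
#' @return A `scalar_field` of quantity `"delta_rho_gcm3"`.
#' @export
index_to_density <- function(dn) {
  dn <- as_field(dn, "delta_n")
  scalar_field(dn$grid / 0.322, "delta_rho_gcm3", dn$pixel_size_um,
               origin = dn$origin)
}

#' Convert a density change map to a gauge pressure map (Tait EOS)
#'
#' Evaluates \eqn{P = k_0/n [(\rho/\rho_0)^n - 1] + P_0} with
#' \eqn{\rho = \rho_0 + \Delta\rho} and reports the gauge pressure
#' \eqn{P - P_0} in MPa. Strictly increasing in the density change and
#' reducing to the linear acoustic relation \eqn{P \approx c_s^2 \Delta\rho}
#' for small signals.
#'
#' @param drho `scalar_field` of quantity `"delta_rho_gcm3"`.
#' @param eos A [tait_eos()] parameter set.
#' @return A `scalar_field` of quantity `"pressure_MPa"`.
#' @export
density_to_pressure <- function(drho, eos = tait_eos()) {
  drho <- as_field(drho, "delta_rho_gcm3")
  stopifnot(inherits(eos, "tait_eos"))
  rho <- eos$rho0_gcm3 + drho$grid
  if (any(rho <= 0)) {
    stop("unphysical density: rho0 + delta_rho <= 0 somewhere in the field",
         call. = FALSE)
  }
  p_gauge_Pa <- eos$k0_Pa / eos$exponent_n * ((rho / eos$rho0_gcm3)^eos$exponent_n - 1)
  scalar_field(p_gauge_Pa / 1e6, "pressure_MPa", drho$pixel_size_um,
               origin = drho$origin)
}

#' Pressure map from an interferogram pair
#'
#' Full inversion chain: demodulate both interferograms
#' ([extract_phase()]), subtract and detrend ([phase_difference()]), then
#' convert phase to refractive index, density, and finally gauge pressure
#' through the Tait equation of state.
#'
#' @param pair An [interferogram_pair()].
#' @param eos A [tait_eos()] parameter set.
#' @param quiet_roi Quiet region passed to [phase_difference()].
#' @param flip_sign Set `TRUE` for the opposite interferometer geometry, in
#'   which compression produces negative phase change.
#' @param ... Further arguments passed to [extract_phase()].
#' @return A `scalar_field` of quantity `"pressure_MPa"`.
#' @export
pressure_map <- function(pair, eos = tait_eos(), quiet_roi = NULL,
                         flip_sign = FALSE, ...) {
  stopifnot(inherits(pair, "interferogram_pair"))
  ph_p <- extract_phase(pair$pumped, carrier = pair$carrier_cycles_px, ...)
  ph_r <- extract_phase(pair$reference, carrier = pair$carrier_cycles_px, ...)
  dphi <- phase_difference(ph_p, ph_r, quiet_roi = quiet_roi)
  if (flip_sign) dphi$grid <- -dphi$grid
  dn <- phase_to_index(dphi, pair$probe_wavelength_nm, pair$optical_path_mm)
  density_to_pressure(index_to_density(dn), eos)
}

#' Average pressure profile across one image axis
#'
#' Collapses a pressure map to a 1D profile: for each position along `axis`
#' within the ROI, the mean and standard deviation of the pressure across
#' the orthogonal axis.
#'
#' @param map `scalar_field` of quantity `"pressure_MPa"`.
#' @param axis `"rows"` (profile indexed by row) or `"cols"`.
#' @param roi Optional `c(row_min, row_max, col_min, col_max)` restriction.
#' @return A data.frame of class `pressure_profile` with columns
#'   `position_um`, `mean_MPa`, `sd_MPa`.
#' @export
pressure_profile <- function(map, axis = c("rows", "cols"), roi = NULL) {
  map <- as_field(map, "pressure_MPa")
  axis <- match.arg(axis)
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  if (is.null(roi)) roi <- c(1, nr, 1, nc)
  check_roi(roi, nr, nc)
  sub <- map$grid[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (axis == "rows") {
    idx <- roi[1]:roi[2]
    m <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
  } else {
    idx <- roi[3]:roi[4]
    m <- colMeans(sub)
    s <- apply(sub, 2, stats::sd)
  }
  s[is.na(s)] <- 0
  structure(
    data.frame(position_um = (idx - 1) * map$pixel_size_um,
               mean_MPa = m, sd_MPa = s),
    class = c("pressure_profile", "data.frame")
  )
}

#' Full width at half maximum of a pressure profile
#'
#' Distance between the two half-maximum crossings of the profile's global
#' maximum, with linear interpolation between samples.
#'
#' @param profile A [pressure_profile()] (or any data.frame with
#'   `position_um` and `mean_MPa`).
#' @return FWHM in um.
#' @export
profile_fwhm <- function(profile) {
  x <- profile$position_um
  y <- profile$mean_MPa
  i <- which.max(y)
  if (y[i] <= 0) {
    stop("unbounded peak: profile has no positive maximum", call. = FALSE)
  }
  half <- y[i] / 2
  left <- NA_real_
  for (j in seq(i, 2)) {
    if (y[j - 1] <= half && y[j] >= half) {
      left <- x[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
      break
    }
  }
  right <- NA_real_
  if (i < length(y)) {
    for (j in i:(length(y) - 1)) {
      if (y[j] >= half && y[j + 1] <= half) {
        right <- x[j] + (y[j] - half) / (y[j] - y[j + 1]) * (x[j + 1] - x[j])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("unbounded peak: no half-maximum crossing on one side", call. = FALSE)
  }
  right - left
}

#' Export a pressure profile as CSV
#'
#' Columns: `position_um`, `mean_MPa`, `std_MPa`.
#'
#' @param profile A [pressure_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  out <- data.frame(position_um = profile$position_um,
                    mean_MPa = profile$mean_MPa,
                    std_MPa = profile$sd_MPa)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
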