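# Closed-form photoacoustic transduction and linear acoustics.
#
# Unit conventions at the API boundary follow the reporting units of the
# field: pressures in MPa, laser fluence in mJ/cm^2, film thicknesses in um,
# times in ns, absorption coefficients in cm^-1, impedances in N s m^-3.
# All arithmetic is carried out in SI internally.

#' Napierian absorption coefficient of a film
#'
#' Converts a decadic absorbance `A` measured across a film of thickness `l`
#' into the Napierian (base-e) absorption coefficient
#' \eqn{\mu_a = 2.3\,A/l}, reported in cm^-1.
#'
#' @param absorbance Decadic absorbance (dimensionless, >= 0).
#' @param thickness_um Film thickness in micrometres (> 0).
#' @return Napierian absorption coefficient in cm^-1.
#' @examples
#' napierian_mu_a(1.23, 70) # ~404 cm^-1
#' @export
napierian_mu_a <- function(absorbance, thickness_um) {
  if (any(thickness_um <= 0)) {
    stop("invalid parameter: 'thickness_um' must be positive", call. = FALSE)
  }
  if (any(absorbance < 0)) {
    stop("invalid parameter: 'absorbance' must be non-negative", call. = FALSE)
  }
  2.3 * absorbance / (thickness_um * 1e-4) # um -> cm
}

#' Grueneisen parameter
#'
#' \eqn{\Gamma = c_s^2 \beta / C_p}: the efficiency with which deposited heat
#' is converted into pressure by thermoelastic expansion.
#'
#' @param sound_speed_ms Speed of sound in m/s.
#' @param thermal_expansion_K Volumetric thermal expansion coefficient in 1/K.
#' @param heat_capacity_JkgK Specific heat capacity at constant pressure in
#'   J kg^-1 K^-1 (> 0).
#' @return Dimensionless Grueneisen parameter.
#' @examples
#' gruneisen(1000, 9.2e-4, 1460) # ~0.63
#' @export
gruneisen <- function(sound_speed_ms, thermal_expansion_K, heat_capacity_JkgK) {
  if (any(heat_capacity_JkgK <= 0)) {
    stop("invalid parameter: 'heat_capacity_JkgK' must be positive", call. = FALSE)
  }
  sound_speed_ms^2 * thermal_expansion_K / heat_capacity_JkgK
}

#' Classify a photoacoustic absorber as thin or thick
#'
#' An absorber is "thin" when its optical penetration depth \eqn{1/\mu_a} is
#' smaller than the acoustic transit length \eqn{c_s \tau_L} during the laser
#' pulse, and "thick" otherwise. The boundary case
#' \eqn{1/\mu_a = c_s \tau_L} is assigned to "thick".
#'
#' @param mu_a_cm1 Napierian absorption coefficient in cm^-1 (> 0).
#' @param sound_speed_ms Speed of sound in the absorber in m/s (> 0).
#' @param pulse_fwhm_ns Laser pulse duration (FWHM) in ns (> 0).
#' @return `"thin"` or `"thick"`.
#' @examples
#' classify_absorber(7600, 1482, 8) # "thin"
#' classify_absorber(400, 1482, 8)  # "thick"
#' @export
classify_absorber <- function(mu_a_cm1, sound_speed_ms, pulse_fwhm_ns) {
  if (any(c(mu_a_cm1, sound_speed_ms, pulse_fwhm_ns) <= 0)) {
    stop("invalid parameter: all arguments must be positive", call. = FALSE)
  }
  penetration_m <- 1 / (mu_a_cm1 * 100)
  transit_m <- sound_speed_ms * pulse_fwhm_ns * 1e-9
  ifelse(penetration_m < transit_m, "thin", "thick")
}

#' Peak pressure generated by a thin absorber
#'
#' For a thin absorber (optical penetration much shorter than the acoustic
#' transit during the pulse) the peak photoacoustic pressure is
#' \eqn{p_{max} = \Gamma E_L / (c_s \tau_L)}.
#'
#' @param gamma Grueneisen parameter (dimensionless).
#' @param fluence_mJcm2 Laser fluence in mJ/cm^2.
#' @param sound_speed_ms Speed of sound in m/s (> 0).
#' @param pulse_fwhm_ns Laser pulse duration (FWHM) in ns (> 0).
#' @return Peak pressure in MPa.
#' @examples
#' peak_pressure_thin(0.63, 100, 1000, 8) # ~78.8 MPa
#' @export
peak_pressure_thin <- function(gamma, fluence_mJcm2, sound_speed_ms, pulse_fwhm_ns) {
  if (any(c(sound_speed_ms, pulse_fwhm_ns) <= 0)) {
    stop("invalid parameter: 'sound_speed_ms' and 'pulse_fwhm_ns' must be positive",
         call. = FALSE)
  }
  fluence_si <- fluence_mJcm2 * 10 # mJ/cm^2 -> J/m^2
  gamma * fluence_si / (sound_speed_ms * pulse_fwhm_ns * 1e-9) / 1e6
}

#' Peak pressure generated by a thick absorber
#'
#' For a thick absorber (penetration depth longer than the acoustic transit)
#' the peak photoacoustic pressure is \eqn{p_{max} = \Gamma E_L \mu_a}.
#'
#' @param gamma Grueneisen parameter (dimensionless, >= 0).
#' @param fluence_mJcm2 Laser fluence in mJ/cm^2 (>= 0).
#' @param mu_a_cm1 Napierian absorption coefficient in cm^-1 (>= 0).
#' @return Peak pressure in MPa.
#' @examples
#' peak_pressure_thick(0.63, 50, 400) # ~12.6 MPa
#' @export
peak_pressure_thick <- function(gamma, fluence_mJcm2, mu_a_cm1) {
  if (any(c(gamma, fluence_mJcm2, mu_a_cm1) < 0)) {
    stop("invalid parameter: arguments must be non-negative", call. = FALSE)
  }
  fluence_si <- fluence_mJcm2 * 10  # J/m^2
  mu_a_si <- mu_a_cm1 * 100         # m^-1
  gamma * fluence_si * mu_a_si / 1e6
}

#' Acoustic intensity transmission coefficient across an interface
#'
#' \eqn{T = 4 Z_1 Z_2 / (Z_1 + Z_2)^2} for a plane wave crossing from a
#' medium of acoustic impedance `z1` into one of impedance `z2`. Symmetric in
#' its arguments, bounded by 1, with equality only for matched impedances.
#'
#' @param z1,z2 Acoustic impedances in N s m^-3 (> 0).
#' @return Intensity transmission coefficient in (0, 1].
#' @examples
#' transmission_coefficient(1.048e6, 1.494e6) # 0.97 (PDMS -> water)
#' transmission_coefficient(14e6, 1.494e6)    # 0.35 (glass -> water)
#' @export
transmission_coefficient <- function(z1, z2) {
  if (any(c(z1, z2) <= 0)) {
    stop("invalid parameter: impedances must be positive", call. = FALSE)
  }
  4 * z1 * z2 / (z1 + z2)^2
}

#' Mechanical Index
#'
#' MI = peak rarefaction pressure (MPa) divided by the square root of the
#' centre frequency (MHz); the standard cavitation-risk proxy. Values above
#' 0.7 indicate risk of cavitation damage; the returned value carries an
#' `exceeds_cavitation_threshold` attribute flagging this.
#'
#' @param p_rarefaction_MPa Magnitude of the peak rarefaction pressure in MPa
#'   (>= 0).
#' @param centre_frequency_MHz Centre frequency in MHz (> 0).
#' @return Mechanical Index (dimensionless) with attribute
#'   `exceeds_cavitation_threshold` (logical).
#' @examples
#' mechanical_index(0.7, 1) # 0.7, at the threshold
#' @export
mechanical_index <- function(p_rarefaction_MPa, centre_frequency_MHz) {
  if (any(centre_frequency_MHz <= 0)) {
    stop("invalid parameter: 'centre_frequency_MHz' must be positive", call. = FALSE)
  }
  if (any(p_rarefaction_MPa < 0)) {
    stop("invalid parameter: 'p_rarefaction_MPa' is a magnitude and must be >= 0",
         call. = FALSE)
  }
  mi <- p_rarefaction_MPa / sqrt(centre_frequency_MHz)
  attr(mi, "exceeds_cavitation_threshold") <- mi > 0.7
  mi
}

#' Material acoustic parameter set
#'
#' Bundles the acoustic and thermoelastic constants of a transducer or
#' coupling material. If `gruneisen_Gamma` is omitted it is derived as
#' \eqn{c_s^2 \beta / C_p}.
#'
#' @param name Material label.
#' @param impedance_Nsm3 Acoustic impedance in N s m^-3 (> 0).
#' @param sound_speed_ms Speed of sound in m/s (> 0).
#' @param density_kgm3 Density in kg/m^3 (> 0).
#' @param thermal_expansion_K Volumetric thermal expansion coefficient in 1/K.
#' @param heat_capacity_JkgK Specific heat capacity in J kg^-1 K^-1 (> 0).
#' @param gruneisen_Gamma Optional Grueneisen parameter; derived when `NULL`.
#' @return An object of class `material_acoustics`.
#' @export
material_acoustics <- function(name, impedance_Nsm3, sound_speed_ms, density_kgm3,
                               thermal_expansion_K, heat_capacity_JkgK,
                               gruneisen_Gamma = NULL) {
  if (impedance_Nsm3 <= 0 || sound_speed_ms <= 0 || heat_capacity_JkgK <= 0 ||
      density_kgm3 <= 0) {
    stop("invalid parameter: impedance, sound speed, density and heat capacity must be positive",
         call. = FALSE)
  }
  if (is.null(gruneisen_Gamma)) {
    gruneisen_Gamma <- gruneisen(sound_speed_ms, thermal_expansion_K, heat_capacity_JkgK)
  }
  structure(
    list(name = name, impedance_Nsm3 = impedance_Nsm3,
         sound_speed_ms = sound_speed_ms, density_kgm3 = density_kgm3,
         thermal_expansion_K = thermal_expansion_K,
         heat_capacity_JkgK = heat_capacity_JkgK,
         gruneisen_Gamma = gruneisen_Gamma),
    class = "material_acoustics"
  )
}

#' Piezophotonic film specification
#'
#' Thickness and absorbance of a light-to-pressure transducer film. The
#' Napierian absorption coefficient is derived from the decadic absorbance
#' when not supplied.
#'
#' @param label Film label.
#' @param thickness_um Film thickness in um (> 0).
#' @param absorbance Decadic absorbance (>= 0).
#' @param mu_a_cm1 Optional Napierian absorption coefficient in cm^-1;
#'   derived from `absorbance` when `NULL`.
#' @return An object of class `film_spec`.
#' @export
film_spec <- function(label, thickness_um, absorbance, mu_a_cm1 = NULL) {
  if (thickness_um <= 0) {
    stop("invalid parameter: 'thickness_um' must be positive", call. = FALSE)
  }
  if (absorbance < 0) {
    stop("invalid parameter: 'absorbance' must be non-negative", call. = FALSE)
  }
  if (is.null(mu_a_cm1)) mu_a_cm1 <- napierian_mu_a(absorbance, thickness_um)
  if (mu_a_cm1 < 0) {
    stop("invalid parameter: 'mu_a_cm1' must be non-negative", call. = FALSE)
  }
  structure(
    list(label = label, thickness_um = thickness_um, absorbance = absorbance,
         mu_a_cm1 = mu_a_cm1),
    class = "film_spec"
  )
}

#' Laser pulse specification
#'
#' @param fluence_mJcm2 Fluence in mJ/cm^2 (>= 0).
#' @param duration_fwhm_ns Pulse duration (FWHM) in ns (> 0).
#' @param wavelength_nm Wavelength in nm.
#' @param rep_rate_Hz Repetition rate in Hz.
#' @return An object of class `laser_pulse`.
#' @export
laser_pulse <- function(fluence_mJcm2, duration_fwhm_ns, wavelength_nm = 532,
                        rep_rate_Hz = 10) {
  if (fluence_mJcm2 < 0) {
    stop("invalid parameter: 'fluence_mJcm2' must be non-negative", call. = FALSE)
  }
  if (duration_fwhm_ns <= 0) {
    stop("invalid parameter: 'duration_fwhm_ns' must be positive", call. = FALSE)
  }
  structure(
    list(fluence_mJcm2 = fluence_mJcm2, duration_fwhm_ns = duration_fwhm_ns,
         wavelength_nm = wavelength_nm, rep_rate_Hz = rep_rate_Hz),
    class = "laser_pulse"
  )
}

#' Load the bundled piezophotonic film property table
#'
#' Reads the reference table of piezophotonic films (thickness, absorbance,
#' Napierian absorption coefficient and measured peak pressure at 50 mJ/cm^2,
#' 532 nm). Absorbances recorded as lower bounds (saturated measurements) are
#' flagged in `absorbance_is_lower_bound`.
#'
#' @param path Path to a film table CSV; defaults to the bundled table.
#' @return A data.frame with one row per film.
#' @export
load_film_table <- function(path = system.file("extdata", "piezophotonic_films.csv",
                                               package = "pawkit")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("film table not found: ", path, call. = FALSE)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read material / film / laser parameters from a YAML config
#'
#' The config uses explicit unit-bearing keys, e.g. `impedance_Nsm3`,
#' `fluence_mJcm2`, `thickness_um`. Recognised top-level sections:
#' `material`, `film`, `laser`; each is optional.
#'
#' @param path Path to a YAML file.
#' @return A list with any of `material` (`material_acoustics`), `film`
#'   (`film_spec`), `laser` (`laser_pulse`).
#' @export
read_physics_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$material)) {
    m <- cfg$material
    out$material <- material_acoustics(
      name = m$name %||% "material",
      impedance_Nsm3 = m$impedance_Nsm3,
      sound_speed_ms = m$sound_speed_ms,
      density_kgm3 = m$density_kgm3,
      thermal_expansion_K = m$thermal_expansion_K %||% 0,
      heat_capacity_JkgK = m$heat_capacity_JkgK,
      gruneisen_Gamma = m$gruneisen_Gamma
    )
  }
  if (!is.null(cfg$film)) {
    f <- cfg$film
    out$film <- film_spec(f$label %||% "film", f$thickness_um, f$absorbance,
                          f$mu_a_cm1)
  }
  if (!is.null(cfg$laser)) {
    l <- cfg$laser
    out$laser <- laser_pulse(l$fluence_mJcm2, l$duration_fwhm_ns,
                             l$wavelength_nm %||% 532, l$rep_rate_Hz %||% 10)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
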