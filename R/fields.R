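# 2D scalar fields, the Tait equation of state, and TIFF/CSV interchange.

.field_quantities <- c("intensity", "phase_rad", "delta_n", "delta_rho_gcm3",
                       "pressure_MPa")

#' 2D scalar field on a uniform pixel grid
#'
#' The common container for interferometric data: a real-valued matrix tagged
#' with the physical quantity it holds and the (isotropic) pixel size.
#' Pixel coordinates are 0-based and row-major; `origin` records the grid
#' index of the physical origin.
#'
#' @param grid Numeric matrix, at least 8 x 8.
#' @param quantity One of `"intensity"`, `"phase_rad"`, `"delta_n"`,
#'   `"delta_rho_gcm3"`, `"pressure_MPa"`.
#' @param pixel_size_um Pixel size in um/pixel (> 0).
#' @param origin Length-2 integer (row, col) index of the grid origin.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(grid, quantity, pixel_size_um, origin = c(0L, 0L)) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("'grid' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(grid) < 8 || ncol(grid) < 8) {
    stop("'grid' must be at least 8 x 8", call. = FALSE)
  }
  quantity <- match.arg(quantity, .field_quantities)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    stop("invalid parameter: 'pixel_size_um' must be a positive scalar", call. = FALSE)
  }
  structure(
    list(grid = grid, quantity = quantity, pixel_size_um = pixel_size_um,
         origin = as.integer(origin)),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s, %d x %d px @ %g um/px, range [%.4g, %.4g]\n",
              x$quantity, nrow(x$grid), ncol(x$grid), x$pixel_size_um,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.scalar_field <- function(x) dim(x$grid)

# internal: coerce matrix-or-field to field, checking quantity
as_field <- function(x, quantity, pixel_size_um = 1) {
  if (inherits(x, "scalar_field")) {
    if (!identical(x$quantity, quantity)) {
      stop(sprintf("expected a '%s' field, got '%s'", quantity, x$quantity),
           call. = FALSE)
    }
    x
  } else {
    scalar_field(x, quantity, pixel_size_um)
  }
}

#' Tait equation of state for a liquid
#'
#' Parameters of the empirical Tait pressure-density relation
#' \eqn{P = k_0/n [(\rho/\rho_0)^n - 1] + P_0} used to convert interferometric
#' density changes into pressure. Defaults describe water at 20 C:
#' \eqn{\rho_0 = 0.9982} g/cm^3, \eqn{n = 7.15},
#' \eqn{k_0 = \rho_0 c_s^2} with \eqn{c_s = 1482} m/s, and atmospheric
#' \eqn{P_0}.
#'
#' @param k0_Pa Tait modulus in Pa (> 0).
#' @param exponent_n Tait exponent (> 0).
#' @param rho0_gcm3 Reference density in g/cm^3 (> 0).
#' @param p0_Pa Reference pressure in Pa.
#' @return An object of class `tait_eos`.
#' @export
tait_eos <- function(k0_Pa = 998.2 * 1482^2, exponent_n = 7.15,
                     rho0_gcm3 = 0.9982, p0_Pa = 101325) {
  if (k0_Pa <= 0 || exponent_n <= 0 || rho0_gcm3 <= 0) {
    stop("invalid parameter: 'k0_Pa', 'exponent_n' and 'rho0_gcm3' must be positive",
         call. = FALSE)
  }
  structure(
    list(k0_Pa = k0_Pa, exponent_n = exponent_n, rho0_gcm3 = rho0_gcm3,
         p0_Pa = p0_Pa),
    class = "tait_eos"
  )
}

#' Interferogram pair (pumped and reference)
#'
#' Two intensity images from a Mach-Zehnder interferometer: one with the
#' acoustic pump on (`pumped`) and one without (`reference`), plus the probe
#' optics needed to convert fringe phase to refractive index.
#'
#' @param pumped,reference `scalar_field` objects of quantity `"intensity"`
#'   with identical shape and pixel size.
#' @param probe_wavelength_nm Probe wavelength in nm (> 0).
#' @param optical_path_mm Thickness of the probed liquid layer in mm (> 0).
#' @param carrier_cycles_px Optional known carrier frequency in cycles/pixel;
#'   auto-detected from the spectrum when `NULL`.
#' @return An object of class `interferogram_pair`.
#' @export
interferogram_pair <- function(pumped, reference, probe_wavelength_nm,
                               optical_path_mm, carrier_cycles_px = NULL) {
  pumped <- as_field(pumped, "intensity")
  reference <- as_field(reference, "intensity")
  if (!identical(dim(pumped$grid), dim(reference$grid))) {
    stop("incompatible fields: pumped and reference must share shape", call. = FALSE)
  }
  if (!isTRUE(all.equal(pumped$pixel_size_um, reference$pixel_size_um))) {
    stop("incompatible fields: pumped and reference must share pixel size",
         call. = FALSE)
  }
  if (probe_wavelength_nm <= 0 || optical_path_mm <= 0) {
    stop("invalid parameter: wavelength and optical path must be positive",
         call. = FALSE)
  }
  structure(
    list(pumped = pumped, reference = reference,
         probe_wavelength_nm = probe_wavelength_nm,
         optical_path_mm = optical_path_mm,
         carrier_cycles_px = carrier_cycles_px),
    class = "interferogram_pair"
  )
}

#' Write a scalar field as a float TIFF with a JSON sidecar
#'
#' The TIFF format (as written by the tiff package) stores samples in
#' [0, 1], so the grid is affinely rescaled before writing and the offset,
#' scale, quantity and pixel size are recorded in a `<path>.json` sidecar.
#' [read_field_tiff()] restores the original values from the sidecar.
#'
#' @param field A `scalar_field`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  lo <- min(g); hi <- max(g)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((g - lo) / scale, path, bits.per.sample = 32L)
  meta <- list(offset = lo, scale = scale, quantity = field$quantity,
               pixel_size_um = field$pixel_size_um, origin = field$origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scalar field from a TIFF written by [write_field_tiff()]
#'
#' Without a sidecar the raw pixel values are returned unscaled, tagged with
#' the supplied `quantity` and `pixel_size_um`.
#'
#' @param path TIFF path.
#' @param quantity,pixel_size_um Used when no sidecar is present.
#' @return A `scalar_field`.
#' @export
read_field_tiff <- function(path, quantity = "intensity", pixel_size_um = 1) {
  g <- tiff::readTIFF(path)
  if (length(dim(g)) == 3) g <- g[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    g <- g * meta$scale + meta$offset
    scalar_field(g, meta$quantity, meta$pixel_size_um,
                 origin = meta$origin %||% c(0L, 0L))
  } else {
    scalar_field(g, quantity, pixel_size_um)
  }
}
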