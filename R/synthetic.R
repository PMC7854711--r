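# Seeded generators for every input the pipeline consumes: quasi-1D
# pressure fields, carrier-fringe interferogram pairs, hydrophone pulses,
# and GUV release movies with ground-truth tables.
#
# Every generator is a pure function of (seed, config): the RNG state is
# saved, seeded, and restored, so outputs are bit-reproducible and the
# caller's RNG is untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the parameters of all synthetic-data generators. The defaults
#' embody the signal structure this package is built to analyse: a mostly
#' compressive ~1 MPa pressure pulse of ~36 um spatial FWHM with a
#' rarefaction tail one tenth of the peak; hydrophone pulses of 7 MPa peak,
#' 25 ns temporal FWHM and compression/rarefaction ratio 10; and GUV movies
#' at 2 Hz whose interior fluorescence decays as a t^0.53 power law
#' reaching 25% release at 900 s.
#'
#' @param seed Integer RNG seed.
#' @param geometry `shape` (rows, cols) and `pixel_size_um` of the
#'   interferometric field of view.
#' @param pulse Pressure-pulse parameters: `peak_MPa`, `spatial_fwhm_um`,
#'   `rarefaction_ratio` (peak / |rarefaction|, may be `Inf`),
#'   `position_um` (centre along the propagation axis; `NULL` = grid
#'   centre).
#' @param fringes Carrier-fringe parameters: `carrier_cycles_px`,
#'   `visibility` in (0, 1], `mean_intensity`, `noise_sd` (additive
#'   Gaussian noise on the images).
#' @param optics Probe optics: `lambda_nm`, `path_mm`.
#' @param eos A [tait_eos()].
#' @param movie GUV movie parameters: `shape`, `pixel_size_um`, `n_guvs`,
#'   `radius_um` (min, max), `k` (s^-n), `n` (diffusion exponent),
#'   `duration_s`, `frame_rate_hz`, `i0` (initial interior intensity),
#'   `background` (ambient level), `noise_sigma` (per-pixel Gaussian sd).
#' @param waveform Hydrophone pulse parameters: `p_max_MPa`,
#'   `temporal_fwhm_ns`, `rarefaction_ratio`, `sample_interval_ns`,
#'   `duration_ns` (`NULL` = 10 x FWHM), `noise_sigma`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       geometry = list(),
                       pulse = list(),
                       fringes = list(),
                       optics = list(),
                       eos = tait_eos(),
                       movie = list(),
                       waveform = list()) {
  cfg <- list(
    seed = as.integer(seed),
    geometry = modifyList(list(shape = c(256L, 256L), pixel_size_um = 1),
                          geometry),
    pulse = modifyList(list(peak_MPa = 1, spatial_fwhm_um = 36,
                            rarefaction_ratio = 10, position_um = NULL),
                       pulse, keep.null = TRUE),
    fringes = modifyList(list(carrier_cycles_px = 0.25, visibility = 0.8,
                              mean_intensity = 100, noise_sd = 0),
                         fringes),
    optics = modifyList(list(lambda_nm = 400, path_mm = 2), optics),
    eos = eos,
    movie = modifyList(list(shape = c(128L, 128L), pixel_size_um = 1,
                            n_guvs = 5L, radius_um = c(8, 15),
                            k = 0.25 / 900^0.53, n = 0.53,
                            duration_s = 900, frame_rate_hz = 2,
                            i0 = 100, background = 10, noise_sigma = 5),
                       movie),
    waveform = modifyList(list(p_max_MPa = 7, temporal_fwhm_ns = 25,
                               rarefaction_ratio = 10,
                               sample_interval_ns = 0.25,
                               duration_ns = NULL, noise_sigma = 0),
                          waveform, keep.null = TRUE)
  )
  if (cfg$fringes$visibility <= 0 || cfg$fringes$visibility > 1) {
    stop("invalid parameter: fringe visibility must be in (0, 1]", call. = FALSE)
  }
  if (cfg$pulse$rarefaction_ratio < 1 || cfg$waveform$rarefaction_ratio < 1) {
    stop("invalid parameter: rarefaction_ratio must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from YAML
#'
#' Top-level keys mirror the arguments of [sim_config()]; an `eos` section
#' with `k0_Pa`, `exponent_n`, `rho0_gcm3`, `p0_Pa` overrides the water
#' defaults.
#'
#' @param path YAML path.
#' @param seed Optional seed overriding the file's.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  eos <- if (!is.null(y$eos)) {
    do.call(tait_eos, y$eos)
  } else {
    tait_eos()
  }
  sim_config(seed = seed %||% y$seed %||% 1L,
             geometry = y$geometry %||% list(),
             pulse = y$pulse %||% list(),
             fringes = y$fringes %||% list(),
             optics = y$optics %||% list(),
             eos = eos,
             movie = y$movie %||% list(),
             waveform = y$waveform %||% list())
}

# Asymmetric pulse template: raised-cosine compressive lobe (FWHM = fwhm,
# base width 2*fwhm) with an attached inverted trailing lobe of amplitude
# peak/ratio, reproducing the steep-rise / small-rarefaction-tail morphology
# of photoacoustic pulses. x is distance (or time) from the compressive peak.
pulse_template <- function(x, peak, fwhm, rarefaction_ratio = 10) {
  y <- numeric(length(x))
  main <- abs(x) <= fwhm
  y[main] <- peak * cos(pi * x[main] / (2 * fwhm))^2
  if (is.finite(rarefaction_ratio)) {
    tail <- x > fwhm & x < 3 * fwhm
    y[tail] <- -(peak / rarefaction_ratio) *
      cos(pi * (x[tail] - 2 * fwhm) / (2 * fwhm))^2
  }
  y
}

#' Generate a quasi-1D synthetic pressure field
#'
#' A planar pulse: the asymmetric compressive template along the
#' propagation axis (rows), constant along the orthogonal axis. The peak
#' pressure and FWHM match the config up to pixel quantisation.
#'
#' @param cfg A [sim_config()].
#' @return A `scalar_field` of quantity `"pressure_MPa"`.
#' @export
make_pressure_field <- function(cfg = sim_config()) {
  g <- cfg$geometry; p <- cfg$pulse
  nr <- g$shape[1]; nc <- g$shape[2]; px <- g$pixel_size_um
  extent_um <- (nr - 1) * px
  if (4 * p$spatial_fwhm_um > extent_um) {
    stop("geometry error: pulse (support 4 x FWHM) wider than the grid",
         call. = FALSE)
  }
  pos <- p$position_um %||% (extent_um / 2)
  x <- (0:(nr - 1)) * px - pos
  prof <- pulse_template(x, p$peak_MPa, p$spatial_fwhm_um, p$rarefaction_ratio)
  scalar_field(matrix(prof, nr, nc), "pressure_MPa", px)
}

# invert the Tait EOS: gauge pressure (MPa) -> density change (g/cm^3)
tait_invert <- function(p_MPa, eos) {
  arg <- 1 + eos$exponent_n * (p_MPa * 1e6) / eos$k0_Pa
  if (any(arg <= 0)) {
    stop("unphysical pressure: outside the invertible branch of the Tait EOS",
         call. = FALSE)
  }
  eos$rho0_gcm3 * (arg^(1 / eos$exponent_n) - 1)
}

#' Render a synthetic interferogram pair from a pressure field
#'
#' Forward model of the interferometric measurement: pressure -> density
#' change (inverse Tait) -> refractive-index change
#' (\eqn{\Delta n = 0.322 \Delta\rho}) -> fringe phase
#' (\eqn{\Delta\phi = 2\pi \Delta n\, l/\lambda}) -> carrier fringes
#' \eqn{I = I_0 (1 + V \cos(2\pi f c + \Delta\phi))} along the column
#' coordinate c. The reference image is the unperturbed carrier. Optional
#' additive Gaussian noise (`fringes$noise_sd`) is seeded from the config.
#'
#' @param field A `scalar_field` of quantity `"pressure_MPa"` (defaults to
#'   [make_pressure_field()] of the same config).
#' @param cfg A [sim_config()].
#' @return An [interferogram_pair()].
#' @export
render_interferogram <- function(field = NULL, cfg = sim_config()) {
  field <- field %||% make_pressure_field(cfg)
  field <- as_field(field, "pressure_MPa")
  fr <- cfg$fringes; op <- cfg$optics
  drho <- tait_invert(field$grid, cfg$eos)
  dn <- 0.322 * drho
  dphi <- 2 * pi * dn * (op$path_mm * 1e-3) / (op$lambda_nm * 1e-9)
  nr <- nrow(dphi); nc <- ncol(dphi)
  psi <- matrix(2 * pi * fr$carrier_cycles_px * (0:(nc - 1)),
                nr, nc, byrow = TRUE)
  i0 <- fr$mean_intensity
  pumped <- i0 * (1 + fr$visibility * cos(psi + dphi))
  reference <- i0 * (1 + fr$visibility * cos(psi))
  if (fr$noise_sd > 0) {
    noise <- with_seed(cfg$seed, list(
      p = matrix(rnorm(nr * nc, 0, fr$noise_sd), nr, nc),
      r = matrix(rnorm(nr * nc, 0, fr$noise_sd), nr, nc)
    ))
    pumped <- pumped + noise$p
    reference <- reference + noise$r
  }
  px <- field$pixel_size_um
  interferogram_pair(scalar_field(pumped, "intensity", px),
                     scalar_field(reference, "intensity", px),
                     probe_wavelength_nm = op$lambda_nm,
                     optical_path_mm = op$path_mm)
}

#' Generate a synthetic hydrophone waveform
#'
#' The asymmetric compressive pulse template in time: peak `p_max_MPa`,
#' temporal FWHM `temporal_fwhm_ns`, trailing rarefaction at
#' `p_max / rarefaction_ratio`, plus optional seeded Gaussian noise. The
#' pulse is centred at 3 x FWHM so the leading samples provide a clean
#' baseline.
#'
#' @param cfg A [sim_config()].
#' @return A calibrated [waveform()] in MPa.
#' @export
make_waveform <- function(cfg = sim_config()) {
  wf <- cfg$waveform
  dt <- wf$sample_interval_ns
  if (wf$temporal_fwhm_ns / dt < 8) {
    stop("sampling error: need at least 8 samples across the pulse FWHM",
         call. = FALSE)
  }
  dur <- wf$duration_ns %||% (10 * wf$temporal_fwhm_ns)
  t <- seq(0, dur, by = dt)
  v <- pulse_template(t - 3 * wf$temporal_fwhm_ns, wf$p_max_MPa,
                      wf$temporal_fwhm_ns, wf$rarefaction_ratio)
  if (wf$noise_sigma > 0) {
    v <- v + with_seed(cfg$seed, rnorm(length(v), 0, wf$noise_sigma))
  }
  waveform(t, v, calibrated = TRUE)
}

#' Generate a synthetic GUV release movie with ground truth
#'
#' Stationary bright discs on a dark background: disc i has interior
#' intensity \eqn{B + I_0 \max(0, 1 - k t^n)} at frame time t over ambient
#' level B, i.e. its background-corrected intensity follows the power-law
#' release model exactly. Disc centres are drawn uniformly (seeded) with
#' non-overlap enforced by rejection; per-pixel Gaussian noise is added to
#' every frame.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `guv_movie`: `stack` (array
#'   `[row, col, frame]`), `times_s`, `truth` (data.frame with `guv`,
#'   `row`, `col`, `radius_um`, `i0`, `k`, `n`), and `config`.
#' @export
make_guv_movie <- function(cfg = sim_config()) {
  mv <- cfg$movie
  nr <- mv$shape[1]; nc <- mv$shape[2]; px <- mv$pixel_size_um
  nt <- floor(mv$duration_s * mv$frame_rate_hz) + 1
  times <- (0:(nt - 1)) / mv$frame_rate_hz

  placement <- with_seed(cfg$seed, {
    rows <- numeric(0); cols <- numeric(0); rads <- numeric(0)
    tries <- 0
    while (length(rows) < mv$n_guvs) {
      tries <- tries + 1
      if (tries > 1000) {
        stop("packing error: could not place ", mv$n_guvs,
             " non-overlapping GUVs after 1000 attempts", call. = FALSE)
      }
      r_um <- runif(1, mv$radius_um[1], mv$radius_um[2])
      r_px <- r_um / px
      cr <- runif(1, r_px + 2, nr - r_px - 1)
      cc <- runif(1, r_px + 2, nc - r_px - 1)
      if (length(rows) == 0 ||
          all(sqrt((rows - cr)^2 + (cols - cc)^2) > (rads + r_px) / 1 + 3)) {
        rows <- c(rows, cr); cols <- c(cols, cc); rads <- c(rads, r_px)
      }
    }
    list(rows = rows, cols = cols, rads = rads,
         noise = if (mv$noise_sigma > 0) {
           array(rnorm(nr * nc * nt, 0, mv$noise_sigma), dim = c(nr, nc, nt))
         })
  })

  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  masks <- lapply(seq_len(mv$n_guvs), function(i) {
    (rr - placement$rows[i])^2 + (cc - placement$cols[i])^2 <=
      placement$rads[i]^2
  })

  release <- pmax(0, 1 - mv$k * times^mv$n)
  stack <- array(mv$background, dim = c(nr, nc, nt))
  for (t in seq_len(nt)) {
    fr <- stack[, , t]
    for (i in seq_len(mv$n_guvs)) {
      fr[masks[[i]]] <- mv$background + mv$i0 * release[t]
    }
    stack[, , t] <- fr
  }
  if (!is.null(placement$noise)) stack <- stack + placement$noise

  structure(
    list(stack = stack, times_s = times,
         truth = data.frame(guv = seq_len(mv$n_guvs),
                            row = placement$rows, col = placement$cols,
                            radius_um = placement$rads * px,
                            i0 = mv$i0, k = mv$k, n = mv$n),
         config = cfg),
    class = "guv_movie"
  )
}

#' Write a GUV movie as a multi-page TIFF plus truth CSV
#'
#' Pages are normalized to [0, 1] jointly (a single scale for the whole
#' stack) with the scale recorded in a JSON sidecar, as in
#' [write_field_tiff()]. The ground-truth table is written next to the
#' stack as `<path>.truth.csv`.
#'
#' @param movie A [make_guv_movie()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  st <- movie$stack
  lo <- min(st); hi <- max(st)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(st)[3]), function(t) (st[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = lo, scale = scale, frame_rate_hz = movie$config$movie$frame_rate_hz,
         pixel_size_um = movie$config$movie$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(movie$truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a GUV movie stack written by [write_movie_tiff()]
#'
#' @param path TIFF path.
#' @return A list with `stack` (3D array), `frame_rate_hz`, `pixel_size_um`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  st <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
  sidecar <- paste0(path, ".json")
  frame_rate <- 2; px <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    st <- st * meta$scale + meta$offset
    frame_rate <- meta$frame_rate_hz %||% 2
    px <- meta$pixel_size_um %||% 1
  }
  list(stack = st, frame_rate_hz = frame_rate, pixel_size_um = px)
}
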