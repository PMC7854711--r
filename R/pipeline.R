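# End-to-end pipeline orchestration and the run manifest.

config_hash <- function(config) {
  # canonical JSON -> md5; stable for identical configs
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 15,
                         null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a simulate / analyse pipeline and write a manifest
#'
#' Deterministically (given the config seed) executes a chain of stages and
#' writes every product plus a JSON run manifest (`run_manifest.json`)
#' listing the command, config hash, seed, inputs, outputs, tool version
#' and timestamp.
#'
#' Supported stages:
#' \describe{
#'   \item{`simulate-interferogram`}{pressure field + interferogram pair
#'     (TIFFs).}
#'   \item{`pressure-map`}{inverts the pair to a pressure map (TIFF) and a
#'     propagation-axis profile (CSV); requires `simulate-interferogram`.}
#'   \item{`simulate-waveform`}{hydrophone pulse (CSV).}
#'   \item{`waveform-metrics`}{metrics of the simulated pulse (JSON).}
#'   \item{`simulate-movie`}{GUV movie (multi-page TIFF + truth CSV).}
#'   \item{`track`}{detect + track + background-correct (tracks CSV).}
#'   \item{`fit`}{pooled Ritger-Peppas release fit (JSON).}
#' }
#'
#' @param config A [sim_config()] (or path to a YAML config).
#' @param stages Character vector of stage names, executed in order.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("simulate-movie", "track", "fit"),
                         out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config, seed = seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  known <- c("simulate-interferogram", "pressure-map", "simulate-waveform",
             "waveform-metrics", "simulate-movie", "track", "fit")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("usage error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- new.env(parent = emptyenv())

  for (stage in stages) {
    res <- tryCatch(
      switch(stage,
        "simulate-interferogram" = {
          state$field <- make_pressure_field(config)
          state$pair <- render_interferogram(state$field, config)
          p1 <- file.path(out_dir, "pressure_truth.tif")
          p2 <- file.path(out_dir, "pumped.tif")
          p3 <- file.path(out_dir, "reference.tif")
          write_field_tiff(state$field, p1)
          write_field_tiff(state$pair$pumped, p2)
          write_field_tiff(state$pair$reference, p3)
          c(p1, p2, p3)
        },
        "pressure-map" = {
          if (is.null(state$pair)) state$pair <- render_interferogram(cfg = config)
          state$map <- pressure_map(state$pair, config$eos)
          prof <- pressure_profile(state$map, axis = "rows")
          p1 <- file.path(out_dir, "pressure_map.tif")
          p2 <- file.path(out_dir, "pressure_profile.csv")
          write_field_tiff(state$map, p1)
          write_profile_csv(prof, p2)
          c(p1, p2)
        },
        "simulate-waveform" = {
          state$waveform <- make_waveform(config)
          p1 <- file.path(out_dir, "waveform.csv")
          write_waveform_csv(state$waveform, p1)
          p1
        },
        "waveform-metrics" = {
          if (is.null(state$waveform)) state$waveform <- make_waveform(config)
          m <- waveform_metrics(state$waveform)
          p1 <- file.path(out_dir, "waveform_metrics.json")
          jsonlite::write_json(
            c(list(schema = "pawkit/waveform_metrics/1"), unclass(m)),
            p1, auto_unbox = TRUE, digits = NA)
          p1
        },
        "simulate-movie" = {
          state$movie <- make_guv_movie(config)
          p1 <- file.path(out_dir, "movie.tif")
          write_movie_tiff(state$movie, p1)
          c(p1, paste0(p1, ".truth.csv"))
        },
        "track" = {
          if (is.null(state$movie)) state$movie <- make_guv_movie(config)
          mv <- config$movie
          tr <- track_guvs(state$movie$stack,
                           frame_times_s = state$movie$times_s,
                           min_radius_um = max(1, 0.5 * mv$radius_um[1]),
                           max_radius_um = 2 * mv$radius_um[2],
                           pixel_size_um = mv$pixel_size_um,
                           max_displacement_um = 5)
          roi <- guv_free_roi(state$movie, tr)
          state$tracks <- background_correct(tr, state$movie$stack, roi)
          p1 <- file.path(out_dir, "tracks.csv")
          write_tracks_csv(state$tracks, p1)
          p1
        },
        "fit" = {
          if (is.null(state$tracks)) {
            stop("stage 'fit' requires stage 'track' earlier in the chain")
          }
          curve <- release_curve(state$tracks, track_id = "pooled")
          fit <- fit_ritger_peppas(curve)
          p1 <- file.path(out_dir, "fit.json")
          write_release_fit_json(fit, p1)
          p1
        }
      ),
      error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    outputs <- c(outputs, res)
  }

  manifest <- list(
    schema = "pawkit/run_manifest/1",
    command = paste("run", paste(stages, collapse = " ")),
    config_hash = config_hash(config),
    seed = config$seed,
    input_paths = character(0),
    output_paths = outputs,
    tool_version = as.character(packageVersion("pawkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(out_dir, "run_manifest.json")
  manifest$output_paths <- c(outputs, mpath)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Find a GUV-free background rectangle
#'
#' Scans the four corners of the field of view for a square region that no
#' tracked GUV (circle of its equivalent radius, plus a 1 um guard) enters
#' in any frame, for use as the background ROI of [background_correct()].
#'
#' @param movie A [make_guv_movie()] result (or any list with `stack` and
#'   `config`).
#' @param tracks A `guv_tracks` data.frame.
#' @param size_px Side length of the square ROI in pixels.
#' @return `c(row_min, row_max, col_min, col_max)`.
#' @export
guv_free_roi <- function(movie, tracks, size_px = 12) {
  nr <- dim(movie$stack)[1]; nc <- dim(movie$stack)[2]
  px <- movie$config$movie$pixel_size_um
  corners <- list(c(1, size_px, 1, size_px),
                  c(1, size_px, nc - size_px + 1, nc),
                  c(nr - size_px + 1, nr, 1, size_px),
                  c(nr - size_px + 1, nr, nc - size_px + 1, nc))
  for (roi in corners) {
    cr <- pmin(pmax(tracks$row, roi[1]), roi[2])
    cc <- pmin(pmax(tracks$col, roi[3]), roi[4])
    d_px <- sqrt((tracks$row - cr)^2 + (tracks$col - cc)^2)
    if (all(d_px * px >= tracks$radius_um + 1)) return(roi)
  }
  stop("no GUV-free background region found in the corners of the field",
       call. = FALSE)
}
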