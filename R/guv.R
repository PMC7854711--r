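# GUV detection/tracking in fluorescence time-lapse stacks, background
# correction, Ritger-Peppas release fitting, and group statistics.
#
# Detection uses EBImage (Otsu threshold, connected-component labelling,
# erosion); tracking is greedy nearest-neighbour linking with a distance
# cap, adequate for gel-immobilised, essentially stationary GUVs.

# coerce a stack (3D array [row, col, frame] or list of matrices) to 3D array
as_stack <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  if (is.list(frames)) {
    dims <- lapply(frames, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
      stop("incompatible stack: frames differ in geometry", call. = FALSE)
    }
    return(array(unlist(frames), dim = c(dim(frames[[1]]), length(frames))))
  }
  if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1)))
  stop("'frames' must be a 3D array or a list of matrices", call. = FALSE)
}

#' Detect GUVs in a single fluorescence frame
#'
#' Global thresholding (Otsu by default) followed by connected-component
#' labelling; regions are filtered by equivalent radius
#' \eqn{r = s\sqrt{A/\pi}} (pixel size `s`, area `A`). The interior mean
#' intensity is computed over the region mask eroded by 1 px, to exclude
#' the rim.
#'
#' @param frame Numeric matrix or `scalar_field` of quantity `"intensity"`.
#' @param min_radius_um,max_radius_um Equivalent-radius bounds in um.
#' @param pixel_size_um Pixel size in um (used when `frame` is a matrix).
#' @param threshold Optional absolute intensity threshold overriding Otsu.
#' @return A list with `regions` (data.frame: `label`, `row`, `col`,
#'   `radius_um`, `intensity`) and `labels` (the label matrix). An empty
#'   `regions` data.frame means nothing was detected (not an error).
#' @export
detect_guvs <- function(frame, min_radius_um, max_radius_um,
                        pixel_size_um = 1, threshold = NULL) {
  if (inherits(frame, "scalar_field")) {
    pixel_size_um <- frame$pixel_size_um
    frame <- frame$grid
  }
  if (!is.matrix(frame) || length(frame) == 0) {
    stop("'frame' must be a non-empty matrix", call. = FALSE)
  }
  if (min_radius_um <= 0 || min_radius_um >= max_radius_um) {
    stop("invalid parameter: need 0 < min_radius_um < max_radius_um", call. = FALSE)
  }
  empty <- list(
    regions = data.frame(label = integer(), row = numeric(), col = numeric(),
                         radius_um = numeric(), intensity = numeric()),
    labels = matrix(0L, nrow(frame), ncol(frame))
  )
  rng <- range(frame)
  if (diff(rng) <= 0) return(empty)
  if (is.null(threshold)) {
    x01 <- (frame - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::as.Image(x01), range = c(0, 1))
    mask <- x01 > th01
  } else {
    mask <- frame > threshold
  }
  if (!any(mask)) return(empty)

  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(lab[lab > 0])
  radius <- pixel_size_um * sqrt(areas / pi)
  keep <- which(radius >= min_radius_um & radius <= max_radius_um)
  if (length(keep) == 0) return(empty)

  lab[!(lab %in% keep)] <- 0L
  eroded <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0

  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- ((idx - 1) %% nrow(frame)) + 1
  cc <- ((idx - 1) %/% nrow(frame)) + 1
  cen_r <- tapply(rr, l, mean)
  cen_c <- tapply(cc, l, mean)
  # interior mean over the eroded mask; fall back to the full region if
  # erosion empties a small region
  er <- eroded[idx]
  intensity <- vapply(names(cen_r), function(lb) {
    sel <- l == as.integer(lb)
    if (any(sel & er)) mean(frame[idx[sel & er]]) else mean(frame[idx[sel]])
  }, numeric(1))

  ord <- order(as.integer(names(cen_r)))
  list(
    regions = data.frame(
      label = as.integer(names(cen_r))[ord],
      row = as.numeric(cen_r)[ord],
      col = as.numeric(cen_c)[ord],
      radius_um = radius[as.integer(names(cen_r))[ord]],
      intensity = as.numeric(intensity)[ord]
    ),
    labels = lab
  )
}

#' Track GUVs through a time-lapse stack
#'
#' Detects GUVs in every frame ([detect_guvs()]) and links detections
#' frame-to-frame by greedy nearest-neighbour assignment subject to a
#' maximum displacement. Unmatched detections start new tracks; unmatched
#' tracks are terminated (never mislinked). Tracks shorter than
#' `min_track_length` frames are dropped.
#'
#' @param frames 3D array `[row, col, frame]` or list of matrices.
#' @param frame_times_s Optional frame times in s; defaults to
#'   `(0:(n-1)) / frame_rate_hz`.
#' @param frame_rate_hz Frame rate in Hz (default 2, the usual acquisition
#'   rate for GUV release movies).
#' @param min_radius_um,max_radius_um Radius bounds passed to [detect_guvs()].
#' @param pixel_size_um Pixel size in um.
#' @param max_displacement_um Linking distance cap in um.
#' @param min_track_length Minimum track length (frames) to keep.
#' @param threshold Optional absolute threshold passed to [detect_guvs()].
#' @return A data.frame of class `guv_tracks` with columns `track_id`,
#'   `frame`, `t_s`, `row`, `col`, `radius_um`, `I_raw` (interior mean
#'   intensity); attributes `pixel_size_um` and `n_frames`.
#' @export
track_guvs <- function(frames, frame_times_s = NULL, frame_rate_hz = 2,
                       min_radius_um = 3, max_radius_um = 50,
                       pixel_size_um = 1, max_displacement_um = 5,
                       min_track_length = 3, threshold = NULL) {
  stack <- as_stack(frames)
  nt <- dim(stack)[3]
  if (nt < 2) stop("tracking requires at least 2 frames", call. = FALSE)
  if (is.null(frame_times_s)) frame_times_s <- (seq_len(nt) - 1) / frame_rate_hz

  rows <- list()
  heads <- data.frame(track_id = integer(), row = numeric(), col = numeric())
  next_id <- 1L
  for (t in seq_len(nt)) {
    det <- detect_guvs(stack[, , t], min_radius_um, max_radius_um,
                       pixel_size_um, threshold)$regions
    assigned_track <- integer(0)
    assigned_det <- integer(0)
    if (nrow(det) > 0 && nrow(heads) > 0) {
      dmat <- outer(heads$row, det$row, "-")^2 + outer(heads$col, det$col, "-")^2
      dmat <- sqrt(dmat) * pixel_size_um
      # greedy: repeatedly take the globally closest admissible pair
      repeat {
        j <- which.min(dmat)
        if (length(j) == 0 || !is.finite(dmat[j]) ||
            dmat[j] > max_displacement_um) break
        ij <- arrayInd(j, dim(dmat))
        assigned_track <- c(assigned_track, ij[1])
        assigned_det <- c(assigned_det, ij[2])
        dmat[ij[1], ] <- Inf
        dmat[, ij[2]] <- Inf
      }
    }
    ids <- integer(nrow(det))
    if (length(assigned_det) > 0) {
      ids[assigned_det] <- heads$track_id[assigned_track]
    }
    new <- which(ids == 0L)
    if (length(new) > 0) {
      ids[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    if (nrow(det) > 0) {
      rows[[t]] <- data.frame(track_id = ids, frame = t, t_s = frame_times_s[t],
                              row = det$row, col = det$col,
                              radius_um = det$radius_um, I_raw = det$intensity)
    }
    heads <- if (nrow(det) > 0) {
      data.frame(track_id = ids, row = det$row, col = det$col)
    } else {
      heads[0, ]
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track_id = integer(), frame = integer(),
                                      t_s = numeric(), row = numeric(),
                                      col = numeric(), radius_um = numeric(),
                                      I_raw = numeric())
  len <- table(out$track_id)
  keep <- as.integer(names(len)[len >= min_track_length])
  out <- out[out$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("guv_tracks", "data.frame"),
            pixel_size_um = pixel_size_um, n_frames = nt)
}

#' Background-correct tracked GUV intensities
#'
#' Subtracts the per-frame mean intensity over a GUV-free rectangle from
#' each track's interior intensity. The rectangle must not intersect any
#' tracked GUV (circle of its equivalent radius) in any frame.
#'
#' @param tracks A `guv_tracks` data.frame from [track_guvs()].
#' @param frames The stack the tracks came from.
#' @param background_roi `c(row_min, row_max, col_min, col_max)` (1-based,
#'   inclusive) of a region containing no GUVs.
#' @return `tracks` with columns `I_bg` and `I_corr` added.
#' @export
background_correct <- function(tracks, frames, background_roi) {
  stack <- as_stack(frames)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  check_roi(background_roi, nr, nc)
  px <- attr(tracks, "pixel_size_um") %||% 1
  # circle/rectangle intersection: distance from centre to the rectangle
  cr <- pmin(pmax(tracks$row, background_roi[1]), background_roi[2])
  cc <- pmin(pmax(tracks$col, background_roi[3]), background_roi[4])
  d_px <- sqrt((tracks$row - cr)^2 + (tracks$col - cc)^2)
  if (any(d_px * px < tracks$radius_um)) {
    stop("contaminated-background: background_roi overlaps a tracked GUV",
         call. = FALSE)
  }
  bg <- apply(stack[background_roi[1]:background_roi[2],
                    background_roi[3]:background_roi[4], , drop = FALSE],
              3, mean)
  tracks$I_bg <- bg[tracks$frame]
  tracks$I_corr <- tracks$I_raw - tracks$I_bg
  tracks
}

#' Release curve of a single GUV track
#'
#' Fraction released at time t, defined as \eqn{1 - I_t / I_0} where
#' \eqn{I_t} is the background-corrected interior intensity and \eqn{I_0}
#' its value in the first frame (so the fraction at t = 0 is exactly 0).
#' Values are clipped to [0, 1]; the number of clipped points is recorded
#' in the `n_clipped` attribute.
#'
#' @param tracks A background-corrected `guv_tracks` data.frame.
#' @param track_id Which track to use; may be omitted when only one track
#'   is present. Use `track_id = "pooled"` to average the corrected
#'   intensities of all tracks frame-by-frame before forming the curve.
#' @return A data.frame of class `release_curve` with `time_s` and
#'   `fraction`, attributes `n_clipped` and `mode` (`"single"` or
#'   `"pooled"`).
#' @export
release_curve <- function(tracks, track_id = NULL) {
  if (is.null(tracks$I_corr)) {
    stop("tracks lack corrected intensities; run background_correct() first",
         call. = FALSE)
  }
  mode <- "single"
  if (identical(track_id, "pooled")) {
    t_s <- sort(unique(tracks$t_s))
    it <- tapply(tracks$I_corr, tracks$t_s, mean)
    d <- data.frame(t_s = t_s, I_corr = as.numeric(it[as.character(t_s)]))
    mode <- "pooled"
  } else {
    if (is.null(track_id)) {
      ids <- unique(tracks$track_id)
      if (length(ids) != 1) {
        stop("multiple tracks present; supply 'track_id'", call. = FALSE)
      }
      track_id <- ids
    }
    d <- tracks[tracks$track_id == track_id, c("t_s", "I_corr")]
    d <- d[order(d$t_s), ]
  }
  i0 <- d$I_corr[1]
  if (!is.finite(i0) || i0 <= 0) {
    stop("invalid baseline: initial corrected intensity must be positive",
         call. = FALSE)
  }
  frac <- 1 - d$I_corr / i0
  n_clipped <- sum(frac < 0 | frac > 1)
  frac <- pmin(pmax(frac, 0), 1)
  structure(
    data.frame(time_s = d$t_s - d$t_s[1], fraction = frac),
    class = c("release_curve", "data.frame"),
    n_clipped = n_clipped, mode = mode
  )
}

#' Fit the Ritger-Peppas release model
#'
#' Nonlinear least squares of the power law \eqn{M_t/M_\infty = k t^n} on
#' the untransformed (t, fraction) pairs, restricted to points with
#' 0 < fraction < `release_cap` and t > 0. The power law is only valid for
#' fractional release below 0.6, the default cap. Complete release at
#' infinite time is assumed (the released fraction is taken directly as
#' \eqn{M_t/M_\infty}; no plateau parameter is fitted). Starting values come
#' from a log-log regression.
#'
#' @param curve A [release_curve()] (or data.frame with `time_s` and
#'   `fraction`).
#' @param release_cap Upper validity bound on the fraction (default 0.6).
#' @return An object of class `release_fit`: list with `k`, `n`, `se_k`,
#'   `se_n`, `n_points_used`, `validity_mask` (logical over the curve's
#'   points), `residuals`, `mode`.
#' @export
fit_ritger_peppas <- function(curve, release_cap = 0.6) {
  t <- curve$time_s
  f <- curve$fraction
  mask <- is.finite(f) & is.finite(t) & t > 0 & f > 0 & f < release_cap
  if (sum(mask) < 3) {
    stop("insufficient-data: need at least 3 points with t > 0 and 0 < fraction < ",
         release_cap, call. = FALSE)
  }
  tt <- t[mask]; ff <- f[mask]
  start_fit <- lm(log(ff) ~ log(tt))
  start <- list(k = exp(coef(start_fit)[[1]]), n = coef(start_fit)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(ff ~ k * tt^n, start = start,
                      lower = c(k = 0, n = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) {
      stop("fit-failure: Ritger-Peppas fit did not converge (",
           conditionMessage(e), "); starting values were k=",
           signif(start$k, 4), ", n=", signif(start$n, 4), call. = FALSE)
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k = NA_real_, n = NA_real_))
  structure(
    list(k = est[["k"]], n = est[["n"]],
         se_k = se[["k"]], se_n = se[["n"]],
         n_points_used = sum(mask), validity_mask = mask,
         residuals = stats::residuals(fit),
         mode = attr(curve, "mode") %||% "single"),
    class = "release_fit"
  )
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> k = %.4g +/- %.2g s^-n, n = %.3f +/- %.3f (%d points, %s curve)\n",
              x$k, x$se_k, x$n, x$se_n, x$n_points_used, x$mode))
  invisible(x)
}

#' Two-tailed independent-samples t-test between groups
#'
#' Pooled-variance (classical Student) two-tailed t-test, reporting group
#' means and standard errors of the mean.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return An object of class `group_comparison`: list with `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `t_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient-data: each group needs at least 2 values", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = TRUE)
  structure(
    list(mean_a = mean(a), mean_b = mean(b),
         sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         n_a = length(a), n_b = length(b)),
    class = "group_comparison"
  )
}

#' Export GUV tracks as CSV
#'
#' Columns: `track_id`, `frame`, `t_s`, `row`, `col`, `radius_um`, `I_raw`,
#' and `I_bg`/`I_corr` when present.
#'
#' @param tracks A `guv_tracks` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Export a release fit as JSON
#'
#' @param fit A [fit_ritger_peppas()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_release_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(schema = "pawkit/release_fit/1",
         k = fit$k, n = fit$n, se_k = fit$se_k, se_n = fit$se_n,
         n_points_used = fit$n_points_used, mode = fit$mode,
         validity_mask = fit$validity_mask, residuals = fit$residuals),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
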