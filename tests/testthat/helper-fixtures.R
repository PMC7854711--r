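# Shared fixture builders. Everything is generated in code; no binary data.

# a frame with bright discs on a constant background
disc_frame <- function(nr = 64, nc = 64, rows = numeric(), cols = numeric(),
                       radii = numeric(), intensity = 100, background = 10) {
  fr <- matrix(background, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_along(rows)) {
    fr[(rr - rows[i])^2 + (cc - cols[i])^2 <= radii[i]^2] <- intensity
  }
  fr
}

# carrier fringes with an arbitrary additive phase map (matrix), no noise
fringe_image <- function(phase = NULL, nr = 128, nc = 128, carrier = 0.25,
                         i0 = 100, visibility = 0.8) {
  if (is.null(phase)) phase <- matrix(0, nr, nc)
  psi <- matrix(2 * pi * carrier * (0:(nc - 1)), nr, nc, byrow = TRUE)
  i0 * (1 + visibility * cos(psi + phase))
}

# a centred 2D Gaussian bump (ridge when sd_col = Inf)
gauss_bump <- function(nr, nc, amplitude, sd_row, sd_col = sd_row,
                       row0 = (nr + 1) / 2, col0 = (nc + 1) / 2) {
  r <- outer((seq_len(nr) - row0)^2 / (2 * sd_row^2),
             (seq_len(nc) - col0)^2 / (2 * sd_col^2), "+")
  amplitude * exp(-r)
}

# small GUV-movie config used across tests (64 x 64, 3 vesicles)
small_movie_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             movie = modifyList(list(shape = c(64L, 64L), n_guvs = 3L,
                                     radius_um = c(6, 10), duration_s = 900,
                                     frame_rate_hz = 0.5),
                                list(...)))
}

# track + background-correct a generated movie with standard settings
analyse_movie <- function(movie) {
  tr <- track_guvs(movie$stack, frame_times_s = movie$times_s,
                   min_radius_um = 3, max_radius_um = 20,
                   pixel_size_um = movie$config$movie$pixel_size_um,
                   max_displacement_um = 5)
  background_correct(tr, movie$stack, guv_free_roi(movie, tr))
}
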