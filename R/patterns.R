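#' Multi-level chessboard pattern
#'
#' Tiled pattern in which each square tile carries one of a set of values
#' (e.g. 12 light levels), assigned cyclically with a per-row offset so that
#' neighbouring tiles differ and every value covers an equal area when the
#' tile count is a multiple of the number of values.
#'
#' @param n_tiles `c(rows, cols)` of tiles.
#' @param tile_px tile edge in pixels.
#' @param values vector of values (light levels or speeds), one per level.
#' @return list with `pattern` (numeric matrix) and `labels` (integer matrix
#'   of level indices into `values`).
#' @export
pattern_chessboard <- function(n_tiles = c(6, 6), tile_px = 20,
                               values = seq(0, 220, length.out = 12)) {
  nv <- length(values)
  idx <- matrix(0L, n_tiles[1], n_tiles[2])
  for (i in seq_len(n_tiles[1])) {
    for (j in seq_len(n_tiles[2])) {
      # cycle with a half-cycle row offset: neighbouring tiles differ and,
      # when cols * rows is a multiple of the level count (e.g. 6 x 6 tiles
      # with 12 levels), every level covers the same area
      idx[i, j] <- 1L + ((j - 1L) + (i - 1L) * (nv %/% 2L)) %% nv
    }
  }
  labels <- idx[rep(seq_len(n_tiles[1]), each = tile_px),
                rep(seq_len(n_tiles[2]), each = tile_px)]
  list(pattern = matrix(values[labels], nrow(labels), ncol(labels)),
       labels = labels)
}

#' Intensity levels evenly spaced in inverse speed
#'
#' Chooses `n` light intensities whose mean speeds, through the hyperbolic
#' response, have evenly spaced inverse values between `1/v(I_max)` and
#' `1/v(0)`. In the density-vs-inverse-speed representation this gives the
#' level points uniform leverage, so the linear fit and its intercept are
#' well conditioned (a uniformly spaced intensity ladder crams all the fast
#' levels into a sliver of the 1/v axis because the response saturates).
#'
#' @param resp an [intensity_response()].
#' @param n number of levels.
#' @param I_max brightest level (default 255).
#' @return numeric vector of `n` intensities, dimmest first.
#' @export
inverse_speed_levels <- function(resp, n = 12, I_max = 255) {
  v_hi <- mean_speed(I_max, resp)
  inv <- seq(1 / resp$v_dark, 1 / v_hi, length.out = n)
  v <- 1 / inv
  I <- resp$I_half * (v - resp$v_dark) / (resp$v_sat - v)
  pmin(pmax(I, 0), I_max)
}

#' Two-level stripe pattern
#'
#' Vertical stripes alternating between two values, equal areas.
#'
#' @param dim `c(ny, nx)` pixels; `nx` must be a multiple of `period_px`.
#' @param period_px full stripe period in pixels (half low, half high).
#' @param values `c(low, high)`.
#' @return list with `pattern` and integer `labels` (1 = low, 2 = high).
#' @export
pattern_stripes <- function(dim = c(64, 128), period_px = 64,
                            values = c(0, 255)) {
  if (dim[2] %% period_px != 0 || period_px %% 2 != 0) {
    stop("nx must be a multiple of period_px, and period_px even")
  }
  phase <- ((seq_len(dim[2]) - 1) %% period_px) < period_px / 2
  lab <- matrix(ifelse(rep(phase, each = dim[1]), 1L, 2L), dim[1], dim[2])
  list(pattern = matrix(values[lab], dim[1], dim[2]), labels = lab)
}

#' Sinusoidal stripe pattern
#'
#' `mean * (1 + contrast * cos(2 pi x / period))` along x — a single spatial
#' frequency, convenient because it is an eigenfunction of the memory-blur
#' convolution.
#'
#' @param dim `c(ny, nx)` pixels.
#' @param period_px period in pixels.
#' @param mean_value mean level.
#' @param contrast relative modulation amplitude.
#' @export
pattern_sine <- function(dim = c(64, 256), period_px = 64,
                         mean_value = 5, contrast = 0.1) {
  x <- seq_len(dim[2]) - 1
  row <- mean_value * (1 + contrast * cos(2 * pi * x / period_px))
  matrix(rep(row, each = dim[1]), dim[1], dim[2])
}
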