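#' Rendering configuration for synthetic microscopy frames
#'
#' Parameters of the microscope-like renderer: each agent is splatted as a
#' Gaussian point-spread function, a stray background is added, the frame
#' is multiplied by a smooth illumination envelope, and shot/read noise is
#' applied. This is a synthetic stand-in for dark-field (density) and
#' bright-field (DDM) imaging of a bacterial layer.
#'
#' @param psf_sigma PSF standard deviation (µm).
#' @param counts_per_agent integrated signal per agent (counts).
#' @param stray_background additive background level (counts/pixel).
#' @param envelope `NULL` for flat illumination, or a matrix of relative
#'   gain (same grid as the rendered frames).
#' @param poisson if `TRUE` apply Poisson shot noise to the
#'   (background + signal) counts.
#' @param gaussian_sd additive Gaussian read-noise s.d. (counts), 0 for
#'   none.
#' @export
render_config <- function(psf_sigma = 2, counts_per_agent = 30,
                          stray_background = 5, envelope = NULL,
                          poisson = TRUE, gaussian_sd = 0) {
  stopifnot(psf_sigma > 0, counts_per_agent > 0, stray_background >= 0,
            gaussian_sd >= 0)
  if (!is.null(envelope)) {
    envelope <- as.matrix(envelope)
    if (any(envelope <= 0)) stop("illumination envelope must be positive")
  }
  structure(list(psf_sigma = psf_sigma,
                 counts_per_agent = counts_per_agent,
                 stray_background = stray_background, envelope = envelope,
                 poisson = poisson, gaussian_sd = gaussian_sd),
            class = "render_config")
}

# periodic Gaussian smoothing of a matrix via FFT (unit-mass kernel)
gaussian_filter <- function(m, sigma_um, pixel_size) {
  if (sigma_um <= 0) return(m)
  fft_filter(m, pixel_size, function(q) exp(-q^2 * sigma_um^2 / 2))
}

# deposit unit masses on the pixel grid with bilinear (cloud-in-cell)
# weighting so that sub-pixel motion shifts the image phase continuously;
# nearest-pixel binning would quantize positions to the 2 um grid and
# distort the measured intermediate scattering function at q ~ 1/pixel
deposit_cic <- function(positions, grid_dim, pixel_size) {
  ny <- grid_dim[1]; nx <- grid_dim[2]
  gx <- positions[, 1] / pixel_size - 0.5
  gy <- positions[, 2] / pixel_size - 0.5
  i0x <- floor(gx); i0y <- floor(gy)
  wx <- gx - i0x; wy <- gy - i0y
  jx0 <- (as.integer(i0x) %% nx + nx) %% nx
  jx1 <- (jx0 + 1L) %% nx
  jy0 <- (as.integer(i0y) %% ny + ny) %% ny
  jy1 <- (jy0 + 1L) %% ny
  idx <- c(1L + jy0 + ny * jx0, 1L + jy0 + ny * jx1,
           1L + jy1 + ny * jx0, 1L + jy1 + ny * jx1)
  w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  acc <- numeric(ny * nx)
  tap <- tapply(w, idx, sum)
  acc[as.integer(names(tap))] <- tap
  matrix(acc, ny, nx)
}

#' Render a dark-field frame from agent positions
#'
#' Dark-field signal is proportional to the local cell count: positions are
#' binned on the pixel grid, convolved with the Gaussian PSF, scaled to
#' counts, offset by the stray background, multiplied by the illumination
#' envelope, and corrupted with noise.
#'
#' @param positions `n x 2` matrix of positions (µm).
#' @param grid_dim `c(ny, nx)` pixels.
#' @param pixel_size pixel edge (µm).
#' @param cfg a [render_config()].
#' @return numeric matrix of pixel intensities (counts).
#' @export
render_darkfield <- function(positions, grid_dim, pixel_size, cfg) {
  stopifnot(inherits(cfg, "render_config"))
  ny <- grid_dim[1]; nx <- grid_dim[2]
  counts <- deposit_cic(positions, grid_dim, pixel_size)
  img <- gaussian_filter(counts, cfg$psf_sigma, pixel_size) *
    cfg$counts_per_agent + cfg$stray_background
  if (!is.null(cfg$envelope)) img <- img * cfg$envelope
  if (cfg$poisson) {
    img <- matrix(rpois(length(img), pmax(img, 0)), ny, nx)
  }
  if (cfg$gaussian_sd > 0) {
    img <- img + rnorm(length(img), sd = cfg$gaussian_sd)
  }
  img
}

#' Render a bright-field frame from agent positions
#'
#' Bright-field cells appear as signed contrast on a gray background (the
#' frame Fourier transform then carries the density fluctuations needed by
#' DDM): `frame = background + contrast * PSF-smoothed counts + noise`.
#'
#' @inheritParams render_darkfield
#' @param background gray level.
#' @param contrast signal per agent (negative for dark cells on gray).
#' @param noise_sd Gaussian noise s.d.
#' @export
render_brightfield <- function(positions, grid_dim, pixel_size,
                               psf_sigma = 1.5, background = 100,
                               contrast = -20, noise_sd = 1) {
  counts <- deposit_cic(positions, grid_dim, pixel_size)
  img <- background + contrast * gaussian_filter(counts, psf_sigma,
                                                 pixel_size)
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  img
}

#' Render an image stack from position snapshots
#'
#' @param snapshots list of `n x 2` position matrices (e.g. from
#'   [run_to_stationary()]).
#' @param grid_dim `c(ny, nx)` pixels.
#' @param pixel_size pixel edge (µm).
#' @param frame_interval time between snapshots (s).
#' @param mode `"brightfield"` or `"darkfield"`.
#' @param ... passed to the frame renderer.
#' @return an [image_stack()].
#' @export
render_stack <- function(snapshots, grid_dim, pixel_size, frame_interval,
                         mode = c("brightfield", "darkfield"), ...) {
  mode <- match.arg(mode)
  nt <- length(snapshots)
  fr <- array(0, c(grid_dim[1], grid_dim[2], nt))
  for (k in seq_len(nt)) {
    fr[, , k] <- if (mode == "brightfield") {
      render_brightfield(snapshots[[k]], grid_dim, pixel_size, ...)
    } else {
      render_darkfield(snapshots[[k]], grid_dim, pixel_size, ...)
    }
  }
  image_stack(fr, pixel_size, frame_interval)
}

#' Flat-field reference from uniform-sample frames
#'
#' Average of frames acquired while the sample is still homogeneous,
#' smoothed with a wide Gaussian (default s.d. 100 µm) so that only the
#' slowly varying illumination envelope remains. Dividing later frames by
#' this reference removes the envelope.
#'
#' @param frames array `ny x nx x T` (T >= 2) or list of matrices.
#' @param pixel_size pixel edge (µm).
#' @param sigma_um smoothing s.d. (µm).
#' @return matrix `rho0`, strictly positive.
#' @export
flatfield_reference <- function(frames, pixel_size, sigma_um = 100) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    c(dim(frames[[1]]), length(frames)))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2)
  avg <- apply(frames, c(1, 2), mean)
  rho0 <- gaussian_filter(avg, sigma_um, pixel_size)
  if (any(rho0 <= 0)) stop("flat-field reference has non-positive values")
  rho0
}

#' Normalized density from a raw density frame and a flat-field reference
#'
#' `rho* = rho / rho0` pixelwise; on a homogeneous sample this is ~1
#' everywhere, so spatial structure in `rho*` is density, not illumination.
#'
#' @param raw raw density frame (typically a 50-frame average).
#' @param rho0 flat-field reference from [flatfield_reference()].
#' @param pixel_size pixel edge (µm), stored on the result.
#' @return a `density_map` matrix.
#' @export
normalize_density <- function(raw, rho0, pixel_size = 2) {
  raw <- as.matrix(raw); rho0 <- as.matrix(rho0)
  if (!all(dim(raw) == dim(rho0))) stop("raw and rho0 shapes differ")
  if (any(rho0 <= 0)) stop("rho0 must be strictly positive")
  structure(raw / rho0, pixel_size = pixel_size,
            class = c("density_map", "matrix", "array"))
}

#' Flat background subtraction
#'
#' Subtracts the 5th percentile of the intensity histogram (linear
#' interpolation between order statistics) and clips at zero.
#'
#' @param frame numeric matrix.
#' @param prob percentile used as the background level (default 0.05).
#' @export
background_subtract <- function(frame, prob = 0.05) {
  stopifnot(length(frame) > 0)
  bg <- quantile(frame, prob, names = FALSE)
  pmax(frame - bg, 0)
}

#' Rescale a density map so its 10th/90th percentiles match a target's
#'
#' Affine map
#' `rho_s = (t90 - t10)/(r90 - r10) * (rho* - r10) + t10`
#' bringing the 10th and 90th percentile of the measured histogram onto the
#' target's, so that shape — not overall contrast or offset — is compared.
#'
#' @param rho measured normalized density map.
#' @param target target density map (same shape).
#' @param probs the two matched percentiles, default `c(0.1, 0.9)`.
#' @return rescaled map, same class/attributes as `rho`.
#' @export
percentile_rescale <- function(rho, target, probs = c(0.1, 0.9)) {
  r <- quantile(rho, probs, names = FALSE)
  tg <- quantile(target, probs, names = FALSE)
  if (abs(r[2] - r[1]) < 1e-12 * max(abs(r), 1)) {
    stop("degenerate histogram: matched percentiles coincide")
  }
  out <- (tg[2] - tg[1]) / (r[2] - r[1]) * (rho - r[1]) + tg[1]
  attributes(out) <- attributes(rho)
  out
}

#' Distance between a rescaled density map and a target
#'
#' Root of the sum of squared pixel differences,
#' `dist = sqrt(sum((rho_s - target)^2))`. Apply [percentile_rescale()]
#' first; divide by the value at iteration 0 to report the normalized
#' distance.
#'
#' @param rho_s rescaled density map.
#' @param target target map, same shape.
#' @export
map_distance <- function(rho_s, target) {
  if (!all(dim(as.matrix(rho_s)) == dim(as.matrix(target)))) {
    stop("maps must share one shape")
  }
  sqrt(sum((as.matrix(rho_s) - as.matrix(target))^2))
}

#' @importFrom stats rpois
NULL
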