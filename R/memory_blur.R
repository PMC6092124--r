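#' Speed map on a pixel grid
#'
#' Wraps a matrix of local mean swimming speeds (µm/s) with its pixel size.
#' Maps are indexed `[row = y, col = x]`. The `blurred` flag records whether
#' the map is the light-imposed (instantaneous-response) map `V` or the
#' effective map `w` after memory blur.
#'
#' @param grid numeric matrix of speeds, all finite and `> 0`.
#' @param pixel_size pixel edge in µm (default 2, the projector pixel at the
#'   sample plane).
#' @param blurred logical provenance flag.
#' @export
speed_map <- function(grid, pixel_size = 2, blurred = FALSE) {
  grid <- as.matrix(grid)
  if (!all(is.finite(grid)) || any(grid <= 0)) {
    stop("speed map must be finite and strictly positive")
  }
  structure(grid, pixel_size = pixel_size, blurred = blurred,
            class = c("speed_map", "matrix", "array"))
}

#' @export
print.speed_map <- function(x, ...) {
  cat(sprintf("Speed map %d x %d px (%.3g um/px), %s, range %.3g-%.3g um/s\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              if (isTRUE(attr(x, "blurred"))) "blurred (w)" else
                "instantaneous (V)",
              min(x), max(x)))
  invisible(x)
}

#' Convert a light pattern to the imposed speed map V
#'
#' @param light matrix of light intensities (e.g. 8-bit levels 0-255).
#' @param resp an [intensity_response()].
#' @param pixel_size pixel edge in µm.
#' @export
light_to_speed_map <- function(light, resp, pixel_size = 2) {
  speed_map(mean_speed(as.matrix(light), resp), pixel_size = pixel_size)
}

#' Fourier transform of the memory-blur kernel
#'
#' The effective speed map seen by swimmers with exponential speed memory is
#' the imposed map convolved with a kernel whose real-space form is not
#' analytic but whose 2-D Fourier transform is
#' \deqn{\tilde\gamma(q) = \frac{k}{q} \arctan\left(\frac{q}{k}\right),}
#' where `k^{-1} = v_bar * tau_m` is the memory decay length (mean speed
#' times relaxation time) and `q` the wave-vector modulus. It equals 1 at
#' `q = 0` (unit mass) and decreases monotonically to 0.
#'
#' @param q wave-vector modulus (µm^-1), vectorised, `>= 0`.
#' @param k inverse decay length (µm^-1), `> 0`.
#' @export
kernel_ft <- function(q, k) {
  stopifnot(is.numeric(q), is.numeric(k))
  if (any(q < 0)) stop("q must be non-negative")
  if (any(k <= 0)) stop("k must be positive")
  x <- q / k
  out <- ifelse(x < 1e-4, 1 - x^2 / 3, atan(x) / pmax(x, .Machine$double.xmin))
  out
}

#' Three-dimensional memory-blur kernel in real space
#'
#' Radial density `(k / 4 pi r^2) exp(-k r)`: the probability density of
#' finding, a memory time in the past, a swimmer that is now at the origin,
#' for straight runs with exponentially distributed look-back time. Unit
#' mass over 3-D space. Its z-projection gives the 2-D kernel used by
#' [blur_speed_map()], analytic only in Fourier space ([kernel_ft()]).
#'
#' @param r distance (µm), `> 0` (singular at the origin).
#' @param k inverse decay length (µm^-1), `> 0`.
#' @return kernel density in µm^-3.
#' @export
kernel_3d <- function(r, k) {
  stopifnot(k > 0)
  if (any(r <= 0)) stop("r must be > 0 (kernel is singular at the origin)")
  k / (4 * pi * r^2) * exp(-k * r)
}

# wave-vector modulus grid matching stats::fft layout for an ny x nx matrix
fft_q_grid <- function(ny, nx, pixel_size) {
  fq <- function(n) {
    f <- c(0:floor((n - 1) / 2), -(n - floor((n - 1) / 2) - 1):-1)
    2 * pi * f / (n * pixel_size)
  }
  qy <- fq(ny)
  qx <- fq(nx)
  sqrt(outer(qy^2, qx^2, "+"))
}

# FFT convolution of a matrix with a kernel given by its Fourier transform
# ft_fun(qmag); periodic or mirror-padded boundaries
fft_filter <- function(m, pixel_size, ft_fun, pad = c("periodic", "mirror")) {
  pad <- match.arg(pad)
  if (pad == "mirror") {
    m2 <- rbind(m, m[nrow(m):1, , drop = FALSE])
    m2 <- cbind(m2, m2[, ncol(m2):1, drop = FALSE])
    res <- fft_filter(m2, pixel_size, ft_fun, pad = "periodic")
    return(res[seq_len(nrow(m)), seq_len(ncol(m)), drop = FALSE])
  }
  q <- fft_q_grid(nrow(m), ncol(m), pixel_size)
  Re(fft(fft(m) * ft_fun(q), inverse = TRUE)) / length(m)
}

#' Memory-blurred ("actual") speed map
#'
#' Computes the effective speed map experienced by swimmers with a
#' two-timescale light response,
#' \deqn{w = \beta V + (1-\beta)\, \gamma * V,}
#' where the convolution (evaluated in Fourier space with [kernel_ft()])
#' spreads the imposed map `V` over the memory decay length
#' `k^{-1} = v_bar tau_m`. A uniform map is unchanged; `beta = 1` is the
#' memoryless limit. Valid for weak speed modulations about the mean.
#'
#' @param V a [speed_map()] (instantaneous-response map).
#' @param mem a [memory_params()].
#' @param k optional inverse decay length (µm^-1); by default
#'   `1 / (mean(V) * tau_m)`.
#' @param pad boundary handling for the FFT convolution, `"periodic"`
#'   (default) or `"mirror"`.
#' @return a [speed_map()] with `blurred = TRUE`.
#' @export
blur_speed_map <- function(V, mem, k = NULL, pad = c("periodic", "mirror")) {
  stopifnot(inherits(V, "speed_map"), inherits(mem, "memory_params"))
  pad <- match.arg(pad)
  px <- attr(V, "pixel_size")
  if (is.null(k)) k <- 1 / (mean(V) * mem$tau_m)
  stopifnot(k > 0)
  conv <- fft_filter(unclass(V), px, function(q) kernel_ft(q, k), pad = pad)
  w <- mem$beta * unclass(V) + (1 - mem$beta) * conv
  speed_map(w, pixel_size = px, blurred = TRUE)
}

#' Predicted stationary normalized density from a speed map
#'
#' For an isotropic self-propelled particle the stationary density is
#' proportional to the inverse local (effective) speed. With only a fraction
#' `alpha` of the imaged objects motile and light-responsive, the normalized
#' stationary density is
#' \deqn{\rho^*(x,y) = \alpha\left(\frac{w^{-1}(x,y)}{\overline{w^{-1}}}
#'   - 1\right) + 1,}
#' which has spatial mean exactly 1; the non-responsive fraction contributes
#' the uniform baseline `1 - alpha`.
#'
#' @param w a [speed_map()] — use the blurred map from [blur_speed_map()]
#'   when memory matters, or the instantaneous map for an ideal response.
#' @param alpha motile / light-responsive fraction in `[0, 1]`.
#' @return matrix of normalized density with attributes `pixel_size` and
#'   `alpha`, class `density_map`.
#' @export
predict_density <- function(w, alpha = 0.5) {
  stopifnot(inherits(w, "speed_map"), alpha >= 0, alpha <= 1)
  winv <- 1 / unclass(w)
  rho <- alpha * (winv / mean(winv) - 1) + 1
  structure(rho, pixel_size = attr(w, "pixel_size"), alpha = alpha,
            class = c("density_map", "matrix", "array"))
}

#' Level-averaged density versus inverse speed
#'
#' Averages a normalized density map over the pixel sets sharing the same
#' illumination level and pairs each level mean with the inverse of the
#' level's imposed mean speed — the representation in which the
#' density-speed law `rho ~ 1/v` is a straight line whose intercept at
#' `1/v = 0` is the non-responsive baseline `1 - alpha`.
#'
#' @param rho normalized density matrix (e.g. from [predict_density()] or
#'   [density_histogram()]).
#' @param V the imposed [speed_map()] (instantaneous response).
#' @param levels integer/factor matrix of level labels, congruent with `rho`.
#' @return data.frame with one row per level: `level`, `speed_um_per_s`,
#'   `inv_speed_s_per_um`, `mean_density`, `sd_density`, `n_pixels`.
#' @export
density_vs_inverse_speed <- function(rho, V, levels) {
  rho <- as.matrix(rho); Vm <- as.matrix(unclass(V))
  lev <- as.vector(as.matrix(levels))
  if (!all(dim(rho) == dim(Vm)) || length(lev) != length(rho)) {
    stop("rho, V and levels must share one grid")
  }
  ul <- sort(unique(lev))
  if (length(ul) < 1) stop("no levels found")
  out <- do.call(rbind, lapply(ul, function(l) {
    sel <- lev == l
    if (!any(sel)) return(NULL)
    data.frame(level = l,
               speed_um_per_s = mean(Vm[sel]),
               mean_density = mean(rho[sel]),
               sd_density = sd(rho[sel]),
               n_pixels = sum(sel))
  }))
  out$inv_speed_s_per_um <- 1 / out$speed_um_per_s
  out[, c("level", "speed_um_per_s", "inv_speed_s_per_um",
          "mean_density", "sd_density", "n_pixels")]
}

#' Linear fit of the high-speed branch of density vs inverse speed
#'
#' Fits `mean_density ~ inv_speed` over the fastest levels (where the local
#' density-speed law holds best; slow levels bend below the line when memory
#' blur matters). The intercept estimates the non-responsive baseline
#' `1 - alpha`.
#'
#' @param tbl output of [density_vs_inverse_speed()].
#' @param top_fraction fraction of levels (by speed, fastest first) used in
#'   the fit; default 0.5. At least 2 levels are required.
#' @return list with `intercept`, `slope`, the `lm` fit, and the subset used.
#' @export
fit_density_line <- function(tbl, top_fraction = 0.5) {
  n_use <- max(2, ceiling(nrow(tbl) * top_fraction))
  if (nrow(tbl) < 2) stop("need at least 2 levels for a line fit")
  ord <- order(tbl$speed_um_per_s, decreasing = TRUE)
  sub <- tbl[ord[seq_len(min(n_use, nrow(tbl)))], ]
  fit <- lm(mean_density ~ inv_speed_s_per_um, data = sub)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       fit = fit, used = sub)
}
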