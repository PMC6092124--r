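#' Image stack container
#'
#' @param frames numeric array `ny x nx x T` of frames at constant interval.
#' @param pixel_size pixel edge (µm).
#' @param frame_interval time between frames (s).
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            all(is.finite(frames)), pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px, %g um/px, %g s/frame\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Image structure function (differential dynamic microscopy)
#'
#' Computes
#' \deqn{g(q, t) = \langle |M(\mathbf{q}, t') - M(\mathbf{q}, t' + t)|^2
#'   \rangle,}
#' the mean squared modulus of the difference between the spatial Fourier
#' transforms of frames separated by lag `t`, averaged over start times
#' (time-translation invariance) and azimuthally over shells of equal
#' `|q|` (isotropy). `q = 0` and wave vectors beyond the Nyquist modulus of
#' the shorter image side are excluded.
#'
#' @param stack an [image_stack()].
#' @param lags lag times (s); rounded to whole frame intervals, must stay
#'   below the stack duration.
#' @param max_pairs maximum number of start times averaged per lag.
#' @return object of class `ddm_curves`: list with `q` (shell-mean moduli,
#'   µm^-1), `lags` (s), matrix `g` (`length(q) x length(lags)`), shell
#'   pixel counts `n_px`, and the stack geometry.
#' @export
image_structure_function <- function(stack, lags = NULL, max_pairs = 50) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  ny <- dim(fr)[1]; nx <- dim(fr)[2]; nt <- dim(fr)[3]
  dtf <- stack$frame_interval
  if (is.null(lags)) {
    li <- unique(round(exp(seq(0, log(nt - 1), length.out = 24))))
  } else {
    li <- unique(pmax(1, round(lags / dtf)))
  }
  if (any(li > nt - 1)) stop("lag exceeds stack duration")
  # FFT of every frame, stored as complex matrices
  F <- vector("list", nt)
  for (k in seq_len(nt)) F[[k]] <- fft(fr[, , k])
  # azimuthal shell assignment
  qmag <- fft_q_grid(ny, nx, stack$pixel_size)
  dq <- 2 * pi / (min(ny, nx) * stack$pixel_size)
  q_nyq <- pi / stack$pixel_size
  shell <- as.integer(round(qmag / dq))
  ok <- shell >= 1L & qmag <= q_nyq
  shell_f <- factor(shell[ok])
  n_px <- as.integer(table(shell_f))
  q_mean <- as.numeric(tapply(qmag[ok], shell_f, mean))
  g <- matrix(0, length(q_mean), length(li))
  for (j in seq_along(li)) {
    L <- li[j]
    starts <- unique(round(seq(1, nt - L, length.out = min(max_pairs, nt - L))))
    acc <- numeric(sum(ok))
    for (s in starts) {
      d <- F[[s + L]] - F[[s]]
      acc <- acc + (Re(d)^2 + Im(d)^2)[ok]
    }
    acc <- acc / length(starts)
    g[, j] <- as.numeric(tapply(acc, shell_f, mean))
  }
  structure(list(q = q_mean, lags = li * dtf, g = g, n_px = n_px,
                 pixel_size = stack$pixel_size, dim = c(ny, nx)),
            class = "ddm_curves")
}

#' Schultz speed distribution density
#'
#' \deqn{P(v') = \frac{1}{v'}\left(\frac{Z+1}{v} v'\right)^{Z+1}
#'   \frac{e^{-(Z+1) v'/v}}{\Gamma(Z+1)},}
#' the gamma distribution with shape `Z + 1` and rate `(Z + 1)/v`; mean `v`,
#' variance `v^2/(Z + 1)`. Evaluated in log space to stay finite for large
#' `Z`.
#'
#' @param v_prime speeds at which to evaluate (µm/s), `> 0`.
#' @param v mean speed (µm/s), `> 0`.
#' @param Z shape parameter, `> -1`.
#' @export
schultz_pdf <- function(v_prime, v, Z) {
  stopifnot(v > 0, Z > -1)
  out <- numeric(length(v_prime))
  pos <- v_prime > 0
  lp <- (Z + 1) * log((Z + 1) / v) + Z * log(v_prime[pos]) -
    (Z + 1) * v_prime[pos] / v - lgamma(Z + 1)
  out[pos] <- exp(lp)
  out
}

# Schultz-averaged cosine: E[cos(a u)] for u ~ Schultz(mean 1, shape Z),
# i.e. gamma(shape Z+1, rate Z+1); closed form via the characteristic
# function of the gamma distribution
schultz_cos <- function(a, Z) {
  th <- a / (Z + 1)
  (1 + th^2)^(-(Z + 1) / 2) * cos((Z + 1) * atan(th))
}

# Schultz-averaged 2-D orientation factor: E[J0(x u)] with
# J0(y) = (2/pi) int_0^{pi/2} cos(y sin(phi)) dphi, angle integral by
# Gauss-Legendre (inner speed average closed form)
schultz_j0 <- function(x, Z, n_nodes = 48) {
  gl <- legendre_nodes(n_nodes)
  phi <- pi / 4 * (gl$x + 1)          # map [-1,1] -> [0, pi/2]
  w <- gl$w * pi / 4
  out <- numeric(length(x))
  for (i in seq_along(phi)) {
    out <- out + w[i] * schultz_cos(x * sin(phi[i]), Z)
  }
  2 / pi * out
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached
legendre_nodes <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- res
    res
  }
})

# Schultz-averaged sinc: int P(v') sin(q v' t)/(q v' t) dv'
# closed form; x = q * v * t
schultz_sinc <- function(x, Z) {
  th <- x / (Z + 1)
  small <- abs(x) < 1e-4
  out <- numeric(length(x))
  if (any(small)) {
    # <sinc> ~ 1 - <v'^2> (qt)^2/6 with <v'^2> = v^2 (Z+2)/(Z+1)
    out[small] <- 1 - (Z + 2) / (Z + 1) * x[small]^2 / 6
  }
  if (any(!small)) {
    xs <- x[!small]; ths <- th[!small]
    if (Z > 1e-6) {
      out[!small] <- (Z + 1) / (Z * xs) * sin(Z * atan(ths)) *
        (1 + ths^2)^(-Z / 2)
    } else {
      out[!small] <- atan(xs) / xs   # Z -> 0 (exponential) limit
    }
  }
  out
}

#' Intermediate scattering function of independent smooth swimmers
#'
#' ISF model for a mixture of Brownian diffusers (fraction `1 - alpha`) and
#' straight swimmers with Schultz-distributed speeds (fraction `alpha`),
#' all with diffusivity `D`:
#' \deqn{F(q,t) = (1-\alpha) e^{-q^2 D t} + \alpha e^{-q^2 D t}
#'   \int_0^\infty P(v')\, \mathrm{sinc}(q v' t)\, dv'}
#' with `sinc(x) = sin(x)/x` (unnormalized) and `P` the Schultz density
#' with mean `v` and shape `Z = (v/sigma)^2 - 1`. The Schultz-weighted sinc
#' integral has a closed form used by default; `method = "quadrature"`
#' evaluates it by adaptive quadrature instead (slow, used for validation).
#'
#' The `sinc` orientation factor is the isotropic average over 3-D swimming
#' directions — the thick-sample geometry in which a 3-D suspension is
#' imaged in projection. For strictly 2-D motion (as in the in-plane agent
#' simulation) the isotropic average is the Bessel function `J0(q v' t)`;
#' choose it with `geometry = "2d"`.
#'
#' @param q wave-vector modulus (µm^-1).
#' @param t lag time(s) (s), vectorised.
#' @param v mean swimming speed (µm/s).
#' @param sigma speed standard deviation (µm/s).
#' @param alpha motile fraction in `[0, 1]`.
#' @param D diffusivity (µm²/s).
#' @param geometry orientation average: `"3d"` (sinc, default) or `"2d"`
#'   (J0).
#' @param method `"closed"` (default) or `"quadrature"`.
#' @export
isf_smooth_swimmer <- function(q, t, v, sigma, alpha, D,
                               geometry = c("3d", "2d"),
                               method = c("closed", "quadrature")) {
  method <- match.arg(method)
  geometry <- match.arg(geometry)
  stopifnot(q > 0, v > 0, sigma >= 0, alpha >= 0, alpha <= 1, D >= 0)
  Z <- if (sigma > 0) (v / sigma)^2 - 1 else Inf
  if (!is.finite(Z) || Z > 1e8) Z <- 1e8
  if (Z <= -1) stop("sigma too large: Schultz shape Z must exceed -1")
  env <- exp(-q^2 * D * t)
  if (geometry == "2d") {
    sw <- schultz_j0(q * v * t, Z)
  } else if (method == "closed") {
    sw <- schultz_sinc(q * v * t, Z)
  } else {
    sw <- vapply(t, function(ti) {
      if (q * v * ti == 0) return(1)
      integrate(function(vp) schultz_pdf(vp, v, Z) *
                  sin(q * vp * ti) / (q * vp * ti),
                0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
    }, numeric(1))
  }
  env * ((1 - alpha) + alpha * sw)
}

#' Fit the swimmer ISF model to DDM curves
#'
#' Per-q nonlinear least squares of
#' `g(q, t) = A(q) * (1 - F(q, t)) + B(q)` over the amplitude `A`, noise
#' floor `B`, and the swimmer parameters `(v, sigma, alpha, D)`, for every
#' shell in the requested q-band, followed by band averaging. The band
#' default (0.45-1.2 µm^-1) is where bacterial-scale dynamics dominate the
#' signal.
#'
#' @param curves a `ddm_curves` object from [image_structure_function()].
#' @param q_min,q_max fit band (µm^-1).
#' @param geometry orientation average of the swimmer ISF, `"3d"` (sinc;
#'   thick sample imaged in projection, the default) or `"2d"` (J0; strictly
#'   in-plane motion, as generated by the 2-D agent simulator).
#' @param start optional named list overriding starting values for
#'   `v`, `sigma`, `alpha`, `D`.
#' @return list with band-averaged `v`, `sigma`, `alpha`, `D` (+ `*_sd`
#'   spreads across q), the per-q table `per_q`, and the number of shells
#'   fitted.
#' @export
fit_ddm <- function(curves, q_min = 0.45, q_max = 1.2,
                    geometry = c("3d", "2d"), start = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(curves, "ddm_curves"))
  sel <- which(curves$q >= q_min & curves$q <= q_max)
  if (length(sel) == 0) stop("no q shells inside the requested band")
  t <- curves$lags
  rows <- list()
  for (i in sel) {
    q <- curves$q[i]
    gq <- curves$g[i, ]
    B0 <- max(min(gq), 1e-12)
    A0 <- max(max(gq) - B0, 1e-12)
    # v from the time where g reaches half its plateau: q v t_half ~ 2
    th <- t[which.min(abs(gq - (B0 + 0.5 * A0)))]
    v0 <- min(max(2 / (q * th), 0.5), 50)
    st <- list(A = A0, B = B0, v = v0, sigma = 0.4 * v0, alpha = 0.6,
               D = 0.3)
    if (!is.null(start)) st[names(start)] <- start
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ A * (1 - isf_smooth_swimmer(q, t, v, sigma, alpha, D,
                                        geometry = geometry)) + B,
        data = data.frame(t = t, g = gq), start = st,
        lower = c(A = 0, B = 0, v = 0.01, sigma = 1e-3, alpha = 0, D = 0),
        upper = c(A = Inf, B = Inf, v = 100, sigma = 50, alpha = 1, D = 50),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("DDM fit failed at q = %.3g, shell excluded", q))
      next
    }
    cf <- coef(fit)
    rows[[length(rows) + 1L]] <-
      data.frame(q = q, A = cf["A"], B = cf["B"], v = cf["v"],
                 sigma = cf["sigma"], alpha = cf["alpha"], D = cf["D"],
                 row.names = NULL)
  }
  if (length(rows) == 0) stop("all per-q DDM fits failed")
  per_q <- do.call(rbind, rows)
  list(v = mean(per_q$v), sigma = mean(per_q$sigma),
       alpha = mean(per_q$alpha), D = mean(per_q$D),
       v_sd = sd(per_q$v), sigma_sd = sd(per_q$sigma),
       alpha_sd = sd(per_q$alpha), D_sd = sd(per_q$D),
       per_q = per_q, n_shells = nrow(per_q))
}
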