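#' Reconstruction parameters
#'
#' @param n_iterations FISTA iteration count.
#' @param apod_rolloff fraction of the spoke tail tapered down.
#' @param apod_end_scale taper value at the spoke end.
#' @param nonneg apply a nonnegativity proximal step.
#' @param l1_weight optional image-domain l1 penalty weight (0 = off).
#' @param os,width oversampling and kernel width of the gridded operator.
#' @param exact_grid_max grids up to this size use the exact NUDFT
#'   operator (0: always use the validated KB-gridded operator).
#' @return an object of class `recon_params`.
#' @export
recon_params <- function(n_iterations = 13, apod_rolloff = 0.25,
                         apod_end_scale = 0.2, nonneg = TRUE,
                         l1_weight = 0, os = 1.5, width = 5,
                         exact_grid_max = 0) {
  stopifnot(n_iterations >= 1, apod_rolloff >= 0, apod_rolloff <= 1,
            apod_end_scale >= 0, apod_end_scale <= 1, l1_weight >= 0)
  p <- list(n_iterations = as.integer(n_iterations),
            apod_rolloff = apod_rolloff,
            apod_end_scale = apod_end_scale,
            nonneg = isTRUE(nonneg),
            l1_weight = l1_weight,
            os = os, width = width,
            exact_grid_max = as.integer(exact_grid_max))
  class(p) <- "recon_params"
  p
}

#' Deconvolve the excitation-pulse spectral profile from a stream
#'
#' Per-spoke regularised division of the sample spectrum by the pulse
#' profile: \eqn{s \bar h / \max(|h|^2, \lambda)}. Exact identity for a
#' flat profile of 1.
#'
#' @param stream a `kspace_stream`.
#' @param pulse_profile complex/real vector, length >= samples per spoke.
#' @param lambda Tikhonov floor on `|h|^2`.
#' @param zero_tol profile magnitudes below this are treated as zeros and
#'   rejected.
#' @return the deconvolved `kspace_stream`.
#' @export
deconvolve_rf <- function(stream, pulse_profile, lambda = 1e-6,
                          zero_tol = 1e-3) {
  stopifnot(inherits(stream, "kspace_stream"))
  n_samp <- ncol(stream$samples)
  if (length(pulse_profile) < n_samp)
    stop("pulse profile shorter than spoke")
  h <- pulse_profile[seq_len(n_samp)]
  if (any(Mod(h) < zero_tol))
    stop("pulse profile has zeros (magnitude below tolerance) within the band")
  g <- Conj(h) / pmax(Mod(h)^2, lambda)
  stream$samples <- sweep(stream$samples, 2, g, "*")
  stream$dc_reference <- stream$samples[, 1]
  stream$pulse_profile <- NULL
  stream
}

#' Cosine taper over the high-frequency spoke tail
#'
#' Taper value per sample: 1 for `|k|` below `(1 - rolloff)` of the spoke
#' maximum, then a half-cosine decaying to `end_scale` at the spoke end.
#' DC is never touched.
#'
#' @param n_samp samples per spoke.
#' @param rolloff tapered tail fraction in `[0, 1]`.
#' @param end_scale taper value at the spoke end.
#' @return numeric vector of per-sample scale factors.
#' @export
spoke_taper <- function(n_samp, rolloff = 0.25, end_scale = 0.2) {
  stopifnot(rolloff >= 0, rolloff <= 1)
  f <- spoke_radii(n_samp) / 0.5
  s <- rep(1, n_samp)
  if (rolloff > 0) {
    tail <- f > (1 - rolloff)
    u <- (f[tail] - (1 - rolloff)) / rolloff
    s[tail] <- end_scale + (1 - end_scale) * 0.5 * (1 + cos(pi * u))
  }
  s
}

#' Scale down the high-frequency ends of the spokes
#'
#' Gibbs-ringing mitigation: multiplies each spoke by [spoke_taper()].
#'
#' @param stream a `kspace_stream`.
#' @param params a [recon_params()].
#' @return the apodized `kspace_stream`.
#' @export
apodize_spokes <- function(stream, params = recon_params()) {
  stopifnot(inherits(stream, "kspace_stream"))
  s <- spoke_taper(ncol(stream$samples), params$apod_rolloff,
                   params$apod_end_scale)
  stream$samples <- sweep(stream$samples, 2, s, "*")
  stream
}

#' Radial density-compensation weights
#'
#' Weights proportional to `|k|^2` along a center-out spoke; the DC sample
#' receives the weight of the first nonzero sample; normalised so that the
#' weights of the full spoke set sum to 1.
#'
#' @param nu per-sample radii (any units proportional to `|k|`).
#' @param n_spokes number of spokes in the set sharing these radii.
#' @return per-sample weight vector (one spoke).
#' @export
density_compensation <- function(nu, n_spokes = 1L) {
  w <- nu^2
  nz <- which(nu > 0)
  if (length(nz)) w[nu == 0] <- w[nz[1]]
  w / (sum(w) * n_spokes)
}

#' Density-compensated adjoint (gridding) reconstruction of one volume
#'
#' Applies the conjugate-transpose radial Fourier operator to
#' density-weighted data, takes the real part and (optionally) clamps to
#' nonnegative values.
#'
#' @param stream a `kspace_stream`.
#' @param params a [recon_params()].
#' @param volume which volume of the stream to reconstruct.
#' @param plan optional pre-built [nufft_plan()] for the stream geometry.
#' @return real 3D array.
#' @export
grid_adjoint <- function(stream, params = recon_params(), volume = 1L,
                         plan = NULL) {
  stopifnot(inherits(stream, "kspace_stream"))
  if (is.null(plan)) plan <- stream_plan(stream, params)
  nsp <- nrow(stream$directions)
  rows <- (volume - 1L) * nsp + seq_len(nsp)
  y <- as.vector(t(stream$samples[rows, , drop = FALSE]))
  w <- rep(density_compensation(stream$nu, nsp), times = nsp)
  x <- Re(nufft_adjoint(plan, y * w))
  if (params$nonneg) x <- pmax(x, 0)
  x
}

#' NUFFT plan matching a stream's geometry
#' @param stream a `kspace_stream`.
#' @param params a [recon_params()].
#' @return a [nufft_plan()].
#' @export
stream_plan <- function(stream, params = recon_params()) {
  nufft_plan(stream$directions, ncol(stream$samples), stream$matrix_size,
             exact = stream$matrix_size <= params$exact_grid_max,
             os = params$os, width = params$width)
}

#' FISTA reconstruction of one volume
#'
#' Iterative gridding: minimises the density-compensated weighted least
#' squares \eqn{\tfrac12\|W^{1/2}(Ax - y)\|^2} (W the radial \eqn{|k|^2}
#' density weights, so the gridding reconstruction is the first-order
#' stationary point target and the problem is well conditioned) plus an
#' optional l1 penalty, with a nonnegativity proximal step. The monotone
#' FISTA variant is used so the objective trace is non-increasing.
#' Initialised from the density-compensated adjoint, rescaled by a
#' one-step least-squares fit; step size `1/L` with `L` from cached power
#' iteration on the weighted normal operator.
#'
#' @param y complex sample vector for one volume (sample-fastest), or a
#'   `kspace_stream` (with `volume`).
#' @param plan a [nufft_plan()] for the spoke geometry (required when `y`
#'   is a bare vector; built automatically from a stream).
#' @param params a [recon_params()].
#' @param volume stream volume index when `y` is a stream.
#' @return list with `image` (real 3D array) and `objective` (length
#'   `n_iterations` trace of the data-fidelity objective).
#' @export
fista_reconstruct <- function(y, plan = NULL, params = recon_params(),
                              volume = 1L) {
  if (inherits(y, "kspace_stream")) {
    stream <- y
    if (is.null(plan)) plan <- stream_plan(stream, params)
    nsp <- nrow(stream$directions)
    rows <- (volume - 1L) * nsp + seq_len(nsp)
    y <- as.vector(t(stream$samples[rows, , drop = FALSE]))
    w0 <- rep(density_compensation(stream$nu, nsp), times = nsp)
  } else {
    if (is.null(plan)) stop("a nufft_plan is required")
    nsp <- plan$n_spokes
    w0 <- rep(density_compensation(plan$nu, nsp), times = nsp)
  }
  stopifnot(inherits(plan, "nufft_plan"), length(y) == plan$M)

  prox <- function(x, step) {
    if (params$l1_weight > 0)
      x <- sign(x) * pmax(abs(x) - step * params$l1_weight, 0)
    if (params$nonneg) x <- pmax(x, 0)
    x
  }
  obj <- function(ax) 0.5 * sum(w0 * Mod(ax - y)^2)

  # density-compensated adjoint init, least-squares rescaled; the forward
  # projection of every iterate is tracked through the momentum updates so
  # each iteration costs one forward and one adjoint application
  x0 <- Re(nufft_adjoint(plan, y * w0))
  if (params$nonneg) x0 <- pmax(x0, 0)
  ax0 <- nufft_forward(plan, x0)
  den <- sum(w0 * Mod(ax0)^2)
  alpha <- if (den > 0) max(0, Re(sum(w0 * Conj(ax0) * y)) / den) else 0
  x0 <- alpha * x0
  ax0 <- alpha * ax0

  L <- if (is.null(plan$lipschitz_w)) {
    plan$lipschitz_w <- nufft_lipschitz(plan, weights = w0)
    plan$lipschitz_w
  } else plan$lipschitz_w
  x_prev <- x0
  ax_prev <- ax0
  f_prev <- obj(ax_prev)
  yk <- x_prev
  ayk <- ax_prev
  tk <- 1
  trace <- numeric(params$n_iterations)
  for (it in seq_len(params$n_iterations)) {
    g <- Re(nufft_adjoint(plan, w0 * (ayk - y)))
    z <- prox(yk - g / L, 1 / L)
    az <- nufft_forward(plan, z)
    fz <- obj(az)
    if (fz <= f_prev) {
      xk <- z; fk <- fz; axk <- az
    } else {
      xk <- x_prev; fk <- f_prev; axk <- ax_prev
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yk <- xk + (tk / t_new) * (z - xk) + ((tk - 1) / t_new) * (xk - x_prev)
    ayk <- axk + (tk / t_new) * (az - axk) +
      ((tk - 1) / t_new) * (axk - ax_prev)
    trace[it] <- fk
    if (fk > 10 * max(trace[1], .Machine$double.eps))
      stop("FISTA diverged: objective exceeded 10x its initial value")
    x_prev <- xk
    ax_prev <- axk
    f_prev <- fk
    tk <- t_new
  }
  list(image = x_prev, objective = trace)
}

#' Reconstructed 4D image series
#'
#' @param data real 4D array (x, y, z, t).
#' @param voxel_size voxel edge length, mm.
#' @param volume_tr volume repetition time, s.
#' @param fov_index source FOV label.
#' @return an object of class `image_series`.
#' @export
image_series <- function(data, voxel_size, volume_tr, fov_index = 0L) {
  stopifnot(length(dim(data)) == 4, all(is.finite(data)))
  s <- list(data = data, voxel_size = voxel_size, volume_tr = volume_tr,
            fov_index = as.integer(fov_index))
  class(s) <- "image_series"
  s
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image series (FOV %d): %dx%dx%d, %d volumes, voxel %.3g mm, TR %.3g s\n",
    x$fov_index, d[1], d[2], d[3], d[4], x$voxel_size, x$volume_tr))
  invisible(x)
}

#' Reconstruct a whole stream into an image series
#'
#' Per volume: RF-pulse deconvolution (when the stream carries a pulse
#' profile), spoke apodization, then FISTA. A trailing partial volume is
#' dropped with a warning.
#'
#' @param stream a `kspace_stream`.
#' @param params a [recon_params()].
#' @param pulse_profile optional profile overriding the one recorded on
#'   the stream.
#' @param verbose print per-volume progress.
#' @return an `image_series`; the per-volume objective traces are attached
#'   as attribute `"objective"` (iterations x volumes matrix).
#' @export
reconstruct_series <- function(stream, params = recon_params(),
                               pulse_profile = NULL, verbose = FALSE) {
  stopifnot(inherits(stream, "kspace_stream"))
  nsp <- nrow(stream$directions)
  nt <- nrow(stream$samples) %/% nsp
  if (nrow(stream$samples) %% nsp != 0)
    warning("dropping trailing partial volume from stream")
  if (nt < 1) stop("stream does not span a whole volume")
  profile <- if (!is.null(pulse_profile)) pulse_profile else
    stream$pulse_profile
  if (!is.null(profile)) stream <- deconvolve_rf(stream, profile)
  stream <- apodize_spokes(stream, params)
  plan <- stream_plan(stream, params)
  nufft_lipschitz(plan)  # cache once
  n <- stream$matrix_size
  data <- array(0, dim = c(n, n, n, nt))
  objective <- matrix(NA_real_, params$n_iterations, nt)
  for (v in seq_len(nt)) {
    r <- fista_reconstruct(stream, plan, params, volume = v)
    data[, , , v] <- r$image
    objective[, v] <- r$objective
    if (verbose && v %% 25 == 0)
      message(sprintf("  reconstructed volume %d/%d", v, nt))
  }
  out <- image_series(data, stream$fov_size / n, stream$volume_tr,
                      stream$fov_index)
  attr(out, "objective") <- objective
  out
}
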