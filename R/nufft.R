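## Non-uniform Fourier operators for 3D center-out radial trajectories.
##
## Two implementations behind one plan interface:
##  * exact type-II NUDFT (O(M * Nvox), reference/oracle, small grids);
##  * Kaiser-Bessel gridded NUFFT (oversampled FFT + separable KB
##    interpolation), the production operator, validated against the exact
##    one on small grids.
## Coordinates are normalised spatial frequencies in cycles/voxel with the
## spatial origin at the grid centre floor(N/2); max |nu| = 0.5 (Nyquist of
## the prescribed matrix, |k| = matrix_size / (2 fov) in cycles/mm).

# circular shift by half the (even) dimension; self-inverse
fftshift_even <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + n / 2) %% n) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# centered DFT via sign masks: for even n, the centered transform
# S(m) = sum_q A(q) exp(-2pi i (m-n/2)(q-n/2)/n) equals
# phi * (-1)^m * FFT(A * (-1)^q), phi = (-1)^(n/2) per axis.
# The (+/-1) masks are precomputed in the plan, avoiding fftshift copies.

# continuous Fourier transform of the KB kernel (per-axis deapodization)
kb_hat <- function(f, width, beta, du = 5e-4) {
  u <- seq(0, width / 2, by = du)
  k <- kb_kernel(u, width, beta)
  vapply(f, function(ff) 2 * sum(k * cos(2 * pi * u * ff)) * du -
           k[1] * du, numeric(1))
}

kb_kernel <- function(u, width, beta) {
  x <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- x >= 0
  out[ok] <- besselI(beta * sqrt(x[ok]), 0) / besselI(beta, 0)
  out
}

#' Radial sample radii in cycles/voxel
#'
#' Center-out spoke with `n_samp` samples from DC to the grid Nyquist
#' (0.5 cycles/voxel).
#' @param n_samp samples per spoke.
#' @return numeric vector of length `n_samp`.
#' @export
spoke_radii <- function(n_samp) {
  stopifnot(n_samp >= 2)
  (seq_len(n_samp) - 1) * 0.5 / (n_samp - 1)
}

#' Plan a non-uniform Fourier operator for a radial spoke set
#'
#' @param directions matrix of unit spoke directions (rows).
#' @param n_samp samples per spoke (center-out, DC to Nyquist).
#' @param matrix_size image grid size per dimension.
#' @param exact use the exact NUDFT (small grids / oracle tests) instead of
#'   Kaiser-Bessel gridding.
#' @param os grid oversampling factor of the gridded operator.
#' @param width KB kernel width in oversampled grid units.
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(directions, n_samp, matrix_size, exact = FALSE,
                       os = 1.5, width = 5) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, n_samp >= 2, matrix_size >= 4)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
  n <- as.integer(matrix_size)
  nu <- spoke_radii(n_samp)
  nsp <- nrow(directions)
  coords <- directions[rep(seq_len(nsp), each = n_samp), , drop = FALSE] *
    nu[rep(seq_len(n_samp), times = nsp)]
  plan <- new.env(parent = emptyenv())
  plan$n <- n
  plan$dims <- rep(n, 3L)
  plan$n_samp <- as.integer(n_samp)
  plan$n_spokes <- nsp
  plan$M <- nsp * n_samp
  plan$nu <- nu
  plan$coords_nu <- coords
  plan$exact <- isTRUE(exact)
  if (!plan$exact) {
    ng <- 2L * ceiling(os * n / 2)
    beta <- pi * sqrt((width / os * (os - 0.5))^2 - 0.8)
    ntab <- as.integer(width / 2 * 4096) + 2L
    tab <- kb_kernel(seq(0, width / 2, length.out = ntab), width, beta)
    plan$ng <- ng
    plan$gdims <- rep(ng, 3L)
    plan$width <- width
    plan$beta <- beta
    plan$table <- tab
    plan$table_scale <- (ntab - 1) / (width / 2)
    plan$coords_grid <- coords * ng + ng / 2
    # separable deapodization over the cropped image region
    p <- (seq_len(n) - 1) - n / 2
    d1 <- 1 / kb_hat(p / ng, width, beta)
    plan$pad_idx <- (ng / 2 - n / 2) + seq_len(n)
    sgn1g <- (-1)^(seq_len(ng) - 1)
    sgn1c <- sgn1g[plan$pad_idx]
    phi <- ((-1)^(ng / 2))^3
    # image-side mask folded into the deapodizer; spectrum-side mask
    # carries the centering phase phi
    plan$deapod <- outer(outer(d1 * sgn1c, d1 * sgn1c), d1 * sgn1c)
    plan$post <- phi * outer(outer(sgn1g, sgn1g), sgn1g)
  }
  class(plan) <- "nufft_plan"
  plan
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf("NUFFT plan: %d spokes x %d samples on %d^3 (%s)\n",
              x$n_spokes, x$n_samp, x$n,
              if (x$exact) "exact NUDFT" else
                sprintf("KB gridding, grid %d^3, width %g", x$ng, x$width)))
  invisible(x)
}

#' Apply the forward radial Fourier operator
#'
#' @param plan a [nufft_plan()].
#' @param x real or complex 3D array on the plan's grid.
#' @return complex sample vector (sample-fastest, spokes sequential).
#' @export
nufft_forward <- function(plan, x) {
  stopifnot(inherits(plan, "nufft_plan"))
  if (!all(dim(x) == plan$dims)) stop("image dimensions do not match plan")
  if (plan$exact)
    return(as.vector(cpp_nudft_forward(as.complex(x), plan$dims,
                                       plan$coords_nu)))
  a <- array(0i, dim = plan$gdims)
  a[plan$pad_idx, plan$pad_idx, plan$pad_idx] <- x * plan$deapod
  s <- stats::fft(a) * plan$post
  as.vector(cpp_kb_gather(s, plan$gdims, plan$coords_grid, plan$width,
                          plan$table, plan$table_scale))
}

#' Apply the adjoint (conjugate-transpose) radial Fourier operator
#'
#' @param plan a [nufft_plan()].
#' @param y complex sample vector of length `plan$M`.
#' @return complex 3D array on the plan's grid.
#' @export
nufft_adjoint <- function(plan, y) {
  stopifnot(inherits(plan, "nufft_plan"))
  if (length(y) != plan$M) stop("sample vector length does not match plan")
  if (plan$exact) {
    img <- cpp_nudft_adjoint(as.complex(y), plan$dims, plan$coords_nu)
    return(array(img, dim = plan$dims))
  }
  s <- array(cpp_kb_scatter(as.complex(y), plan$gdims, plan$coords_grid,
                            plan$width, plan$table, plan$table_scale),
             dim = plan$gdims)
  a <- stats::fft(s * plan$post, inverse = TRUE)
  a[plan$pad_idx, plan$pad_idx, plan$pad_idx] * plan$deapod
}

#' Lipschitz constant of the normal operator (power iteration)
#'
#' Largest eigenvalue of \eqn{A^H A}, estimated by power iteration
#' (relative tolerance 1e-3, at most 50 iterations, deterministic start)
#' and cached in the plan.
#'
#' @param plan a [nufft_plan()].
#' @param weights optional per-sample real weights applied inside the
#'   normal operator (for weighted least squares; unused by default).
#' @return scalar Lipschitz estimate.
#' @export
nufft_lipschitz <- function(plan, weights = NULL) {
  stopifnot(inherits(plan, "nufft_plan"))
  if (!is.null(plan$lipschitz) && is.null(weights)) return(plan$lipschitz)
  rng <- make_local_rng(271828L)
  v <- array(rng(prod(plan$dims)) - 0.5, dim = plan$dims)
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(50L)) {
    y <- nufft_forward(plan, v)
    if (!is.null(weights)) y <- y * weights
    w <- Re(nufft_adjoint(plan, y))
    lam_new <- sqrt(sum(w^2))
    w <- w / lam_new
    if (abs(lam_new - lam) <= 1e-3 * lam_new) {
      lam <- lam_new
      break
    }
    lam <- lam_new
    v <- w
  }
  if (is.null(weights)) plan$lipschitz <- lam
  lam
}
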