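#' Block stimulation paradigm
#'
#' The hindlimb-stimulation timeline: an initial rest period followed by
#' `n_blocks` repeats of a stimulation block and a rest interval.
#'
#' @param initial_rest initial rest, s.
#' @param block_on stimulation-block duration, s.
#' @param block_off post-block rest, s.
#' @param n_blocks number of stimulation blocks.
#' @param stim_frequency stimulation pulse frequency, Hz (metadata).
#' @param stim_current stimulation current, mA (metadata).
#' @return an object of class `paradigm`.
#' @export
paradigm <- function(initial_rest = 60, block_on = 24, block_off = 90,
                     n_blocks = 6, stim_frequency = 9, stim_current = 2) {
  stopifnot(initial_rest >= 0, block_on > 0, block_off >= 0, n_blocks >= 0)
  p <- list(initial_rest = initial_rest, block_on = block_on,
            block_off = block_off, n_blocks = as.integer(n_blocks),
            stim_frequency = stim_frequency, stim_current = stim_current)
  class(p) <- "paradigm"
  p
}

#' Total paradigm duration in seconds
#' @param par a [paradigm()].
#' @export
paradigm_duration <- function(par) {
  par$initial_rest + par$n_blocks * (par$block_on + par$block_off)
}

#' Stimulation-block onset times in seconds
#' @param par a [paradigm()].
#' @export
paradigm_onsets <- function(par) {
  if (par$n_blocks == 0L) return(numeric(0))
  par$initial_rest + (seq_len(par$n_blocks) - 1) *
    (par$block_on + par$block_off)
}

#' Boxcar regressor sampled at volume acquisition times
#'
#' Element `v` is 1 iff the start time of volume `v` falls inside a
#' stimulation block, 0 otherwise.
#'
#' @param par a [paradigm()].
#' @param volume_tr volume repetition time, s.
#' @return a 0/1 vector of length `ceiling(total duration / volume_tr)`.
#' @export
make_paradigm <- function(par, volume_tr) {
  stopifnot(inherits(par, "paradigm"), volume_tr > 0)
  total <- paradigm_duration(par)
  n <- ceiling(total / volume_tr)
  t <- (seq_len(n) - 1) * volume_tr
  box <- numeric(n)
  for (on in paradigm_onsets(par))
    box[t >= on & t < on + par$block_on] <- 1
  box
}

#' Gamma-variate impulse response parameters
#'
#' `delay` is the mean and `variation` the standard deviation of the
#' gamma-density hemodynamic kernel (moment matching:
#' shape \eqn{k = (delay/variation)^2}, scale
#' \eqn{\theta = variation^2/delay}).
#'
#' @param delay response delay (kernel mean), s.
#' @param variation response dispersion (kernel SD), s.
#' @return an object of class `irf_params`.
#' @export
irf_params <- function(delay = 2.8, variation = 1.4) {
  if (!is.numeric(delay) || delay <= 0)
    stop("delay must be positive")
  if (!is.numeric(variation) || variation <= 0)
    stop("variation must be positive")
  p <- list(delay = delay, variation = variation,
            shape = (delay / variation)^2,
            scale = variation^2 / delay)
  class(p) <- "irf_params"
  p
}

#' Gamma-variate impulse response kernel
#'
#' Gamma density with mean `delay` and SD `variation`, evaluated on the
#' supplied time grid and renormalised so that the discrete sum times the
#' grid spacing is 1.
#'
#' @param t non-negative, increasing, uniformly spaced time grid, s.
#' @param irf an [irf_params()] object.
#' @return kernel values on `t`.
#' @export
gamma_irf <- function(t, irf = irf_params()) {
  stopifnot(inherits(irf, "irf_params"))
  if (any(t < 0) || is.unsorted(t, strictly = TRUE))
    stop("t must be non-negative and strictly increasing")
  k <- stats::dgamma(t, shape = irf$shape, scale = irf$scale)
  dt <- t[2] - t[1]
  s <- sum(k) * dt
  if (s <= 0) stop("kernel mass is zero on the supplied grid")
  k / s
}

#' Boxcar-convolved hemodynamic response sampled at volume times
#'
#' Convolves the stimulation boxcar with the gamma-variate kernel on a fine
#' time grid, rescales to unit peak (so injected effect sizes are peak
#' fractional changes), applies an optional latency shift, and samples at
#' the volume start times.
#'
#' @param par a [paradigm()].
#' @param irf an [irf_params()].
#' @param volume_tr volume repetition time, s.
#' @param latency_shift additional response delay, s.
#' @param n_volumes number of volumes; default covers the paradigm.
#' @param dt_fine fine-grid step for the convolution, s.
#' @return response vector of length `n_volumes`, peak value <= 1.
#' @export
task_response <- function(par, irf = irf_params(), volume_tr,
                          latency_shift = 0, n_volumes = NULL,
                          dt_fine = 0.05) {
  stopifnot(inherits(par, "paradigm"), volume_tr > 0)
  total <- paradigm_duration(par)
  if (is.null(n_volumes)) n_volumes <- ceiling(total / volume_tr)
  tf <- seq(0, total + 10 * irf$delay + latency_shift, by = dt_fine)
  box <- numeric(length(tf))
  for (on in paradigm_onsets(par))
    box[tf >= on & tf < on + par$block_on] <- 1
  if (all(box == 0)) return(numeric(n_volumes))
  kern <- gamma_irf(seq(0, stats::qgamma(1 - 1e-8, shape = irf$shape,
                                         scale = irf$scale), by = dt_fine),
                    irf)
  r <- stats::convolve(box, rev(kern), type = "open")[seq_along(tf)] * dt_fine
  pk <- max(r)
  if (pk > 0) r <- r / pk
  tv <- (seq_len(n_volumes) - 1) * volume_tr - latency_shift
  out <- stats::approx(tf, r, xout = tv, rule = 2, yleft = 0)$y
  out[tv < 0] <- 0
  out
}

# ---- geometry helpers (internal) -------------------------------------------

ellipsoid_mask <- function(n, center, semi) {
  g <- seq_len(n) - 1
  x <- outer(outer((g - center[1])^2 / semi[1]^2, (g - center[2])^2 / semi[2]^2,
                   "+"), (g - center[3])^2 / semi[3]^2, "+")
  x <= 1
}

sphere_mask <- function(n, center, radius) {
  ellipsoid_mask(n, center, rep(radius, 3))
}

cylinder_mask <- function(n, center_xy, radius, z_range) {
  g <- seq_len(n) - 1
  disc <- outer((g - center_xy[1])^2, (g - center_xy[2])^2, "+") <= radius^2
  zin <- g >= z_range[1] & g <= z_range[2]
  array(outer(as.vector(disc), zin, "&"), dim = c(n, n, n))
}

# smooth, seeded intra-object texture: a sum of broad Gaussian bumps
smooth_texture <- function(n, n_bumps, amp, width, rng_fun) {
  g <- seq_len(n) - 1
  tex <- array(0, dim = c(n, n, n))
  for (b in seq_len(n_bumps)) {
    c0 <- rng_fun(3) * (n - 1)
    bump <- exp(-outer(outer((g - c0[1])^2, (g - c0[2])^2, "+"),
                       (g - c0[3])^2, "+") / (2 * width^2))
    tex <- tex + (2 * rng_fun(1) - 1) * amp * bump
  }
  tex
}

#' Dual-organ digital phantom
#'
#' Builds the two ground-truth baseline volumes: an ellipsoidal brain-like
#' head (FOV 0) with a lateralised cortical activation region and a midline
#' cerebellar region, and a cylindrical spinal-cord segment (FOV 1) with a
#' unilateral dorsal-quadrant activation region. Baselines carry a smooth,
#' seeded intra-object texture on top of a constant level.
#'
#' @param matrix_size grid size per dimension (>= 16).
#' @param effect_size length-2 peak fractional signal change at the
#'   response peak, `c(brain, cord)`.
#' @param noise_sd complex k-space noise SD relative to the mean DC
#'   magnitude (consumed by [acquire_dual()]).
#' @param motion_events list of events `list(fov=, volume=, shift=c(x,y,z))`;
#'   from `volume` onwards the object of that FOV is displaced by `shift`
#'   voxels (absolute offset, later events supersede earlier ones).
#' @param latency_shift length-2 additional response delay per FOV, s. The
#'   default delays the cord response by 9 s relative to the brain,
#'   emulating the slower dorsal-cord hemodynamics.
#' @param seed integer seed for the baseline texture.
#' @return An object of class `dual_phantom` with elements `volumes`,
#'   `activation_masks`, `object_masks` (each a list of two 3D arrays),
#'   `effect_size`, `noise_sd`, `motion_events`, `latency_shift`,
#'   `roi_voxels` (per-FOV activation voxel counts; the brain entry counts
#'   cortical + cerebellar voxels).
#' @export
make_dual_phantom <- function(matrix_size = 32,
                              effect_size = c(brain = 0.005, cord = 0.010),
                              noise_sd = 0.25,
                              motion_events = list(),
                              latency_shift = c(0, 9),
                              seed = 1L) {
  n <- as.integer(matrix_size)
  if (n < 16) stop("matrix_size must be >= 16")
  stopifnot(length(effect_size) == 2, all(effect_size >= 0),
            length(latency_shift) == 2, noise_sd >= 0)
  # deterministic texture RNG independent of the global stream
  rng_fun <- make_local_rng(seed)

  c0 <- (n - 1) / 2
  # FOV 0: brain-like ellipsoid
  head <- ellipsoid_mask(n, rep(c0, 3), c(0.42, 0.36, 0.32) * n)
  cortex <- sphere_mask(n, c(c0 + 0.22 * n, c0 + 0.05 * n, c0 + 0.18 * n),
                        0.09 * n) & head
  cereb <- sphere_mask(n, c(c0, c0 - 0.22 * n, c0 - 0.10 * n),
                       0.07 * n) & head
  brain_roi <- cortex | cereb
  base0 <- array(0, dim = c(n, n, n))
  base0[head] <- 100
  base0 <- base0 * (1 + pmax(-0.4, pmin(0.4,
    smooth_texture(n, 6, 0.15, 0.18 * n, rng_fun))))
  base0[!head] <- 0

  # FOV 1: cylindrical cord segment along z
  radius <- 0.14 * n
  cord <- cylinder_mask(n, c(c0, c0), radius, c(0.1 * n, 0.9 * n))
  g <- seq_len(n) - 1
  right <- array(rep(g > c0, times = n * n), dim = c(n, n, n))      # +x half
  dorsal <- aperm(array(rep(g > c0, times = n * n), dim = c(n, n, n)),
                  c(2, 1, 3))                                       # +y half
  core <- cylinder_mask(n, c(c0 + 0.05 * n, c0 + 0.05 * n), 0.45 * radius,
                        c(0.30 * n, 0.62 * n))
  cord_roi <- cord & core & right & dorsal
  base1 <- array(0, dim = c(n, n, n))
  base1[cord] <- 100
  base1 <- base1 * (1 + pmax(-0.4, pmin(0.4,
    smooth_texture(n, 4, 0.10, 0.20 * n, rng_fun))))
  base1[!cord] <- 0

  if (!any(cord_roi) || !any(brain_roi))
    stop("activation ROI is empty; increase matrix_size")
  if (any(brain_roi & !head) || any(cord_roi & !cord))
    stop("activation ROI extends beyond the object mask")

  p <- list(volumes = list(base0, base1),
            activation_masks = list(brain_roi, cord_roi),
            object_masks = list(head, cord),
            effect_size = unname(effect_size),
            noise_sd = noise_sd,
            motion_events = motion_events,
            latency_shift = unname(latency_shift),
            matrix_size = n,
            seed = as.integer(seed),
            roi_voxels = c(brain = sum(brain_roi), cord = sum(cord_roi)))
  class(p) <- "dual_phantom"
  p
}

#' @export
print.dual_phantom <- function(x, ...) {
  cat(sprintf("Dual phantom %d^3: brain ROI %d vox (effect %.2g), cord ROI %d vox (effect %.2g)\n",
              x$matrix_size, x$roi_voxels[1], x$effect_size[1],
              x$roi_voxels[2], x$effect_size[2]))
  cat(sprintf("  k-space noise sd %.3g x DC, %d motion event(s), latency shift %g / %g s\n",
              x$noise_sd, length(x$motion_events), x$latency_shift[1],
              x$latency_shift[2]))
  invisible(x)
}

# local RNG closure so phantom generation never disturbs the global stream
make_local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(k) {
    orig <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, envir = globalenv())
    r <- stats::runif(k)
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(orig)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", orig, envir = globalenv())
    r
  }
}

# integer-voxel circular shift of a 3D array
shift3d <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    s <- ((seq_len(d[ax]) - 1 - round(shift[ax])) %% d[ax]) + 1
    s
  })
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Render the ground-truth 4D image series for both FOVs
#'
#' Voxel `v` of volume `t` equals
#' `baseline(v) * (1 + effect_size * mask(v) * r(t))`, where `r` is the
#' unit-peak boxcar-convolved gamma response with the FOV's latency shift.
#' Motion events displace whole volumes by integer voxel counts.
#'
#' @param phantom a [make_dual_phantom()] object.
#' @param par a [paradigm()].
#' @param irf an [irf_params()].
#' @param volume_tr volume repetition time, s.
#' @param n_volumes number of volumes; default covers the paradigm.
#' @return list of two 4D arrays (x, y, z, t).
#' @export
render_truth_series <- function(phantom, par = paradigm(),
                                irf = irf_params(), volume_tr = 3,
                                n_volumes = NULL) {
  stopifnot(inherits(phantom, "dual_phantom"))
  if (is.null(n_volumes))
    n_volumes <- ceiling(paradigm_duration(par) / volume_tr)
  n <- phantom$matrix_size
  out <- vector("list", 2L)
  for (f in 1:2) {
    r <- task_response(par, irf, volume_tr,
                       latency_shift = phantom$latency_shift[f],
                       n_volumes = n_volumes)
    base <- phantom$volumes[[f]]
    act <- base * phantom$activation_masks[[f]] * phantom$effect_size[f]
    series <- array(0, dim = c(n, n, n, n_volumes))
    # current displacement from motion events for this FOV
    ev <- Filter(function(e) is.null(e$fov) || e$fov == f - 1L,
                 phantom$motion_events)
    ev_vol <- vapply(ev, function(e) as.integer(e$volume), integer(1))
    shift <- c(0, 0, 0)
    for (v in seq_len(n_volumes)) {
      if (length(ev)) {
        hit <- which(ev_vol <= v)
        if (length(hit)) shift <- ev[[max(hit)]]$shift else shift <- c(0, 0, 0)
      }
      vol <- base + act * r[v]
      if (any(shift != 0)) vol <- shift3d(vol, shift)
      series[, , , v] <- vol
    }
    out[[f]] <- series
  }
  out
}
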