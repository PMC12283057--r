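#' k-space stream for one field of view
#'
#' Internal constructor; streams are produced by [acquire_dual()].
#'
#' @param samples complex matrix, one row per spoke (volume-major), one
#'   column per readout sample (center-out).
#' @param directions spoke-orientation matrix for one volume.
#' @param fov_index 0 or 1.
#' @param matrix_size,fov_size grid size and FOV edge length (mm).
#' @param n_volumes number of whole volumes in the stream.
#' @param volume_tr volume repetition time, s.
#' @param noise_sd relative complex noise SD used during acquisition.
#' @param pulse_profile per-sample excitation-pulse spectral profile that
#'   was applied by the forward model (NULL if none).
#' @return an object of class `kspace_stream`.
#' @keywords internal
kspace_stream <- function(samples, directions, fov_index, matrix_size,
                          fov_size, n_volumes, volume_tr, noise_sd = 0,
                          pulse_profile = NULL) {
  s <- list(samples = samples,
            directions = directions,
            nu = spoke_radii(ncol(samples)),
            delta_k = (matrix_size / (2 * fov_size)) / (ncol(samples) - 1),
            fov_index = as.integer(fov_index),
            matrix_size = as.integer(matrix_size),
            fov_size = fov_size,
            n_volumes = as.integer(n_volumes),
            volume_tr = volume_tr,
            noise_sd = noise_sd,
            pulse_profile = pulse_profile,
            dc_reference = samples[, 1])
  class(s) <- "kspace_stream"
  s
}

#' @export
print.kspace_stream <- function(x, ...) {
  cat(sprintf(
    "k-space stream (FOV %d): %d spokes x %d samples, %d volumes, dk %.4g cyc/mm\n",
    x$fov_index, nrow(x$samples), ncol(x$samples), x$n_volumes, x$delta_k))
  invisible(x)
}

#' Physical k-space coordinates of a stream's samples
#'
#' @param stream a `kspace_stream`.
#' @param spokes which spoke rows (default: one volume's worth).
#' @return matrix (samples x 3) of coordinates in cycles/mm, sample-fastest.
#' @export
k_coords <- function(stream, spokes = seq_len(nrow(stream$directions))) {
  ns <- ncol(stream$samples)
  dir_idx <- ((spokes - 1) %% nrow(stream$directions)) + 1
  d <- stream$directions[rep(dir_idx, each = ns), , drop = FALSE]
  r <- stream$nu[rep(seq_len(ns), times = length(spokes))]
  # nu in cycles/voxel -> cycles/mm
  d * r * stream$matrix_size / stream$fov_size
}

#' Fourier samples of a volume along one radial spoke
#'
#' Exact type-II NUDFT of the volume at `k_j = j * dk * direction`,
#' `j = 0 ... n_samp - 1`, with the sample spacing set by the FOV's
#' readout-gradient scale (Nyquist of the prescribed grid at the spoke
#' end).
#'
#' @param volume real 3D array.
#' @param direction unit 3-vector.
#' @param params a [sequence_params()]; sets the sample count.
#' @param fov which FOV's gradient scale to use (0 or 1).
#' @return complex vector of length `samples_per_spoke(params)`.
#' @export
sample_spoke <- function(volume, direction, params, fov = 0L) {
  stopifnot(inherits(params, "sequence_params"))
  direction <- as.numeric(direction)
  if (length(direction) != 3 || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit 3-vector")
  n_samp <- samples_per_spoke(params)
  coords <- outer(spoke_radii(n_samp), direction)
  as.vector(cpp_nudft_forward(as.complex(volume), dim(volume), coords))
}

#' Forward-model the interleaved dual-FOV radial acquisition
#'
#' Samples the two ground-truth 4D series along the scheduled spokes. Each
#' excitation samples the truth volume active at its timestamp (volumes
#' are frozen within a volume TR). Independent complex Gaussian noise with
#' standard deviation `noise_sd` times the mean DC magnitude is added per
#' sample; an optional coil-coupling coefficient mixes a fraction of the
#' other FOV's signal into each stream; an optional excitation-pulse
#' spectral profile multiplies each spoke (exercised by the deconvolution
#' step of the reconstruction).
#'
#' @param series0,series1 4D truth arrays for FOV 0 and FOV 1.
#' @param schedule a [make_dual_schedule()] object.
#' @param params a [sequence_params()].
#' @param noise_sd complex noise SD relative to mean DC magnitude.
#' @param seed RNG seed for the noise.
#' @param coupling inter-coil coupling coefficient (default 0).
#' @param pulse_profile optional complex/real vector (length >= samples per
#'   spoke) applied multiplicatively along every spoke.
#' @param volume_tr volume repetition time in s (metadata on the streams).
#' @param exact use the exact NUDFT forward model regardless of grid size.
#' @return list of two `kspace_stream` objects.
#' @export
acquire_dual <- function(series0, series1, schedule, params, noise_sd = 0,
                         seed = 1L, coupling = 0, pulse_profile = NULL,
                         volume_tr = NULL, exact = NULL) {
  stopifnot(inherits(schedule, "spoke_schedule"),
            inherits(params, "sequence_params"))
  n <- params$matrix_size
  if (!all(dim(series0)[1:3] == n) || !all(dim(series1)[1:3] == n))
    stop("series grids do not match matrix_size")
  nt <- params$n_volumes
  if (dim(series0)[4] < nt || dim(series1)[4] < nt)
    stop("schedule time overruns the truth series length")
  if (is.null(volume_tr)) volume_tr <- schedule$volume_time_ms / 1000
  n_samp <- samples_per_spoke(params)
  if (!is.null(pulse_profile)) {
    if (length(pulse_profile) < n_samp)
      stop("pulse profile shorter than spoke")
    pulse_profile <- pulse_profile[seq_len(n_samp)]
  }
  if (is.null(exact)) exact <- FALSE
  plan <- nufft_plan(schedule$directions, n_samp, n, exact = exact)
  nsp <- nrow(schedule$directions)
  series <- list(series0, series1)
  raw <- vector("list", 2L)
  for (f in 1:2) {
    sm <- matrix(0i, nrow = nsp * nt, ncol = n_samp)
    for (v in seq_len(nt)) {
      y <- nufft_forward(plan, series[[f]][, , , v])
      sm[(v - 1) * nsp + seq_len(nsp), ] <-
        matrix(y, nrow = n_samp, ncol = nsp)[, , drop = FALSE] |> t()
    }
    if (!is.null(pulse_profile))
      sm <- sweep(sm, 2, pulse_profile, "*")
    raw[[f]] <- sm
  }
  if (coupling != 0) {
    mixed0 <- raw[[1]] + coupling * raw[[2]]
    mixed1 <- raw[[2]] + coupling * raw[[1]]
    raw[[1]] <- mixed0
    raw[[2]] <- mixed1
  }
  streams <- vector("list", 2L)
  with_seed_local(seed, {
    for (f in 1:2) {
      sm <- raw[[f]]
      if (noise_sd > 0) {
        sd_abs <- noise_sd * mean(Mod(sm[, 1]))
        m <- length(sm)
        sm <- sm + complex(real = stats::rnorm(m, sd = sd_abs / sqrt(2)),
                           imaginary = stats::rnorm(m, sd = sd_abs / sqrt(2)))
      }
      streams[[f]] <- kspace_stream(sm, schedule$directions, f - 1L, n,
                                    params$fov_size[f], nt, volume_tr,
                                    noise_sd, pulse_profile)
    }
  })
  streams
}
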