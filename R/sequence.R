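#' Acquisition parameters for the dual-FOV MB-SWIFT sequence
#'
#' Bundles the timing and geometry of the interleaved dual field-of-view
#' zero-TE 3D-radial acquisition. Within every repetition time `tr_pair`
#' (which covers one excitation of *each* FOV at the same readout-gradient
#' orientation) two spokes are acquired, one per FOV; a full image volume
#' needs `n_spokes_per_volume` orientations.
#'
#' @param tr_pair repetition time covering the two spokes of a pair, ms.
#' @param n_spokes_per_volume number of spoke orientations per image volume.
#' @param n_volumes number of image volumes (time points) per FOV.
#' @param bandwidth per-FOV readout bandwidth, kHz.
#' @param oversampling readout oversampling factor.
#' @param matrix_size reconstruction matrix size per dimension (isotropic).
#' @param fov_size field-of-view edge length in mm; length 1 (both FOVs
#'   equal) or length 2 (FOV 0, FOV 1).
#' @param flip_angle nominal excitation flip angle, degrees (metadata).
#' @param n_gaps number of readout gaps between pulse elements per spoke.
#' @param samples_per_gap acquired points per gap before oversampling.
#' @param gap_readout readout duration per gap, microseconds.
#' @param pulse_element_width,pre_excitation_delay,post_excitation_delay
#'   fine timing of the gapped excitation, microseconds (metadata).
#' @param gradient_switch_time gradient re-orientation time per pair,
#'   microseconds (metadata).
#' @param fov_offsets per-FOV transmitter frequency offset, Hz (metadata).
#'
#' @return An object of class `sequence_params`. The sweep range
#'   (`bandwidth / samples_per_gap`, kHz) is derived and stored.
#' @export
sequence_params <- function(tr_pair = 1.94,
                            n_spokes_per_volume = 1547,
                            n_volumes = 248,
                            bandwidth = 192,
                            oversampling = 2,
                            matrix_size = 64,
                            fov_size = 40,
                            flip_angle = 6,
                            n_gaps = 4,
                            samples_per_gap = 32,
                            gap_readout = 167.5,
                            pulse_element_width = 2.6,
                            pre_excitation_delay = 0.1,
                            post_excitation_delay = 2.5,
                            gradient_switch_time = 292.5,
                            fov_offsets = c(0, 0)) {
  stopifnot(tr_pair > 0, n_spokes_per_volume >= 1, n_volumes >= 1,
            bandwidth > 0, oversampling >= 1, matrix_size >= 2,
            all(fov_size > 0), n_gaps >= 1, samples_per_gap >= 1,
            gap_readout > 0)
  if (length(fov_size) == 1L) fov_size <- rep(fov_size, 2L)
  if (length(fov_size) != 2L)
    stop("fov_size must have length 1 or 2")
  p <- list(tr_pair = tr_pair,
            n_spokes_per_volume = as.integer(n_spokes_per_volume),
            n_volumes = as.integer(n_volumes),
            bandwidth = bandwidth,
            oversampling = oversampling,
            matrix_size = as.integer(matrix_size),
            fov_size = fov_size,
            flip_angle = flip_angle,
            n_gaps = as.integer(n_gaps),
            samples_per_gap = as.integer(samples_per_gap),
            gap_readout = gap_readout,
            pulse_element_width = pulse_element_width,
            pre_excitation_delay = pre_excitation_delay,
            post_excitation_delay = post_excitation_delay,
            gradient_switch_time = gradient_switch_time,
            sweep_range = bandwidth / samples_per_gap,
            fov_offsets = fov_offsets)
  class(p) <- "sequence_params"
  p
}

#' @export
print.sequence_params <- function(x, ...) {
  cat("Dual-FOV MB-SWIFT sequence parameters\n")
  cat(sprintf("  TR (spoke pair): %.3g ms, spokes/volume: %d, volumes: %d\n",
              x$tr_pair, x$n_spokes_per_volume, x$n_volumes))
  cat(sprintf("  matrix %d^3, FOV %g / %g mm, BW %g kHz (os %g)\n",
              x$matrix_size, x$fov_size[1], x$fov_size[2], x$bandwidth,
              x$oversampling))
  invisible(x)
}

#' Samples per spoke after oversampling
#' @param params a [sequence_params()] object.
#' @return integer sample count along one spoke.
#' @export
samples_per_spoke <- function(params) {
  as.integer(params$samples_per_gap * params$oversampling)
}

#' 3D-radial spoke directions on a spherical spiral
#'
#' Places `n_spokes` unit vectors along a single continuous spiral over the
#' sphere from pole to pole (uniform steps in the polar cosine, azimuth
#' advanced in proportion to the local circumference), giving near-uniform
#' angular coverage with one spiral per volume.
#'
#' @param n_spokes number of directions (>= 1).
#' @param ordering trajectory type; only `"spherical_spiral"` is defined.
#' @return an `n_spokes` x 3 matrix of unit row vectors.
#' @export
make_spoke_directions <- function(n_spokes, ordering = "spherical_spiral") {
  ordering <- match.arg(ordering)
  if (!is.numeric(n_spokes) || length(n_spokes) != 1L || n_spokes < 1 ||
      n_spokes != round(n_spokes))
    stop("n_spokes must be a positive integer")
  n <- as.integer(n_spokes)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  z <- seq(1, -1, length.out = n)
  s <- sqrt(pmax(0, 1 - z^2))
  # azimuth increment ~ 3.6/sqrt(n)/sin(theta) (generalized spiral spacing)
  phi <- numeric(n)
  if (n > 2)
    for (i in 2:(n - 1))
      phi[i] <- phi[i - 1] + 3.6 / sqrt(n) / s[i]
  phi[n] <- phi[n - 1]
  d <- cbind(s * cos(phi), s * sin(phi), z)
  unname(d / sqrt(rowSums(d^2)))
}

#' Interleaved dual-FOV excitation schedule for one volume
#'
#' Expands a set of spoke directions into the per-excitation schedule: each
#' gradient orientation is held for a whole TR pair during which FOV 0 and
#' then FOV 1 are excited, `tr_pair / 2` apart. The relative readout
#' gradient amplitude per FOV scales inversely with its FOV size
#' (normalised so equal FOVs give 1).
#'
#' @param params a [sequence_params()] object.
#' @param directions matrix of unit vectors, one row per spoke orientation;
#'   must have `n_spokes_per_volume` rows.
#' @return An object of class `spoke_schedule`: a list with the
#'   per-excitation table (`time_ms`, `fov`, `spoke`), the `directions`
#'   matrix, and `gradient_scale` (length 2).
#' @export
make_dual_schedule <- function(params, directions) {
  stopifnot(inherits(params, "sequence_params"))
  directions <- as.matrix(directions)
  if (nrow(directions) != params$n_spokes_per_volume)
    stop("directions must have n_spokes_per_volume rows")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("directions must be unit vectors")
  ns <- params$n_spokes_per_volume
  # amplitude ~ 1/FOV, referenced to FOV 0 so equal FOVs give scale 1
  gradient_scale <- params$fov_size[1] / params$fov_size
  excitations <- data.frame(
    index = seq_len(2L * ns) - 1L,
    time_ms = (seq_len(2L * ns) - 1L) * params$tr_pair / 2,
    fov = rep(c(0L, 1L), ns),
    spoke = rep(seq_len(ns), each = 2L)
  )
  s <- list(excitations = excitations,
            directions = directions,
            gradient_scale = gradient_scale,
            tr_pair = params$tr_pair,
            volume_time_ms = ns * params$tr_pair)
  class(s) <- "spoke_schedule"
  s
}

#' @export
print.spoke_schedule <- function(x, ...) {
  cat(sprintf(
    "Spoke schedule: %d orientations, %d excitations/volume, %.4g ms/volume\n",
    nrow(x$directions), nrow(x$excitations), x$volume_time_ms))
  cat(sprintf("  gradient scale FOV0/FOV1: %g / %g\n",
              x$gradient_scale[1], x$gradient_scale[2]))
  invisible(x)
}

#' Derived timing quantities of the acquisition
#'
#' @param params a [sequence_params()] object.
#' @return a data.frame with columns `quantity`, `value`, `unit` containing
#'   the single-spoke time, total readout per spoke, volume time, total
#'   scan time, per-FOV voxel sizes, sweep range, acquisition bandwidth and
#'   the linewidth tolerance `bandwidth / matrix_size` (the half-maximum
#'   water linewidth the sequence tolerates).
#' @export
timing_summary <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  vol_ms <- params$n_spokes_per_volume * params$tr_pair
  data.frame(
    quantity = c("single_spoke_time", "readout_per_spoke", "volume_time",
                 "total_scan_time", "voxel_size_fov0", "voxel_size_fov1",
                 "sweep_range", "acquisition_bandwidth",
                 "linewidth_tolerance"),
    value = c(params$tr_pair / 2,
              params$n_gaps * params$gap_readout,
              vol_ms,
              vol_ms * params$n_volumes / 1000,
              params$fov_size[1] / params$matrix_size,
              params$fov_size[2] / params$matrix_size,
              params$sweep_range,
              params$bandwidth * params$oversampling,
              params$bandwidth / params$matrix_size),
    unit = c("ms", "us", "ms", "s", "mm", "mm", "kHz", "kHz", "kHz"),
    stringsAsFactors = FALSE
  )
}

#' Export / import a spoke schedule as a plain-text table
#'
#' One row per excitation: index, time (ms), FOV label, direction x/y/z and
#' the per-FOV gradient scale.
#'
#' @param schedule a `spoke_schedule`.
#' @param path file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a `spoke_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  ex <- schedule$excitations
  d <- schedule$directions[ex$spoke, , drop = FALSE]
  tab <- data.frame(index = ex$index, time_ms = ex$time_ms, fov = ex$fov,
                    dx = d[, 1], dy = d[, 2], dz = d[, 3],
                    gradient_scale = schedule$gradient_scale[ex$fov + 1L])
  utils::write.table(format(tab, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  f0 <- tab$fov == 0L
  directions <- as.matrix(tab[f0, c("dx", "dy", "dz")])
  dimnames(directions) <- NULL
  ns <- nrow(directions)
  s <- list(excitations = data.frame(index = tab$index,
                                     time_ms = tab$time_ms,
                                     fov = tab$fov,
                                     spoke = rep(seq_len(ns), each = 2L)),
            directions = directions,
            gradient_scale = c(tab$gradient_scale[match(0L, tab$fov)],
                               tab$gradient_scale[match(1L, tab$fov)]),
            tr_pair = tab$time_ms[3] - tab$time_ms[1],
            volume_time_ms = ns * (tab$time_ms[3] - tab$time_ms[1]))
  class(s) <- "spoke_schedule"
  s
}
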