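#' Write an image series (or single volume) to NIfTI-1
#'
#' Data are stored as float64 so a read of our own write is lossless;
#' voxel size (mm) goes into the spatial pixdims and the volume TR (s)
#' into the fourth, with an RAS-diagonal qform.
#'
#' @param series an `image_series`, or a 3D/4D array (then `voxel_size`
#'   and `volume_tr` must be given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size,volume_tr metadata when `series` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(series, path, voxel_size = NULL, volume_tr = NULL) {
  if (inherits(series, "image_series")) {
    data <- series$data
    voxel_size <- series$voxel_size
    volume_tr <- series$volume_tr
  } else {
    data <- series
    if (is.null(voxel_size)) stop("voxel_size required for array input")
    if (is.null(volume_tr)) volume_tr <- 1
  }
  nd <- length(dim(data))
  if (!nd %in% c(3, 4)) stop("only 3D or 4D images are supported")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3), volume_tr)[seq_len(nd)]
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::qform(img) <- structure(diag(c(rep(voxel_size, 3), 1)), code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 image into an image series
#'
#' @param path NIfTI file path.
#' @return an `image_series` (4D; a 3D file gains a singleton time axis).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (!is.numeric(data))
    stop(sprintf("unsupported NIfTI datatype: %s", storage.mode(data)))
  data <- array(as.vector(data), dim = dim(data))  # strip niftiImage attrs
  pd <- RNifti::pixdim(img)
  nd <- length(dim(data))
  if (!nd %in% c(3, 4)) stop("only 3D or 4D NIfTI images are supported")
  if (nd == 3) data <- array(data, dim = c(dim(data), 1))
  image_series(data, voxel_size = pd[1],
               volume_tr = if (length(pd) >= 4) pd[4] else 1)
}

#' Write a stimulation paradigm as a 3-column onsets file
#'
#' Plain-text table: onset (s), duration (s), amplitude.
#'
#' @param par a [paradigm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(par, path) {
  tab <- data.frame(onset = paradigm_onsets(par),
                    duration = par$block_on,
                    amplitude = 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Persist / load a k-space stream
#'
#' The complex samples go to a raw binary file (interleaved real/imag
#' doubles, row-major by spoke) next to a plain-text YAML sidecar holding
#' the dimensions, trajectory reference and acquisition metadata.
#'
#' @param stream a `kspace_stream`.
#' @param path base path; `<path>.bin` and `<path>.yaml` are written.
#' @return base path (`write`), or the `kspace_stream` (`read`).
#' @export
write_kspace <- function(stream, path) {
  stopifnot(inherits(stream, "kspace_stream"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  m <- as.vector(t(stream$samples))  # sample-fastest on disk
  writeBin(as.vector(rbind(Re(m), Im(m))), con, size = 8)
  side <- list(n_spokes = nrow(stream$samples),
               n_samples = ncol(stream$samples),
               fov_index = stream$fov_index,
               matrix_size = stream$matrix_size,
               fov_size = stream$fov_size,
               n_volumes = stream$n_volumes,
               volume_tr = stream$volume_tr,
               noise_sd = stream$noise_sd,
               delta_k = stream$delta_k,
               directions = apply(stream$directions, 1, paste,
                                  collapse = " "))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  nsp <- side$n_spokes
  ns <- side$n_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "double", n = 2 * nsp * ns, size = 8)
  m <- matrix(raw, nrow = 2)
  samples <- t(matrix(complex(real = m[1, ], imaginary = m[2, ]),
                      nrow = ns, ncol = nsp))
  directions <- do.call(rbind, lapply(side$directions, function(s)
    as.numeric(strsplit(s, " ")[[1]])))
  kspace_stream(samples, directions, side$fov_index, side$matrix_size,
                side$fov_size, side$n_volumes, side$volume_tr,
                side$noise_sd)
}
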