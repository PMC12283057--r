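#' Object mask from a reconstructed series
#'
#' Threshold on the temporal-mean image, as done for real data where no
#' ground-truth support is available.
#'
#' @param series an `image_series` or 4D array.
#' @param frac threshold as a fraction of the mean image's maximum.
#' @return logical 3D array.
#' @export
object_mask_from_series <- function(series, frac = 0.2) {
  d <- series_data(series)
  m <- apply(d, 1:3, mean)
  m > frac * max(m)
}

#' Simulate, acquire and reconstruct one synthetic subject
#'
#' Ground-truth phantom rendering, interleaved dual-FOV radial sampling
#' with k-space noise, and per-volume FISTA reconstruction of both FOVs.
#'
#' @param config an [experiment_config()].
#' @param subject_seed integer seed identifying the subject.
#' @param verbose print stage progress.
#' @return list with `phantom`, `paradigm`, `irf`, `schedule`, `streams`
#'   (two `kspace_stream`s) and `recon` (two `image_series`).
#' @export
simulate_subject <- function(config, subject_seed = config$subjects[1],
                             verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  params <- config_build(config, "sequence")
  par <- config_build(config, "paradigm")
  irf <- config_build(config, "irf")
  phantom <- config_build(config, "phantom",
                          matrix_size = params$matrix_size,
                          seed = subject_seed)
  rp <- config_build(config, "recon")
  tr <- config$volume_tr
  if (verbose) message("rendering ground truth ...")
  truth <- render_truth_series(phantom, par, irf, tr,
                               n_volumes = params$n_volumes)
  dirs <- make_spoke_directions(params$n_spokes_per_volume)
  schedule <- make_dual_schedule(params, dirs)
  if (verbose) message("sampling k-space ...")
  streams <- acquire_dual(truth[[1]], truth[[2]], schedule, params,
                          noise_sd = phantom$noise_sd,
                          seed = subject_seed * 13L + 7L,
                          volume_tr = tr, exact = FALSE)
  if (verbose) message("reconstructing ...")
  recon <- lapply(streams, reconstruct_series, params = rp,
                  verbose = verbose)
  list(phantom = phantom, paradigm = par, irf = irf, schedule = schedule,
       truth = truth, streams = streams, recon = recon,
       sequence = params, subject_seed = subject_seed)
}

#' Preprocess one reconstructed FOV series
#'
#' The subject-level cleaning chain: centre-of-mass motion estimation,
#' translation motion correction to the first volume, spatial ICA,
#' automatic motion-component labelling (correlation and edge-fraction
#' rules) and regression of the motion components. High-pass filtering
#' and prewhitening are applied inside the GLM stage so that percent
#' signal change can be read from the cleaned (unfiltered) series.
#'
#' @param series an `image_series`.
#' @param params a [preproc_params()].
#' @param seed RNG seed for the ICA.
#' @param mask optional object mask; derived from the series when NULL.
#' @return list with `series` (cleaned), `mask`, `motion` (centre-of-mass
#'   trace of the uncorrected series), `correction` (registration trace),
#'   `components` (labelled `component_set`).
#' @export
preprocess_series <- function(series, params = preproc_params(), seed = 1L,
                              mask = NULL) {
  motion <- center_of_mass_motion(series)
  mc <- rigid_motion_correct(series)
  if (is.null(mask)) mask <- object_mask_from_series(mc$series)
  comps <- decompose_components(mc$series, params, seed = seed, mask = mask)
  comps <- classify_motion_components(comps, motion, mask, params)
  clean <- regress_out(mc$series, comps)
  list(series = clean, mask = mask, motion = motion,
       correction = mc$trace, components = comps)
}

#' Subject-level GLM on a cleaned series
#'
#' High-pass filters the series and the task regressor identically
#' (discrete-cosine basis), then fits the prewhitened voxelwise GLM and
#' extracts suprathreshold clusters.
#'
#' @param clean an `image_series` from [preprocess_series()].
#' @param mask logical 3D object mask.
#' @param par a [paradigm()].
#' @param irf an [irf_params()].
#' @param pp a [preproc_params()] (high-pass cutoff).
#' @param sp a [stats_params()] (cluster threshold).
#' @return list with `glm` (`glm_result`) and `clusters`.
#' @export
glm_subject <- function(clean, mask, par, irf = irf_params(),
                        pp = preproc_params(), sp = stats_params()) {
  tr <- clean$volume_tr
  nt <- dim(clean$data)[4]
  hp <- highpass(clean, tr, pp$highpass_cutoff)
  task <- task_response(par, irf, tr, n_volumes = nt)
  task_hp <- highpass(task, tr, pp$highpass_cutoff)
  design <- cbind(task = task_hp, intercept = 1)
  g <- fit_glm(hp, design, mask, prewhiten = TRUE)
  cl <- extract_clusters(g, mask, sp)
  list(glm = g, clusters = cl)
}

#' Run the full synthetic experiment
#'
#' For each subject seed: simulate, acquire, reconstruct, preprocess and
#' fit the subject-level GLM for both FOVs; with two or more subjects a
#' group-level sign-flip TFCE inference is run on the subject task-effect
#' maps, and per-subject peak latencies of the two FOVs are compared with
#' a paired t test. When `out_dir` is given, all stage outputs are
#' written (NIfTI images, TSV/CSV tables, YAML manifest).
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return list with per-subject results (`subjects`), `group` (or NULL),
#'   `latency` (per-subject latency table + paired test, or NULL) and
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  pp <- config_build(config, "preproc")
  sp <- config_build(config, "stats")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, subjects = config$subjects,
                   config = unclass(config), outputs = list())
  subjects <- list()
  for (ss in config$subjects) {
    if (verbose) message(sprintf("subject seed %d", ss))
    sim <- simulate_subject(config, ss, verbose = verbose)
    fovs <- list()
    for (f in 1:2) {
      prep <- preprocess_series(sim$recon[[f]], pp,
                                seed = ss * 101L + f)
      gl <- glm_subject(prep$series, prep$mask, sim$paradigm, sim$irf,
                        pp, sp)
      # percent signal change from the detected activation (largest
      # cluster), falling back to the ground-truth ROI if none found
      roi <- if (nrow(gl$clusters$table) > 0) gl$clusters$labels == 1L
             else sim$phantom$activation_masks[[f]]
      tc <- extract_timecourse(prep$series, roi, sim$paradigm)
      fovs[[f]] <- list(prep = prep, glm = gl$glm,
                        clusters = gl$clusters, timecourse = tc,
                        cluster_found = nrow(gl$clusters$table) > 0)
    }
    subj <- list(seed = ss, sim = sim, fov = fovs)
    if (!is.null(out_dir)) {
      sd <- file.path(out_dir, sprintf("subject-%d", ss))
      dir.create(sd, showWarnings = FALSE)
      for (f in 1:2) {
        tag <- sprintf("fov%d", f - 1)
        write_nifti(sim$recon[[f]], file.path(sd, paste0(tag, "_recon.nii.gz")))
        write_nifti(fovs[[f]]$prep$series,
                    file.path(sd, paste0(tag, "_clean.nii.gz")))
        write_nifti(array(fovs[[f]]$glm$z, dim = dim(fovs[[f]]$glm$z)),
                    file.path(sd, paste0(tag, "_zmap.nii.gz")),
                    voxel_size = sim$recon[[f]]$voxel_size, volume_tr = 1)
        utils::write.table(fovs[[f]]$prep$motion,
                           file.path(sd, paste0(tag, "_motion.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.csv(fovs[[f]]$prep$components$report,
                         file.path(sd, paste0(tag, "_components.csv")),
                         row.names = FALSE)
        utils::write.csv(fovs[[f]]$clusters$table,
                         file.path(sd, paste0(tag, "_clusters.csv")),
                         row.names = FALSE)
      }
      write_onsets(sim$paradigm, file.path(sd, "onsets.txt"))
      manifest$outputs[[sprintf("subject-%d", ss)]] <- list.files(sd)
    }
    subjects[[as.character(ss)]] <- subj
  }

  group <- NULL
  latency <- NULL
  if (length(subjects) >= 2) {
    if (verbose) message("group inference ...")
    group <- vector("list", 2L)
    for (f in 1:2) {
      maps <- lapply(subjects, function(s) {
        b <- s$fov[[f]]$glm$beta
        b[is.na(b)] <- 0
        b
      })
      masks <- lapply(subjects, function(s) s$fov[[f]]$prep$mask)
      gmask <- Reduce("&", masks)
      group[[f]] <- group_inference(maps, gmask, sp,
                                    seed = config$seed * 17L + f)
    }
    lat <- t(vapply(subjects, function(s)
      c(brain = s$fov[[1]]$timecourse$peak_latency_s,
        cord = s$fov[[2]]$timecourse$peak_latency_s), numeric(2)))
    latency <- list(per_subject = data.frame(seed = rownames(lat),
                                             brain = lat[, 1],
                                             cord = lat[, 2]),
                    test = compare_peak_latencies(lat[, 1], lat[, 2]))
    if (!is.null(out_dir)) {
      for (f in 1:2)
        write_nifti(group[[f]]$p_fwe,
                    file.path(out_dir, sprintf("group_fov%d_pfwe.nii.gz",
                                               f - 1)),
                    voxel_size = 1, volume_tr = 1)
      utils::write.csv(latency$per_subject,
                       file.path(out_dir, "latencies.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest$md5 <- as.list(tools::md5sum(files))
    names(manifest$md5) <- list.files(out_dir, recursive = TRUE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(subjects = subjects, group = group, latency = latency,
       manifest = manifest)
}
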