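# the standard synthetic case (validation profile), computed once and
# shared between the parameter-recovery and preprocessing-efficacy tests
.chain_cache <- new.env()

validation_chain <- function(subject_seed = 1L) {
  key <- as.character(subject_seed)
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  cfg <- experiment_profile("validation")
  pp <- do.call(preproc_params, cfg$preproc)
  sp <- do.call(stats_params, cfg$stats)
  sim <- simulate_subject(cfg, subject_seed = subject_seed)
  fov <- list()
  for (f in 1:2) {
    prep <- preprocess_series(sim$recon[[f]], pp,
                              seed = subject_seed * 101L + f)
    gl <- glm_subject(prep$series, prep$mask, sim$paradigm, sim$irf, pp, sp)
    roi_truth <- sim$phantom$activation_masks[[f]]
    roi <- if (nrow(gl$clusters$table) > 0) gl$clusters$labels == 1L
           else roi_truth
    gl0 <- glm_subject(sim$recon[[f]],
                       object_mask_from_series(sim$recon[[f]]),
                       sim$paradigm, sim$irf, pp, sp)
    fov[[f]] <- list(
      prep = prep, glm = gl$glm, clusters = gl$clusters,
      tc_cluster = extract_timecourse(prep$series, roi, sim$paradigm),
      tc_truth = extract_timecourse(prep$series, roi_truth, sim$paradigm),
      sens_with = mean(gl$glm$z[roi_truth] > sp$z_threshold),
      sens_without = mean(gl0$glm$z[roi_truth] > sp$z_threshold),
      residual_motion = max(abs(as.matrix(
        center_of_mass_motion(prep$series)[, c("dx", "dy", "dz")])))
    )
  }
  res <- list(sim = sim, fov = fov, pp = pp, sp = sp)
  .chain_cache[[key]] <- res
  res
}
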