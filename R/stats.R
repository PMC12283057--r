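#' Statistical-inference parameters
#'
#' @param z_threshold cluster-forming z threshold for subject-level maps.
#' @param alpha_fwe family-wise error level for group inference.
#' @param n_permutations number of sign-flip permutations at group level;
#'   `NULL` means exhaustive (`2^n`) when `n <= 12` subjects, else 1000.
#' @param tfce_e,tfce_h TFCE extent and height exponents.
#' @param tfce_dh TFCE integration step as a fraction of the map maximum.
#' @return an object of class `stats_params`.
#' @export
stats_params <- function(z_threshold = 3.1, alpha_fwe = 0.05,
                         n_permutations = NULL, tfce_e = 0.5, tfce_h = 2,
                         tfce_dh = 0.01) {
  stopifnot(alpha_fwe > 0, alpha_fwe < 1, tfce_e > 0, tfce_h > 0,
            tfce_dh > 0, tfce_dh <= 1)
  p <- list(z_threshold = z_threshold, alpha_fwe = alpha_fwe,
            n_permutations = n_permutations, tfce_e = tfce_e,
            tfce_h = tfce_h, tfce_dh = tfce_dh)
  class(p) <- "stats_params"
  p
}

#' GLM design matrix with the gamma-variate task regressor
#'
#' Task regressor: stimulation boxcar convolved with the gamma-variate
#' impulse response, sampled at volume times and unit-peak scaled;
#' an intercept column is appended (confounds are appended by the caller).
#'
#' @param par a [paradigm()].
#' @param irf an [irf_params()].
#' @param volume_tr volume repetition time, s.
#' @param n_volumes number of volumes.
#' @param confounds optional matrix of extra columns.
#' @return design matrix with columns `task`, `intercept`, confounds.
#' @export
build_design <- function(par, irf = irf_params(), volume_tr,
                         n_volumes = NULL, confounds = NULL) {
  task <- task_response(par, irf, volume_tr, n_volumes = n_volumes)
  X <- cbind(task = task, intercept = 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nrow(X))
      stop("confound rows do not match volume count")
    X <- cbind(X, confounds)
  }
  X
}

#' Voxelwise GLM with optional AR(1) prewhitening
#'
#' Ordinary least squares per voxel; with `prewhiten = TRUE` a per-voxel
#' AR(1) coefficient is estimated from first-pass residuals and both data
#' and design are quasi-differenced (single-pass Cochrane-Orcutt, first
#' sample dropped) before refitting. The task-effect t statistic is mapped
#' to a z statistic through the t CDF at the residual degrees of freedom.
#'
#' @param series an `image_series` or 4D array.
#' @param design design matrix from [build_design()]; column 1 is the
#'   effect of interest.
#' @param mask optional logical 3D array restricting the fit.
#' @param prewhiten estimate and remove AR(1) autocorrelation.
#' @param z_cap absolute bound applied to non-finite / overflowing z.
#' @return an object of class `glm_result`: `beta`, `se`, `t`, `z` (3D
#'   arrays, NA outside mask), `df`, `phi`, `design`, `mask`.
#' @export
fit_glm <- function(series, design, mask = NULL, prewhiten = TRUE,
                    z_cap = 50) {
  d <- series_data(series)
  dims <- dim(d)[1:3]
  nt <- dim(d)[4]
  X <- as.matrix(design)
  if (nrow(X) != nt) stop("design rows do not match volume count")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  mv <- as.vector(mask)
  Y <- series_to_matrix(d)[, mv, drop = FALSE]
  nvox <- ncol(Y)

  if (prewhiten) {
    beta0 <- solve(crossprod(X), crossprod(X, Y))
    res <- Y - X %*% beta0
    num <- colSums(res[-1, , drop = FALSE] * res[-nt, , drop = FALSE])
    den <- colSums(res^2)
    phi <- ifelse(den > 0, num / den, 0)
    phi <- pmax(pmin(phi, 0.99), -0.99)
    Y2 <- Y[-1, , drop = FALSE]
    Y1 <- Y[-nt, , drop = FALSE]
    X2 <- X[-1, , drop = FALSE]
    X1 <- X[-nt, , drop = FALSE]
    # per-voxel cross products are quadratic polynomials in phi
    A0 <- crossprod(X2)
    A1 <- crossprod(X2, X1) + crossprod(X1, X2)
    A2 <- crossprod(X1)
    B0 <- crossprod(X2, Y2)
    B1 <- crossprod(X1, Y2) + crossprod(X2, Y1)
    B2 <- crossprod(X1, Y1)
    C0 <- colSums(Y2^2)
    C1 <- colSums(Y2 * Y1)
    C2 <- colSums(Y1^2)
    df <- (nt - 1) - p
    beta <- se <- rep(NA_real_, nvox)
    for (v in seq_len(nvox)) {
      ph <- phi[v]
      XtX <- A0 - ph * A1 + ph^2 * A2
      XtY <- B0[, v] - ph * B1[, v] + ph^2 * B2[, v]
      yty <- C0[v] - 2 * ph * C1[v] + ph^2 * C2[v]
      XtXi <- solve(XtX)
      b <- XtXi %*% XtY
      rss <- max(0, yty - sum(b * XtY))
      beta[v] <- b[1]
      se[v] <- sqrt(rss / df * XtXi[1, 1])
    }
  } else {
    phi <- rep(0, nvox)
    df <- nt - p
    XtXi <- solve(crossprod(X))
    B <- XtXi %*% crossprod(X, Y)
    res <- Y - X %*% B
    rss <- pmax(0, colSums(res^2))
    beta <- B[1, ]
    se <- sqrt(rss / df * XtXi[1, 1])
  }
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  z <- sign(tstat) *
    stats::qnorm(stats::pt(abs(tstat), df, lower.tail = FALSE,
                           log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(z)] <- sign(tstat[!is.finite(z)]) * z_cap
  z[is.na(z)] <- 0
  z <- pmax(pmin(z, z_cap), -z_cap)

  put <- function(x) {
    a <- array(NA_real_, dim = dims)
    a[mv] <- x
    a
  }
  r <- list(beta = put(beta), se = put(se), t = put(tstat), z = put(z),
            df = df, phi = put(phi), design = X, mask = mask)
  class(r) <- "glm_result"
  r
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("GLM result: %d in-mask voxels, df = %d, max z = %.2f\n",
              sum(x$mask), x$df, max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Suprathreshold clusters of a z map
#'
#' 6-connected components of `{z > z_threshold}` within the mask, sorted
#' by size (descending). Centroids are 0-based voxel coordinates.
#'
#' @param zmap 3D z array or a `glm_result`.
#' @param mask optional logical 3D array.
#' @param params a [stats_params()].
#' @return list with `table` (data.frame: cluster, n_voxels, peak_z,
#'   mean_z, cx, cy, cz) and `labels` (3D integer array, 0 = background,
#'   relabelled in table order).
#' @export
extract_clusters <- function(zmap, mask = NULL, params = stats_params()) {
  if (inherits(zmap, "glm_result")) {
    if (is.null(mask)) mask <- zmap$mask
    zmap <- zmap$z
  }
  dims <- dim(zmap)
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  z <- zmap
  z[is.na(z)] <- -Inf
  supra <- (z > params$z_threshold) & mask
  lab <- array(cpp_label3d(as.vector(supra), dims), dim = dims)
  k <- max(lab)
  if (k == 0)
    return(list(table = data.frame(cluster = integer(0),
                                   n_voxels = integer(0),
                                   peak_z = numeric(0), mean_z = numeric(0),
                                   cx = numeric(0), cy = numeric(0),
                                   cz = numeric(0)),
                labels = lab))
  rows <- lapply(seq_len(k), function(i) {
    idx <- which(lab == i)
    co <- arrayInd(idx, dims) - 1L
    data.frame(cluster = i, n_voxels = length(idx), peak_z = max(z[idx]),
               mean_z = mean(z[idx]), cx = mean(co[, 1]), cy = mean(co[, 2]),
               cz = mean(co[, 3]))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$n_voxels, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  relab <- array(0L, dim = dims)
  for (i in seq_along(ord)) relab[lab == tab$cluster[i]] <- i
  tab$cluster <- seq_along(ord)
  rownames(tab) <- NULL
  list(table = tab, labels = relab)
}

#' Threshold-free cluster enhancement
#'
#' Brute-force TFCE: for thresholds `h` spaced `dh` (a fraction of the map
#' maximum) apart, each suprathreshold voxel accumulates
#' `extent(h, v)^E * h^H * dh`, with extent the 6-connected component size
#' at height `h`. Only positive values are enhanced; negative input is
#' treated as 0 (enhance the sign-flipped map separately for two-sided
#' use).
#'
#' @param statmap non-negative 3D statistic array (negatives zeroed).
#' @param mask optional logical 3D array; outside voxels are zeroed.
#' @param params a [stats_params()].
#' @return 3D array of enhanced values.
#' @export
tfce <- function(statmap, mask = NULL, params = stats_params()) {
  dims <- dim(statmap)
  s <- statmap
  s[is.na(s)] <- 0
  s[s < 0] <- 0
  if (!is.null(mask)) s[!mask] <- 0
  array(cpp_tfce(as.vector(s), dims, params$tfce_e, params$tfce_h,
                 params$tfce_dh), dim = dims)
}

#' Group-level sign-flip permutation inference with TFCE
#'
#' One-sample test across subject effect maps: the group statistic is the
#' TFCE-enhanced one-sample t map; family-wise-error-corrected p-values
#' come from the max-statistic distribution over sign-flip permutations
#' (exhaustive `2^n` flips when `n <= 12` subjects, else `n_permutations`
#' random flips including the identity).
#'
#' @param subject_maps list of 3D subject effect maps (or voxels x n
#'   matrix with `dims` attribute).
#' @param mask optional logical 3D array.
#' @param params a [stats_params()].
#' @param seed RNG seed (used only for non-exhaustive flips).
#' @return an object of class `group_result`: `p_fwe` (3D), `significant`
#'   (3D logical, `p < alpha_fwe`), `tfce_map`, `t_map`, `n_permutations`,
#'   `max_stats` (permutation max-statistic distribution).
#' @export
group_inference <- function(subject_maps, mask = NULL,
                            params = stats_params(), seed = 1L) {
  if (is.list(subject_maps)) {
    dims <- dim(subject_maps[[1]])
    M <- vapply(subject_maps, as.vector, numeric(prod(dims)))
  } else {
    M <- as.matrix(subject_maps)
    dims <- attr(subject_maps, "dims")
    if (is.null(dims)) stop("matrix input needs a dims attribute")
  }
  n <- ncol(M)
  if (n < 2) stop("group inference needs at least 2 subjects")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  mv <- as.vector(mask)
  M[!mv, ] <- 0

  exhaustive <- is.null(params$n_permutations) && n <= 12
  flips <- if (exhaustive) {
    f <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    t(f)
  } else {
    np <- if (is.null(params$n_permutations)) 1000L else
      as.integer(params$n_permutations)
    with_seed_local(seed, {
      f <- matrix(sample(c(1, -1), n * np, replace = TRUE), n, np)
      f[, 1] <- 1
      f
    })
  }
  np <- ncol(flips)
  ss <- rowSums(M^2)
  tmap_for <- function(s) {
    m <- as.vector(M %*% s) / n
    va <- pmax(0, (ss - n * m^2) / (n - 1))
    se <- sqrt(va / n)
    tt <- ifelse(se > 0, m / se, 0)
    tt
  }
  # observed statistic = identity flip
  t_obs <- tmap_for(rep(1, n))
  tf_obs <- tfce(array(t_obs, dim = dims), mask, params)
  max_stats <- numeric(np)
  for (i in seq_len(np)) {
    tp <- tmap_for(flips[, i])
    tfp <- cpp_tfce(pmax(tp * mv, 0), dims, params$tfce_e, params$tfce_h,
                    params$tfce_dh)
    max_stats[i] <- max(tfp)
  }
  pv <- vapply(as.vector(tf_obs), function(v) mean(max_stats >= v),
               numeric(1))
  p_fwe <- array(pv, dim = dims)
  p_fwe[!mask] <- 1
  res <- list(p_fwe = p_fwe,
              significant = (p_fwe < params$alpha_fwe) & mask,
              tfce_map = tf_obs,
              t_map = array(t_obs, dim = dims),
              n_permutations = np,
              exhaustive = exhaustive,
              max_stats = max_stats,
              n_subjects = n)
  class(res) <- "group_result"
  res
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "group inference: n = %d, %d %s sign-flips, %d significant voxel(s)\n",
    x$n_subjects, x$n_permutations,
    if (x$exhaustive) "exhaustive" else "random", sum(x$significant)))
  invisible(x)
}

#' ROI percent-signal-change time course, block average and peak latency
#'
#' ROI mean time course normalised to the initial-rest baseline (mean over
#' volumes acquired before the first stimulation block), in percent;
#' block-triggered average over the stimulation blocks. Peak latency is
#' measured at volume-TR resolution as the mean lag over the block
#' average's near-peak region (values within 80 % of the maximum): for a
#' single-peaked curve this is the argmax, while for responses that
#' saturate into a plateau (a boxcar much longer than the impulse
#' response) it stays well defined under noise, and a pure latency shift
#' moves it by exactly that shift.
#'
#' @param series an `image_series` or 4D array.
#' @param cluster_mask logical 3D array (non-empty).
#' @param par a [paradigm()].
#' @param volume_tr volume repetition time, s (from the `image_series`
#'   when omitted).
#' @return list with `time` (s), `psc` (percent), `block` (data.frame:
#'   `lag_s`, `mean_psc`), `peak_latency_s`, `peak_psc`.
#' @export
extract_timecourse <- function(series, cluster_mask, par = paradigm(),
                               volume_tr = NULL) {
  if (inherits(series, "image_series") && is.null(volume_tr))
    volume_tr <- series$volume_tr
  if (is.null(volume_tr)) stop("volume_tr required")
  d <- series_data(series)
  if (!any(cluster_mask)) stop("cluster mask is empty")
  nt <- dim(d)[4]
  Y <- series_to_matrix(d)[, as.vector(cluster_mask), drop = FALSE]
  ts <- rowMeans(Y)
  n_rest <- max(1, floor(par$initial_rest / volume_tr))
  base <- mean(ts[seq_len(min(n_rest, nt))])
  if (base == 0) stop("zero baseline in ROI")
  psc <- 100 * (ts / base - 1)
  tt <- (seq_len(nt) - 1) * volume_tr

  onsets <- paradigm_onsets(par)
  win <- floor((par$block_on + par$block_off) / volume_tr)
  segs <- lapply(onsets, function(on) {
    i0 <- which.min(abs(tt - on))
    idx <- i0 + 0:(win - 1)
    idx <- idx[idx <= nt]
    c(psc[idx], rep(NA, win - length(idx)))
  })
  block_mean <- rowMeans(do.call(cbind, segs), na.rm = TRUE)
  lag_s <- (0:(win - 1)) * volume_tr
  pk <- which.max(block_mean)
  near_peak <- block_mean >= 0.8 * block_mean[pk] &
    sign(block_mean) == sign(block_mean[pk])
  list(time = tt, psc = psc,
       block = data.frame(lag_s = lag_s, mean_psc = block_mean),
       peak_latency_s = mean(lag_s[near_peak]),
       peak_psc = block_mean[pk])
}

#' Paired comparison of per-subject peak latencies
#'
#' Paired t test on per-subject peak-latency differences between the two
#' FOVs.
#'
#' @param latencies_a,latencies_b paired per-subject latency vectors, s.
#' @return list with `t`, `df`, `p_value`, `mean_difference`; when the
#'   differences have zero variance the t statistic is undefined and the
#'   limit p (0 for a nonzero shared difference, 1 otherwise) is reported
#'   with a warning.
#' @export
compare_peak_latencies <- function(latencies_a, latencies_b) {
  stopifnot(length(latencies_a) == length(latencies_b),
            length(latencies_a) >= 2)
  dd <- latencies_b - latencies_a
  if (stats::sd(dd) == 0) {
    warning("zero variance of paired differences; p reported as limit case")
    return(list(t = NA_real_, df = length(dd) - 1,
                p_value = if (mean(dd) == 0) 1 else 0,
                mean_difference = mean(dd)))
  }
  ht <- stats::t.test(latencies_b, latencies_a, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(dd))
}
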