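#' Preprocessing parameters
#'
#' @param n_components number of spatial ICA components.
#' @param motion_corr_threshold component-vs-motion correlation above which
#'   (strictly) a component is labelled motion.
#' @param edge_fraction_threshold fraction of a component's suprathreshold
#'   map voxels on the object edge / outside above which (strictly) it is
#'   labelled motion.
#' @param highpass_cutoff temporal high-pass cutoff, Hz.
#' @param edge_width edge-shell width in voxels.
#' @param ar_order autoregressive order for prewhitening (AR(1) used).
#' @param map_z_threshold |z| threshold defining a component's
#'   suprathreshold spatial-map voxels.
#' @return an object of class `preproc_params`.
#' @export
preproc_params <- function(n_components = 15, motion_corr_threshold = 0.75,
                           edge_fraction_threshold = 0.70,
                           highpass_cutoff = 0.01, edge_width = 1,
                           ar_order = 1, map_z_threshold = 2) {
  stopifnot(n_components >= 1,
            motion_corr_threshold >= 0, motion_corr_threshold <= 1,
            edge_fraction_threshold >= 0, edge_fraction_threshold <= 1,
            highpass_cutoff > 0, edge_width >= 0, ar_order >= 1)
  p <- list(n_components = as.integer(n_components),
            motion_corr_threshold = motion_corr_threshold,
            edge_fraction_threshold = edge_fraction_threshold,
            highpass_cutoff = highpass_cutoff,
            edge_width = as.integer(edge_width),
            ar_order = as.integer(ar_order),
            map_z_threshold = map_z_threshold)
  class(p) <- "preproc_params"
  p
}

series_data <- function(series) {
  if (inherits(series, "image_series")) series$data else series
}

series_like <- function(series, data) {
  if (inherits(series, "image_series")) {
    series$data <- data
    series
  } else data
}

#' Centre-of-mass motion estimate
#'
#' Per-volume intensity-weighted centroid displacement relative to the
#' first volume, in voxels, along each axis.
#'
#' @param series an `image_series` or 4D array.
#' @return data.frame with columns `volume`, `dx`, `dy`, `dz`.
#' @export
center_of_mass_motion <- function(series) {
  d <- series_data(series)
  nt <- dim(d)[4]
  n <- dim(d)[1:3]
  gx <- seq_len(n[1]) - 1
  gy <- seq_len(n[2]) - 1
  gz <- seq_len(n[3]) - 1
  com <- matrix(0, nt, 3)
  for (v in seq_len(nt)) {
    vol <- abs(d[, , , v])
    s <- sum(vol)
    if (s == 0) stop(sprintf("volume %d is all zero: centroid undefined", v))
    com[v, 1] <- sum(apply(vol, 1, sum) * gx) / s
    com[v, 2] <- sum(apply(vol, 2, sum) * gy) / s
    com[v, 3] <- sum(apply(vol, 3, sum) * gz) / s
  }
  data.frame(volume = seq_len(nt) - 1L,
             dx = com[, 1] - com[1, 1],
             dy = com[, 2] - com[1, 2],
             dz = com[, 3] - com[1, 3])
}

# translate a 3D volume by a (possibly fractional) shift via Fourier phase
fourier_shift3d <- function(vol, shift) {
  d <- dim(vol)
  f <- stats::fft(vol)
  for (ax in 1:3) {
    if (shift[ax] == 0) next
    freq <- c(0:(d[ax] %/% 2), -((d[ax] - d[ax] %/% 2 - 1):1)) / d[ax]
    if (d[ax] %% 2 == 0) freq[d[ax] / 2 + 1] <- d[ax] %/% 2 / d[ax]
    ph <- exp(-2i * pi * freq * shift[ax])
    per <- c(ax, setdiff(1:3, ax))
    f <- aperm(aperm(f, per) * ph, order(per))
  }
  Re(stats::fft(f, inverse = TRUE)) / prod(d)
}

#' Rigid (translation) motion correction to the first volume
#'
#' Estimates per-volume translation by FFT cross-correlation with the
#' first volume (integer peak plus per-axis parabolic sub-voxel
#' refinement) and resamples each volume by Fourier-shift interpolation.
#' Rotations are not estimated and reported as 0. Volumes whose peak
#' normalised correlation is below `min_corr` are flagged and passed
#' through uncorrected.
#'
#' @param series an `image_series` or 4D array.
#' @param min_corr registration-failure threshold on the peak normalised
#'   correlation.
#' @return list with `series` (corrected, same type as input), `trace`
#'   (data.frame: volume, tx, ty, tz, rx, ry, rz, flagged), where t* are
#'   the estimated displacements (voxels) that were removed.
#' @export
rigid_motion_correct <- function(series, min_corr = 0.2) {
  d <- series_data(series)
  nt <- dim(d)[4]
  if (nt < 2) stop("need at least 2 volumes")
  dims <- dim(d)[1:3]
  ref <- d[, , , 1]
  fref <- stats::fft(ref)
  nref <- sqrt(sum(ref^2))
  out <- d
  tr <- matrix(0, nt, 3)
  flagged <- logical(nt)
  for (v in 2:nt) {
    vol <- d[, , , v]
    cc <- Re(stats::fft(fref * Conj(stats::fft(vol)), inverse = TRUE)) /
      prod(dims)
    pk <- which.max(cc)
    idx <- arrayInd(pk, dims) - 1L
    peak_corr <- cc[pk] / (nref * sqrt(sum(vol^2)))
    if (!is.finite(peak_corr) || peak_corr < min_corr) {
      flagged[v] <- TRUE
      next
    }
    shift <- numeric(3)
    for (ax in 1:3) {
      i0 <- idx[ax]
      im <- (i0 - 1) %% dims[ax]
      ip <- (i0 + 1) %% dims[ax]
      sel <- function(i) {
        j <- idx
        j[ax] <- i
        cc[matrix(j + 1L, 1)]
      }
      ym <- sel(im); y0 <- sel(i0); yp <- sel(ip)
      denom <- ym - 2 * y0 + yp
      frac <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
      frac <- max(-0.5, min(0.5, frac))
      s <- i0 + frac
      if (s > dims[ax] / 2) s <- s - dims[ax]
      shift[ax] <- s
    }
    # cross-correlation peaks at minus the object displacement
    shift <- -shift
    tr[v, ] <- shift
    out[, , , v] <- fourier_shift3d(vol, -shift)
  }
  res <- data.frame(volume = seq_len(nt) - 1L,
                    tx = tr[, 1], ty = tr[, 2], tz = tr[, 3],
                    rx = 0, ry = 0, rz = 0, flagged = flagged)
  list(series = series_like(series, out), trace = res)
}

#' Spatial ICA decomposition of a 4D series
#'
#' Per-voxel demeaning, PCA reduction to `n_components`, then FastICA
#' (symmetric orthogonalisation, tanh contrast) on the whitened spatial
#' maps. Components are variance-normalised, ordered by explained temporal
#' variance, and sign-fixed so each map's largest-magnitude voxel is
#' positive. Deterministic for a fixed seed.
#'
#' @param series an `image_series` or 4D array.
#' @param params a [preproc_params()] (uses `n_components`).
#' @param seed RNG seed for the ICA initialisation.
#' @param mask optional object mask; when given, the decomposition is
#'   restricted to the mask dilated by two voxels (the analysis region a
#'   brain-masked ICA would use), and map values outside that region are
#'   zero.
#' @param max_iter,tol FastICA iteration controls.
#' @return an object of class `component_set`: `maps` (voxels x r matrix),
#'   `time_courses` (T x r, unit variance), `dims` (spatial), `labels`
#'   (filled by [classify_motion_components()]), `analysis_mask`.
#' @export
decompose_components <- function(series, params = preproc_params(),
                                 seed = 1L, mask = NULL, max_iter = 200,
                                 tol = 1e-6) {
  d <- series_data(series)
  dims <- dim(d)[1:3]
  nt <- dim(d)[4]
  r <- params$n_components
  if (nt <= r) stop("need more volumes than components")
  analysis <- if (is.null(mask)) array(TRUE, dim = dims) else
    dilate_mask(mask, 2L)
  av <- as.vector(analysis)
  X <- series_to_matrix(d)[, av, drop = FALSE]  # T x V (analysis region)
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = min(nt, 50), nv = 0)
  pos <- sv$d > max(sv$d) * 1e-10
  if (sum(pos) < r) {
    warning(sprintf("rank %d < %d components; reducing", sum(pos), r))
    r <- sum(pos)
  }
  U <- sv$u[, seq_len(r), drop = FALSE]
  D <- sv$d[seq_len(r)]
  V <- crossprod(X, U) %*% diag(1 / D, r)       # V x r, orthonormal cols
  nv <- nrow(V)
  Z <- t(V) * sqrt(nv)                          # r x V, unit-variance rows

  W <- with_seed_local(seed, {
    w0 <- matrix(stats::rnorm(r * r), r, r)
    qr.Q(qr(w0))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- rowMeans(1 - G^2)
    W_new <- (G %*% t(Z)) / nv - diag(Gp, r) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S <- W %*% Z                                  # r x V spatial sources
  # time courses by projection (S rows orthonormal up to 1/sqrt(V))
  TC <- X %*% t(S) / nv                         # T x r
  # order by explained variance, fix signs via map extremum
  ord <- order(colSums(TC^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  TC <- TC[, ord, drop = FALSE]
  for (i in seq_len(r)) {
    sgn <- sign(S[i, which.max(abs(S[i, ]))])
    if (sgn < 0) {
      S[i, ] <- -S[i, ]
      TC[, i] <- -TC[, i]
    }
  }
  tc_sd <- apply(TC, 2, stats::sd)
  tc_sd[tc_sd == 0] <- 1
  TC <- sweep(TC, 2, tc_sd, "/")
  maps_full <- matrix(0, prod(dims), r)
  maps_full[av, ] <- t(S)
  cs <- list(maps = maps_full, time_courses = TC, dims = dims,
             n_components = r, labels = rep(NA_character_, r),
             analysis_mask = analysis)
  class(cs) <- "component_set"
  cs
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component set: %d components on %dx%dx%d grid",
              x$n_components, x$dims[1], x$dims[2], x$dims[3]))
  if (!all(is.na(x$labels)))
    cat(sprintf(" (%d labelled motion)", sum(x$labels == "motion")))
  cat("\n")
  invisible(x)
}

# dilate a logical 3D mask by `width` 6-neighbourhood steps
dilate_mask <- function(mask, width = 1L) {
  !erode_mask(!mask, width)
}

# erode a logical 3D mask by one 6-neighbourhood step, `width` times
erode_mask <- function(mask, width = 1L) {
  m <- mask
  d <- dim(m)
  for (w in seq_len(width)) {
    res <- m
    for (ax in 1:3) {
      # neighbour along +ax and -ax with FALSE padding
      perm <- c(ax, setdiff(1:3, ax))
      mp <- aperm(m, perm)
      n1 <- dim(mp)[1]
      fwd <- mp[c(2:n1, n1), , , drop = FALSE]
      fwd[n1, , ] <- FALSE
      bwd <- mp[c(1, 1:(n1 - 1)), , , drop = FALSE]
      bwd[1, , ] <- FALSE
      res <- res & aperm(fwd, order(perm)) & aperm(bwd, order(perm))
    }
    m <- res
  }
  m
}

#' Label motion components
#'
#' A component is labelled `"motion"` iff (1) the maximum absolute Pearson
#' correlation of its time course with any of the three centre-of-mass
#' motion traces strictly exceeds `motion_corr_threshold`, or (2) the
#' fraction of its suprathreshold spatial-map voxels (|z| above
#' `map_z_threshold`) lying within `edge_width` voxels of the object-mask
#' boundary or outside the mask strictly exceeds
#' `edge_fraction_threshold`. An empty suprathreshold map makes
#' criterion 2 false.
#'
#' @param components a [decompose_components()] result.
#' @param motion data.frame from [center_of_mass_motion()] (columns
#'   dx/dy/dz) or a numeric matrix of motion parameters (columns).
#' @param object_mask logical 3D array of the imaged object.
#' @param params a [preproc_params()].
#' @return the `component_set` with `labels` filled and a `report`
#'   data.frame attached (`component`, `max_abs_corr`, `edge_fraction`,
#'   `label`).
#' @export
classify_motion_components <- function(components, motion, object_mask,
                                       params = preproc_params()) {
  stopifnot(inherits(components, "component_set"))
  mo <- if (is.data.frame(motion))
    as.matrix(motion[, c("dx", "dy", "dz")]) else as.matrix(motion)
  if (nrow(mo) != nrow(components$time_courses))
    stop("motion trace length does not match component time courses")
  edge_or_out <- !erode_mask(object_mask, params$edge_width)
  analysis <- if (!is.null(components$analysis_mask))
    as.vector(components$analysis_mask) else rep(TRUE, prod(components$dims))
  r <- components$n_components
  maxcor <- numeric(r)
  edgefrac <- numeric(r)
  for (i in seq_len(r)) {
    tc <- components$time_courses[, i]
    cors <- suppressWarnings(apply(mo, 2, function(m)
      if (stats::sd(m) == 0) 0 else abs(stats::cor(tc, m))))
    maxcor[i] <- max(cors, na.rm = TRUE)
    map <- components$maps[analysis, i]
    zmap <- (map - mean(map)) / stats::sd(map)
    supra <- abs(zmap) > params$map_z_threshold
    edgefrac[i] <- if (!any(supra)) 0 else
      sum(supra & as.vector(edge_or_out)[analysis]) / sum(supra)
  }
  lab <- ifelse(maxcor > params$motion_corr_threshold |
                  edgefrac > params$edge_fraction_threshold,
                "motion", "signal")
  components$labels <- lab
  components$report <- data.frame(component = seq_len(r),
                                  max_abs_corr = maxcor,
                                  edge_fraction = edgefrac,
                                  label = lab)
  components
}

#' Regress motion components out of a series
#'
#' Voxelwise least-squares projection removing the motion-labelled
#' component time courses (plus an intercept); voxel means are restored so
#' baseline levels are preserved. Identity when no component is labelled
#' motion.
#'
#' @param series an `image_series` or 4D array.
#' @param components a labelled `component_set` (or a T x k matrix of
#'   regressors to remove).
#' @return the cleaned series (same type as input).
#' @export
regress_out <- function(series, components) {
  d <- series_data(series)
  tc <- if (inherits(components, "component_set")) {
    if (all(is.na(components$labels)))
      stop("components are unlabelled; run classify_motion_components()")
    components$time_courses[, components$labels == "motion", drop = FALSE]
  } else as.matrix(components)
  if (ncol(tc) == 0) return(series)
  Y <- series_to_matrix(d)
  mu <- colMeans(Y)
  X <- cbind(1, tc)
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X %*% beta
  res <- sweep(res, 2, mu, "+")
  series_like(series, matrix_to_series(res, dim(d)[1:3]))
}

#' Temporal high-pass filter (discrete-cosine basis regression)
#'
#' Removes per-voxel the discrete cosine basis functions with frequency
#' below `cutoff` (drift terms); voxel means are restored. The same filter
#' should be applied to GLM regressors so task amplitude estimates remain
#' unbiased when task energy lies near the cutoff.
#'
#' @param series an `image_series`, 4D array, a T x V matrix, or a vector.
#' @param volume_tr volume repetition time, s (taken from an
#'   `image_series` when omitted).
#' @param cutoff high-pass cutoff, Hz; must be below the Nyquist frequency
#'   `1 / (2 volume_tr)`.
#' @return filtered object of the same type.
#' @export
highpass <- function(series, volume_tr = NULL, cutoff = 0.01) {
  if (inherits(series, "image_series") && is.null(volume_tr))
    volume_tr <- series$volume_tr
  if (is.null(volume_tr)) stop("volume_tr required")
  if (cutoff >= 1 / (2 * volume_tr))
    stop("cutoff must be below the Nyquist frequency")
  vec <- !inherits(series, "image_series") && is.null(dim(series))
  d <- series_data(series)
  Y <- if (vec) matrix(series, ncol = 1) else
    if (length(dim(d)) == 4) series_to_matrix(d) else as.matrix(d)
  nt <- nrow(Y)
  K <- floor(2 * nt * volume_tr * cutoff)
  if (K >= 1) {
    t_idx <- seq_len(nt) - 0.5
    D <- sapply(seq_len(K), function(k) cos(pi * k * t_idx / nt))
    D <- as.matrix(D)
    mu <- colMeans(Y)
    X <- cbind(1, D)
    beta <- solve(crossprod(X), crossprod(X, Y))
    Y <- Y - X %*% beta
    Y <- sweep(Y, 2, mu, "+")
  }
  if (vec) return(as.vector(Y))
  if (length(dim(d)) == 4)
    series_like(series, matrix_to_series(Y, dim(d)[1:3]))
  else Y
}

#' Gain of the high-pass filter for a given regressor
#'
#' RMS amplitude of the demeaned regressor after filtering relative to
#' before; quantifies task-signal attenuation when the paradigm's
#' fundamental frequency lies near or below the cutoff.
#'
#' @param x regressor vector.
#' @param volume_tr sampling interval, s.
#' @param cutoff high-pass cutoff, Hz.
#' @return scalar gain in `[0, 1]`.
#' @export
highpass_gain <- function(x, volume_tr, cutoff = 0.01) {
  x0 <- x - mean(x)
  if (all(x0 == 0)) return(1)
  xf <- highpass(x, volume_tr, cutoff)
  xf <- xf - mean(xf)
  sqrt(sum(xf^2) / sum(x0^2))
}

#' AR(1) prewhitening (single-pass Cochrane-Orcutt)
#'
#' Estimates a per-voxel AR(1) coefficient from the residuals of an OLS
#' fit to `design`, then returns the quasi-differenced series
#' (`y*_t = y_t - phi y_{t-1}`, first sample scaled by `sqrt(1 - phi^2)`).
#' Coefficients with `|phi| >= 1` are clipped to 0.99 with a warning.
#'
#' @param series an `image_series`, 4D array or T x V matrix.
#' @param design design matrix used to form residuals (default: intercept
#'   only).
#' @param ar_order autoregressive order; only 1 is implemented.
#' @return list with `series` (whitened, same type) and `phi` (per-voxel
#'   coefficients).
#' @export
prewhiten <- function(series, design = NULL, ar_order = 1) {
  if (ar_order != 1) stop("only AR(1) prewhitening is implemented")
  d <- series_data(series)
  Y <- if (length(dim(d)) == 4) series_to_matrix(d) else as.matrix(d)
  nt <- nrow(Y)
  if (nt < 10) stop("need at least 10 volumes")
  X <- if (is.null(design)) matrix(1, nt, 1) else as.matrix(design)
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X %*% beta
  num <- colSums(res[-1, , drop = FALSE] * res[-nt, , drop = FALSE])
  den <- colSums(res^2)
  phi <- ifelse(den > 0, num / den, 0)
  if (any(abs(phi) >= 1)) {
    warning("AR(1) coefficient(s) clipped to 0.99")
    phi <- pmax(pmin(phi, 0.99), -0.99)
  }
  Yw <- Y
  Yw[1, ] <- sqrt(1 - phi^2) * Y[1, ]
  Yw[-1, ] <- Y[-1, , drop = FALSE] -
    sweep(Y[-nt, , drop = FALSE], 2, phi, "*")
  out <- if (length(dim(d)) == 4)
    series_like(series, matrix_to_series(Yw, dim(d)[1:3])) else Yw
  list(series = out, phi = phi)
}
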