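static_series <- function(n = 12, nt = 12, seed = 9) {
  ph <- ball_phantom(n, seed = seed)
  array(rep(ph, nt), dim = c(n, n, n, nt))
}

shifted_series <- function(n = 16, nt = 12, shift = c(0, 0, 2), at = 6) {
  ph <- ball_phantom(n, radius = 0.3)   # keeps shifted object off the edges
  s <- array(rep(ph, nt), dim = c(n, n, n, nt))
  sh <- function(a, k) {
    idx <- lapply(1:3, function(ax)
      ((seq_len(dim(a)[ax]) - 1 - k[ax]) %% dim(a)[ax]) + 1)
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  for (v in at:nt) s[, , , v] <- sh(ph, shift)
  s
}

test_that("centre-of-mass trace detects injected displacement", {
  s <- static_series()
  tr <- center_of_mass_motion(s)
  expect_true(all(abs(as.matrix(tr[, c("dx", "dy", "dz")])) < 1e-12))
  # scale invariance
  tr2 <- center_of_mass_motion(s * 7)
  expect_equal(tr, tr2)
  sm <- shifted_series()
  trm <- center_of_mass_motion(sm)
  expect_equal(trm$dz[6:12], rep(2, 7), tolerance = 0.05)
  expect_equal(trm$dz[1:5], rep(0, 5), tolerance = 1e-9)
  s0 <- s
  s0[, , , 3] <- 0
  expect_error(center_of_mass_motion(s0), "zero")
})

test_that("translation correction removes injected motion", {
  sm <- shifted_series(shift = c(-2, 1, 2))
  mc <- rigid_motion_correct(sm)
  resid <- center_of_mass_motion(mc$series)
  expect_lt(max(abs(as.matrix(resid[, c("dx", "dy", "dz")]))), 0.2)
  expect_equal(mc$trace$tz[6:12], rep(2, 7), tolerance = 0.1)
  expect_true(all(mc$trace[, c("rx", "ry", "rz")] == 0))
  # the relative-motion summary (max |trace|) improves
  before <- max(abs(as.matrix(center_of_mass_motion(sm)[, 2:4])))
  after <- max(abs(as.matrix(resid[, 2:4])))
  expect_lt(after, before)
  # identity on a motion-free series
  s <- static_series()
  mc0 <- rigid_motion_correct(s)
  expect_lt(max(abs(mc0$series - s)), 1e-6 * diff(range(s)))
})

test_that("ICA recovers planted orthogonal spatiotemporal sources", {
  dims <- c(8, 8, 8)
  nt <- 60
  m1 <- array(0, dims); m1[2:4, 2:4, 2:4] <- 1
  m2 <- array(0, dims); m2[6:8, 6:8, 6:8] <- 1
  tc1 <- sin(2 * pi * (1:nt) / 10)
  tc2 <- rep(c(1, -1), nt / 2)
  s <- planted_series(dims, nt, list(list(map = m1, tc = tc1),
                                     list(map = m2, tc = tc2)))
  cs <- decompose_components(s, preproc_params(n_components = 2), seed = 1)
  match_cor <- sapply(list(tc1, tc2), function(tc)
    max(abs(stats::cor(cs$time_courses, tc))))
  expect_true(all(match_cor > 0.95))
  # determinism
  cs2 <- decompose_components(s, preproc_params(n_components = 2), seed = 1)
  expect_identical(cs$maps, cs2$maps)
  # full-rank decomposition reconstructs the demeaned data
  nt2 <- 14
  s2 <- planted_series(dims, nt2, list(list(map = m1, tc = sin(1:nt2))),
                       seed = 8)
  r <- nt2 - 1
  cs3 <- decompose_components(s2, preproc_params(n_components = r), seed = 2)
  X <- t(apply(s2, 4, as.vector))
  Xc <- sweep(X, 2, colMeans(X))
  # project Xc onto the component time courses: full rank -> lossless
  Tc <- cs3$time_courses
  fit <- Tc %*% solve(crossprod(Tc), crossprod(Tc, Xc))
  expect_lt(max(abs(fit - Xc)), 1e-6 * max(abs(Xc)))
  expect_error(decompose_components(s2, preproc_params(n_components = 20)),
               "more volumes")
})

test_that("motion-component rules use strict 0.75 / 0.70 thresholds", {
  dims <- c(8, 8, 8)
  nt <- 40
  mask <- array(FALSE, dims)
  mask[2:7, 2:7, 2:7] <- TRUE
  motion <- data.frame(dx = numeric(nt), dy = numeric(nt),
                       dz = sin(1:nt))
  # hand-built component set (bypasses ICA): 3 planted components
  core <- array(FALSE, dims); core[4:5, 4:5, 4:5] <- TRUE
  ring <- mask & !dualswift:::erode_mask(mask, 1L)
  # sparse edge component: suprathreshold voxels all on the shell/outside
  set.seed(3)
  edge_vox <- sample(which(as.vector(ring | !mask)), 25)
  edge_map <- rep(0, prod(dims))
  edge_map[edge_vox] <- 1
  sparse_core <- rep(0, prod(dims))
  sparse_core[sample(which(as.vector(core)), 8)] <- 1
  mk_sparse <- function(ind) ind * 10 + stats::rnorm(prod(dims), sd = 0.1)
  maps <- cbind(mk_sparse(sparse_core), mk_sparse(sparse_core),
                mk_sparse(edge_map))
  tcs <- cbind(motion$dz,                       # |r| = 1 -> motion
               0.75 * scale(motion$dz) + sqrt(1 - 0.75^2) *
                 scale(stats::rnorm(nt)),       # tuned below to r = 0.75
               stats::rnorm(nt))                # r ~ 0, edge map -> motion
  # make column 2 correlate with dz at exactly 0.75
  e <- stats::residuals(stats::lm(stats::rnorm(nt) ~ motion$dz))
  z1 <- as.vector(scale(motion$dz))
  z2 <- as.vector(scale(e))
  tcs[, 2] <- 0.75 * z1 + sqrt(1 - 0.75^2) * z2
  cs <- structure(list(maps = maps, time_courses = tcs, dims = dims,
                       n_components = 3,
                       labels = rep(NA_character_, 3)),
                  class = "component_set")
  cs <- classify_motion_components(cs, motion, mask, preproc_params())
  expect_equal(cs$report$max_abs_corr[1], 1, tolerance = 1e-12)
  expect_equal(cs$report$max_abs_corr[2], 0.75, tolerance = 1e-9)
  expect_equal(cs$labels, c("motion", "signal", "motion"))
  # |r| = 0.75 exactly is NOT motion (strict inequality), edge rule fired
  expect_gt(cs$report$edge_fraction[3], 0.70)
  expect_lt(cs$report$edge_fraction[1], 0.70)
})

test_that("motion regression removes regressors and nothing else", {
  dims <- c(6, 6, 6)
  nt <- 30
  m <- array(1, dims)
  tc <- sin(1:nt)
  s <- planted_series(dims, nt, list(list(map = m, tc = tc)))
  cs <- structure(list(maps = matrix(as.vector(m)), time_courses =
                         matrix(tc / stats::sd(tc)), dims = dims,
                       n_components = 1, labels = "motion"),
                  class = "component_set")
  clean <- regress_out(s, cs)
  Y <- t(apply(clean, 4, as.vector))
  cors <- abs(stats::cor(Y, tc))
  expect_lt(max(cors, na.rm = TRUE), 1e-10)
  # idempotence
  clean2 <- regress_out(clean, cs)
  expect_lt(max(abs(clean2 - clean)), 1e-10 * max(abs(clean)))
  # voxel means preserved
  expect_equal(apply(clean, 1:3, mean), apply(s, 1:3, mean),
               tolerance = 1e-10)
  # no motion components: identity
  cs$labels <- "signal"
  expect_identical(regress_out(s, cs), s)
})

test_that("DCT high-pass removes drift and passes band signal", {
  nt <- 248
  tr <- 3
  drift <- seq(0, 1, length.out = nt)
  filt <- highpass(drift, tr, 0.01)
  expect_lt(stats::sd(filt), 0.05 * stats::sd(drift))
  s05 <- sin(2 * pi * 0.05 * (0:(nt - 1)) * tr)
  expect_gt(highpass_gain(s05, tr, 0.01), 0.99)
  # the paradigm fundamental (~0.0088 Hz) is below the cutoff: the filter
  # attenuates task energy, and the gain quantifies by how much
  task <- task_response(paradigm(), irf_params(), tr)
  g <- highpass_gain(task, tr, 0.01)
  expect_lt(g, 0.9)
  expect_gt(g, 0.2)
  expect_error(highpass(drift, tr, cutoff = 0.2), "Nyquist")
})

test_that("AR(1) prewhitening recovers and removes autocorrelation", {
  nt <- 200
  nv <- 500
  set.seed(31)
  white <- matrix(rnorm(nt * nv), nt, nv)
  pw <- prewhiten(white)
  expect_lt(abs(mean(pw$phi)), 0.05)
  ar <- apply(matrix(rnorm((nt + 50) * nv), nt + 50, nv), 2,
              function(e) stats::filter(e, 0.4, method = "recursive"))
  ar <- ar[51:(50 + nt), ]
  pw2 <- prewhiten(ar)
  expect_equal(mean(pw2$phi), 0.4, tolerance = 0.05)
  lag1 <- function(m) mean(sapply(seq_len(ncol(m)), function(j)
    stats::cor(m[-1, j], m[-nrow(m), j])))
  expect_lt(abs(lag1(pw2$series)), 0.05)
})
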