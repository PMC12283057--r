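test_that("boxcar regressor follows the block paradigm arithmetic", {
  box <- make_paradigm(paradigm(), 3)
  expect_length(box, 248)
  expect_equal(sum(box), 6 * 8)  # 24 s on / 3 s TR = 8 volumes per block
  # first block occupies volumes starting at t = 60 s
  expect_equal(which(box == 1)[1:8], 21:28)
  box0 <- make_paradigm(paradigm(n_blocks = 0), 3)
  expect_length(box0, 20)
  expect_true(all(box0 == 0))
})

test_that("gamma IRF is the moment-matched gamma density", {
  t <- seq(0, 30, by = 0.01)
  k <- gamma_irf(t, irf_params(2.8, 1.4))
  # shape 4, scale 0.7 -> mode at 2.1 s
  expect_equal(t[which.max(k)], 2.1, tolerance = 0.02)
  expect_equal(sum(k) * 0.01, 1, tolerance = 1e-6)
  expect_equal(k[1], 0)
  # narrow-variation limit concentrates mass at the delay
  kn <- gamma_irf(t, irf_params(2.8, 0.05))
  expect_gt(sum(kn[abs(t - 2.8) <= 0.1]) * 0.01, 0.95)
  expect_error(irf_params(-1, 1), "delay")
  expect_error(irf_params(2.8, 0), "variation")
})

test_that("task response has unit peak and expected latency behaviour", {
  par <- paradigm()
  r <- task_response(par, irf_params(), 3)
  expect_length(r, 248)
  expect_true(max(r) <= 1 + 1e-9)
  expect_gt(max(r), 0.98)          # TR sampling close to the fine-grid peak
  expect_true(all(abs(r[1:20]) < 1e-9))  # initial rest
  r0 <- task_response(paradigm(n_blocks = 0), irf_params(), 3)
  expect_true(all(r0 == 0))
  # latency shift moves the sampled response
  r9 <- task_response(par, irf_params(), 3, latency_shift = 9)
  expect_equal(which.max(r9[1:60]) - which.max(r[1:60]), 3)
})

test_that("dual phantom is deterministic with the required geometry", {
  p1 <- make_dual_phantom(matrix_size = 24, seed = 3)
  p2 <- make_dual_phantom(matrix_size = 24, seed = 3)
  expect_identical(p1$volumes, p2$volumes)
  for (f in 1:2) {
    expect_true(all(p1$volumes[[f]] >= 0))
    expect_gt(sum(p1$activation_masks[[f]]), 0)
    expect_true(all(p1$object_masks[[f]][p1$activation_masks[[f]]]))
  }
  # cord ROI confined to one lateral and the dorsal half of the cylinder
  n <- 24
  roi_idx <- which(p1$activation_masks[[2]], arr.ind = TRUE) - 1
  expect_true(all(roi_idx[, 1] > (n - 1) / 2))
  expect_true(all(roi_idx[, 2] > (n - 1) / 2))
  expect_error(make_dual_phantom(matrix_size = 8), "matrix_size")
})

test_that("rendered series injects the exact fractional response", {
  ph <- make_dual_phantom(matrix_size = 16, effect_size = c(0.02, 0.01),
                          latency_shift = c(0, 0), seed = 2)
  par <- paradigm(initial_rest = 12, block_on = 12, block_off = 12,
                  n_blocks = 2)
  tr <- 3
  s <- render_truth_series(ph, par, irf_params(), tr)
  r <- task_response(par, irf_params(), tr)
  for (f in 1:2) {
    roi <- ph$activation_masks[[f]]
    v <- which(roi)[1]
    idx <- arrayInd(v, dim(roi))
    ts <- s[[f]][idx[1], idx[2], idx[3], ]
    base <- ph$volumes[[f]][v]
    expect_equal(ts / base - 1, ph$effect_size[f] * r, tolerance = 1e-12)
    # non-ROI voxels are constant
    out_v <- which(ph$object_masks[[f]] & !roi)[1]
    oi <- arrayInd(out_v, dim(roi))
    expect_equal(diff(range(s[[f]][oi[1], oi[2], oi[3], ])), 0)
    # conservation at zero effect
  }
  ph0 <- make_dual_phantom(matrix_size = 16, effect_size = c(0, 0), seed = 2)
  s0 <- render_truth_series(ph0, par, irf_params(), tr)
  sums <- apply(s0[[1]], 4, sum)
  expect_equal(max(sums) - min(sums), 0)
})

test_that("motion events displace the centre of mass by the commanded shift", {
  ph <- make_dual_phantom(
    matrix_size = 16, effect_size = c(0, 0), seed = 4,
    motion_events = list(list(fov = 0L, volume = 3L, shift = c(0, 0, 2))))
  par <- paradigm(initial_rest = 12, block_on = 6, block_off = 6,
                  n_blocks = 1)
  s <- render_truth_series(ph, par, irf_params(), 3)
  tr <- center_of_mass_motion(s[[1]])
  expect_equal(tr$dz[1:2], c(0, 0))
  expect_equal(tr$dz[3:8], rep(2, 6), tolerance = 1e-9)
  expect_equal(tr$dx, rep(0, 8), tolerance = 1e-9)
})
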