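make_tiny_truth <- function(n = 16, nt = 3, amp = 0) {
  ph <- ball_phantom(n)
  s <- array(0, dim = c(n, n, n, nt))
  for (v in seq_len(nt)) s[, , , v] <- ph * (1 + amp * (v - 1))
  s
}

tiny_setup <- function(n = 16, nsp = 12, nt = 3) {
  p <- sequence_params(matrix_size = n, n_spokes_per_volume = nsp,
                       n_volumes = nt, samples_per_gap = 16,
                       oversampling = 2)
  list(params = p,
       schedule = make_dual_schedule(p, make_spoke_directions(nsp)))
}

test_that("dual acquisition carries the scheduled spoke counts per volume", {
  st <- tiny_setup()
  tr0 <- make_tiny_truth()
  tr1 <- make_tiny_truth()
  streams <- acquire_dual(tr0, tr1, st$schedule, st$params, exact = TRUE)
  for (f in 1:2) {
    expect_s3_class(streams[[f]], "kspace_stream")
    expect_equal(nrow(streams[[f]]$samples), 12 * 3)
    expect_equal(ncol(streams[[f]]$samples), 32)
    expect_equal(streams[[f]]$fov_index, f - 1L)
  }
  # static phantom, no noise: every volume's spokes identical
  sm <- streams[[1]]$samples
  expect_equal(sm[1:12, ], sm[13:24, ], tolerance = 1e-12)
  expect_equal(sm[1:12, ], sm[25:36, ], tolerance = 1e-12)
  # |k| increases monotonically centre-out and ends at the grid Nyquist
  expect_true(all(diff(streams[[1]]$nu) > 0))
  kc <- k_coords(streams[[1]], spokes = 1)
  expect_equal(max(sqrt(rowSums(kc^2))), 16 / (2 * 40), tolerance = 1e-12)
})

test_that("acquisition samples each volume's truth at its own time", {
  st <- tiny_setup()
  tr0 <- make_tiny_truth(amp = 0.5)
  streams <- acquire_dual(tr0, make_tiny_truth(), st$schedule, st$params,
                          exact = TRUE)
  dc <- Mod(streams[[1]]$dc_reference)
  expect_equal(mean(dc[13:24]) / mean(dc[1:12]), 1.5, tolerance = 1e-9)
  expect_equal(mean(dc[25:36]) / mean(dc[1:12]), 2.0, tolerance = 1e-9)
  short <- make_tiny_truth(nt = 2)
  expect_error(acquire_dual(short, short, st$schedule, st$params),
               "overrun")
})

test_that("forward model is linear and streams are independent", {
  st <- tiny_setup(nt = 1)
  a <- make_tiny_truth(nt = 1)
  b <- array(ball_phantom(16, seed = 21), dim = c(16, 16, 16, 1))
  sa <- acquire_dual(a, a, st$schedule, st$params, exact = TRUE)
  sb <- acquire_dual(b, b, st$schedule, st$params, exact = TRUE)
  sab <- acquire_dual(2 * a + 3 * b, 2 * a + 3 * b, st$schedule, st$params,
                      exact = TRUE)
  expect_equal(sab[[1]]$samples, 2 * sa[[1]]$samples + 3 * sb[[1]]$samples,
               tolerance = 1e-9)
  # FOV 1 stream does not depend on the FOV 0 phantom at zero coupling
  s1 <- acquire_dual(a, b, st$schedule, st$params, exact = TRUE)
  s2 <- acquire_dual(2 * a, b, st$schedule, st$params, exact = TRUE)
  expect_equal(s1[[2]]$samples, s2[[2]]$samples, tolerance = 1e-12)
  # leakage scales linearly with the coupling coefficient
  eps1 <- acquire_dual(a, b, st$schedule, st$params, coupling = 0.01,
                       exact = TRUE)
  eps2 <- acquire_dual(a, b, st$schedule, st$params, coupling = 0.02,
                       exact = TRUE)
  leak1 <- eps1[[2]]$samples - s1[[2]]$samples
  leak2 <- eps2[[2]]$samples - s1[[2]]$samples
  expect_equal(leak2, 2 * leak1, tolerance = 1e-9)
})

test_that("k-space noise is seed-deterministic at the prescribed level", {
  st <- tiny_setup()
  tr <- make_tiny_truth()
  s1 <- acquire_dual(tr, tr, st$schedule, st$params, noise_sd = 0.01,
                     seed = 42, exact = TRUE)
  s2 <- acquire_dual(tr, tr, st$schedule, st$params, noise_sd = 0.01,
                     seed = 42, exact = TRUE)
  s3 <- acquire_dual(tr, tr, st$schedule, st$params, noise_sd = 0.01,
                     seed = 43, exact = TRUE)
  expect_identical(s1[[1]]$samples, s2[[1]]$samples)
  expect_false(identical(s1[[1]]$samples, s3[[1]]$samples))
  clean <- acquire_dual(tr, tr, st$schedule, st$params, exact = TRUE)
  resid <- s1[[1]]$samples - clean[[1]]$samples
  target <- 0.01 * mean(Mod(clean[[1]]$samples[, 1]))
  expect_equal(sqrt(mean(Mod(resid)^2)), target, tolerance = 0.1)
})
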