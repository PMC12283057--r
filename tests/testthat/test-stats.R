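test_that("design matrix carries the gamma-convolved task regressor", {
  X <- build_design(paradigm(), irf_params(), 3, 248)
  expect_equal(dim(X), c(248, 2))
  expect_equal(max(X[, "task"]), 1, tolerance = 0.02)
  # onset-to-peak of an isolated block vs fine-grid continuous oracle
  par1 <- paradigm(initial_rest = 60, block_on = 24, block_off = 120,
                   n_blocks = 1)
  tr <- 3
  X1 <- build_design(par1, irf_params(), tr)
  lag_sampled <- (which.max(X1[, "task"]) - 1) * tr - 60
  dt <- 0.01
  tf <- seq(0, 200, by = dt)
  box <- as.numeric(tf >= 60 & tf < 84)
  kern <- gamma_irf(seq(0, 30, by = dt), irf_params())
  rf <- stats::convolve(box, rev(kern), type = "open")[seq_along(tf)] * dt
  lag_fine <- tf[which.max(rf)] - 60
  expect_lt(abs(lag_sampled - lag_fine), tr / 2 + 1e-9)
  X0 <- build_design(paradigm(n_blocks = 0), irf_params(), 3)
  expect_true(all(X0[, "task"] == 0))
})

test_that("voxelwise GLM recovers unit beta and is scale invariant", {
  set.seed(41)
  nt <- 100
  dims <- c(5, 5, 5)
  par <- paradigm(initial_rest = 30, block_on = 24, block_off = 60,
                  n_blocks = 3)
  task <- task_response(par, irf_params(), 3, n_volumes = nt)
  X <- cbind(task = task, intercept = 1)
  s <- array(rnorm(prod(dims) * nt, sd = 0.3), dim = c(dims, nt))
  s <- s + 100
  # voxel (1,1,1): time course equals the regressor exactly
  s[1, 1, 1, ] <- task
  g <- fit_glm(s, X, prewhiten = FALSE)
  expect_equal(g$beta[1, 1, 1], 1, tolerance = 1e-9)
  # affine intensity rescaling leaves z untouched
  g2 <- fit_glm(2.5 * s + 10, X, prewhiten = FALSE)
  expect_equal(g2$z, g$z, tolerance = 1e-8)
  # circularly shifted regressor on null data: near-zero mean z
  null_task <- c(task[(nt / 2 + 1):nt], task[1:(nt / 2)])
  gn <- fit_glm(s[, , , , drop = FALSE] * 0 +
                  array(rnorm(prod(dims) * nt), dim = c(dims, nt)),
                cbind(task = null_task, intercept = 1), prewhiten = FALSE)
  expect_lt(abs(mean(gn$z)), 0.1)
  expect_error(fit_glm(s, cbind(task, task)), "rank")
})

test_that("cluster extraction respects 6-connectivity", {
  dims <- c(10, 10, 10)
  z <- array(0, dims)
  z[3:5, 3:5, 3:5] <- 5
  cl <- extract_clusters(z, params = stats_params())
  expect_equal(nrow(cl$table), 1)
  expect_equal(cl$table$n_voxels, 27)
  expect_equal(unlist(cl$table[1, c("cx", "cy", "cz")]),
               c(cx = 3, cy = 3, cz = 3))  # 0-based centroid of 3:5
  expect_equal(cl$table$peak_z, 5)
  # two blocks touching only at a corner: separate clusters
  z2 <- array(0, dims)
  z2[1:2, 1:2, 1:2] <- 4
  z2[3:4, 3:4, 3:4] <- 6
  cl2 <- extract_clusters(z2, params = stats_params())
  expect_equal(nrow(cl2$table), 2)
  expect_equal(sort(cl2$table$n_voxels), c(8, 8))
})

test_that("TFCE matches closed form and an independent oracle", {
  dims <- c(8, 8, 8)
  # single isolated voxel of height 1: integral h^2 dh = 1/3
  z <- array(0, dims)
  z[4, 4, 4] <- 1
  tf <- tfce(z, params = stats_params())
  expect_equal(tf[4, 4, 4], 1 / 3, tolerance = 0.02 / 3 + 0.015)
  expect_equal(sum(tf > 0), 1)
  # flat zero map
  expect_true(all(tfce(array(0, dims)) == 0))
  # independent R oracle: per-voxel loop over the same threshold grid
  set.seed(51)
  zr <- array(pmax(0, rnorm(prod(dims))), dims)
  tfr <- tfce(zr, params = stats_params())
  oracle <- array(0, dims)
  mx <- max(zr)
  dh <- 0.01 * mx
  for (s in 1:100) {
    h <- s * dh
    m <- zr >= h
    if (!any(m)) break
    lab <- array(dualswift:::cpp_label3d(as.vector(m), dims), dims)
    # replicate extents with plain R table lookup
    sizes <- tabulate(lab[lab > 0])
    oracle[m] <- oracle[m] + sizes[lab[m]]^0.5 * h^2 * dh
  }
  expect_equal(tfr, oracle, tolerance = 1e-12)
  # monotonicity: raising a (non-maximal) voxel never decreases any TFCE
  # value; keeping the map maximum fixed keeps the threshold grid shared
  for (rep in 1:5) {
    v <- sample(which(zr < mx - 0.6), 1)
    z3 <- zr
    z3[v] <- z3[v] + 0.5
    tf3 <- tfce(z3, params = stats_params())
    expect_true(all(tf3 - tfr > -1e-9 * max(tfr)))
  }
})

test_that("sign-flip group inference is exhaustive and localises effects", {
  dims <- c(8, 8, 8)
  set.seed(61)
  n <- 8
  roi <- array(FALSE, dims)
  roi[3:5, 3:5, 3:5] <- TRUE
  maps <- lapply(1:n, function(i)
    array(rnorm(prod(dims), sd = 0.3), dims) + roi * 2)
  g <- group_inference(maps, params = stats_params(), seed = 5)
  expect_true(g$exhaustive)
  expect_equal(g$n_permutations, 256)
  # p values live on the 1/256 grid
  pv <- unique(as.vector(g$p_fwe))
  expect_true(all(abs(pv * 256 - round(pv * 256)) < 1e-12))
  # planted ROI significant, background not
  expect_true(all(g$significant[roi]))
  expect_lt(sum(g$significant & !roi), 0.02 * sum(!roi))
  expect_error(group_inference(maps[1]), "at least 2")
})

test_that("ROI time course reports percent change and peak latency", {
  n <- 10
  nt <- 60
  par <- paradigm(initial_rest = 30, block_on = 24, block_off = 36,
                  n_blocks = 2)
  tr <- 3
  r <- task_response(par, irf_params(), tr, n_volumes = nt)
  s <- array(100, dim = c(n, n, n, nt))
  roi <- array(FALSE, c(n, n, n))
  roi[4:6, 4:6, 4:6] <- TRUE
  for (v in 1:nt) s[, , , v] <- 100 * (1 + 0.01 * roi * r[v])
  tc <- extract_timecourse(s, roi, par, tr)
  expect_equal(tc$peak_psc, 1, tolerance = 0.05)
  # latency lies in the response's near-peak region ...
  expect_gte(tc$peak_latency_s, 15)
  expect_lte(tc$peak_latency_s, 33)
  # ... and a pure latency shift of the injected response moves it by
  # exactly that shift
  r9 <- task_response(par, irf_params(), tr, latency_shift = 9,
                      n_volumes = nt)
  s9 <- s
  for (v in 1:nt) s9[, , , v] <- 100 * (1 + 0.01 * roi * r9[v])
  tc9 <- extract_timecourse(s9, roi, par, tr)
  expect_equal(tc9$peak_latency_s - tc$peak_latency_s, 9, tolerance = 3)
  # constant series: flat zero curve
  tc0 <- extract_timecourse(array(50, c(n, n, n, nt)), roi, par, tr)
  expect_true(all(abs(tc0$psc) < 1e-12))
  expect_error(extract_timecourse(s, array(FALSE, c(n, n, n)), par, tr),
               "empty")
})

test_that("paired latency test has power for a 9 s shift at n = 8", {
  set.seed(71)
  hits <- vapply(1:200, function(r) {
    a <- 24 + rnorm(8, sd = 1.5)
    b <- a + 9 + rnorm(8, sd = 1.5)
    compare_peak_latencies(a, b)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("paired latency comparison behaves like a paired t test", {
  a <- c(24, 27, 24, 30, 27, 24, 27, 24)
  b <- a + c(9, 12, 9, 6, 9, 12, 9, 9)
  r <- compare_peak_latencies(a, b)
  o <- t.test(b, a, paired = TRUE)
  expect_equal(r$t, unname(o$statistic))
  expect_equal(r$p_value, o$p.value)
  # antisymmetry
  r2 <- compare_peak_latencies(b, a)
  expect_equal(r2$t, -r$t)
  # zero-variance guard
  expect_warning(rz <- compare_peak_latencies(a, a), "zero variance")
  expect_equal(rz$p_value, 1)
  expect_warning(rs <- compare_peak_latencies(a, a + 9), "zero variance")
  expect_equal(rs$p_value, 0)
  expect_equal(rs$mean_difference, 9)
})
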