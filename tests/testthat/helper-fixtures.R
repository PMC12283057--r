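# shared fixtures, all generated in code

# deterministic smooth nonnegative test object on an n^3 grid
ball_phantom <- function(n = 16, seed = 7, radius = 0.4) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    g <- seq_len(n) - 1
    c0 <- (n - 1) / 2
    ph <- array(0, dim = c(n, n, n))
    sph <- outer(outer((g - c0)^2, (g - c0)^2, "+"), (g - c0)^2, "+") <=
      (radius * n)^2
    ph[sph] <- 1 + 0.3 * runif(sum(sph))
    ph
  })
}

# brute-force type-II NUDFT oracle (plain R, independent of the package's
# C++ operators)
brute_nudft <- function(img, coords) {
  n <- dim(img)
  g1 <- (0:(n[1] - 1)) - n[1] %/% 2
  g2 <- (0:(n[2] - 1)) - n[2] %/% 2
  g3 <- (0:(n[3] - 1)) - n[3] %/% 2
  idx <- as.matrix(expand.grid(x = g1, y = g2, z = g3))
  vapply(seq_len(nrow(coords)), function(m) {
    ph <- -2 * pi * (idx %*% coords[m, ])
    sum(img * complex(real = cos(ph), imaginary = sin(ph)))
  }, complex(1))
}

# spokes giving ~3x angular oversampling relative to the radial Nyquist
# count pi * n^2 for an n^3 grid
nyquist_spokes <- function(n, factor = 1) round(factor * pi * n^2)

# small 4D series with planted spatiotemporal structure
planted_series <- function(dims = c(8, 8, 8), nt = 40, sources, seed = 5) {
  stopifnot(is.list(sources))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  base <- array(100, dim = c(dims, nt))
  for (s in sources)
    for (v in seq_len(nt))
      base[, , , v] <- base[, , , v] + s$map * s$tc[v]
  base + array(rnorm(prod(dims) * nt, sd = 0.05), dim = c(dims, nt))
}
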