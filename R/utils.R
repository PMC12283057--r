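## internal helpers

# evaluate `expr` under a given seed without disturbing the caller's RNG
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  orig <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", orig, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# flatten a 4D series to a time x voxel matrix and back
series_to_matrix <- function(series) {
  d <- dim(series)
  t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_to_series <- function(m, dims3) {
  array(t(m), dim = c(dims3, nrow(m)))
}

nrmse <- function(x, ref) {
  sqrt(mean((x - ref)^2)) / (max(ref) - min(ref))
}
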