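# Internal helpers ----------------------------------------------------------

# Evaluate `code` with the global RNG seeded to `seed`, restoring any
# pre-existing RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%g, %g]", name, lower, upper)
  x
}

# deterministic low-discrepancy jitter without touching the global RNG
lcg_runif <- function(n, seed = 20L) {
  state <- as.double(seed %% 2147483647L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 16807) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

complex_array <- function(x, dim) array(as.complex(x), dim = dim)

# nearest-neighbour rigid resampling (same pose convention as apply_rigid);
# NA outside the source FOV. Used to move piecewise-constant parameter maps
# between rigid frames without fabricating intermediate values.
nn_rigid_transform <- function(img, tx, ty, theta_deg) {
  n1 <- nrow(img); n2 <- ncol(img)
  th <- theta_deg * pi / 180
  xc <- rep(seq_len(n1) - 1 - n1 %/% 2, n2) - tx
  yc <- rep(seq_len(n2) - 1 - n2 %/% 2, each = n1) - ty
  xs <- round(cos(th) * xc + sin(th) * yc + n1 %/% 2)
  ys <- round(-sin(th) * xc + cos(th) * yc + n2 %/% 2)
  ok <- xs >= 0 & xs < n1 & ys >= 0 & ys < n2
  out <- rep(NA_real_, n1 * n2)
  out[ok] <- img[cbind(xs[ok] + 1, ys[ok] + 1)]
  matrix(out, n1, n2)
}

# 4-neighbourhood erosion of a logical mask
erode_mask <- function(mask, iter = 1) {
  for (k in seq_len(iter)) {
    n1 <- nrow(mask); n2 <- ncol(mask)
    sh <- function(di, dj) {
      out <- matrix(FALSE, n1, n2)
      si <- seq_len(n1) - di; sj <- seq_len(n2) - dj
      ok_i <- si >= 1 & si <= n1; ok_j <- sj >= 1 & sj <= n2
      out[ok_i, ok_j] <- mask[si[ok_i], sj[ok_j]]
      out
    }
    mask <- mask & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
  }
  mask
}

# union of the per-tissue-class eroded interiors of a tissue_maps phantom
tissue_interior_mask <- function(maps, erode = 2) {
  key <- paste(maps$t1_ms, maps$t2_ms)
  out <- matrix(FALSE, maps$matrix, maps$matrix)
  for (k in unique(key[maps$mask])) {
    cls <- matrix(key == k, maps$matrix) & maps$mask
    out <- out | erode_mask(cls, iter = erode)
  }
  out
}

# linear interpolation with constant extrapolation at both ends
interp_constant_ends <- function(x, y, xout) {
  approx(x, y, xout = xout, rule = 2)$y
}
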