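# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own algorithms: plain loops, Floyd-Warshall, direct
# enumeration.

# element-wise max over z by explicit looping
bf_project_max <- function(vox, channel) {
  d <- dim(vox)
  out <- matrix(-Inf, d[3], d[4])
  for (y in seq_len(d[3])) for (x in seq_len(d[4])) {
    for (z in seq_len(d[2])) out[y, x] <- max(out[y, x], vox[channel, z, y, x])
  }
  out
}

# threshold + recursive flood fill (8-connectivity) from a seed pixel
bf_flood_component <- function(img, thr, seed_rc) {
  mask <- img > thr
  comp <- matrix(FALSE, nrow(img), ncol(img))
  stack <- list(seed_rc)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    y <- p[1]; x <- p[2]
    if (y < 1 || y > nrow(img) || x < 1 || x > ncol(img)) next
    if (!mask[y, x] || comp[y, x]) next
    comp[y, x] <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy != 0 || dx != 0) stack[[length(stack) + 1]] <- c(y + dy, x + dx)
    }
  }
  comp
}

# longest shortest-path (weighted graph diameter) over a pixel skeleton via
# Floyd-Warshall; cost 1 axial, sqrt(2) diagonal
bf_longest_geodesic <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dy <- abs(px[i, 1] - px[j, 1]); dx <- abs(px[i, 2] - px[j, 2])
    if (dy <= 1 && dx <= 1) d[i, j] <- d[j, i] <- if (dy + dx == 2) sqrt(2) else 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  max(d[is.finite(d)])
}

# exact two-sided Mann-Whitney p by direct enumeration of group assignments,
# counting pairwise wins (independent of the package's rank-sum route)
bf_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}

# polygon interior centroid by dense supersampled rasterization (10x10 per px)
bf_polygon_centroid <- function(vx, vy, supersample = 10) {
  xr <- range(vx); yr <- range(vy)
  step <- 1 / supersample
  gx <- seq(xr[1] - 1, xr[2] + 1, by = step)
  gy <- seq(yr[1] - 1, yr[2] + 1, by = step)
  pts <- expand.grid(x = gx, y = gy)
  n <- length(vx)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > pts$y) != (vy[j] > pts$y)) &
      (pts$x < (vx[j] - vx[i]) * (pts$y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  c(x = mean(pts$x[inside]), y = mean(pts$y[inside]))
}

# hand-evaluated Welch statistic from the textbook formula
bf_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# small synthetic field used by several tests (fast: ~90x90 px)
tiny_field_params <- function(seed = 1, ...) {
  field_params(
    field_size_px = c(96, 96), n_centrosomes = 3, ciliation_fraction = 1,
    cilium_length_um_range = c(2, 4), seed = seed, ...
  )
}
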