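# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Brute-force flood fill with a given connectivity, in plain R.
floodfill_labels <- function(mask, connectivity = 18) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (lin in which(mask == 1)) {
    if (labels[lin] != 0L) next
    nxt <- nxt + 1L
    stack <- lin
    labels[lin] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        j <- i + offs[r, ]
        if (any(j < 1) || any(j > d)) next
        if (mask[j[1], j[2], j[3]] == 1 &&
            labels[j[1], j[2], j[3]] == 0L) {
          labels[j[1], j[2], j[3]] <- nxt
          stack <- c(stack, (j[3] - 1) * d[1] * d[2] + (j[2] - 1) * d[1] +
                       j[1])
        }
      }
    }
  }
  labels
}

# Partition signature invariant to label numbering.
partition_signature <- function(labels) {
  fg <- which(labels != 0)
  split(fg, labels[fg])[order(vapply(split(fg, labels[fg]), min, 0))]
}

# Rotation-matrix oracle for the beam frame: rotate the gantry-0 frame
# about the SI axis by the gantry angle (right-handed about +SI with
# the package's clockwise-from-anterior convention).
frame_oracle <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  rot <- rbind(c(1, 0, 0),
               c(0, cos(g), -sin(g)),
               c(0, sin(g), cos(g)))
  list(ez = as.numeric(rot %*% c(0, -1, 0)),
       ey = as.numeric(rot %*% c(0, 0, 1)),
       ex = c(1, 0, 0))
}

# Exhaustive gamma oracle: full-grid search at 1/3-voxel steps, no
# pruning, plain R. Returns the gamma map (NA below threshold).
gamma_oracle <- function(ref, eval, spacing, dd_frac, dta, thr_frac,
                        step_div = 3) {
  d <- dim(ref)
  dmax <- max(ref)
  tol <- dd_frac * dmax
  thr <- thr_frac * dmax
  # all probe positions (fractional voxel indices) and interpolated dose
  f1 <- seq(0, d[1] - 1, by = 1 / step_div)
  f2 <- seq(0, d[2] - 1, by = 1 / step_div)
  f3 <- seq(0, d[3] - 1, by = 1 / step_div)
  probes <- as.matrix(expand.grid(f1, f2, f3))
  de <- trilinear_oracle(eval, probes)
  pw <- sweep(probes, 2, spacing, "*")
  out <- array(NA_real_, d)
  for (lin in which(ref >= thr)) {
    i <- arrayInd(lin, d) - 1
    pos <- i * spacing
    dist2 <- (pw[, 1] - pos[1])^2 + (pw[, 2] - pos[2])^2 +
      (pw[, 3] - pos[3])^2
    g2 <- dist2 / dta^2 + (de - ref[lin])^2 / tol^2
    out[lin] <- sqrt(min(g2))
  }
  out
}

# Straightforward R trilinear interpolation at 0-based fractional
# indices (points assumed inside the hull).
trilinear_oracle <- function(vals, pts) {
  d <- dim(vals)
  i <- pmin(pmax(floor(pts), 0), pmax(d - 2, 0))
  f <- pts - i
  v <- rep(0, nrow(pts))
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
    w <- (if (o1 == 1) f[, 1] else 1 - f[, 1]) *
      (if (o2 == 1) f[, 2] else 1 - f[, 2]) *
      (if (o3 == 1) f[, 3] else 1 - f[, 3])
    idx <- cbind(pmin(i[, 1] + o1, d[1] - 1) + 1,
                 pmin(i[, 2] + o2, d[2] - 1) + 1,
                 pmin(i[, 3] + o3, d[3] - 1) + 1)
    v <- v + w * vals[idx]
  }
  v
}

# Independent 1D evaluation of the oracle marching scheme for a single
# ray of densities (used against the full 3D implementation).
march_ray_oracle <- function(rho, ds, mu, L) {
  n <- length(rho)
  t <- cumsum(rho) * ds - rho * ds / 2
  E <- numeric(n)
  e <- 0
  for (k in seq_len(n)) {
    e <- e + (rho[k] - e) * min(1, rho[k] * ds / L)
    E[k] <- e
  }
  E * exp(-mu * t)
}

# Brute-force 26-neighbourhood dilation (loop over foreground voxels).
dilate_oracle <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (lin in which(mask == 1)) {
    i <- arrayInd(lin, d)
    for (o1 in -1:1) for (o2 in -1:1) for (o3 in -1:1) {
      j <- i + c(o1, o2, o3)
      if (all(j >= 1) && all(j <= d)) out[j[1], j[2], j[3]] <- 1
    }
  }
  out
}

# Small helpers for synthetic volumes.
const_volume <- function(value, shape = c(8, 8, 8), spacing = c(1, 1, 1),
                         quantity = "MRI") {
  volume_grid(array(value, shape), spacing = spacing, quantity = quantity)
}

smooth_random_field <- function(shape, seed, base = 1) {
  set.seed(seed)
  u <- lapply(shape, function(n) (seq_len(n) - 1) / (n - 1))
  f <- array(base, shape)
  for (m in 1:3) {
    a <- runif(3, -2, 2)
    ph <- runif(3, 0, 2 * pi)
    f <- f + 0.3 * outer(outer(cos(a[1] * pi * u[[1]] + ph[1]),
                               cos(a[2] * pi * u[[2]] + ph[2])),
                         cos(a[3] * pi * u[[3]] + ph[3]))
  }
  f
}
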