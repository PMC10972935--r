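# Independent oracles used across the suite. Everything here is written
# against the plain mathematical definitions (finite differences, exhaustive
# enumeration, base eigen()), not against the package's implementation paths.

# --- independent Gaussian smoothing + finite-difference Hessian -------------

# 1D convolution along one axis with replicate padding, direct summation.
oracle_conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + kernel[t] * sl
  }
  out
}

oracle_gauss_smooth <- function(a, sigma_vox) {
  for (ax in 1:3) {
    r <- max(1L, ceiling(4 * sigma_vox[ax]))
    x <- seq(-r, r)
    g <- exp(-x^2 / (2 * sigma_vox[ax]^2))
    a <- oracle_conv_axis(a, g / sum(g), ax)
  }
  a
}

# Central-difference Hessian (in mm) of the Gaussian-smoothed volume,
# scale-normalized by scale^2 like the filter under test.
oracle_hessian <- function(data, spacing, scale) {
  s <- oracle_gauss_smooth(data, scale / spacing)
  d <- dim(s)
  ax_shift <- function(a, axis, off) {
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    switch(axis,
           a[idx, , , drop = FALSE],
           a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  d1 <- function(a, ax) (ax_shift(a, ax, 1L) - ax_shift(a, ax, -1L)) / (2 * spacing[ax])
  d2 <- function(a, ax) {
    (ax_shift(a, ax, 1L) - 2 * a + ax_shift(a, ax, -1L)) / spacing[ax]^2
  }
  list(xx = d2(s, 1) * scale^2, yy = d2(s, 2) * scale^2, zz = d2(s, 3) * scale^2,
       xy = d1(d1(s, 1), 2) * scale^2, xz = d1(d1(s, 1), 3) * scale^2,
       yz = d1(d1(s, 2), 3) * scale^2)
}

# Direct per-voxel vesselness from a Hessian field: base eigen() on each 3x3
# matrix, magnitude sort, and the tube-response formula evaluated literally.
oracle_vesselness_dense <- function(H, alpha = 0.5, beta = 0.5, gamma) {
  d <- dim(H$xx)
  out <- array(0, d)
  for (i in seq_len(prod(d))) {
    M <- matrix(c(H$xx[i], H$xy[i], H$xz[i],
                  H$xy[i], H$yy[i], H$yz[i],
                  H$xz[i], H$yz[i], H$zz[i]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev))]
    l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
    if (l2 > 0 || l3 > 0 || l3 == 0) next
    Ra <- abs(l2) / abs(l3)
    Rb <- if (l2 * l3 == 0) 0 else abs(l1) / sqrt(abs(l2 * l3))
    S <- sqrt(l1^2 + l2^2 + l3^2)
    out[i] <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * gamma^2)))
  }
  out
}

# --- exhaustive surface-distance oracle -------------------------------------

# Surface voxels by brute-force neighbour checks (0-based indices).
oracle_surface <- function(m) {
  d <- dim(m)
  pts <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (m[x, y, z] == 0) next
    border <- FALSE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- c(x, y, z) + s
      if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) { border <- TRUE; break }
    }
    if (border) pts <- rbind(pts, c(x, y, z) - 1)
  }
  pts
}

oracle_pair_dists <- function(A, B, spacing) {
  apply(A, 1, function(p) {
    min(sqrt(colSums((t(B) - p)^2 * spacing^2)))
  })
}

oracle_surface_metrics <- function(a, b, spacing, tau) {
  Sa <- oracle_surface(a); Sb <- oracle_surface(b)
  da <- oracle_pair_dists(Sa, Sb, spacing)
  db <- oracle_pair_dists(Sb, Sa, spacing)
  # same roundoff-tie convention as the implementation: distances equal to
  # tau up to 1e-9 mm count as within tolerance
  list(hd95 = unname(stats::quantile(c(da, db), 0.95, type = 7)),
       hd = max(c(da, db)),
       nsd = 100 * (sum(da <= tau + 1e-9) + sum(db <= tau + 1e-9)) /
         (length(da) + length(db)))
}

# --- misc helpers ------------------------------------------------------------

rand_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  label_mask(array(rbinom(prod(dims), 1, p), dims))
}

tiny_phantom_cfg <- function(...) {
  phantom_config(size = 32, spacing = 0.5, semi_axes = c(6, 5, 4.5),
                 tube_radius = 1.0, ...)
}
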