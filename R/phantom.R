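# Deterministic synthetic phantoms: a bright ellipsoidal organ (pancreas
# surrogate) containing a thin dark curved tube (duct surrogate), with ground
# truth masks. Emulates the small-target, low-contrast regime of dilated-duct
# CT at the duct-stage working resolution, so every pipeline stage is
# testable without clinical data.

#' Phantom configuration
#'
#' Defaults emulate a normalized portal-venous CT ROI at the duct-stage
#' resolution: 64^3 voxels at 0.5 mm, an organ ellipsoid with semi-axes
#' 12 x 9 x 7 mm at intensity 0.55, a curved dark tube of radius 1 mm at
#' intensity 0.3, background 0.1, additive Gaussian noise sigma 0.02. The
#' tube radius must stay below a quarter of the smallest semi-axis so the
#' duct fits strictly inside the organ.
#'
#' @param size grid voxels per axis (recycled to length 3).
#' @param spacing isotropic voxel spacing in mm.
#' @param semi_axes ellipsoid semi-axes in mm (length 3).
#' @param tube_radius duct radius in mm.
#' @param n_control control points of the duct centerline (>= 2).
#' @param intensities named list/vector: `background`, `organ`, `duct`
#'   (normalized units; duct darker than organ).
#' @param noise_sigma standard deviation of additive Gaussian noise (>= 0).
#' @param straight if `TRUE` the centerline is a straight axis-parallel tube
#'   (analytic volume checks); otherwise a smooth random curve.
#' @param seed integer seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(size = 64, spacing = 0.5, semi_axes = c(12, 9, 7),
                           tube_radius = 1.0, n_control = 4,
                           intensities = c(background = 0.1, organ = 0.55, duct = 0.3),
                           noise_sigma = 0.02, straight = FALSE, seed = 1L) {
  size <- as.integer(rep(size, length.out = 3))
  if (tube_radius >= min(semi_axes) / 4) {
    stop_ductseg("tube radius %.2f mm must be < min semi-axis / 4 = %.2f mm",
                 tube_radius, min(semi_axes) / 4, class = "ductseg_config_error")
  }
  if (intensities[["duct"]] >= intensities[["organ"]]) {
    stop_ductseg("duct intensity must be below organ intensity",
                 class = "ductseg_config_error")
  }
  if (noise_sigma < 0) stop_ductseg("noise_sigma must be >= 0", class = "ductseg_config_error")
  if (any(2 * semi_axes >= size * spacing)) {
    stop_ductseg("ellipsoid does not fit in the grid", class = "ductseg_config_error")
  }
  structure(list(size = size, spacing = spacing, semi_axes = as.numeric(semi_axes),
                 tube_radius = tube_radius, n_control = as.integer(n_control),
                 intensities = intensities, noise_sigma = noise_sigma,
                 straight = straight, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate one duct phantom
#'
#' Builds the organ ellipsoid and duct tube masks and the corresponding
#' intensity volume (organ bright, duct dark, plus Gaussian noise). The duct
#' centerline is a smooth spline through random control points confined to
#' the inner 65% of the ellipsoid, so the duct lies strictly inside the
#' organ; with `straight = TRUE` it is a straight tube along the major axis.
#'
#' @param cfg a [phantom_config()].
#' @return list with `volume` ([volume()]), `pancreas` ([label_mask()]),
#'   `duct` ([label_mask()]), and `centerline` (matrix of mm coordinates).
#' @export
generate_duct_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$size; sp <- cfg$spacing
  center <- (d - 1) / 2 * sp
  ax <- cfg$semi_axes
  co <- lapply(1:3, function(k) (seq_len(d[k]) - 1) * sp - center[k])
  # ellipsoid mask
  e2 <- outer(outer((co[[1]] / ax[1])^2, (co[[2]] / ax[2])^2, "+"),
              (co[[3]] / ax[3])^2, "+")
  pancreas <- array(as.numeric(e2 <= 1), d)
  with_seed(cfg$seed, {
    # centerline control points in the inner ellipsoid (scale 0.65)
    s <- 0.65
    nc <- cfg$n_control
    tx <- seq(-s * ax[1], s * ax[1], length.out = nc)
    if (cfg$straight) {
      ctrl <- cbind(tx, 0, 0)
    } else {
      ctrl <- cbind(tx,
                    stats::runif(nc, -0.4, 0.4) * s * ax[2],
                    stats::runif(nc, -0.4, 0.4) * s * ax[3])
    }
    # dense smooth centerline (natural splines y(x), z(x))
    xs <- seq(tx[1], tx[nc], by = sp / 2)
    cl <- cbind(xs,
                stats::spline(tx, ctrl[, 2], xout = xs)$y,
                stats::spline(tx, ctrl[, 3], xout = xs)$y)
    # stamp spheres of tube_radius along the centerline
    duct <- array(FALSE, d)
    r <- cfg$tube_radius
    rv <- ceiling(r / sp) + 1L
    for (i in seq_len(nrow(cl))) {
      cv <- (cl[i, ] + center) / sp  # 0-based voxel coords
      lo <- pmax(floor(cv) - rv, 0)
      hi <- pmin(ceiling(cv) + rv, d - 1)
      ix <- (lo[1]:hi[1]); iy <- (lo[2]:hi[2]); iz <- (lo[3]:hi[3])
      dx2 <- (ix * sp - center[1] - cl[i, 1])^2
      dy2 <- (iy * sp - center[2] - cl[i, 2])^2
      dz2 <- (iz * sp - center[3] - cl[i, 3])^2
      ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
      duct[ix + 1, iy + 1, iz + 1] <- duct[ix + 1, iy + 1, iz + 1] | ball
    }
    duct <- array(as.numeric(duct), d)
    if (any(duct > pancreas)) {
      stop_ductseg("tube does not fit strictly inside the ellipsoid",
                   class = "ductseg_config_error")
    }
    ints <- cfg$intensities
    vol <- array(ints[["background"]], d)
    vol[pancreas == 1] <- ints[["organ"]]
    vol[duct == 1] <- ints[["duct"]]
    if (cfg$noise_sigma > 0) {
      vol <- vol + array(stats::rnorm(prod(d), sd = cfg$noise_sigma), d)
    }
    list(volume = volume(vol, rep(sp, 3)),
         pancreas = label_mask(pancreas, rep(sp, 3)),
         duct = label_mask(duct, rep(sp, 3)),
         centerline = cl)
  })
}

#' Generate a phantom dataset
#'
#' `n` phantoms with per-case seeds derived deterministically from the master
#' seed. Every case is validated to be in the small-target regime: duct
#' foreground below 1% of all voxels.
#'
#' @param n number of phantoms (>= 1).
#' @param cfg a [phantom_config()] (its `seed` is overridden per case).
#' @param seed master seed.
#' @return list of `n` phantom triples (see [generate_duct_phantom()]).
#' @export
generate_dataset <- function(n, cfg = phantom_config(), seed = 1L) {
  stopifnot(n >= 1)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, n))
  lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- case_seeds[i]
    ph <- generate_duct_phantom(ci)
    frac <- sum(ph$duct$data) / prod(dim(ph$duct$data))
    if (frac >= 0.01) {
      stop_ductseg("phantom %d leaves the small-target regime (duct fraction %.3f)",
                   i, frac, class = "ductseg_config_error")
    }
    ph
  })
}
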