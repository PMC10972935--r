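# Tubular-structure enhancement: scale-space Hessian, magnitude-ordered
# eigenvalues, the Frangi vesselness response, and the mask-restricted
# post-processing that turns the response into the network's second input
# channel.

#' Parameters of the Frangi vesselness filter
#'
#' `alpha` and `beta` control the sensitivity to the plate-vs-tube ratio
#' `Ra = |l2|/|l3|` and the blob ratio `Rb = |l1|/sqrt(|l2 l3|)`; both default
#' to 0.5. The structure-strength cutoff `gamma` is by default recomputed per
#' scale as half of the maximum Hessian (Frobenius) norm over the volume, or
#' can be fixed to a number. `scales` are Gaussian standard deviations in mm;
#' the defaults cover duct radii of roughly 1-4 voxels at 0.5 mm spacing.
#' `polarity = "dark"` enhances dark tubes on a bright background (the duct
#' within the pancreas) by negating intensities before differentiation, so
#' that the bright-tube eigenvalue condition `l2 <= 0, l3 <= 0` fires on the
#' duct; `"bright"` leaves intensities untouched.
#'
#' @param alpha,beta positive sensitivity parameters.
#' @param gamma `"half-max-norm"` or a fixed positive number.
#' @param scales positive Gaussian sigmas in mm.
#' @param polarity `"dark"` or `"bright"`.
#' @return object of class `vesselness_params`.
#' @export
vesselness_params <- function(alpha = 0.5, beta = 0.5, gamma = "half-max-norm",
                              scales = c(0.5, 1, 1.5, 2), polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0) {
    stop_ductseg("alpha and beta must be positive", class = "ductseg_parameter_error")
  }
  if (length(scales) < 1 || any(!is.finite(scales)) || any(scales <= 0)) {
    stop_ductseg("scales must be a nonempty set of positive sigmas (mm)",
                 class = "ductseg_parameter_error")
  }
  if (is.numeric(gamma) && gamma <= 0) {
    stop_ductseg("fixed gamma must be positive", class = "ductseg_parameter_error")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 scales = as.numeric(scales), polarity = polarity),
            class = "vesselness_params")
}

# Sampled Gaussian (order 0/1/2 derivative) kernel at sigma (in voxels),
# truncated at 4 sigma. Order-0 kernels are normalized to unit sum.
gaussian_kernel <- function(sigma_vox, order = 0) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma_vox^2 * g,  # odd symmetry: sums to zero exactly
         "2" = {
           k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
           k - mean(k)  # kill the sampling residual so constants map to zero
         })
}

# Convolution matrix (n x n) for a centered kernel with replicate padding.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (t in seq_along(j)) A[i, j[t]] <- A[i, j[t]] + kernel[t]
  }
  A
}

#' Scale-space Hessian field of a volume
#'
#' Second derivatives by separable Gaussian-derivative convolution at the
#' given scale, spacing-aware (derivatives are per mm) and scale-normalized by
#' `scale^2` so responses are comparable across scales. Replicate padding is
#' used at the borders.
#'
#' @param v a [volume()].
#' @param scale Gaussian sigma in mm (> 0).
#' @return named list of six 3D arrays: `xx, yy, zz, xy, xz, yz`.
#' @export
hessian_field <- function(v, scale) {
  stopifnot(inherits(v, "volume"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop_ductseg("scale must be a positive sigma in mm", class = "ductseg_parameter_error")
  }
  d <- dim(v$data)
  sp <- v$spacing
  # per-axis convolution matrices for derivative orders 0..2, in mm units
  mats <- lapply(1:3, function(ax) {
    sv <- scale / sp[ax]
    lapply(0:2, function(o) conv_matrix(d[ax], gaussian_kernel(sv, o)) / sp[ax]^o)
  })
  deriv <- function(ox, oy, oz) {
    out <- apply_axis(v$data, mats[[1]][[ox + 1]], 1)
    out <- apply_axis(out, mats[[2]][[oy + 1]], 2)
    apply_axis(out, mats[[3]][[oz + 1]], 3) * scale^2
  }
  list(xx = deriv(2, 0, 0), yy = deriv(0, 2, 0), zz = deriv(0, 0, 2),
       xy = deriv(1, 1, 0), xz = deriv(1, 0, 1), yz = deriv(0, 1, 1))
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized over voxels.
# Returns a 3-column matrix in descending algebraic order.
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  n <- length(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(safe, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1 <- ifelse(safe, e1, q); e2 <- ifelse(safe, e2, q); e3 <- ifelse(safe, e3, q)
  cbind(e1, e2, e3)
}

#' Order eigenvalues by increasing magnitude
#'
#' Returns the permutation of the inputs with `|l1| <= |l2| <= |l3|`, the
#' ordering in which the tube-shape ratios are defined. Vectorized: scalar
#' inputs give a length-3 vector, equal-length vectors give a 3-column matrix
#' with columns `l1, l2, l3`.
#'
#' @param e1,e2,e3 numeric vectors of eigenvalues.
#' @return numeric vector (length 3) or matrix with columns `l1, l2, l3`.
#' @export
sort_eigs <- function(e1, e2, e3) {
  scalar <- length(e1) == 1
  E <- cbind(e1, e2, e3)
  A <- abs(E)
  n <- nrow(E)
  imax <- max.col(A, ties.method = "first")
  imin <- max.col(-A, ties.method = "last")
  imid <- 6L - imax - imin
  out <- cbind(l1 = E[cbind(seq_len(n), imin)],
               l2 = E[cbind(seq_len(n), imid)],
               l3 = E[cbind(seq_len(n), imax)])
  if (scalar) out[1, ] else out
}

#' Geometric shape ratios of an eigenvalue triple
#'
#' `Ra = |l2|/|l3|` separates tubes from plates, `Rb = |l1|/sqrt(|l2 l3|)`
#' flags blobs, and `S = sqrt(l1^2 + l2^2 + l3^2)` measures structure strength
#' against low-contrast background. For the degenerate case `l3 = 0` (no
#' curvature, hence no tube) `Ra` and `Rb` are defined as 0; `Rb` is likewise
#' 0 whenever `l2 l3 = 0` (which forces `l1 = 0` under magnitude ordering).
#'
#' @param t numeric triple `(l1, l2, l3)` with `|l1| <= |l2| <= |l3|`, or a
#'   3-column matrix of such triples.
#' @return named vector `(Ra, Rb, S)` or a 3-column matrix.
#' @export
geometric_ratios <- function(t) {
  scalar <- is.null(dim(t))
  T <- if (scalar) matrix(t, 1) else t
  a1 <- abs(T[, 1]); a2 <- abs(T[, 2]); a3 <- abs(T[, 3])
  Ra <- ifelse(a3 > 0, a2 / pmax(a3, .Machine$double.xmin), 0)
  pr <- a2 * a3
  Rb <- ifelse(pr > 0, a1 / sqrt(pmax(pr, .Machine$double.xmin)), 0)
  S <- sqrt(a1^2 + a2^2 + a3^2)
  out <- cbind(Ra = Ra, Rb = Rb, S = S)
  if (scalar) out[1, ] else out
}

#' Frangi vesselness response of an eigenvalue triple
#'
#' `F = (1 - exp(-Ra^2/2a^2)) * exp(-Rb^2/2b^2) * (1 - exp(-S^2/2g^2))` when
#' `l2 <= 0` and `l3 <= 0` (a bright tube against darker surroundings), and 0
#' otherwise. Dark tubes are handled upstream by negating intensities (see
#' [vesselness_params()]).
#'
#' @param t eigenvalue triple(s) ordered by magnitude, as in [geometric_ratios()].
#' @param p a [vesselness_params()].
#' @param gamma positive structure-strength cutoff for this scale.
#' @return vesselness in `[0, 1]`, same length as rows of `t`.
#' @export
vesselness <- function(t, p, gamma) {
  stopifnot(inherits(p, "vesselness_params"))
  if (!is.numeric(gamma) || gamma <= 0) {
    stop_ductseg("gamma must be positive", class = "ductseg_parameter_error")
  }
  scalar <- is.null(dim(t))
  T <- if (scalar) matrix(t, 1) else t
  r <- geometric_ratios(T)
  f <- (1 - exp(-r[, "Ra"]^2 / (2 * p$alpha^2))) *
    exp(-r[, "Rb"]^2 / (2 * p$beta^2)) *
    (1 - exp(-r[, "S"]^2 / (2 * gamma^2)))
  f <- ifelse(T[, 2] <= 0 & T[, 3] <= 0, f, 0)
  if (scalar) f[[1]] else f
}

#' Multi-scale Frangi filtering of a volume
#'
#' Per-voxel maximum of the vesselness response over the configured scales.
#' With `polarity = "dark"` the intensities are negated before the Hessian is
#' computed so the filter responds to the dark duct. When
#' `gamma = "half-max-norm"`, gamma is recomputed at every scale as half the
#' maximum Hessian Frobenius norm over the volume (restricted to `mask` when
#' given).
#'
#' @param v a [volume()], typically normalized to `[0, 1]`.
#' @param p a [vesselness_params()].
#' @param mask optional [label_mask()] restricting the gamma statistic.
#' @return [volume()] of vesselness responses in `[0, 1]`.
#' @export
frangi_filter <- function(v, p, mask = NULL) {
  stopifnot(inherits(v, "volume"), inherits(p, "vesselness_params"))
  if (!is.null(mask)) check_aligned(v, mask)
  src <- v
  if (p$polarity == "dark") src <- volume(-v$data, v$spacing, v$origin)
  best <- array(0, dim(v$data))
  for (s in p$scales) {
    H <- hessian_field(src, s)
    fro2 <- H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2)
    if (is.numeric(p$gamma)) {
      gam <- p$gamma
    } else {
      m2 <- if (is.null(mask)) max(fro2) else suppressWarnings(max(fro2[mask$data != 0]))
      # a vanishing Hessian norm (constant volume up to roundoff) means no
      # structure at this scale
      if (!is.finite(m2) || sqrt(m2) < 1e-8) next
      gam <- sqrt(m2) / 2
    }
    E <- eig_sym3(as.vector(H$xx), as.vector(H$yy), as.vector(H$zz),
                  as.vector(H$xy), as.vector(H$xz), as.vector(H$yz))
    t3 <- sort_eigs(E[, 1], E[, 2], E[, 3])
    f <- vesselness(t3, p, gam)
    best <- pmax(best, array(f, dim(v$data)))
  }
  volume(best, v$spacing, v$origin)
}

#' Mask and normalize the enhancement channel
#'
#' Zeroes the filter response outside the pancreas mask and min-max rescales
#' the remaining values inside the mask to `[0, 1]`. A constant response
#' inside the mask maps to all zeros.
#'
#' @param e enhancement [volume()] (e.g. from [frangi_filter()]).
#' @param m aligned pancreas [label_mask()].
#' @param normalize if `FALSE`, only the masking step is applied (the
#'   un-normalized variant of the input channel).
#' @return [volume()] that is zero outside `m`.
#' @export
postprocess_enhancement <- function(e, m, normalize = TRUE) {
  stopifnot(inherits(e, "volume"), inherits(m, "label_mask"))
  check_aligned(e, m)
  inside <- m$data != 0
  out <- array(0, dim(e$data))
  if (any(inside)) {
    vals <- e$data[inside]
    if (normalize) {
      rng <- range(vals)
      out[inside] <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else 0
    } else {
      out[inside] <- vals
    }
  }
  volume(out, e$spacing, e$origin)
}
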