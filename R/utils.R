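# Internal array helpers shared by preprocessing, filtering and the network code.

#' Apply a matrix along one axis of an array
#'
#' Computes the tensor contraction `out[i, ...] = sum_a M[i, a] * x[a, ...]`
#' along the chosen axis, leaving all other axes untouched. This is the
#' workhorse behind separable interpolation, adaptive average pooling,
#' trilinear upsampling and separable Gaussian convolution.
#'
#' @param x array (any number of dimensions >= axis).
#' @param M numeric matrix with `ncol(M) == dim(x)[axis]`.
#' @param axis integer axis index.
#' @return array with `dim(x)[axis]` replaced by `nrow(M)`.
#' @keywords internal
apply_axis <- function(x, M, axis) {
  d <- dim(x)
  stopifnot(ncol(M) == d[axis])
  ds_axismap(x, d, M, axis)
}

# Linear-interpolation matrix mapping n_in samples at positions `pos_in` to the
# requested output positions (both in the same continuous index coordinate,
# 0-based voxel centers). Out-of-range positions clamp to the border sample.
interp_matrix <- function(n_in, pos_out) {
  A <- matrix(0, length(pos_out), n_in)
  p <- pmin(pmax(pos_out, 0), n_in - 1)
  lo <- pmin(floor(p), n_in - 1)
  w <- p - lo
  for (i in seq_along(p)) {
    j <- lo[i] + 1
    if (w[i] < .Machine$double.eps || j == n_in) {
      A[i, j] <- A[i, j] + 1
    } else {
      A[i, j] <- 1 - w[i]
      A[i, j + 1] <- w[i]
    }
  }
  A
}

# Adaptive average pooling matrix: output bin i averages input samples whose
# index falls in [floor(i*n/m), ceiling((i+1)*n/m)) -- the PyTorch convention.
adaptive_pool_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- floor((i - 1) * n_in / n_out) + 1
    b <- ceiling(i * n_in / n_out)
    A[i, a:b] <- 1 / (b - a + 1)
  }
  A
}

# Trilinear upsampling matrix for integer factor f (voxel-center alignment,
# i.e. output center j maps to input coordinate (j + 0.5)/f - 0.5).
upsample_matrix <- function(n_in, n_out) {
  f <- n_out / n_in
  interp_matrix(n_in, (seq_len(n_out) - 0.5) / f - 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ductseg <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ductseg_error")))
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_ductseg("spacing must be 3 positive finite values, got [%s]",
                 paste(format(spacing), collapse = ", "), class = "ductseg_format_error")
  }
  as.numeric(spacing)
}
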