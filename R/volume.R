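# Volumetric containers and the preprocessing chain: HU clipping + min-max
# normalization, isotropic resampling, pancreas-ROI cropping and the inverse
# placement of ROI predictions back into the full grid.

#' Volumetric image with world spacing
#'
#' A `volume` is a 3D scalar grid plus per-axis voxel spacing in millimetres
#' and a world origin offset. It carries CT intensities (Hounsfield units or
#' normalized values) as well as derived maps such as the tubular-enhancement
#' channel. Axis order is (x, y, z) as stored in the NIfTI header; voxel
#' centers sit at `origin + index * spacing` with 0-based indices.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, mm per voxel along each axis (positive).
#' @param origin numeric length-3 world offset in mm.
#' @return object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_ductseg("volume data must be a 3D array", class = "ductseg_format_error")
  }
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume")
}

#' Binary label mask aligned to a volume
#'
#' Same geometry as [volume()] but with values restricted to \{0, 1\}. Used for
#' the coarse pancreas mask, the duct ground truth and binarized predictions.
#'
#' @inheritParams volume
#' @return object of class `c("label_mask", "volume")`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume(data, spacing, origin)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1))) {
    stop_ductseg("label mask must be binary (values in {0, 1})",
                 class = "ductseg_format_error")
  }
  class(v) <- c("label_mask", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing [%s] mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop_ductseg("grids are not aligned (shape/spacing mismatch)",
                 class = "ductseg_alignment_error")
  }
  invisible(TRUE)
}

#' Read a volume from a NIfTI file
#'
#' Spacing and origin are taken from the file header (`pixdim` and the
#' qform/sform translation); intensities are returned in file units.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask logical; if `TRUE` validate and return a [label_mask()].
#' @return a [volume()] or [label_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) {
    stop_ductseg("file not found: %s", path, class = "ductseg_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    stop_ductseg("expected a 3D image, got %d dimensions in %s",
                 length(d), path, class = "ductseg_format_error")
  }
  spacing <- check_spacing(RNifti::pixdim(img))
  org <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                  error = function(e) c(0, 0, 0))
  dat <- array(as.numeric(img), dim = d)
  if (mask) label_mask(dat, spacing, org) else volume(dat, spacing, org)
}

#' Write a volume to a NIfTI file
#'
#' @param v a [volume()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  qf <- structure(diag(c(v$spacing, 1)), code = 2L)
  qf[1:3, 4] <- v$origin
  img <- RNifti::`qform<-`(img, qf)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Clip CT intensities and rescale to [0, 1]
#'
#' Keeps intensities within `[lo, hi]` Hounsfield units and min-max rescales
#' the clipped range to `[0, 1]`: `(clip(x, lo, hi) - lo) / (hi - lo)`. The
#' defaults (-200, 200) bracket the soft-tissue window in which the pancreas
#' and duct are visible on portal-venous CT. Bounds are fixed rather than
#' per-volume so intensities are comparable across cases.
#'
#' @param v a [volume()].
#' @param lo,hi clipping bounds in HU, `lo < hi`.
#' @return normalized [volume()] with values in `[0, 1]`.
#' @export
clip_normalize <- function(v, lo = -200, hi = 200) {
  stopifnot(inherits(v, "volume"))
  if (!(lo < hi)) {
    stop_ductseg("clip bounds must satisfy lo < hi (got %g >= %g)", lo, hi,
                 class = "ductseg_parameter_error")
  }
  out <- (pmin(pmax(v$data, lo), hi) - lo) / (hi - lo)
  volume(array(out, dim(v$data)), v$spacing, v$origin)
}

#' Resample a volume to isotropic spacing
#'
#' The output grid has spacing `(target, target, target)` mm and per-axis shape
#' `round(shape * spacing / target)`. Continuous images are interpolated
#' trilinearly; masks use nearest-neighbour lookup, which preserves the binary
#' value set. When the input is already isotropic at `target` the data pass
#' through unchanged.
#'
#' @param v a [volume()] or [label_mask()].
#' @param target isotropic target spacing in mm (> 0).
#' @param mode `"continuous"` (trilinear) or `"nearest"`. Defaults to
#'   `"nearest"` for label masks and `"continuous"` otherwise.
#' @return resampled object of the same class as `v`.
#' @export
resample_isotropic <- function(v, target,
                               mode = if (inherits(v, "label_mask")) "nearest" else "continuous") {
  stopifnot(inherits(v, "volume"))
  mode <- match.arg(mode, c("continuous", "nearest"))
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target) || target <= 0) {
    stop_ductseg("target spacing must be a positive number",
                 class = "ductseg_parameter_error")
  }
  d <- dim(v$data)
  nd <- pmax(1L, as.integer(round(d * v$spacing / target)))
  if (all(nd == d) && max(abs(v$spacing - target)) < 1e-12) {
    return(v)
  }
  out <- v$data
  if (mode == "continuous") {
    for (ax in 1:3) {
      pos <- (seq_len(nd[ax]) - 1) * target / v$spacing[ax]
      out <- apply_axis(out, interp_matrix(d[ax], pos), ax)
    }
  } else {
    idx <- lapply(1:3, function(ax) {
      pmin(pmax(round((seq_len(nd[ax]) - 1) * target / v$spacing[ax]), 0), d[ax] - 1) + 1
    })
    out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out <- array(out, nd)
  if (inherits(v, "label_mask") && mode == "nearest") {
    label_mask(out, rep(target, 3), v$origin)
  } else {
    volume(out, rep(target, 3), v$origin)
  }
}

#' Crop the pancreas region of interest
#'
#' Finds the bounding box of the (nonempty) mask, expands it by `margin`
#' voxels, and centers a window of exactly `target_size` voxels on it (grown
#' beyond `target_size` only if the expanded bounding box itself is larger).
#' The window is clamped to the volume bounds; any remainder is zero-padded
#' (0 is the clip floor after normalization) and recorded so the crop is
#' exactly invertible via [restore_prediction()].
#'
#' @param v a [volume()] to crop.
#' @param m aligned pancreas [label_mask()] (nonempty).
#' @param target_size output window size per axis, recycled to length 3.
#'   Default 160 voxels per axis, the duct-stage network input.
#' @param margin bounding-box expansion in voxels before padding.
#' @return list with elements `roi` (cropped [volume()]) and `record`
#'   (a `crop_record` usable with [apply_crop()] / [restore_prediction()]).
#' @export
crop_roi <- function(v, m, target_size = c(160, 160, 160), margin = 16) {
  stopifnot(inherits(v, "volume"), inherits(m, "label_mask"))
  check_aligned(v, m)
  if (sum(m$data) == 0) {
    stop_ductseg("cannot crop ROI from an empty mask", class = "ductseg_empty_roi_error")
  }
  target_size <- as.integer(rep(target_size, length.out = 3))
  d <- dim(v$data)
  idx <- which(m$data != 0, arr.ind = TRUE)
  lo <- as.integer(apply(idx, 2, min)) - 1L  # 0-based
  hi <- as.integer(apply(idx, 2, max)) - 1L
  lo <- lo - as.integer(margin)
  hi <- hi + as.integer(margin)
  want <- pmax(target_size, hi - lo + 1L)
  center <- (lo + hi) / 2
  start <- as.integer(round(center - (want - 1) / 2))  # 0-based, may be negative
  # clamp the window into the volume when it fits; center it when it does not
  start <- as.integer(ifelse(want <= d, pmin(pmax(start, 0L), d - want),
                             (d - want) %/% 2L))
  end <- start + want - 1L
  ex_lo <- pmax(start, 0L)           # extracted region, 0-based inclusive
  ex_hi <- pmin(end, d - 1L)
  pad_lo <- ex_lo - start
  pad_hi <- end - ex_hi
  rec <- structure(list(start = ex_lo, shape = ex_hi - ex_lo + 1L,
                        orig_shape = d, pad_lo = pad_lo, pad_hi = pad_hi,
                        spacing = v$spacing, origin = v$origin),
                   class = "crop_record")
  list(roi = apply_crop(v, rec), record = rec)
}

#' Crop any aligned grid with an existing crop record
#'
#' Applies the window computed by [crop_roi()] to another grid of the same
#' geometry (e.g. the duct ground truth or the pancreas mask itself).
#'
#' @param v a [volume()] or [label_mask()] with the record's original shape.
#' @param rec a `crop_record`.
#' @return cropped object of the same class as `v`.
#' @export
apply_crop <- function(v, rec) {
  stopifnot(inherits(v, "volume"), inherits(rec, "crop_record"))
  if (!identical(dim(v$data), as.integer(rec$orig_shape))) {
    stop_ductseg("grid shape does not match the crop record",
                 class = "ductseg_alignment_error")
  }
  sl <- lapply(1:3, function(ax) seq.int(rec$start[ax] + 1L, length.out = rec$shape[ax]))
  core <- v$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  out_dim <- rec$shape + rec$pad_lo + rec$pad_hi
  out <- array(0, out_dim)
  dst <- lapply(1:3, function(ax) seq.int(rec$pad_lo[ax] + 1L, length.out = rec$shape[ax]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- core
  org <- v$origin + (rec$start - rec$pad_lo) * v$spacing
  if (inherits(v, "label_mask")) label_mask(out, v$spacing, org)
  else volume(out, v$spacing, org)
}

#' Place an ROI prediction back into the full-size grid
#'
#' Exact inverse of the crop: padding added by [crop_roi()] is stripped and
#' the window content is written at its recorded position; everything outside
#' the window is background (0).
#'
#' @param p predicted [label_mask()] (or [volume()]) with the record's padded
#'   window shape.
#' @param rec the `crop_record` returned by [crop_roi()].
#' @return full-size object of the same class as `p`.
#' @export
restore_prediction <- function(p, rec) {
  stopifnot(inherits(p, "volume"), inherits(rec, "crop_record"))
  want <- as.integer(rec$shape + rec$pad_lo + rec$pad_hi)
  if (!identical(dim(p$data), want)) {
    stop_ductseg("prediction shape [%s] does not match crop window [%s]",
                 paste(dim(p$data), collapse = "x"), paste(want, collapse = "x"),
                 class = "ductseg_alignment_error")
  }
  src <- lapply(1:3, function(ax) seq.int(rec$pad_lo[ax] + 1L, length.out = rec$shape[ax]))
  core <- p$data[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out <- array(0, as.integer(rec$orig_shape))
  dst <- lapply(1:3, function(ax) seq.int(rec$start[ax] + 1L, length.out = rec$shape[ax]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- core
  if (inherits(p, "label_mask")) label_mask(out, rec$spacing, rec$origin)
  else volume(out, rec$spacing, rec$origin)
}
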