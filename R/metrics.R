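# Spacing-aware segmentation metrics: Dice similarity, sensitivity,
# 95th-percentile Hausdorff distance and normalized surface distance.
# Surfaces are foreground voxels with at least one 6-connected background
# neighbour (voxels on the grid border count as surface); surface-to-surface
# distances are Euclidean in world millimetres between voxel centers.

mask_data <- function(m) {
  if (inherits(m, "volume")) m$data else m
}

check_pair <- function(a, b) {
  da <- dim(mask_data(a)); db <- dim(mask_data(b))
  if (!identical(da, db)) {
    stop_ductseg("masks are not aligned (shapes %s vs %s)",
                 paste(da, collapse = "x"), paste(db, collapse = "x"),
                 class = "ductseg_alignment_error")
  }
  if (inherits(a, "volume") && inherits(b, "volume") &&
      max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop_ductseg("masks are not aligned (spacing mismatch)",
                 class = "ductseg_alignment_error")
  }
}

#' Dice similarity coefficient (percent)
#'
#' `200 * |A intersect B| / (|A| + |B|)`. Two empty masks are in perfect
#' agreement by convention (100).
#'
#' @param a,b binary masks ([label_mask()] or 3D arrays) on the same grid.
#' @return DSC in `[0, 100]`.
#' @export
dsc <- function(a, b) {
  check_pair(a, b)
  av <- mask_data(a); bv <- mask_data(b)
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(100)
  200 * sum(av * bv) / (sa + sb)
}

#' Sensitivity / recall (percent)
#'
#' Fraction of ground-truth voxels recovered by the prediction:
#' `100 * |pred intersect gt| / |gt|`. Undefined for an empty ground truth.
#'
#' @param pred predicted binary mask.
#' @param gt ground-truth binary mask (nonempty).
#' @return sensitivity in `[0, 100]`.
#' @export
sensitivity <- function(pred, gt) {
  check_pair(pred, gt)
  pv <- mask_data(pred); gv <- mask_data(gt)
  if (sum(gv) == 0) {
    stop_ductseg("sensitivity is undefined for an empty ground truth",
                 class = "ductseg_undefined_metric_error")
  }
  100 * sum(pv * gv) / sum(gv)
}

# 0-based voxel indices of surface voxels (foreground with a 6-neighbour
# background voxel; out-of-grid counts as background).
surface_voxels <- function(m) {
  v <- mask_data(m) != 0
  d <- dim(v)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, dir) {
    # TRUE where the 6-neighbour in direction (ax, dir) exists and is foreground
    out <- array(FALSE, d)
    n <- d[ax]
    if (n == 1) return(out)
    src <- vector("list", 3); dst <- vector("list", 3)
    for (k in 1:3) { src[[k]] <- seq_len(d[k]); dst[[k]] <- seq_len(d[k]) }
    if (dir > 0) { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    else { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (dir in c(-1, 1)) interior <- interior & shift_ok(ax, dir)
  which(v & !interior, arr.ind = TRUE) - 1L
}

# For each row of P (0-based voxel indices), the Euclidean distance in mm to
# the nearest row of Q. Chunked pairwise computation, exact.
nearest_dists <- function(P, Q, spacing, chunk = 2048L) {
  Pmm <- sweep(P, 2, spacing, "*")
  Qmm <- sweep(Q, 2, spacing, "*")
  nq <- nrow(Qmm)
  q2 <- rowSums(Qmm^2)
  out <- numeric(nrow(Pmm))
  for (s in seq(1, nrow(Pmm), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(Pmm))
    Pc <- Pmm[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), q2, "+") - 2 * Pc %*% t(Qmm)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

surface_dist_sets <- function(a, b, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (inherits(a, "volume")) a$spacing else c(1, 1, 1)
  }
  av <- mask_data(a); bv <- mask_data(b)
  if (sum(av) == 0 || sum(bv) == 0) {
    stop_ductseg("surface distances are undefined for an empty mask",
                 class = "ductseg_undefined_metric_error")
  }
  Sa <- surface_voxels(a); Sb <- surface_voxels(b)
  list(ab = nearest_dists(Sa, Sb, spacing), ba = nearest_dists(Sb, Sa, spacing))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The given percentile of the pooled symmetric surface-to-surface nearest
#' distances; `percentile = 100` gives the exact Hausdorff distance.
#'
#' @param a,b nonempty binary masks on the same grid.
#' @param spacing mm per voxel (taken from `a` when it is a [label_mask()]).
#' @param percentile percentile of the pooled distances.
#' @return distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL, percentile = 95) {
  check_pair(a, b)
  ds <- surface_dist_sets(a, b, spacing)
  unname(stats::quantile(c(ds$ab, ds$ba), percentile / 100, type = 7))
}

#' Normalized surface distance (percent)
#'
#' Fraction of surface voxels of each mask lying within a tolerance `tau` of
#' the other mask's surface:
#' `100 * (|Sa within tau of Sb| + |Sb within tau of Sa|) / (|Sa| + |Sb|)`.
#'
#' @param a,b nonempty binary masks on the same grid.
#' @param spacing mm per voxel (taken from `a` when it is a [label_mask()]).
#' @param tau tolerance in mm (> 0).
#' @return NSD in `[0, 100]`.
#' @export
nsd <- function(a, b, spacing = NULL, tau = 1.0) {
  check_pair(a, b)
  if (tau <= 0) stop_ductseg("tau must be > 0", class = "ductseg_parameter_error")
  ds <- surface_dist_sets(a, b, spacing)
  # inclusive threshold with a 1e-9 mm guard: distances that equal tau up to
  # floating-point roundoff (e.g. sqrt(0.6^2 + 0.8^2) vs tau = 1) count as in
  tol <- tau + 1e-9
  100 * (sum(ds$ab <= tol) + sum(ds$ba <= tol)) / (length(ds$ab) + length(ds$ba))
}

#' Per-case metrics report
#'
#' Computes all four evaluation measures for one case. An empty prediction
#' yields DSC 0, sensitivity 0 and missing (`NA`) surface metrics rather than
#' fabricated values.
#'
#' @param pred predicted binary mask.
#' @param gt ground-truth binary mask (nonempty).
#' @param spacing mm per voxel.
#' @param tau NSD tolerance in mm.
#' @param case_id optional identifier copied into the report.
#' @return one-row data.frame with `case_id`, `dsc`, `sensitivity`, `nsd`,
#'   `hd95`.
#' @export
metrics_report <- function(pred, gt, spacing = NULL, tau = 1.0, case_id = NA) {
  check_pair(pred, gt)
  empty_pred <- sum(mask_data(pred)) == 0
  data.frame(case_id = case_id,
             dsc = dsc(pred, gt),
             sensitivity = sensitivity(pred, gt),
             nsd = if (empty_pred) NA_real_ else nsd(pred, gt, spacing, tau),
             hd95 = if (empty_pred) NA_real_ else hd95(pred, gt, spacing))
}

#' Mean and standard deviation summary of per-case metrics
#'
#' @param reports data.frame of rows from [metrics_report()].
#' @return data.frame with one row per metric: mean, sd, n (missing values
#'   dropped per metric).
#' @export
summarize_metrics <- function(reports) {
  cols <- c("dsc", "sensitivity", "nsd", "hd95")
  do.call(rbind, lapply(cols, function(cl) {
    x <- reports[[cl]]
    data.frame(metric = cl, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE), n = sum(!is.na(x)))
  }))
}
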