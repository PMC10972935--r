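# Coarse-to-fine cascade orchestration: coarse pancreas mask -> isotropic
# resampling -> ROI crop -> tubular-enhancement channel -> attention-gated
# duct segmentation -> restoration to the full grid -> evaluation.

#' Cascade configuration
#'
#' Bundles the two-stage geometry (pancreas stage at 1 mm, duct stage at
#' 0.5 mm isotropic), the ROI size, the network variant and backbone, the
#' vesselness parameters and the training configuration. The pancreas mask
#' either comes from a trained stage-1 model or is supplied directly (oracle
#' mask mode, which makes the full pipeline testable without the public
#' pancreas dataset).
#'
#' @param variant a [variant_spec()] or variant name.
#' @param backbone a [backbone_config()]; its `in_channels` must match the
#'   variant. Default: 4-level V-Net with 16 initial filters and instance
#'   normalization, the best duct-stage combination.
#' @param vessel_params a [vesselness_params()].
#' @param train a [train_config()].
#' @param stage1_spacing isotropic spacing of the pancreas stage in mm.
#' @param stage2_spacing isotropic spacing of the duct stage in mm.
#' @param roi_size ROI window voxels per axis (default 160); must be
#'   divisible by `2^(levels - 1)` of the backbone.
#' @param margin ROI bounding-box margin in voxels.
#' @param clip HU clipping bounds applied before normalization, or `NULL`
#'   when inputs are already normalized to `[0, 1]` (e.g. phantoms).
#' @param tau NSD tolerance in mm for evaluation.
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(variant = "nmcpamnet", backbone = NULL,
                           vessel_params = vesselness_params(),
                           train = train_config(),
                           stage1_spacing = 1.0, stage2_spacing = 0.5,
                           roi_size = 160, margin = 16,
                           clip = c(-200, 200), tau = 1.0) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(variant, "variant_spec"))
  in_ch <- if (variant$enhancement_channel == "none") 1L else 2L
  if (is.null(backbone)) {
    backbone <- backbone_config("vnet", levels = 4, initial_filters = 16,
                                norm = "IN", in_channels = in_ch)
  }
  stopifnot(inherits(backbone, "backbone_config"))
  if (backbone$in_channels != in_ch) {
    stop_ductseg("backbone in_channels (%d) inconsistent with variant %s",
                 backbone$in_channels, variant$name, class = "ductseg_config_error")
  }
  if (stage1_spacing <= 0 || stage2_spacing <= 0) {
    stop_ductseg("stage spacings must be positive", class = "ductseg_parameter_error")
  }
  roi_size <- as.integer(rep(roi_size, length.out = 3))
  if (any(roi_size %% 2^(backbone$levels - 1) != 0)) {
    stop_ductseg("roi_size must be divisible by 2^(levels-1) = %d",
                 2^(backbone$levels - 1), class = "ductseg_config_error")
  }
  structure(list(variant = variant, backbone = backbone,
                 vessel_params = vessel_params, train = train,
                 stage1_spacing = stage1_spacing, stage2_spacing = stage2_spacing,
                 roi_size = roi_size, margin = margin, clip = clip, tau = tau),
            class = "cascade_config")
}

# Trim/zero-pad a resampled mask at the high end so it shares the CT grid
# (resampling two grids with different native spacings can differ by one
# voxel of rounding per axis).
match_grid <- function(m, ref_dim) {
  d <- dim(m$data)
  if (identical(d, as.integer(ref_dim))) return(m)
  out <- array(0, ref_dim)
  take <- pmin(d, ref_dim)
  out[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])] <-
    m$data[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])]
  if (inherits(m, "label_mask")) label_mask(out, m$spacing, m$origin)
  else volume(out, m$spacing, m$origin)
}

# Duct-stage preprocessing shared by training and inference: normalization,
# resampling to the stage-2 grid, ROI cropping and (for 2-channel variants)
# the enhancement channel. Never touches the duct ground truth.
prepare_roi_inputs <- function(ct, pancreas, cfg) {
  stopifnot(inherits(ct, "volume"), inherits(pancreas, "label_mask"))
  log <- list()
  if (!is.null(cfg$clip)) {
    ct <- clip_normalize(ct, cfg$clip[1], cfg$clip[2])
    log$clip <- cfg$clip
  }
  ct2 <- resample_isotropic(ct, cfg$stage2_spacing, mode = "continuous")
  m2 <- match_grid(resample_isotropic(pancreas, cfg$stage2_spacing, mode = "nearest"),
                   dim(ct2$data))
  log$resample <- dim(ct2$data)
  cr <- crop_roi(ct2, m2, target_size = cfg$roi_size, margin = cfg$margin)
  roi <- cr$roi
  mask_roi <- apply_crop(m2, cr$record)
  log$roi <- dim(roi$data)
  enh <- NULL
  if (cfg$variant$enhancement_channel != "none") {
    raw <- frangi_filter(roi, cfg$vessel_params, mask = mask_roi)
    enh <- postprocess_enhancement(raw, mask_roi,
                                   normalize = cfg$variant$enhancement_channel == "normalized")
    log$enhancement <- cfg$variant$enhancement_channel
  }
  list(roi = roi, mask_roi = mask_roi, enhancement = enh, record = cr$record,
       mask_full = m2, log = log)
}

#' Run the duct-segmentation cascade on one case
#'
#' Executes the full chain: intensity normalization, resampling to the
#' duct-stage spacing, pancreas-mask acquisition (oracle mask or stage-1
#' model), ROI cropping, enhancement-channel computation (for 2-channel
#' variants), network prediction, and restoration of the prediction into the
#' full-size grid. The duct ground truth, when provided, is used only for the
#' final evaluation.
#'
#' @param ct the input CT [volume()] (HU, or normalized when `cfg$clip` is `NULL`).
#' @param cfg a [cascade_config()].
#' @param model a trained `duct_fcn` matching `cfg$variant`.
#' @param pancreas oracle pancreas [label_mask()] aligned to `ct` (or at the
#'   stage-1 spacing); required unless `stage1_model` is given.
#' @param duct optional duct ground-truth [label_mask()] aligned to `ct`.
#' @param stage1_model optional trained backbone for coarse pancreas
#'   segmentation, used when `pancreas` is `NULL`.
#' @param case_id identifier carried into the metrics report.
#' @return list with `prediction` (full-size [label_mask()]), `probability`
#'   (ROI [volume()]), `enhancement` (ROI [volume()] or `NULL`), `record`
#'   (crop record), `metrics` (one-row data.frame or `NULL`) and `log`.
#' @export
run_cascade <- function(ct, cfg, model, pancreas = NULL, duct = NULL,
                        stage1_model = NULL, case_id = NA) {
  stopifnot(inherits(cfg, "cascade_config"), inherits(model, "duct_fcn"))
  if (is.null(pancreas)) {
    if (is.null(stage1_model)) {
      stop_ductseg("need an oracle pancreas mask or a stage-1 model",
                   class = "ductseg_config_error")
    }
    ct1 <- if (!is.null(cfg$clip)) clip_normalize(ct, cfg$clip[1], cfg$clip[2]) else ct
    ct1 <- resample_isotropic(ct1, cfg$stage1_spacing, mode = "continuous")
    pr <- stats::predict(stage1_model, ct1, threshold = cfg$train$threshold)
    pancreas <- pr$mask
  }
  if (sum(pancreas$data) == 0) {
    stop_ductseg("stage-1 pancreas mask is empty (case %s)", case_id,
                 class = "ductseg_empty_roi_error")
  }
  prep <- prepare_roi_inputs(ct, pancreas, cfg)
  pred <- stats::predict(model, prep$roi, pancreas = prep$mask_roi,
                         enhancement = prep$enhancement,
                         threshold = cfg$train$threshold)
  full <- restore_prediction(pred$mask, prep$record)
  metrics <- NULL
  if (!is.null(duct)) {
    gt2 <- match_grid(resample_isotropic(duct, cfg$stage2_spacing, mode = "nearest"),
                      dim(full$data))
    metrics <- metrics_report(full, gt2, spacing = full$spacing, tau = cfg$tau,
                              case_id = case_id)
  }
  list(prediction = full, probability = pred$probability,
       enhancement = prep$enhancement, record = prep$record,
       metrics = metrics, log = prep$log)
}

#' Cross-validated duct-segmentation experiment
#'
#' Splits the cases into `cfg$train$fold_count` folds, trains one network per
#' fold on the training split and evaluates it on the held-out cases through
#' the full cascade. Deterministic for a given `cfg$train$seed`.
#'
#' @param cases list of cases, each a list with `volume` (CT), `pancreas`
#'   (oracle mask) and `duct` (ground truth) — the layout produced by
#'   [generate_dataset()].
#' @param cfg a [cascade_config()].
#' @param verbose print per-fold progress.
#' @return list with `per_case` (data.frame of [metrics_report()] rows, one
#'   per case), `summary` (from [summarize_metrics()]), `folds` (assignment)
#'   and `histories` (per-fold loss histories).
#' @export
run_experiment <- function(cases, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "cascade_config"))
  n <- length(cases)
  k <- cfg$train$fold_count
  if (n < k) stop_ductseg("need at least %d cases for %d folds", k, k,
                          class = "ductseg_parameter_error")
  folds <- make_folds(n, k, seed = cfg$train$seed)
  prepped <- lapply(cases, function(cs) prepare_roi_inputs(cs$volume, cs$pancreas, cfg))
  roi_case <- function(i) {
    p <- prepped[[i]]
    duct_roi <- apply_crop(match_grid(
      resample_isotropic(cases[[i]]$duct, cfg$stage2_spacing, mode = "nearest"),
      as.integer(p$record$orig_shape)), p$record)
    as_training_case(p$roi, duct = duct_roi, pancreas = p$mask_roi,
                     enhancement = p$enhancement)
  }
  rows <- vector("list", n)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    va_idx <- which(folds == f)
    if (verbose) message(sprintf("fold %d/%d: %d train / %d val cases",
                                 f, k, length(tr_idx), length(va_idx)))
    model <- build_variant(cfg$variant, cfg$backbone, seed = cfg$train$seed + f)
    fit <- train_model(model, lapply(tr_idx, roi_case), cfg$train)
    histories[[f]] <- fit$history
    for (i in va_idx) {
      res <- run_cascade(cases[[i]]$volume, cfg, fit$model,
                         pancreas = cases[[i]]$pancreas, duct = cases[[i]]$duct,
                         case_id = i)
      rows[[i]] <- cbind(res$metrics, fold = f)
    }
  }
  per_case <- do.call(rbind, rows)
  list(per_case = per_case, summary = summarize_metrics(per_case),
       folds = folds, histories = histories)
}
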