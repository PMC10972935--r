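# The scalable volumetric FCN family: V-Net and 3D U-Net backbones, the
# pancreas-mask-guided (anatomical) attention gate, multi-scale aggregation,
# and the five network variants compared for duct segmentation.
#
# V-Net convention (pinned to the published parameter counts): 5x5x5 convs,
# min(level, 3) convs per stage with a residual connection around each stage,
# 2x2x2 stride-2 down-convolutions doubling channels, 2x2x2 transposed
# up-convolutions halving channels, and additive fusion of the encoder skip
# with the upsampled decoder feature. 3D U-Net convention: 3x3x3 convs with
# channel doubling inside each level, 2x2x2 max pooling, channel-preserving
# up-convolutions and concatenated skips.

#' Backbone configuration
#'
#' @param family `"vnet"` or `"unet3d"`.
#' @param levels number of resolution levels (>= 2). The duct-stage networks
#'   use 4; the standard V-Net has 5.
#' @param initial_filters channels produced by the first convolution
#'   (V-Net standard 16, 3D U-Net standard 32).
#' @param norm `"IN"` (instance) or `"BN"` (batch) normalization.
#' @param in_channels 1 (CT only) or 2 (CT + enhancement channel).
#' @param out_classes output channels (1: duct probability).
#' @param input_size optional per-axis input size; must be divisible by
#'   `2^(levels - 1)`. Parameter counts do not depend on it (the networks are
#'   fully convolutional); it is validated at forward time.
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(family = c("vnet", "unet3d"), levels = 4,
                            initial_filters = 16, norm = c("IN", "BN"),
                            in_channels = 1, out_classes = 1,
                            input_size = NULL) {
  family <- match.arg(family)
  norm <- match.arg(norm)
  if (levels < 2) stop_ductseg("levels must be >= 2", class = "ductseg_config_error")
  if (initial_filters < 1) stop_ductseg("initial_filters must be >= 1", class = "ductseg_config_error")
  if (!in_channels %in% c(1, 2)) stop_ductseg("in_channels must be 1 or 2", class = "ductseg_config_error")
  if (!is.null(input_size)) {
    input_size <- as.integer(rep(input_size, length.out = 3))
    if (any(input_size %% 2^(levels - 1) != 0)) {
      stop_ductseg("input_size must be divisible by 2^(levels-1) = %d",
                   2^(levels - 1), class = "ductseg_config_error")
    }
  }
  structure(list(family = family, levels = as.integer(levels),
                 initial_filters = as.integer(initial_filters), norm = norm,
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes), input_size = input_size),
            class = "backbone_config")
}

#' Network variant specification
#'
#' The five ablation variants: `attention_unet` (self-gated attention
#' baseline), `panet` (pancreas-mask attention), `pamnet` (+ multi-scale
#' aggregation), `mcpamnet` (+ un-normalized tubular-enhancement channel) and
#' `nmcpamnet` (+ min-max-normalized enhancement channel).
#'
#' @param name one of `"attention_unet"`, `"panet"`, `"pamnet"`,
#'   `"mcpamnet"`, `"nmcpamnet"`.
#' @return object of class `variant_spec` with fields `attention_source`
#'   (`"self_gating"` or `"pancreas_mask"`), `multiscale_aggregation` and
#'   `enhancement_channel` (`"none"`, `"raw"`, `"normalized"`).
#' @export
variant_spec <- function(name = c("nmcpamnet", "attention_unet", "panet",
                                  "pamnet", "mcpamnet")) {
  name <- match.arg(name)
  spec <- switch(name,
    attention_unet = list(attention_source = "self_gating",
                          multiscale_aggregation = FALSE, enhancement_channel = "none"),
    panet = list(attention_source = "pancreas_mask",
                 multiscale_aggregation = FALSE, enhancement_channel = "none"),
    pamnet = list(attention_source = "pancreas_mask",
                  multiscale_aggregation = TRUE, enhancement_channel = "none"),
    mcpamnet = list(attention_source = "pancreas_mask",
                    multiscale_aggregation = TRUE, enhancement_channel = "raw"),
    nmcpamnet = list(attention_source = "pancreas_mask",
                     multiscale_aggregation = TRUE, enhancement_channel = "normalized"))
  structure(c(list(name = name), spec), class = "variant_spec")
}

# ---- layer registry ---------------------------------------------------------

new_registry <- function() {
  r <- new.env(parent = emptyenv())
  r$shapes <- list(); r$meta <- list()
  r
}

reg_conv <- function(reg, name, cin, cout, k, stride = 1L, pad = "same",
                     bias = TRUE, norm = NULL, act = NULL, transpose = FALSE) {
  reg$shapes[[paste0(name, ".W")]] <- c(k^3 * cin, cout)
  if (bias) reg$shapes[[paste0(name, ".b")]] <- cout
  if (!is.null(norm)) {
    reg$shapes[[paste0(name, ".g")]] <- cout
    reg$shapes[[paste0(name, ".be")]] <- cout
  }
  if (identical(act, "prelu")) reg$shapes[[paste0(name, ".a")]] <- cout
  reg$meta[[name]] <- list(cin = cin, cout = cout, k = as.integer(k),
                           stride = as.integer(stride), pad = pad, bias = bias,
                           norm = norm, act = act, transpose = transpose)
  invisible(reg)
}

vnet_channels <- function(cfg) cfg$initial_filters * 2^(0:(cfg$levels - 1))
unet_channels <- function(cfg) {
  list(a = cfg$initial_filters * 2^(0:(cfg$levels - 1)),
       b = cfg$initial_filters * 2^(1:cfg$levels))
}
n_stage_convs <- function(i) min(i, 3L)

register_backbone <- function(reg, cfg, variant = NULL) {
  L <- cfg$levels
  act <- if (cfg$family == "vnet") "prelu" else "relu"
  if (cfg$family == "vnet") {
    ch <- vnet_channels(cfg)
    for (i in seq_len(L)) {
      for (j in seq_len(n_stage_convs(i))) {
        cin <- if (i == 1 && j == 1) cfg$in_channels else ch[i]
        reg_conv(reg, sprintf("enc%d.conv%d", i, j), cin, ch[i], 5, norm = cfg$norm, act = act)
      }
      if (i < L) reg_conv(reg, sprintf("down%d", i), ch[i], ch[i + 1], 2,
                          stride = 2, pad = "valid", norm = cfg$norm, act = act)
    }
    for (i in seq.int(L - 1, 1)) {
      reg_conv(reg, sprintf("up%d", i), ch[i + 1], ch[i], 2, norm = cfg$norm,
               act = act, transpose = TRUE)
      for (j in seq_len(n_stage_convs(i))) {
        reg_conv(reg, sprintf("dec%d.conv%d", i, j), ch[i], ch[i], 5, norm = cfg$norm, act = act)
      }
    }
    skip_ch <- ch[seq_len(L - 1)]
    dec_ch <- ch
  } else {
    cc <- unet_channels(cfg)
    for (i in seq_len(L)) {
      cin <- if (i == 1) cfg$in_channels else cc$b[i - 1]
      reg_conv(reg, sprintf("enc%d.conv1", i), cin, cc$a[i], 3, norm = cfg$norm, act = act)
      reg_conv(reg, sprintf("enc%d.conv2", i), cc$a[i], cc$b[i], 3, norm = cfg$norm, act = act)
    }
    for (i in seq.int(L - 1, 1)) {
      reg_conv(reg, sprintf("up%d", i), cc$b[i + 1], cc$b[i + 1], 2,
               norm = cfg$norm, act = act, transpose = TRUE)
      reg_conv(reg, sprintf("dec%d.conv1", i), cc$b[i + 1] + cc$b[i], cc$b[i], 3,
               norm = cfg$norm, act = act)
      reg_conv(reg, sprintf("dec%d.conv2", i), cc$b[i], cc$b[i], 3, norm = cfg$norm, act = act)
    }
    skip_ch <- cc$b[seq_len(L - 1)]
    dec_ch <- cc$b
  }
  if (!is.null(variant)) {
    src_ch <- function(i) {
      if (variant$attention_source == "pancreas_mask") 1L else dec_ch[i + 1]
    }
    for (i in seq_len(L - 1)) {
      reg_conv(reg, sprintf("att%d.x", i), skip_ch[i], 1L, 2, stride = 2, pad = "valid")
      reg_conv(reg, sprintf("att%d.g", i), src_ch(i), 1L, 1)
    }
    if (variant$multiscale_aggregation) {
      for (i in seq_len(L)) {
        reg_conv(reg, sprintf("agg.head%d", i), dec_ch[i], cfg$out_classes, 1)
      }
      reg_conv(reg, "agg.fuse", L * cfg$out_classes, cfg$out_classes, 1)
    } else {
      reg_conv(reg, "out", dec_ch[1], cfg$out_classes, 1)
    }
  } else {
    reg_conv(reg, "out", dec_ch[1], cfg$out_classes, 1)
  }
  invisible(reg)
}

init_params <- function(shapes, meta, seed = 1L) {
  set.seed(seed)
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    suffix <- sub(".*\\.", "", nm)
    params[[nm]] <- switch(suffix,
      W = matrix(stats::rnorm(prod(sh), sd = sqrt(2 / sh[1])), sh[1], sh[2]),
      b = numeric(sh),
      g = rep(1, sh),
      be = numeric(sh),
      a = rep(0.25, sh),
      stop("unknown parameter suffix: ", nm))
  }
  params
}

#' Build a backbone network
#'
#' Constructs a plain encoder-decoder FCN (no attention, no aggregation) of
#' the configured family, with channels doubling per level. Weights use
#' Kaiming-style initialization under the given seed.
#'
#' @param cfg a [backbone_config()].
#' @param init if `FALSE`, only layer shapes are created (enough for
#'   [count_parameters()]) and no weight memory is allocated.
#' @param seed integer seed for weight initialization.
#' @return object of class `duct_fcn`.
#' @export
build_backbone <- function(cfg, init = TRUE, seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  reg <- new_registry()
  register_backbone(reg, cfg, variant = NULL)
  model <- structure(list(config = cfg, variant = NULL, shapes = reg$shapes,
                          meta = reg$meta, params = NULL,
                          state = new.env(parent = emptyenv())),
                     class = "duct_fcn")
  if (init) model$params <- init_params(reg$shapes, reg$meta, seed)
  model
}

#' Assemble one of the duct-segmentation variants
#'
#' Adds the attention gates (mask-guided or self-gated), the optional
#' multi-scale aggregation head and the enhancement input channel to a
#' backbone of the configured family. The forward pass of the returned model
#' takes the CT ROI (with the enhancement channel when the variant uses one)
#' plus the pancreas mask and returns per-voxel duct probabilities.
#'
#' @param variant a [variant_spec()] or variant name.
#' @param cfg a [backbone_config()]; `in_channels` must be 2 exactly when the
#'   variant uses an enhancement channel.
#' @inheritParams build_backbone
#' @return object of class `duct_fcn`.
#' @export
build_variant <- function(variant, cfg, init = TRUE, seed = 1L) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(variant, "variant_spec"), inherits(cfg, "backbone_config"))
  want_in <- if (variant$enhancement_channel == "none") 1L else 2L
  if (cfg$in_channels != want_in) {
    stop_ductseg("variant %s requires in_channels = %d (got %d)",
                 variant$name, want_in, cfg$in_channels, class = "ductseg_config_error")
  }
  reg <- new_registry()
  register_backbone(reg, cfg, variant = variant)
  model <- structure(list(config = cfg, variant = variant, shapes = reg$shapes,
                          meta = reg$meta, params = NULL,
                          state = new.env(parent = emptyenv())),
                     class = "duct_fcn")
  if (init) model$params <- init_params(reg$shapes, reg$meta, seed)
  model
}

#' Count trainable parameters
#'
#' Number of trainable scalars (convolution weights and biases, normalization
#' affine parameters, PReLU slopes). Counts depend only on the layer shapes,
#' never on the input size: the networks are fully convolutional.
#'
#' @param model a `duct_fcn` from [build_backbone()] or [build_variant()].
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "duct_fcn"))
  sum(vapply(model$shapes, prod, numeric(1)))
}

#' @export
print.duct_fcn <- function(x, ...) {
  v <- if (is.null(x$variant)) "backbone" else x$variant$name
  cat(sprintf("<duct_fcn> %s (%s, levels %d, filters %d, %s), %.1f M parameters%s\n",
              v, x$config$family, x$config$levels, x$config$initial_filters,
              x$config$norm, count_parameters(x) / 1e6,
              if (is.null(x$params)) " (shapes only)" else ""))
  invisible(x)
}

# ---- forward pass -----------------------------------------------------------

conv_block <- function(tape, model, name, x, train) {
  m <- model$meta[[name]]
  W <- ag_param(tape, model$params[[paste0(name, ".W")]], paste0(name, ".W"))
  b <- if (m$bias) ag_param(tape, model$params[[paste0(name, ".b")]], paste0(name, ".b")) else NULL
  y <- if (m$transpose) ag_convT2(tape, x, W, b)
       else ag_conv3(tape, x, W, b, m$k, m$stride, m$pad)
  if (!is.null(m$norm)) {
    ga <- ag_param(tape, model$params[[paste0(name, ".g")]], paste0(name, ".g"))
    be <- ag_param(tape, model$params[[paste0(name, ".be")]], paste0(name, ".be"))
    y <- if (m$norm == "IN") ag_instnorm(tape, y, ga, be)
         else ag_batchnorm(tape, y, ga, be, model$state, name, train = train)
  }
  if (identical(m$act, "relu")) y <- ag_relu(tape, y)
  if (identical(m$act, "prelu")) {
    al <- ag_param(tape, model$params[[paste0(name, ".a")]], paste0(name, ".a"))
    y <- ag_prelu(tape, y, al)
  }
  y
}

# Attention gate at decoder level i: the skip feature passes a 2^3 stride-2
# convolution, the gating source (adaptively pooled mask, or the deeper
# decoder feature which already sits at that resolution) passes a 1^3
# convolution; their sum goes through a sigmoid and the coefficients are
# trilinearly upsampled to the skip's resolution and multiplied in.
attention_gate_fwd <- function(tape, model, i, skip, src, train) {
  xg <- conv_block(tape, model, sprintf("att%d.x", i), skip, train)
  g <- conv_block(tape, model, sprintf("att%d.g", i), src, train)
  A_half <- ag_sigmoid(tape, ag_add(tape, xg, g))
  d_half <- dim(A_half$value); d_skip <- dim(skip$value)
  Ms <- lapply(1:3, function(ax) upsample_matrix(d_half[ax], d_skip[ax]))
  A <- ag_axismap(tape, A_half, Ms)
  list(gated = ag_gate_mul(tape, skip, A), coefficients = A$value)
}

pool_mask_to <- function(tape, mask_node, target_dims) {
  d <- dim(mask_node$value)
  Ms <- lapply(1:3, function(ax) {
    if (d[ax] == target_dims[ax]) NULL else adaptive_pool_matrix(d[ax], target_dims[ax])
  })
  ag_axismap(tape, mask_node, Ms)
}

# Full forward pass. x: (X,Y,Z,N,Cin) array; mask: (X,Y,Z,N,1) array or NULL.
# Returns list(logits = node, attention = list of coefficient arrays).
fcn_forward <- function(model, x, mask = NULL, train = FALSE, tape = ag_tape()) {
  cfg <- model$config
  variant <- model$variant
  L <- cfg$levels
  d <- dim(x)
  if (length(d) != 5 || d[5] != cfg$in_channels) {
    stop_ductseg("input must be (X,Y,Z,N,%d), got [%s]", cfg$in_channels,
                 paste(d, collapse = ","), class = "ductseg_config_error")
  }
  if (any(d[1:3] %% 2^(L - 1) != 0)) {
    stop_ductseg("spatial input size must be divisible by 2^(levels-1) = %d",
                 2^(L - 1), class = "ductseg_config_error")
  }
  use_att <- !is.null(variant)
  att_src <- if (use_att) variant$attention_source else NULL
  if (identical(att_src, "pancreas_mask")) {
    if (is.null(mask)) stop_ductseg("this variant requires a pancreas mask input",
                                    class = "ductseg_config_error")
    if (!identical(dim(mask)[1:4], d[1:4])) {
      stop_ductseg("mask grid does not align with the network input",
                   class = "ductseg_alignment_error")
    }
    mask_node <- ag_const(tape, mask)
  }
  xn <- ag_const(tape, x)
  vnet <- cfg$family == "vnet"
  skips <- vector("list", L - 1)
  dec_out <- vector("list", L)
  attention <- list()
  u <- xn
  for (i in seq_len(L)) {
    inp <- u
    if (vnet) {
      for (j in seq_len(n_stage_convs(i))) {
        u <- conv_block(tape, model, sprintf("enc%d.conv%d", i, j), u, train)
      }
      if (i > 1) u <- ag_add(tape, u, inp)  # residual (channels match)
    } else {
      u <- conv_block(tape, model, sprintf("enc%d.conv1", i), u, train)
      u <- conv_block(tape, model, sprintf("enc%d.conv2", i), u, train)
    }
    if (i < L) {
      skips[[i]] <- u
      u <- if (vnet) conv_block(tape, model, sprintf("down%d", i), u, train)
           else ag_maxpool2(tape, u)
    }
  }
  dec_out[[L]] <- u
  for (i in seq.int(L - 1, 1)) {
    deeper <- u
    up <- conv_block(tape, model, sprintf("up%d", i), u, train)
    s <- skips[[i]]
    if (use_att) {
      src <- if (att_src == "pancreas_mask") {
        pool_mask_to(tape, mask_node, dim(deeper$value)[1:3])
      } else deeper
      gt <- attention_gate_fwd(tape, model, i, s, src, train)
      s <- gt$gated
      attention[[sprintf("level%d", i)]] <- gt$coefficients
    }
    if (vnet) {
      u <- ag_add(tape, up, s)
      inp <- u
      for (j in seq_len(n_stage_convs(i))) {
        u <- conv_block(tape, model, sprintf("dec%d.conv%d", i, j), u, train)
      }
      u <- ag_add(tape, u, inp)
    } else {
      u <- ag_concat(tape, list(up, s))
      u <- conv_block(tape, model, sprintf("dec%d.conv1", i), u, train)
      u <- conv_block(tape, model, sprintf("dec%d.conv2", i), u, train)
    }
    dec_out[[i]] <- u
  }
  if (use_att && variant$multiscale_aggregation) {
    full <- dim(dec_out[[1]]$value)[1:3]
    maps <- lapply(seq_len(L), function(i) {
      h <- conv_block(tape, model, sprintf("agg.head%d", i), dec_out[[i]], train)
      dh <- dim(h$value)[1:3]
      if (all(dh == full)) h
      else ag_axismap(tape, h, lapply(1:3, function(ax) upsample_matrix(dh[ax], full[ax])))
    })
    logits <- conv_block(tape, model, "agg.fuse", ag_concat(tape, maps), train)
  } else {
    logits <- conv_block(tape, model, "out", dec_out[[1]], train)
  }
  list(logits = logits, attention = attention, tape = tape)
}

#' Apply the anatomical attention gate to a feature map
#'
#' Functional form of the gate used inside the networks, for inspection and
#' testing: the feature grid is reduced by a 2x2x2 stride-2 convolution, the
#' pancreas mask is adaptively average-pooled to that resolution and mapped by
#' a 1x1x1 convolution, their sum passes a sigmoid, and the resulting
#' coefficients (in `[0, 1]`) are trilinearly upsampled and multiplied into
#' the feature map.
#'
#' @param x numeric 4D array (X, Y, Z, C): the feature map at one level.
#' @param m binary 3D array or [label_mask()]: the pancreas mask at input
#'   resolution (spatial dims must be a multiple of the feature map's).
#' @param weights optional list with elements `Wx` (`8*C x 1`), `bx`, `Wg`
#'   (`1 x 1`), `bg`; random Kaiming weights under `seed` when omitted.
#' @param seed seed for random gate weights.
#' @return list with `gated` (4D array like `x`) and `coefficients`
#'   (3D array in `[0, 1]` at the feature map's resolution).
#' @export
anatomical_attention <- function(x, m, weights = NULL, seed = 1L) {
  stopifnot(is.array(x), length(dim(x)) == 4)
  md <- if (inherits(m, "label_mask")) m$data else m
  stopifnot(is.array(md), length(dim(md)) == 3)
  if (any(dim(md) %% dim(x)[1:3] != 0)) {
    stop_ductseg("mask dims must be an integer multiple of the feature map dims",
                 class = "ductseg_alignment_error")
  }
  C <- dim(x)[4]
  if (is.null(weights)) {
    set.seed(seed)
    weights <- list(Wx = matrix(stats::rnorm(8 * C, sd = sqrt(2 / (8 * C))), 8 * C, 1),
                    bx = 0, Wg = matrix(stats::rnorm(1, sd = sqrt(2)), 1, 1), bg = 0)
  }
  tape <- ag_tape()
  xn <- ag_const(tape, array(x, c(dim(x)[1:3], 1, C)))
  mn <- ag_const(tape, array(md, c(dim(md), 1, 1)))
  xg <- ag_conv3(tape, xn, ag_const(tape, weights$Wx), ag_const(tape, weights$bx),
                 2L, 2L, "valid")
  half <- dim(xg$value)[1:3]
  mp <- pool_mask_to(tape, mn, half)
  g <- ag_conv3(tape, mp, ag_const(tape, weights$Wg), ag_const(tape, weights$bg),
                1L, 1L, "same")
  A_half <- ag_sigmoid(tape, ag_add(tape, xg, g))
  Ms <- lapply(1:3, function(ax) upsample_matrix(half[ax], dim(x)[ax]))
  A <- ag_axismap(tape, A_half, Ms)
  gated <- ag_gate_mul(tape, xn, A)
  list(gated = array(gated$value, dim(x)),
       coefficients = array(A$value, dim(x)[1:3]))
}

#' Aggregate per-level decoder predictions at full resolution
#'
#' Functional form of the multi-scale aggregation head: each level's feature
#' map is mapped by a 1x1x1 convolution to class channels, trilinearly
#' upsampled to the finest level's resolution, concatenated, and fused by a
#' final 1x1x1 convolution.
#'
#' @param features list of 4D arrays (X_l, Y_l, Z_l, C_l), finest level first.
#' @param weights optional list with per-level `heads` (each `list(W, b)`,
#'   `W` of shape `C_l x out_classes`) and `fuse` (`list(W, b)`,
#'   `W` of shape `length(features)*out_classes x out_classes`); random
#'   weights under `seed` when omitted.
#' @param out_classes output channels.
#' @param seed seed for random weights.
#' @return 4D array (X_1, Y_1, Z_1, out_classes) of logits.
#' @export
multiscale_aggregate <- function(features, weights = NULL, out_classes = 1L, seed = 1L) {
  stopifnot(is.list(features), length(features) >= 1)
  L <- length(features)
  full <- dim(features[[1]])[1:3]
  if (is.null(weights)) {
    set.seed(seed)
    weights <- list(
      heads = lapply(features, function(f) {
        C <- dim(f)[4]
        list(W = matrix(stats::rnorm(C * out_classes, sd = sqrt(2 / C)), C, out_classes),
             b = numeric(out_classes))
      }),
      fuse = list(W = matrix(stats::rnorm(L * out_classes * out_classes,
                                          sd = sqrt(2 / (L * out_classes))),
                             L * out_classes, out_classes),
                  b = numeric(out_classes)))
  }
  if (length(weights$heads) != L) {
    stop_ductseg("need one head per level (%d heads for %d levels)",
                 length(weights$heads), L, class = "ductseg_config_error")
  }
  tape <- ag_tape()
  maps <- lapply(seq_len(L), function(i) {
    f <- features[[i]]
    fn <- ag_const(tape, array(f, c(dim(f)[1:3], 1, dim(f)[4])))
    h <- ag_conv3(tape, fn, ag_const(tape, weights$heads[[i]]$W),
                  ag_const(tape, weights$heads[[i]]$b), 1L, 1L, "same")
    dh <- dim(h$value)[1:3]
    if (all(dh == full)) h
    else ag_axismap(tape, h, lapply(1:3, function(ax) upsample_matrix(dh[ax], full[ax])))
  })
  fused <- ag_conv3(tape, ag_concat(tape, maps), ag_const(tape, weights$fuse$W),
                    ag_const(tape, weights$fuse$b), 1L, 1L, "same")
  array(fused$value, c(full, out_classes))
}
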