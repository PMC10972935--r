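# Dice-loss optimization: training configuration, cross-validation folds,
# the Adam training loop and prediction.

#' Training configuration
#'
#' Defaults follow the duct-segmentation setup: Adam with learning rate 1e-4
#' minimizing the soft Dice loss, batch size 2, four cross-validation folds,
#' probability threshold 0.5 for binarization. `max_iterations` counts
#' gradient steps (one batch each).
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size cases per gradient step (>= 1).
#' @param max_iterations number of gradient steps.
#' @param seed integer seed controlling all training randomness.
#' @param fold_count folds for cross-validation (>= 2).
#' @param threshold probability threshold for binarizing predictions.
#' @param dice_eps smoothing constant of the Dice loss.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 2,
                         max_iterations = 100, seed = 1L, fold_count = 4,
                         threshold = 0.5, dice_eps = 1e-5) {
  if (learning_rate <= 0) stop_ductseg("learning_rate must be > 0", class = "ductseg_parameter_error")
  if (batch_size < 1) stop_ductseg("batch_size must be >= 1", class = "ductseg_parameter_error")
  if (fold_count < 2) stop_ductseg("fold_count must be >= 2", class = "ductseg_parameter_error")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations), seed = as.integer(seed),
                 fold_count = as.integer(fold_count), threshold = threshold,
                 dice_eps = dice_eps),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` between a
#' probability grid and a binary target. Lies in `[0, 1]`; 0 for perfect
#' overlap, ~1 for disjoint supports. Symmetric in its arguments.
#'
#' @param prob probability array or [volume()] with values in `[0, 1]`.
#' @param target binary array or [label_mask()] of the same shape.
#' @param eps smoothing constant keeping the loss defined for empty grids.
#' @return scalar loss.
#' @export
dice_loss <- function(prob, target, eps = 1e-5) {
  p <- if (inherits(prob, "volume")) prob$data else prob
  t <- if (inherits(target, "volume")) target$data else target
  if (!identical(dim(p), dim(t))) {
    stop_ductseg("probability and target shapes differ", class = "ductseg_alignment_error")
  }
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Balanced cross-validation folds
#'
#' Randomly partitions `n_cases` cases into `k` folds whose sizes differ by at
#' most one. Deterministic for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param n_cases number of cases (>= k).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per case.
#' @export
make_folds <- function(n_cases, k, seed = 1L) {
  if (n_cases < k) {
    stop_ductseg("need at least as many cases (%d) as folds (%d)", n_cases, k,
                 class = "ductseg_parameter_error")
  }
  with_seed(seed, {
    ids <- rep(seq_len(k), length.out = n_cases)  # sizes differ by <= 1
    sample(ids)
  })
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assemble a training case
#'
#' Stacks the CT (and optional enhancement channel) into the network input
#' layout and attaches the duct target and pancreas mask. All grids must be
#' aligned and sized for the chosen network (spatial dims divisible by
#' `2^(levels-1)`).
#'
#' @param ct normalized CT ROI, [volume()] or 3D array.
#' @param duct duct ground truth, [label_mask()] or 3D array (may be `NULL`
#'   for prediction-only cases).
#' @param pancreas pancreas mask for anatomical attention, or `NULL`.
#' @param enhancement tubular-enhancement channel, or `NULL`.
#' @return list with `image` (4D array X,Y,Z,C), `mask`, `target`.
#' @export
as_training_case <- function(ct, duct = NULL, pancreas = NULL, enhancement = NULL) {
  arr <- function(x) if (inherits(x, "volume")) x$data else x
  ctd <- arr(ct)
  chans <- list(ctd)
  if (!is.null(enhancement)) chans <- c(chans, list(arr(enhancement)))
  img <- array(unlist(chans), c(dim(ctd), length(chans)))
  list(image = img,
       mask = if (is.null(pancreas)) NULL else arr(pancreas),
       target = if (is.null(duct)) NULL else arr(duct))
}

# Stack a per-case field into the (X,Y,Z,N,C) batch layout.
stack_batch <- function(cases, field, channels) {
  sp <- dim(cases[[1]][[field]])[1:3]
  a <- array(unlist(lapply(cases, function(cs) cs[[field]]), use.names = FALSE),
             c(sp, channels, length(cases)))
  aperm(a, c(1, 2, 3, 5, 4))
}

#' Train a duct-segmentation network
#'
#' Minimizes the soft Dice loss with Adam. Batches are drawn by cyclic
#' reshuffling of the dataset; all randomness derives from `cfg$seed`, so two
#' runs with the same seed produce identical loss histories.
#'
#' @param model a `duct_fcn` from [build_variant()] or [build_backbone()].
#' @param dataset nonempty list of cases from [as_training_case()] (each with
#'   a non-`NULL` `target`).
#' @param cfg a [train_config()].
#' @param verbose print a progress line every `verbose` iterations (0 = quiet).
#' @return list with `model` (trained), `history` (data.frame of iteration
#'   and loss) and `config`.
#' @export
train_model <- function(model, dataset, cfg = train_config(), verbose = 0) {
  stopifnot(inherits(model, "duct_fcn"), inherits(cfg, "train_config"))
  if (length(dataset) == 0) {
    stop_ductseg("training dataset is empty", class = "ductseg_parameter_error")
  }
  if (any(vapply(dataset, function(cs) is.null(cs$target), logical(1)))) {
    stop_ductseg("every training case needs a duct target", class = "ductseg_parameter_error")
  }
  needs_mask <- !is.null(model$variant) &&
    model$variant$attention_source == "pancreas_mask"
  cin <- model$config$in_channels
  losses <- numeric(cfg$max_iterations)
  opt <- adam_state()
  with_seed(cfg$seed, {
    order_pool <- integer(0)
    for (it in seq_len(cfg$max_iterations)) {
      while (length(order_pool) < cfg$batch_size) {
        order_pool <- c(order_pool, sample(length(dataset)))
      }
      take <- order_pool[seq_len(cfg$batch_size)]
      order_pool <- order_pool[-seq_len(cfg$batch_size)]
      batch <- dataset[take]
      x <- stack_batch(batch, "image", cin)
      tgt <- stack_batch(batch, "target", 1L)
      msk <- if (needs_mask) stack_batch(batch, "mask", 1L) else NULL
      fw <- fcn_forward(model, x, msk, train = TRUE)
      prob <- ag_sigmoid(fw$tape, fw$logits)
      loss <- ag_dice(fw$tape, prob, tgt, eps = cfg$dice_eps)
      grads <- ag_backward(fw$tape, loss)
      model$params <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      losses[it] <- loss$value
      if (verbose > 0 && it %% verbose == 0) {
        message(sprintf("iter %d/%d  dice loss %.4f", it, cfg$max_iterations, loss$value))
      }
    }
  })
  list(model = model, history = data.frame(iteration = seq_len(cfg$max_iterations),
                                           loss = losses),
       config = cfg)
}

#' Predict a duct segmentation for one ROI
#'
#' Runs the network in evaluation mode and binarizes the sigmoid output at
#' the chosen threshold.
#'
#' @param object a (trained) `duct_fcn`.
#' @param ct normalized CT ROI, [volume()] or 3D array.
#' @param pancreas pancreas mask (required by mask-attention variants).
#' @param enhancement enhancement channel (required by 2-channel variants).
#' @param threshold probability threshold in `[0, 1]`.
#' @param ... unused.
#' @return list with `probability` ([volume()]) and `mask` ([label_mask()]).
#' @export
predict.duct_fcn <- function(object, ct, pancreas = NULL, enhancement = NULL,
                             threshold = 0.5, ...) {
  spacing <- if (inherits(ct, "volume")) ct$spacing else c(1, 1, 1)
  origin <- if (inherits(ct, "volume")) ct$origin else c(0, 0, 0)
  cs <- as_training_case(ct, duct = NULL, pancreas = pancreas, enhancement = enhancement)
  cin <- object$config$in_channels
  if (dim(cs$image)[4] != cin) {
    stop_ductseg("variant expects %d input channels, got %d", cin, dim(cs$image)[4],
                 class = "ductseg_config_error")
  }
  sp <- dim(cs$image)[1:3]
  x <- array(cs$image, c(sp, 1, cin))
  needs_mask <- !is.null(object$variant) &&
    object$variant$attention_source == "pancreas_mask"
  msk <- if (needs_mask) {
    if (is.null(cs$mask)) stop_ductseg("this variant requires a pancreas mask",
                                       class = "ductseg_config_error")
    array(cs$mask, c(sp, 1, 1))
  } else NULL
  fw <- fcn_forward(object, x, msk, train = FALSE)
  prob <- array(1 / (1 + exp(-fw$logits$value)), sp)
  list(probability = volume(prob, spacing, origin),
       mask = label_mask(array(as.numeric(prob >= threshold), sp), spacing, origin),
       attention = fw$attention)
}
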