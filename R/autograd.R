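# Minimal reverse-mode automatic differentiation over 5D tensors, sufficient
# to train the volumetric FCN family on CPU. Tensors are arrays with dims
# (X, Y, Z, N, C): spatial axes first, then batch, then channels -- chosen so
# that a strided spatial slice reshapes directly into a (voxel*batch) x channel
# matrix and every convolution becomes a sum of k^3 small BLAS matmuls
# (one per kernel offset), without materializing an im2col buffer.
#
# A tape records nodes in creation order; backward() walks the tape in
# reverse, calling each node's pullback and accumulating gradients into its
# parents. Parameters are leaf nodes carrying a name under which their
# gradient is collected.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_node <- function(tape, value, parents = list(), backfn = NULL, pname = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$pname <- pname
  nd$rg <- !is.null(pname) || any(vapply(parents, function(p) p$rg, logical(1)))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_const <- function(tape, value) ag_node(tape, value)

ag_param <- function(tape, value, name) ag_node(tape, value, pname = name)

# Accumulate gradient g into node nd.
ag_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (p$rg && !is.null(gs[[k]])) ag_accum(p, gs[[k]])
    }
    if (is.null(nd$pname)) nd$grad <- NULL  # free intermediate gradients
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$pname) && !is.null(nd$grad)) {
      g <- nd$grad
      if (is.null(grads[[nd$pname]])) grads[[nd$pname]] <- g
      else grads[[nd$pname]] <- grads[[nd$pname]] + g
    }
  }
  grads
}

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b),
          function(g, nd) list(g, g))
}

ag_relu <- function(tape, x) {
  m <- x$value > 0
  ag_node(tape, x$value * m, list(x), function(g, nd) list(g * m))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(g, nd) list(g * s * (1 - s)))
}

# PReLU with one learnable slope per channel (channels = last dim).
ag_prelu <- function(tape, x, alpha) {
  xv <- x$value
  C <- dim(xv)[length(dim(xv))]
  rep_each <- length(xv) / C
  av <- rep(alpha$value, each = rep_each)
  pos <- xv > 0
  y <- xv * (pos + av * !pos)
  dim(y) <- dim(xv)
  ag_node(tape, y, list(x, alpha), function(g, nd) {
    dx <- g * (pos + av * !pos)
    dim(dx) <- dim(xv)
    da <- colSums(matrix(g * xv * !pos, ncol = C))
    list(dx, da)
  })
}

# Multiply features (…, C) by a single-channel gate (…, 1); the gate recycles
# across channels because channels are the slowest-varying dimension.
ag_gate_mul <- function(tape, x, a) {
  xv <- x$value; av <- as.vector(a$value)
  d <- dim(xv); C <- d[length(d)]
  y <- xv * av
  dim(y) <- d
  ag_node(tape, y, list(x, a), function(g, nd) {
    dx <- g * av
    dim(dx) <- d
    da <- array(rowSums(matrix(g * xv, ncol = C)), dim(a$value))
    list(dx, da)
  })
}

# Concatenate nodes along the channel (last) dimension.
ag_concat <- function(tape, xs) {
  d1 <- dim(xs[[1]]$value)
  nc <- vapply(xs, function(x) dim(x$value)[length(d1)], numeric(1))
  d <- d1; d[length(d)] <- sum(nc)
  val <- array(unlist(lapply(xs, function(x) x$value), use.names = FALSE), d)
  ag_node(tape, val, xs, function(g, nd) {
    out <- vector("list", length(xs))
    lead <- prod(d1[-length(d1)])
    off <- 0
    gm <- matrix(g, nrow = lead)
    for (k in seq_along(xs)) {
      dk <- d1; dk[length(dk)] <- nc[k]
      out[[k]] <- array(gm[, off + seq_len(nc[k]), drop = FALSE], dk)
      off <- off + nc[k]
    }
    out
  })
}

# ---- convolutions -----------------------------------------------------------

# 3D convolution. x: (X,Y,Z,N,Cin); W: matrix (k^3*Cin, Cout) with rows in
# offset-major order (channel fastest); b: length Cout or NULL. pad = "same"
# (odd k, stride 1) or "valid". The offset gather/scatter and the channel
# contraction run in compiled code (src/conv_ops.cpp).
ag_conv3 <- function(tape, x, W, b, k, stride = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  p <- if (pad == "same") (k - 1L) %/% 2L else 0L
  xv <- x$value
  d <- dim(xv)
  y <- ds_conv3_fwd(xv, d, W$value, if (is.null(b)) NULL else b$value,
                    as.integer(k), as.integer(stride), p)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_node(tape, y, parents, function(g, nd) {
    r <- ds_conv3_bwd(xv, d, W$value, g, as.integer(k), as.integer(stride), p, x$rg)
    out <- list(r$dx, r$dW)
    if (!is.null(b)) out <- c(out, list(r$db))
    out
  })
}

# Transposed convolution, kernel 2, stride 2 (exact 2x upsampling; the eight
# kernel offsets write disjoint output positions). W: matrix (8*Cin, Cout).
ag_convT2 <- function(tape, x, W, b) {
  xv <- x$value
  d <- dim(xv)
  y <- ds_convT2_fwd(xv, d, W$value, if (is.null(b)) NULL else b$value)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_node(tape, y, parents, function(g, nd) {
    r <- ds_convT2_bwd(xv, d, W$value, g, x$rg)
    out <- list(r$dx, r$dW)
    if (!is.null(b)) out <- c(out, list(r$db))
    out
  })
}

# 2x2x2 max pooling, stride 2 (requires even spatial dims).
ag_maxpool2 <- function(tape, x) {
  xv <- x$value
  d <- dim(xv)
  f <- ds_maxpool2_fwd(xv, d)
  ag_node(tape, f$y, list(x), function(g, nd) {
    list(ds_maxpool2_bwd(g, f$arg, d))
  })
}

# Apply fixed per-axis linear maps (trilinear interpolation / adaptive average
# pooling) to the three spatial axes; Ms is a length-3 list, NULL = identity.
ag_axismap <- function(tape, x, Ms) {
  y <- x$value
  for (ax in 1:3) if (!is.null(Ms[[ax]])) y <- apply_axis(y, Ms[[ax]], ax)
  ag_node(tape, y, list(x), function(g, nd) {
    for (ax in 3:1) if (!is.null(Ms[[ax]])) g <- apply_axis(g, t(Ms[[ax]]), ax)
    list(g)
  })
}

# ---- normalization ----------------------------------------------------------

# Shared core: normalize columns of a (rows x groups) view of x, with affine
# parameters per channel. `ncol_groups` is N*C (instance norm) or C (batch
# norm); `gamma_col` maps channels onto group columns.
norm_core_fwd <- function(xv, groups, eps) {
  xm <- matrix(xv, ncol = groups)
  n <- nrow(xm)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  va <- colMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- xc / rep(sd, each = n)
  list(xhat = xhat, sd = sd, mu = mu, va = va)
}

norm_core_bwd <- function(gm, xhat, sd, gamma_col) {
  n <- nrow(gm)
  dxhat <- gm * rep(gamma_col, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) / rep(sd, each = n)
}

# Instance normalization: statistics per (sample, channel) over spatial voxels.
ag_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); N <- d[4]; C <- d[5]
  groups <- N * C
  f <- norm_core_fwd(xv, groups, eps)
  V <- nrow(f$xhat)
  gamma_col <- rep(gamma$value, each = N)
  beta_col <- rep(beta$value, each = N)
  y <- f$xhat * rep(gamma_col, each = V) + rep(beta_col, each = V)
  dim(y) <- d
  ag_node(tape, y, list(x, gamma, beta), function(g, nd) {
    gm <- matrix(g, ncol = groups)
    dgamma <- colSums(matrix(colSums(gm * f$xhat), nrow = N))
    dbeta <- colSums(matrix(colSums(gm), nrow = N))
    dx <- NULL
    if (x$rg) {
      dx <- norm_core_bwd(gm, f$xhat, f$sd, gamma_col)
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

# Batch normalization: statistics per channel over spatial voxels and batch.
# Running statistics live in `state` (an environment) under `name`; at
# evaluation time they replace the batch statistics.
ag_batchnorm <- function(tape, x, gamma, beta, state, name, train = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); C <- d[5]
  if (!train && !is.null(state[[name]])) {
    rs <- state[[name]]
    xm <- matrix(xv, ncol = C)
    xhat <- sweep(sweep(xm, 2, rs$mean), 2, sqrt(rs$var + eps), "/")
    y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
    return(ag_node(tape, array(y, d), list(x, gamma, beta), function(g, nd) {
      gm <- matrix(g, ncol = C)
      dx <- if (x$rg) array(sweep(gm, 2, gamma$value / sqrt(rs$var + eps), "*"), d) else NULL
      list(dx, colSums(gm * xhat), colSums(gm))
    }))
  }
  f <- norm_core_fwd(xv, C, eps)
  if (train) {
    rs <- state[[name]] %||% list(mean = numeric(C), var = rep(1, C))
    state[[name]] <- list(mean = (1 - momentum) * rs$mean + momentum * f$mu,
                          var = (1 - momentum) * rs$var + momentum * f$va)
  }
  y <- f$xhat * rep(gamma$value, each = nrow(f$xhat)) +
    rep(beta$value, each = nrow(f$xhat))
  ag_node(tape, array(y, d), list(x, gamma, beta), function(g, nd) {
    gm <- matrix(g, ncol = C)
    dx <- if (x$rg) array(norm_core_bwd(gm, f$xhat, f$sd, gamma$value), d) else NULL
    list(dx, colSums(gm * f$xhat), colSums(gm))
  })
}

# ---- loss -------------------------------------------------------------------

# Soft Dice loss between a probability tensor and a binary target:
# 1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps).
ag_dice <- function(tape, p, target, eps = 1e-5) {
  pv <- p$value; tv <- target
  num <- 2 * sum(pv * tv) + eps
  den <- sum(pv) + sum(tv) + eps
  ag_node(tape, 1 - num / den, list(p), function(g, nd) {
    list(array(g * (num - 2 * tv * den) / den^2, dim(pv)))
  })
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function() {
  s <- new.env(parent = emptyenv())
  s$t <- 0L; s$m <- list(); s$v <- list()
  s
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]] %||% (g * 0)
    v <- state$v[[nm]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}
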