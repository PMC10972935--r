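# Finite-difference validation of the reverse-mode engine: every operator's
# pullback is checked against central differences on small random tensors.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

relerr <- function(got, want) max(abs(got - want)) / max(1e-8, max(abs(want)))

ns <- asNamespace("ductseg")
attach_op <- function(nm) get(nm, envir = ns)
ag_tape <- attach_op("ag_tape"); ag_node <- attach_op("ag_node")
ag_param <- attach_op("ag_param"); ag_conv3 <- attach_op("ag_conv3")
ag_convT2 <- attach_op("ag_convT2"); ag_maxpool2 <- attach_op("ag_maxpool2")
ag_axismap <- attach_op("ag_axismap"); ag_sigmoid <- attach_op("ag_sigmoid")
ag_dice <- attach_op("ag_dice"); ag_backward <- attach_op("ag_backward")
ag_instnorm <- attach_op("ag_instnorm"); ag_batchnorm <- attach_op("ag_batchnorm")
ag_prelu <- attach_op("ag_prelu"); ag_gate_mul <- attach_op("ag_gate_mul")
ag_concat <- attach_op("ag_concat"); ag_relu <- attach_op("ag_relu")
ag_add <- attach_op("ag_add")

d0 <- c(4, 4, 4, 2, 3)

loss_through <- function(build, xv, target) {
  tape <- ag_tape()
  xn <- ag_node(tape, xv, pname = "x")
  out <- build(tape, xn)
  l <- ag_dice(tape, ag_sigmoid(tape, out), target)
  list(val = l$value, grads = ag_backward(tape, l))
}

test_that("convolution pullbacks match finite differences", {
  set.seed(21)
  x0 <- array(rnorm(prod(d0)), d0)
  W <- matrix(rnorm(27 * 3 * 2) * 0.3, 27 * 3, 2)
  b <- rnorm(2)
  tgt <- array(rbinom(prod(c(d0[1:4], 2)), 1, 0.3), c(d0[1:4], 2))
  run <- function(xv, Wv = W, bv = b) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_conv3(tape, xn, ag_param(tape, Wv, "W"), ag_param(tape, bv, "b"),
                  3L, 1L, "same")
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r <- run(x0)
  expect_lt(relerr(r$grads$x, num_grad(function(z) run(z)$val, x0)), 1e-5)
  expect_lt(relerr(r$grads$W, num_grad(function(z) run(x0, Wv = z)$val, W)), 1e-5)
  expect_lt(relerr(r$grads$b, num_grad(function(z) run(x0, bv = z)$val, b)), 1e-5)
  # strided valid convolution (the down-conv form)
  W2 <- matrix(rnorm(8 * 3 * 2) * 0.3, 8 * 3, 2)
  tgt2 <- array(rbinom(2 * 2 * 2 * 2 * 2, 1, 0.3), c(2, 2, 2, 2, 2))
  run2 <- function(xv, Wv = W2) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_conv3(tape, xn, ag_param(tape, Wv, "W"), NULL, 2L, 2L, "valid")
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt2)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r2 <- run2(x0)
  expect_lt(relerr(r2$grads$x, num_grad(function(z) run2(z)$val, x0)), 1e-5)
  expect_lt(relerr(r2$grads$W, num_grad(function(z) run2(x0, z)$val, W2)), 1e-5)
})

test_that("transposed convolution pullback matches finite differences", {
  set.seed(22)
  x0 <- array(rnorm(prod(d0)), d0)
  WT <- matrix(rnorm(8 * 3 * 2) * 0.3, 8 * 3, 2)
  bT <- rnorm(2)
  tgt <- array(rbinom(8 * 8 * 8 * 2 * 2, 1, 0.3), c(8, 8, 8, 2, 2))
  run <- function(xv, Wv = WT, bv = bT) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_convT2(tape, xn, ag_param(tape, Wv, "W"), ag_param(tape, bv, "b"))
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r <- run(x0)
  expect_lt(relerr(r$grads$x, num_grad(function(z) run(z)$val, x0)), 1e-5)
  expect_lt(relerr(r$grads$W, num_grad(function(z) run(x0, Wv = z)$val, WT)), 1e-5)
  expect_lt(relerr(r$grads$b, num_grad(function(z) run(x0, bv = z)$val, bT)), 1e-5)
})

test_that("pooling, resizing and normalization pullbacks match finite differences", {
  set.seed(23)
  x0 <- array(rnorm(prod(d0)), d0)
  tgt_half <- array(rbinom(2 * 2 * 2 * 2 * 3, 1, 0.3), c(2, 2, 2, 2, 3))
  r <- loss_through(function(tape, xn) ag_maxpool2(tape, xn), x0, tgt_half)
  expect_lt(relerr(r$grads$x,
                   num_grad(function(z) loss_through(function(tape, xn)
                     ag_maxpool2(tape, xn), z, tgt_half)$val, x0)), 1e-4)

  Ms <- list(ductseg:::upsample_matrix(4, 8), NULL, ductseg:::adaptive_pool_matrix(4, 2))
  tgt_ax <- array(rbinom(8 * 4 * 2 * 2 * 3, 1, 0.3), c(8, 4, 2, 2, 3))
  bld <- function(tape, xn) ag_axismap(tape, xn, Ms)
  r <- loss_through(bld, x0, tgt_ax)
  expect_lt(relerr(r$grads$x,
                   num_grad(function(z) loss_through(bld, z, tgt_ax)$val, x0)), 1e-5)

  ga <- rnorm(3) + 1; be <- rnorm(3)
  tgt <- array(rbinom(prod(d0), 1, 0.3), d0)
  run_in <- function(xv, g = ga, bb = be) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_instnorm(tape, xn, ag_param(tape, g, "g"), ag_param(tape, bb, "be"))
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r <- run_in(x0)
  expect_lt(relerr(r$grads$x, num_grad(function(z) run_in(z)$val, x0)), 1e-4)
  expect_lt(relerr(r$grads$g, num_grad(function(z) run_in(x0, g = z)$val, ga)), 1e-5)
  expect_lt(relerr(r$grads$be, num_grad(function(z) run_in(x0, bb = z)$val, be)), 1e-5)

  st <- new.env()
  run_bn <- function(xv, g = ga) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_batchnorm(tape, xn, ag_param(tape, g, "g"), ag_param(tape, be, "be"),
                      st, "bn", train = TRUE)
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r <- run_bn(x0)
  expect_lt(relerr(r$grads$x, num_grad(function(z) run_bn(z)$val, x0)), 1e-4)
  expect_lt(relerr(r$grads$g, num_grad(function(z) run_bn(x0, g = z)$val, ga)), 1e-5)
})

test_that("activation, gating and concatenation pullbacks match finite differences", {
  set.seed(24)
  x0 <- array(rnorm(prod(d0)), d0)
  al <- abs(rnorm(3)) * 0.3
  gate <- array(runif(prod(c(d0[1:4], 1))), c(d0[1:4], 1))
  tgt <- array(rbinom(prod(d0) * 2, 1, 0.3), c(d0[1:4], 6))
  run <- function(xv, a = al, gv = gate) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_prelu(tape, xn, ag_param(tape, a, "a"))
    gn <- ag_node(tape, gv, pname = "gt")
    z <- ag_gate_mul(tape, y, gn)
    cc <- ag_concat(tape, list(z, y))
    l <- ag_dice(tape, ag_sigmoid(tape, cc), tgt)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r <- run(x0)
  expect_lt(relerr(r$grads$x, num_grad(function(z) run(z)$val, x0)), 1e-4)
  expect_lt(relerr(r$grads$a, num_grad(function(z) run(x0, a = z)$val, al)), 1e-5)
  expect_lt(relerr(r$grads$gt, num_grad(function(z) run(x0, gv = z)$val, gate)), 1e-5)
  # a node feeding two consumers accumulates both pullbacks
  tgt1 <- array(rbinom(prod(d0), 1, 0.3), d0)
  run2 <- function(xv) {
    tape <- ag_tape()
    xn <- ag_node(tape, xv, pname = "x")
    y <- ag_add(tape, ag_relu(tape, xn), xn)
    l <- ag_dice(tape, ag_sigmoid(tape, y), tgt1)
    list(val = l$value, grads = ag_backward(tape, l))
  }
  r2 <- run2(x0)
  expect_lt(relerr(r2$grads$x, num_grad(function(z) run2(z)$val, x0)), 1e-4)
})

test_that("whole-network parameter gradients match finite differences", {
  set.seed(25)
  x <- array(rnorm(8^3), c(8, 8, 8, 1, 1))
  x2 <- array(rnorm(8^3 * 2), c(8, 8, 8, 1, 2))
  mk <- array(rbinom(8^3, 1, 0.4), c(8, 8, 8, 1, 1))
  tgt <- array(rbinom(8^3, 1, 0.1), c(8, 8, 8, 1, 1))
  configs <- list(
    list(model = build_variant("panet", backbone_config("vnet", 2, 2, "IN"),
                               seed = 26), x = x),
    list(model = build_variant("nmcpamnet",
                               backbone_config("unet3d", 2, 2, "IN", in_channels = 2),
                               seed = 27), x = x2))
  for (cc in configs) {
    model <- cc$model
    lossf <- function(m) {
      fw <- ductseg:::fcn_forward(m, cc$x, mk, train = TRUE)
      ag_dice(fw$tape, ag_sigmoid(fw$tape, fw$logits), tgt)$value
    }
    fw <- ductseg:::fcn_forward(model, cc$x, mk, train = TRUE)
    grads <- ag_backward(fw$tape,
                         ag_dice(fw$tape, ag_sigmoid(fw$tape, fw$logits), tgt))
    expect_setequal(names(grads), names(model$params))
    # central differences on a spread of parameters across every layer kind
    for (pn in names(model$params)) {
      p <- model$params[[pn]]
      idx <- 1 + (length(p) %/% 2)
      eps <- 1e-6
      f <- function(val) { m2 <- model; m2$params[[pn]][idx] <- val; lossf(m2) }
      ng <- (f(p[idx] + eps) - f(p[idx] - eps)) / (2 * eps)
      expect_lt(abs(grads[[pn]][idx] - ng) / max(1e-7, abs(ng)), 1e-3,
                label = sprintf("gradient of %s", pn))
    }
  }
})
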