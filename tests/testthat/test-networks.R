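# Backbone factory, parameter accounting, attention gate and aggregation
# head. The printed-parameter-count reproduction itself lives in the
# acceptance suite; here we test the structural properties.

test_that("parameter counts ignore input size and normalization flavour", {
  base <- function(...) count_parameters(build_backbone(backbone_config(...), init = FALSE))
  expect_identical(base("vnet", 4, 16, "BN", input_size = 128),
                   base("vnet", 4, 16, "BN", input_size = 160))
  expect_identical(base("vnet", 5, 16, "BN"), base("vnet", 5, 16, "IN"))
  expect_identical(base("unet3d", 3, 8, "BN"), base("unet3d", 3, 8, "IN"))
})

test_that("parameter counts grow strictly with depth and width", {
  base <- function(l, f) count_parameters(build_backbone(
    backbone_config("vnet", l, f, "BN"), init = FALSE))
  expect_gt(base(5, 16), base(4, 16))
  expect_gt(base(6, 16), base(5, 16))
  expect_gt(base(4, 32), base(4, 16))
  ub <- function(l, f) count_parameters(build_backbone(
    backbone_config("unet3d", l, f, "BN"), init = FALSE))
  expect_gt(ub(4, 32), ub(3, 32))
  expect_gt(ub(4, 32), ub(4, 16))
})

test_that("configuration invariants are enforced", {
  expect_error(backbone_config("vnet", levels = 1), class = "ductseg_config_error")
  expect_error(backbone_config("vnet", levels = 4, input_size = 60),
               class = "ductseg_config_error")
  cfg <- backbone_config("vnet", levels = 3, initial_filters = 2, norm = "IN")
  m <- build_backbone(cfg, seed = 1)
  # forward requires spatially divisible inputs
  expect_error(ductseg:::fcn_forward(m, array(0, c(6, 6, 6, 1, 1))),
               class = "ductseg_config_error")
  expect_error(ductseg:::fcn_forward(m, array(0, c(8, 8, 8, 1, 2))),
               class = "ductseg_config_error")
})

test_that("forward passes preserve spatial shape across families and variants", {
  x1 <- array(rnorm(16^3), c(16, 16, 16, 1, 1))
  x2 <- array(rnorm(16^3 * 2), c(16, 16, 16, 1, 2))
  mk <- array(rbinom(16^3, 1, 0.4), c(16, 16, 16, 1, 1))
  for (fam in c("vnet", "unet3d")) {
    m <- build_backbone(backbone_config(fam, 3, 4, "IN"), seed = 2)
    out <- ductseg:::fcn_forward(m, x1)
    expect_identical(dim(out$logits$value), c(16L, 16L, 16L, 1L, 1L))
  }
  specs <- list(
    list(v = "attention_unet", x = x1, mask = NULL, ch = 1L),
    list(v = "panet", x = x1, mask = mk, ch = 1L),
    list(v = "pamnet", x = x1, mask = mk, ch = 1L),
    list(v = "mcpamnet", x = x2, mask = mk, ch = 2L),
    list(v = "nmcpamnet", x = x2, mask = mk, ch = 2L))
  for (s in specs) {
    cfg <- backbone_config("unet3d", 3, 4, "IN", in_channels = s$ch)
    m <- build_variant(s$v, cfg, seed = 3)
    out <- ductseg:::fcn_forward(m, s$x, s$mask)
    expect_identical(dim(out$logits$value), c(16L, 16L, 16L, 1L, 1L))
    if (!identical(s$v, "attention_unet")) {
      expect_length(out$attention, 2)  # one gate per decoder level
    }
  }
})

test_that("variant wiring follows the ablation ladder", {
  v <- variant_spec("attention_unet")
  expect_identical(v$attention_source, "self_gating")
  expect_false(v$multiscale_aggregation)
  for (nm in c("panet", "pamnet", "mcpamnet", "nmcpamnet")) {
    expect_identical(variant_spec(nm)$attention_source, "pancreas_mask")
  }
  expect_false(variant_spec("panet")$multiscale_aggregation)
  expect_true(variant_spec("pamnet")$multiscale_aggregation)
  expect_identical(variant_spec("mcpamnet")$enhancement_channel, "raw")
  expect_identical(variant_spec("nmcpamnet")$enhancement_channel, "normalized")
  # channel-count consistency is enforced
  expect_error(build_variant("nmcpamnet", backbone_config("vnet", 3, 4, "IN")),
               class = "ductseg_config_error")
  expect_error(build_variant("panet", backbone_config("vnet", 3, 4, "IN",
                                                      in_channels = 2)),
               class = "ductseg_config_error")
})

test_that("panet and pamnet differ only by the aggregation head", {
  cfg <- backbone_config("vnet", 3, 4, "IN")
  pa <- build_variant("panet", cfg, init = FALSE)
  pam <- build_variant("pamnet", cfg, init = FALSE)
  only_pa <- setdiff(names(pa$shapes), names(pam$shapes))
  only_pam <- setdiff(names(pam$shapes), names(pa$shapes))
  expect_true(all(grepl("^out\\.", only_pa)))
  expect_true(all(grepl("^agg\\.", only_pam)))
  shared <- intersect(names(pa$shapes), names(pam$shapes))
  expect_identical(pa$shapes[shared], pam$shapes[shared])
})

test_that("attention_unet runs without any mask input", {
  cfg <- backbone_config("unet3d", 3, 4, "IN")
  m <- build_variant("attention_unet", cfg, seed = 4)
  out <- ductseg:::fcn_forward(m, array(rnorm(16^3), c(16, 16, 16, 1, 1)))
  expect_identical(dim(out$logits$value)[1:3], c(16L, 16L, 16L))
  expect_true(all(unlist(out$attention) >= 0 & unlist(out$attention) <= 1))
})

test_that("attention coefficients are sigmoid-bounded and gate as in the formula", {
  set.seed(5)
  x <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  m <- array(rbinom(16^3, 1, 0.4), c(16, 16, 16))
  at <- anatomical_attention(x, m, seed = 6)
  expect_true(all(at$coefficients > 0 & at$coefficients < 1))
  expect_identical(dim(at$coefficients), dim(x)[1:3])
  # coefficients multiply the features voxelwise
  expect_equal(at$gated, x * as.vector(at$coefficients), tolerance = 1e-12)
  # zero gate weights: sigmoid(0) = 0.5 everywhere
  zw <- list(Wx = matrix(0, 8 * 3, 1), bx = 0, Wg = matrix(0, 1, 1), bg = 0)
  at0 <- anatomical_attention(x, m, weights = zw)
  expect_true(all(at0$coefficients == 0.5))
  expect_equal(at0$gated, x / 2, tolerance = 1e-12)
  # saturating bias forces coefficients to 1: gated output = ungated input
  sat <- list(Wx = matrix(0, 8 * 3, 1), bx = 50, Wg = matrix(0, 1, 1), bg = 0)
  at1 <- anatomical_attention(x, m, weights = sat)
  expect_equal(max(abs(at1$coefficients - 1)), 0, tolerance = 1e-12)
  expect_equal(at1$gated, x, tolerance = 1e-10)
})

test_that("multi-scale aggregation fuses upsampled per-level heads", {
  set.seed(7)
  feats <- list(array(rnorm(8^3 * 2), c(8, 8, 8, 2)),
                array(rnorm(4^3 * 4), c(4, 4, 4, 4)))
  out <- multiscale_aggregate(feats, seed = 8)
  expect_identical(dim(out), c(8L, 8L, 8L, 1L))
  # single level degenerates to a 1x1x1 convolution
  w1 <- list(heads = list(list(W = matrix(c(1, -2), 2, 1), b = 0.5)),
             fuse = list(W = matrix(1, 1, 1), b = 0))
  got <- multiscale_aggregate(feats[1], weights = w1)
  want <- array(matrix(feats[[1]], ncol = 2) %*% c(1, -2) + 0.5, c(8, 8, 8, 1))
  expect_equal(got, want, tolerance = 1e-12)
  # zeroing all but one fusion weight reproduces that level's upsampled head
  w2 <- list(heads = list(list(W = matrix(rnorm(2), 2, 1), b = 0),
                          list(W = matrix(rnorm(4), 4, 1), b = 0)),
             fuse = list(W = matrix(c(1, 0), 2, 1), b = 0))
  got2 <- multiscale_aggregate(feats, weights = w2)
  head1 <- array(matrix(feats[[1]], ncol = 2) %*% w2$heads[[1]]$W, c(8, 8, 8, 1))
  expect_equal(got2, head1, tolerance = 1e-12)
  expect_error(multiscale_aggregate(feats, weights = w1),
               class = "ductseg_config_error")
})
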