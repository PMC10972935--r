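# Tubular-structure enhancement: Hessian correctness against analytic and
# finite-difference oracles, eigenvalue ordering, the tube-response formula,
# and mask post-processing.

test_that("Hessian of a constant volume vanishes", {
  v <- volume(array(0.7, c(12, 12, 12)), spacing = c(0.5, 0.5, 0.5))
  H <- hessian_field(v, 1)
  for (comp in H) expect_lt(max(abs(comp)), 1e-12)
})

test_that("Hessian of a quadratic ramp matches the analytic second derivative", {
  n <- 21; a <- 0.3
  xs <- 0:(n - 1)
  arr <- array(rep(a * xs^2, times = n * n), c(n, n, n))
  H <- hessian_field(volume(arr, spacing = c(1, 1, 1)), scale = 1)
  mid <- 8:14
  # scale-normalized by scale^2 = 1; interior only (borders feel the padding)
  expect_equal(H$xx[mid, mid, mid], array(2 * a, c(7, 7, 7)), tolerance = 1e-2)
  expect_lt(max(abs(H$xy[mid, mid, mid])), 1e-10)
  expect_lt(max(abs(H$yy[mid, mid, mid])), 1e-10)
})

test_that("Hessian agrees with a finite-difference oracle on a random volume", {
  set.seed(11)
  base <- array(rnorm(11^3), c(11, 11, 11))
  sm <- oracle_gauss_smooth(base, rep(2, 3))  # smooth field, FD is accurate
  v <- volume(sm, spacing = c(1, 1, 1))
  H <- hessian_field(v, scale = 1.2)
  Ho <- oracle_hessian(sm, rep(1, 3), 1.2)
  mid <- 4:8
  for (comp in c("xx", "yy", "zz", "xy", "xz", "yz")) {
    expect_equal(H[[comp]][mid, mid, mid], Ho[[comp]][mid, mid, mid],
                 tolerance = 0.05)
  }
})

test_that("sort_eigs orders triples by magnitude", {
  expect_equal(unname(sort_eigs(3, -1, 2)), c(-1, 2, 3))
  expect_equal(unname(sort_eigs(0, 0, 0)), c(0, 0, 0))
  # random symmetric matrices: closed-form eigenvalues match base eigen()
  set.seed(12)
  for (i in 1:25) {
    M <- matrix(rnorm(9), 3, 3); M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    got <- ductseg:::eig_sym3(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    expect_equal(sort(as.vector(got)), sort(ev), tolerance = 1e-8)
    srt <- sort_eigs(got[1], got[2], got[3])
    expect_true(all(diff(abs(srt)) >= -1e-12))
  }
  # vectorized form returns one ordered triple per row
  m <- sort_eigs(c(3, 1), c(-1, -5), c(2, 0))
  expect_equal(unname(m[1, ]), c(-1, 2, 3))
  expect_equal(unname(m[2, ]), c(0, 1, -5))
})

test_that("geometric ratios follow the tube-shape definitions", {
  expect_equal(unname(geometric_ratios(c(0, -2, -2))), c(1, 0, sqrt(8)))
  expect_equal(unname(geometric_ratios(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(geometric_ratios(c(1, 1, 1))), c(1, 1, sqrt(3)))
})

test_that("vesselness gates on the eigenvalue signs", {
  p <- vesselness_params()
  # any triple with a positive l2 (or l3) is rejected
  expect_equal(vesselness(c(0, 2, 2), p, gamma = sqrt(2)), 0)
  expect_equal(vesselness(c(0.1, 0.5, -3), p, gamma = 1), 0)
  expect_equal(vesselness(c(0, 0, 0), p, gamma = 1), 0)
  # ideal bright tube: direct evaluation of the response
  got <- vesselness(c(0, -2, -2), p, gamma = sqrt(2))
  expect_equal(got, (1 - exp(-2)) * 1 * (1 - exp(-2)), tolerance = 1e-12)
  expect_error(vesselness(c(0, -1, -1), p, gamma = -1),
               class = "ductseg_parameter_error")
})

test_that("multi-scale filtering is a max over scales and zero on constants", {
  cv <- volume(array(0.5, c(10, 10, 10)), spacing = rep(0.5, 3))
  expect_equal(max(frangi_filter(cv, vesselness_params())$data), 0)
  ph <- generate_duct_phantom(tiny_phantom_cfg(noise_sigma = 0.01))
  p1 <- vesselness_params(scales = 1)
  p12 <- vesselness_params(scales = c(1, 2))
  f1 <- frangi_filter(ph$volume, p1)
  f12 <- frangi_filter(ph$volume, p12)
  expect_true(all(f12$data >= f1$data - 1e-12))
  expect_error(vesselness_params(scales = numeric(0)),
               class = "ductseg_parameter_error")
})

test_that("the dark duct lights up against the organ background", {
  ph <- generate_duct_phantom(tiny_phantom_cfg())
  f <- frangi_filter(ph$volume, vesselness_params(), mask = ph$pancreas)
  tube <- f$data[ph$duct$data == 1]
  organ <- f$data[ph$pancreas$data == 1 & ph$duct$data == 0]
  expect_gt(median(tube), median(organ))
  expect_gt(mean(tube), mean(organ))
  # the dark-tube polarity separates duct from organ better than bright
  fb <- frangi_filter(ph$volume, vesselness_params(polarity = "bright"),
                      mask = ph$pancreas)
  contrast_bright <- median(fb$data[ph$duct$data == 1]) -
    median(fb$data[ph$pancreas$data == 1 & ph$duct$data == 0])
  expect_gt(median(tube) - median(organ), contrast_bright)
})

test_that("voxelwise response matches a dense independent re-evaluation", {
  ph <- generate_duct_phantom(phantom_config(size = 16, spacing = 0.5,
                                             semi_axes = c(3.4, 3, 2.6),
                                             tube_radius = 0.6))
  sc <- 0.5
  # package path, fixed gamma so both sides use the same cutoff
  H <- hessian_field(volume(-ph$volume$data, ph$volume$spacing), sc)
  fro <- sqrt(H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2))
  gam <- max(fro) / 2
  got <- frangi_filter(ph$volume, vesselness_params(gamma = gam, scales = sc))
  # oracle: FD Hessian of the negated smoothed volume + literal formula
  Ho <- oracle_hessian(-ph$volume$data, ph$volume$spacing, sc)
  want <- oracle_vesselness_dense(Ho, gamma = gam)
  mid <- 3:14
  expect_gt(sum(want[mid, mid, mid] > 1e-6), 50)
  expect_lt(max(abs(got$data[mid, mid, mid] - want[mid, mid, mid])), 0.25)
  expect_lt(mean(abs(got$data[mid, mid, mid] - want[mid, mid, mid])), 0.01)
})

test_that("post-processing masks and rescales the response", {
  set.seed(13)
  e <- volume(array(runif(8^3, 1, 3), c(8, 8, 8)))
  m <- rand_mask(c(8, 8, 8), p = 0.4, seed = 14)
  out <- postprocess_enhancement(e, m)
  expect_true(all(out$data[m$data == 0] == 0))
  expect_true(all(out$data >= 0 & out$data <= 1))
  inside <- out$data[m$data == 1]
  expect_equal(max(inside), 1)
  expect_equal(min(inside), 0)
  # argmax voxel inside the mask maps to exactly 1
  expect_equal(out$data[which(m$data == 1)[which.max(e$data[m$data == 1])]], 1)
  # constant response inside the mask degenerates to zero
  cst <- postprocess_enhancement(volume(array(2, c(8, 8, 8))), m)
  expect_true(all(cst$data == 0))
  # un-normalized variant only masks
  raw <- postprocess_enhancement(e, m, normalize = FALSE)
  expect_equal(raw$data[m$data == 1], e$data[m$data == 1])
  expect_error(postprocess_enhancement(e, rand_mask(c(4, 4, 4))),
               class = "ductseg_alignment_error")
})
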