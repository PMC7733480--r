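test_that("brain mask excludes the skull and keeps the vessels", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 120))
  bm <- compute_brain_mask(case$image)
  skull <- case$image$values > 600
  expect_gte(mean(bm$values[skull] == 0), 0.99)
  expect_gte(mean(bm$values[case$vessel_mask$values > 0] > 0), 0.95)
  lab <- connected_components(bm)
  expect_equal(nrow(lab), 1L)
})

test_that("brain masking fails loudly on pure air", {
  air <- volume3d(array(0, c(16, 16, 16)), c(1, 1, 1))
  expect_error(compute_brain_mask(air), "no brain tissue found")
})

test_that("vesselness is zero on constant volumes and bounded in [0,1]", {
  flat <- volume3d(array(7, c(32, 32, 32)), c(1, 1, 1))
  v <- vesselness(flat, vesselness_params(c(1, 4), 3))
  expect_equal(max(abs(v$values)), 0)
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 100))
  masked <- case$image
  masked$values <- masked$values * compute_brain_mask(case$image)$values
  vv <- vesselness(masked, vesselness_params(c(0.5, 3), 4))
  expect_gte(min(vv$values), 0)
  expect_lte(max(vv$values), 1)
})

test_that("the maximizing scale on a radius-2 cylinder tracks the radius", {
  # closed form: a Gaussian tube of cross-sectional sd r has maximal
  # scale-normalized Hessian response at sigma = r, here r = 2 voxels
  d <- c(40, 40, 40)
  arr <- array(0, d)
  for (x in 1:40) for (y in 1:40)
    if ((x - 20)^2 + (y - 20)^2 <= 4) arr[x, y, ] <- 100
  scales <- exp(seq(log(0.5), log(5), length.out = 15))
  smax <- 0
  for (s in scales)
    smax <- max(smax, aneuseg:::cpp_vesselness_scale(as.vector(arr), d, s,
                                                     0.5, 0.5, -1)$smax)
  axis_idx <- 20 + 40 * 19 + 1600 * 19 + 1
  resp <- vapply(scales, function(s)
    aneuseg:::cpp_vesselness_scale(as.vector(arr), d, s, 0.5, 0.5,
                                   smax / 2)$response[axis_idx], 0)
  best <- scales[which.max(resp)]
  expect_gte(best, 1.2)
  expect_lte(best, 2.8)
})

test_that("a cylinder outscores a sphere of equal radius and contrast", {
  d <- c(40, 40, 40)
  cyl <- array(0, d); sph <- array(0, d)
  for (x in 1:40) for (y in 1:40) {
    if ((x - 20)^2 + (y - 20)^2 <= 16) cyl[x, y, ] <- 100
    for (z in 1:40)
      if ((x - 20)^2 + (y - 20)^2 + (z - 20)^2 <= 16) sph[x, y, z] <- 100
  }
  p <- vesselness_params(c(1, 6), 5)
  vc <- vesselness(volume3d(cyl, c(1, 1, 1)), p)
  vs <- vesselness(volume3d(sph, c(1, 1, 1)), p)
  expect_gt(vc$values[20, 20, 20], vs$values[20, 20, 20])
})

test_that("vesselness rejects scales too large for the grid", {
  v <- volume3d(array(stats::runif(24^3), c(24, 24, 24)), c(1, 1, 1))
  expect_error(vesselness(v, vesselness_params(c(1, 8), 3)),
               "half the smallest grid extent")
})

test_that("vesselness with auto c is invariant to intensity rescaling", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 100))
  v1 <- vesselness(case$image, vesselness_params(c(0.5, 3), 3))
  rescaled <- case$image
  rescaled$values <- case$image$values * 3.7 + 11
  v2 <- vesselness(rescaled, vesselness_params(c(0.5, 3), 3))
  expect_equal(v1$values, v2$values, tolerance = 1e-6)
})

test_that("percentile normalization maps the 5th/95th points to 0/1", {
  vals <- array(rep(0:100, length.out = 12^3), c(12, 12, 12))
  v <- volume3d(vals, c(1, 1, 1))
  mask <- mk_mask(array(1, dim(vals)))
  n <- normalize_cta(v, mask = mask)
  q <- stats::quantile(vals, c(0.05, 0.95), names = FALSE)
  expect_equal(n$values[which(vals == q[1])[1]], 0)
  expect_equal(n$values[which(vals == q[2])[1]], 1)
  mid <- which(vals == 50)[1]
  expect_equal(n$values[mid], (50 - q[1]) / (q[2] - q[1]), tolerance = 1e-12)
  expect_equal(max(n$values), 1)  # clipping
  # monotone non-decreasing on masked voxels
  o <- order(as.vector(vals))
  expect_true(all(diff(as.vector(n$values)[o]) >= 0))
})

test_that("z-score normalization centers and scales the masked region", {
  v <- volume3d(array(c(1, 3), c(2, 1, 1)), c(1, 1, 1))
  z <- normalize_zscore(v)
  expect_equal(as.vector(z$values), c(-1, 1))
  set.seed(2)
  v2 <- volume3d(array(stats::rnorm(10^3, 50, 7), c(10, 10, 10)), c(1, 1, 1))
  z2 <- normalize_zscore(v2)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(abs(mean(z2$values)), 1e-6)
  expect_lt(abs(pop_sd(z2$values) - 1), 1e-6)
  z3 <- normalize_zscore(z2)
  expect_equal(z3$values, z2$values, tolerance = 1e-8)
  expect_warning(normalize_zscore(volume3d(array(5, c(3, 3, 3)), c(1, 1, 1))),
                 "zero variance")
})

test_that("build_stack produces the per-variant channel layout", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 120))
  so <- build_stack(case$image, "Orig")
  expect_length(so$channels, 1)
  sv <- build_stack(case$image, "Vess", scale_ranges = list(c(0.5, 2), c(2, 4)))
  expect_length(sv$channels, 3)
  sl <- build_stack(case$image, "LDim")
  expect_length(sl$channels, 1)
  for (ch in sv$channels) {
    expect_equal(ch$spacing, rep(0.5, 3))
    expect_true(same_grid(ch, sv$channels[[1]]))
  }
  # deterministic: running the chain twice is bit-identical
  sv2 <- build_stack(case$image, "Vess", scale_ranges = list(c(0.5, 2), c(2, 4)))
  expect_identical(sv$channels[[2]]$values, sv2$channels[[2]]$values)
})
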