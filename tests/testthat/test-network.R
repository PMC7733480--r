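test_that("model construction follows the receptive-field arithmetic", {
  cf <- network_config(segment_size = 25L)
  expect_equal(cf$out_size, 9L)  # 25 - 8 * 2
  cf45 <- network_config(segment_size = 45L)
  expect_equal(cf45$out_size, 29L)
  expect_error(network_config(segment_size = 15L), "minimum is 17")
  m1 <- build_model(network_config(seed = 1L))
  m2 <- build_model(network_config(seed = 99L))
  expect_equal(n_parameters(m1), n_parameters(m2))
  m3 <- build_model(network_config(channels_in = 3L))
  expect_gt(n_parameters(m3), n_parameters(m1))
})

test_that("patch sampling yields the configured segment shapes", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 150,
                                              spacing = c(1, 1, 1)))
  st <- build_stack(case$image, "Orig", target_mm = 1)
  labels <- resample_isotropic(case$aneurysm_mask, 1, mode = "label")
  for (seg in c(25L, 45L)) {
    cf <- network_config(segment_size = seg, seed = 2L)
    pairs <- sample_patches(st, labels, cf, n = 4, seed = 5)
    expect_length(pairs, 4)
    expect_equal(dim(pairs[[1]]$image_segment)[1:3], rep(seg, 3))
    expect_equal(dim(pairs[[1]]$context_segment)[1:3], rep(cf$lo_in, 3))
    expect_equal(dim(pairs[[1]]$label_segment), rep(cf$out_size, 3))
  }
  cf <- network_config(segment_size = 25L)
  pairs <- sample_patches(st, labels, cf, n = 6, seed = 9)
  # the first half are foreground-centered: center voxel of the label is 1
  ctr <- (cf$out_size + 1) / 2
  for (i in 1:3)
    expect_equal(pairs[[i]]$label_segment[ctr, ctr, ctr], 1)
  # determinism
  pairs2 <- sample_patches(st, labels, cf, n = 6, seed = 9)
  expect_identical(pairs[[2]]$image_segment, pairs2[[2]]$image_segment)
  # no foreground but foreground requested
  empty <- resample_isotropic(
    generate_phantom(small_phantom_spec(aneurysms = list(),
                                        spacing = c(1, 1, 1)))$aneurysm_mask,
    1, mode = "label")
  expect_error(sample_patches(st, empty, cf, n = 4, seed = 1),
               "no foreground voxels")
})

test_that("flip augmentation is an involution that preserves labels", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 150,
                                              spacing = c(1, 1, 1)))
  st <- build_stack(case$image, "Orig", target_mm = 1)
  labels <- resample_isotropic(case$aneurysm_mask, 1, mode = "label")
  cf <- network_config(segment_size = 25L)
  pair <- sample_patches(st, labels, cf, n = 2, seed = 4)[[1]]
  all_flip <- augment_flips(pair, flips = c(TRUE, TRUE, TRUE))
  back <- augment_flips(all_flip, flips = c(TRUE, TRUE, TRUE))
  expect_identical(back$image_segment, pair$image_segment)
  expect_identical(back$context_segment, pair$context_segment)
  expect_identical(back$label_segment, pair$label_segment)
  expect_identical(back$off, pair$off)
  expect_equal(sum(all_flip$label_segment), sum(pair$label_segment))
  f1 <- augment_flips(pair, seed = 31)
  f2 <- augment_flips(pair, seed = 31)
  expect_identical(f1$image_segment, f2$image_segment)
})

test_that("the soft Dice loss matches hand-computed values", {
  t <- array(c(1, 0), c(2, 2, 2))
  expect_equal(dice_loss(t, t, smooth = 1e-12), 0, tolerance = 1e-9)
  expect_equal(dice_loss(1 - t, t, smooth = 1e-12), 1, tolerance = 1e-9)
  # pred 0.5 everywhere, half the 2^3 patch foreground, smooth = 1:
  # 1 - (2 * 2 + 1) / (4 + 4 + 1) = 4/9
  p <- array(0.5, c(2, 2, 2))
  expect_equal(dice_loss(p, t, smooth = 1), 4 / 9, tolerance = 1e-12)
  expect_error(dice_loss(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "shapes differ")
})

test_that("analytic gradients agree with numerical differentiation", {
  cf <- tiny_network_config(channels_in = 2L)
  m <- build_model(cf)
  set.seed(9)
  B <- 2
  batch <- list(
    xhi = array(stats::rnorm(cf$segment_size^3 * 2 * B),
                c(rep(cf$segment_size, 3), 2, B)),
    xlo = array(stats::rnorm(cf$lo_in^3 * 2 * B), c(rep(cf$lo_in, 3), 2, B)),
    off = rbind(c(0L, 1L, 2L), c(2L, 0L, 1L)),
    labels = array(stats::rbinom(cf$out_size^3 * B, 1, 0.3),
                   c(rep(cf$out_size, 3), B)))
  fw <- aneuseg:::net_forward(m, batch, train = TRUE, with_grad = TRUE)
  expect_true(is.finite(fw$loss))
  params <- aneuseg:::model_params(m)
  getp <- function(pl, path) { x <- pl; for (k in path) x <- x[[k]]; x }
  setp <- function(pl, path, val) {
    if (length(path) == 1) { pl[[path[[1]]]] <- val; return(pl) }
    pl[[path[[1]]]] <- setp(pl[[path[[1]]]], path[-1], val)
    pl
  }
  eps <- 1e-5
  checks <- list(list(path = list("cls", "W"), i = 3),
                 list(path = list("fc", "l9", "W"), i = 5),
                 list(path = list("fc", "l10", "a"), i = 1),
                 list(path = list("pathways", "hi", 1L, "W"), i = 10),
                 list(path = list("pathways", "hi", 4L, "W"), i = 7),
                 list(path = list("pathways", "lo", 5L, "W"), i = 3),
                 list(path = list("pathways", "hi", 8L, "gamma"), i = 2),
                 list(path = list("pathways", "lo", 8L, "beta"), i = 2))
  for (ck in checks) {
    x0 <- getp(params, ck$path)
    x <- x0; x[ck$i] <- x[ck$i] + eps
    l1 <- aneuseg:::net_forward(
      aneuseg:::set_model_params(m, setp(params, ck$path, x)), batch,
      train = TRUE)$loss
    x <- x0; x[ck$i] <- x[ck$i] - eps
    l2 <- aneuseg:::net_forward(
      aneuseg:::set_model_params(m, setp(params, ck$path, x)), batch,
      train = TRUE)$loss
    num <- (l1 - l2) / (2 * eps)
    ana <- getp(fw$grads, ck$path)[ck$i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4,
              label = paste("gradient at", paste(unlist(ck$path),
                                                 collapse = "$")))
  }
})

test_that("training runs, logs losses and is reproducible", {
  case <- generate_phantom(small_phantom_spec(volume_mm3 = 200,
                                              grid = c(32, 32, 32),
                                              spacing = c(1, 1, 1)))
  st <- build_stack(case$image, "Orig", target_mm = 1)
  labels <- resample_isotropic(case$aneurysm_mask, 1, mode = "label")
  cf <- tiny_network_config(epochs = 1L, batches_per_epoch = 2L,
                            segment_size = 19L, batch_size = 2L, seed = 21L)
  m1 <- train_fold(list(list(stack = st, labels = labels)), cf)
  expect_equal(nrow(m1$loss_log), 2)
  expect_true(all(is.finite(m1$loss_log$loss)))
  m2 <- train_fold(list(list(stack = st, labels = labels)), cf)
  expect_identical(m1$loss_log$loss, m2$loss_log$loss)
  expect_identical(m1$cls$W, m2$cls$W)
})

test_that("dense prediction covers the grid once, deterministically", {
  set.seed(4)
  arr <- array(stats::rnorm(27^3), c(27, 27, 27))
  st <- array_stack(arr)
  cf <- network_config(segment_size = 25L, seed = 8L)
  m <- build_model(cf)
  p1 <- predict_volume(m, st)
  expect_equal(dim(p1$values), dim(arr))
  expect_gte(min(p1$values), 0)
  expect_lte(max(p1$values), 1)
  p2 <- predict_volume(m, st)
  expect_identical(p1$values, p2$values)
  # channel mismatch rejected
  cf3 <- network_config(channels_in = 3L)
  expect_error(predict_volume(build_model(cf3), st), "expects 3")
})

test_that("tiled inference equals a whole-volume single pass", {
  set.seed(4)
  arr <- array(stats::rnorm(27^3), c(27, 27, 27))
  st <- array_stack(arr)
  # same seed and widths -> identical weights; only the tiling differs
  m_tiled <- build_model(network_config(segment_size = 25L, seed = 8L))
  m_single <- build_model(network_config(segment_size = 43L, seed = 8L))
  p_tiled <- predict_volume(m_tiled, st)     # 27 windows of 9^3
  p_single <- predict_volume(m_single, st)   # one 27^3 window
  expect_equal(p_tiled$values, p_single$values, tolerance = 1e-12)
})

test_that("binarization applies the threshold inclusively", {
  tmpl <- volume3d(array(0, c(3, 3, 3)), c(1, 1, 1))
  p0 <- aneuseg:::probability_map(array(0, c(3, 3, 3)), tmpl)
  expect_equal(sum(binarize(p0)$values), 0)
  p6 <- aneuseg:::probability_map(array(0.6, c(3, 3, 3)), tmpl)
  expect_equal(sum(binarize(p6, 0.5)$values), 27)
  p99 <- aneuseg:::probability_map(array(0.99, c(3, 3, 3)), tmpl)
  expect_equal(sum(binarize(p99, 1)$values), 0)
  expect_error(binarize(p6, 1.5), "threshold")
})
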