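test_that("connected components count voxels and physical volumes", {
  d <- c(10, 10, 10)
  empty <- mk_mask(array(0, d), spacing = c(0.5, 0.5, 0.5))
  expect_equal(nrow(connected_components(empty)), 0)
  two <- array(0, d)
  two[1:2, 1:2, 1:2] <- 1
  two[7:8, 7:8, 7:8] <- 1
  cc <- connected_components(mk_mask(two, spacing = c(0.5, 0.5, 0.5)))
  expect_equal(nrow(cc), 2)
  expect_equal(cc$volume_mm3, c(1, 1))  # 8 voxels x 0.125 mm^3
  # diagonal-touching voxels join under 26-connectivity, split under 6
  diag2 <- array(0, d); diag2[3, 3, 3] <- 1; diag2[4, 4, 4] <- 1
  expect_equal(nrow(connected_components(mk_mask(diag2), 26L)), 1)
  expect_equal(nrow(connected_components(mk_mask(diag2), 6L)), 2)
})

test_that("detection matching handles identity, misses and fragmentation", {
  d <- c(10, 10, 10)
  ref <- array(0, d)
  ref[2:4, 2:4, 2:4] <- 1
  ref[7:9, 7:9, 7:9] <- 1
  r <- match_detections(mk_mask(ref), mk_mask(ref))
  expect_equal(nrow(r$matched), 2)
  expect_equal(nrow(r$fp), 0)
  expect_equal(nrow(r$fn), 0)
  expect_equal(r$matched$dsc, c(1, 1))
  r2 <- match_detections(mk_mask(array(0, d)), mk_mask(ref))
  expect_equal(c(nrow(r2$matched), nrow(r2$fn), nrow(r2$fp)), c(0, 2, 0))
  # one overlapping + one distant predicted blob
  pred <- array(0, d)
  pred[3:4, 3:4, 3:4] <- 1
  pred[8:9, 1:2, 8:9] <- 1
  r3 <- match_detections(mk_mask(pred), mk_mask(ref))
  expect_equal(c(nrow(r3$matched), nrow(r3$fn), nrow(r3$fp)), c(1, 1, 1))
  ora <- match_oracle(pred, ref)
  expect_equal(nrow(r3$matched), ora$tp)
  expect_equal(nrow(r3$fn), ora$fn)
  expect_equal(nrow(r3$fp), ora$fp)
  expect_equal(sort(r3$matched$dsc), ora$dsc, tolerance = 1e-12)
  # fragmented prediction merges into a single TP
  frag <- array(0, d)
  frag[2, 2:4, 2:4] <- 1
  frag[4, 2:4, 2:4] <- 1
  r4 <- match_detections(mk_mask(frag), mk_mask(ref))
  expect_equal(nrow(r4$matched), 1)
  expect_equal(nrow(r4$fp), 0)
})

test_that("detection counting invariants hold on randomized small grids", {
  d <- c(8, 8, 8)
  for (s in 1:25) {
    pred <- random_blobs(d, sample(0:3, 1), seed = 1000 + s)
    ref <- random_blobs(d, sample(0:3, 1), seed = 2000 + s)
    r <- match_detections(mk_mask(pred), mk_mask(ref))
    n_ref <- nrow(connected_components(mk_mask(ref)))
    n_pred <- nrow(connected_components(mk_mask(pred)))
    expect_equal(nrow(r$matched) + nrow(r$fn), n_ref)
    expect_lte(nrow(r$fp), n_pred)
  }
})

test_that("the printed metric formulas reproduce their worked examples", {
  # sensitivity and precision from printed detected/missed and detected/FP
  expect_equal(sensitivity(148, 23), 87)
  expect_equal(sensitivity(57, 22), 72)
  expect_equal(sensitivity(0, 5), 0)
  expect_equal(precision(178, 149), 54)
  expect_equal(precision(57, 14), 80)
  expect_equal(precision(10, 0), 100)
  expect_error(sensitivity(0, 0), "undefined")
  expect_error(precision(0, 0), "undefined")
  # F1 from unrounded percentages
  expect_equal(f1_score(sensitivity(178, 37, rounded = FALSE),
                        precision(178, 149, rounded = FALSE)), 0.66)
  expect_equal(f1_score(sensitivity(57, 22, rounded = FALSE),
                        precision(57, 14, rounded = FALSE)), 0.76)
  expect_equal(f1_score(80, 80), 0.8)  # S = P = p -> F1 = p / 100
  # FPs per scan
  expect_equal(fps_per_scan(26, 185), 0.14)
  expect_equal(fps_per_scan(14, 68), 0.21)
  expect_equal(fps_per_scan(0, 10), 0)
  expect_error(fps_per_scan(3, 0), "n_scans")
})

test_that("DSC is symmetric, bounded and exact on overlap fractions", {
  d <- c(6, 6, 6)
  a <- array(0, d); a[1:4, 1, 1] <- 1
  b <- array(0, d); b[2:5, 1, 1] <- 1
  expect_equal(dsc(mk_mask(a), mk_mask(a)), 1)
  expect_equal(dsc(mk_mask(a), mk_mask(b)), dsc(mk_mask(b), mk_mask(a)))
  expect_equal(dsc(mk_mask(a), mk_mask(b)), 2 * 3 / 8)  # |a|=|b|=4, overlap 3
  cdis <- array(0, d); cdis[6, 6, 6] <- 1
  expect_equal(dsc(mk_mask(a), mk_mask(cdis)), 0)
  expect_error(dsc(mk_mask(array(0, d)), mk_mask(array(0, d))), "undefined")
})

test_that("Pearson volume correlation behaves under affine maps", {
  v <- c(30, 80, 200, 400)
  expect_equal(pearson_volume_correlation(v, v), 1)
  expect_equal(pearson_volume_correlation(v, -v + 500), -1)
  expect_equal(pearson_volume_correlation(v, 2 * v), 1)
  expect_error(pearson_volume_correlation(v[1:2], v[1:2]), "at least 3")
  expect_error(pearson_volume_correlation(v, rep(7, 4)), "zero variance")
})

test_that("volume-binned reports match a hand-filtered oracle", {
  d <- c(14, 14, 14)
  sp <- c(1, 1, 1)
  # reference: three components of 27, 64 and 125 mm^3
  ref <- array(0, d)
  ref[1:3, 1:3, 1:3] <- 1
  ref[6:9, 1:4, 1:4] <- 1
  ref[10:14, 10:14, 10:14] <- 1
  # prediction: hits the 64 and 125 ones, misses the 27, one 8 mm^3 FP
  pred <- array(0, d)
  pred[6:9, 1:4, 1:4] <- 1
  pred[10:13, 10:13, 10:13] <- 1
  pred[1:2, 12:13, 1:2] <- 1
  res <- match_detections(mk_mask(pred, sp), mk_mask(ref, sp))
  rep_all <- volume_binned_report(res, bins = c(30, 50, 100))
  expect_equal(rep_all$tp, c(2, 2, 2, 1))
  expect_equal(rep_all$fn, c(1, 0, 0, 0))
  expect_equal(rep_all$fp, c(1, 0, 0, 0))
  expect_equal(rep_all$sensitivity_pct, c(67, 100, 100, 100))
  expect_equal(rep_all$fps_per_scan, c(1, 0, 0, 0))
  # a single all-encompassing stratum equals the unstratified numbers
  rep_one <- volume_binned_report(res, bins = numeric(0))
  expect_equal(rep_one$sensitivity_pct, 67)
  expect_equal(rep_one$tp, 2)
  # strata above every reference volume are absent, not zero
  rep_high <- volume_binned_report(res, bins = c(1000))
  expect_equal(nrow(rep_high), 1)
  expect_equal(rep_high$stratum, "all")
})

test_that("pooled multi-scan reports divide FPs by the scan count", {
  d <- c(8, 8, 8)
  ref <- array(0, d); ref[2:4, 2:4, 2:4] <- 1
  pred_hit <- ref
  pred_fp <- ref; pred_fp[7:8, 7:8, 7:8] <- 1
  r1 <- match_detections(mk_mask(pred_hit), mk_mask(ref))
  r2 <- match_detections(mk_mask(pred_fp), mk_mask(ref))
  rep2 <- volume_binned_report(list(r1, r2), bins = numeric(0))
  expect_equal(rep2$n_scans, 2)
  expect_equal(rep2$tp, 2)
  expect_equal(rep2$fp, 1)
  expect_equal(rep2$fps_per_scan, 0.5)
})
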