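test_that("fold splits partition cases into near-equal validation folds", {
  fs <- make_folds(1:10, seed = 3)
  expect_equal(fs$k, 5L)
  expect_equal(sort(unname(tabulate(fs$assignments, 5))), rep(2L, 5))
  expect_setequal(names(fs$assignments), as.character(1:10))
  fs2 <- make_folds(1:10, seed = 3)
  expect_identical(fs$assignments, fs2$assignments)
  expect_error(make_folds(1:4, seed = 1), "at least 5 cases")
  fs3 <- make_folds(1:11, seed = 1)
  expect_lte(diff(range(tabulate(fs3$assignments, 5))), 1)
})

test_that("STAPLE fixes perfect agreement and flags degenerate input", {
  truth <- array(0, c(8, 8, 4)); truth[3:5, 3:5, 2:3] <- 1
  masks <- lapply(1:5, function(i) mk_mask(truth))
  res <- staple(masks)
  expect_true(all(res$per_rater$p >= 0.99))
  expect_true(all(res$per_rater$q >= 0.99))
  expect_identical(binarize(res$consensus, 0.5)$values, truth)
  empty <- lapply(1:3, function(i) mk_mask(array(0, c(4, 4, 4))))
  dres <- staple(empty)
  expect_true(dres$degenerate)
  expect_equal(sum(dres$consensus$values), 0)
  expect_error(staple(list(mk_mask(truth))), "at least 2")
})

test_that("STAPLE matches a per-voxel brute-force EM to 1e-6", {
  # enumerable instance: 3 raters on a 3x1x1 grid, masks 110 / 100 / 100
  m1 <- mk_mask(array(c(1, 1, 0), c(3, 1, 1)))
  m2 <- mk_mask(array(c(1, 0, 0), c(3, 1, 1)))
  m3 <- mk_mask(array(c(1, 0, 0), c(3, 1, 1)))
  res <- staple(list(m1, m2, m3))
  ora <- staple_oracle(list(m1, m2, m3))
  expect_equal(as.vector(res$consensus$values), ora$W, tolerance = 1e-6)
  expect_equal(res$per_rater$p, ora$p, tolerance = 1e-6)
  expect_equal(res$per_rater$q, ora$q, tolerance = 1e-6)
  # a second, asymmetric instance
  m4 <- mk_mask(array(c(0, 1, 1), c(3, 1, 1)))
  res2 <- staple(list(m1, m2, m4))
  ora2 <- staple_oracle(list(m1, m2, m4))
  expect_equal(as.vector(res2$consensus$values), ora2$W, tolerance = 1e-6)
})

test_that("STAPLE recovers simulated rater qualities on a 40^3 grid", {
  d <- c(40, 40, 40)
  truth <- array(0, d)
  truth[8:30, 10:28, 12:26] <- 1
  set.seed(17)
  raters <- lapply(1:5, function(j) {
    r <- array(0, d)
    fg <- truth == 1
    r[fg] <- stats::rbinom(sum(fg), 1, 0.9)       # sensitivity 0.9
    r[!fg] <- stats::rbinom(sum(!fg), 1, 0.05)    # specificity 0.95
    mk_mask(r)
  })
  res <- staple(raters)
  expect_true(all(abs(res$per_rater$p - 0.9) <= 0.05))
  expect_true(all(abs(res$per_rater$q - 0.95) <= 0.02))
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(res$log_likelihood) >= -1e-8))
})

test_that("STAPLE consensus respects union/intersection bounds and symmetry", {
  set.seed(23)
  d <- c(12, 12, 6)
  masks <- lapply(1:4, function(j) {
    a <- array(0, d); a[3:9, 3:9, 2:5] <- stats::rbinom(7 * 7 * 4, 1, 0.6)
    mk_mask(a)
  })
  res <- staple(masks)
  cons <- binarize(res$consensus, 0.5)$values
  u <- Reduce(`|`, lapply(masks, function(m) m$values > 0))
  i <- Reduce(`&`, lapply(masks, function(m) m$values > 0))
  expect_true(all(cons[!u] == 0))
  expect_true(all(cons[i] == 1))
  perm <- staple(masks[c(3, 1, 4, 2)])
  expect_equal(perm$consensus$values, res$consensus$values, tolerance = 1e-9)
})

test_that("fold fusion behaves like a quality-weighted majority", {
  d <- c(6, 6, 6)
  base <- array(0, d); base[2:4, 2:4, 2:4] <- 1
  m <- mk_mask(base)
  expect_identical(fuse_folds(lapply(1:5, function(i) m))$values, m$values)
  expect_equal(sum(fuse_folds(lapply(1:5, function(i)
    mk_mask(array(0, d))))$values), 0)
  # 4 of 5 equal-quality raters mark one extra voxel -> foreground
  withv <- base; withv[5, 5, 5] <- 1
  masks <- c(lapply(1:4, function(i) mk_mask(withv)), list(mk_mask(base)))
  fused <- fuse_folds(masks)
  expect_equal(fused$values[5, 5, 5], 1)
  # oracle agreement on the same instance
  ora <- staple_oracle(masks)
  expect_equal(as.vector(staple(masks)$consensus$values), ora$W,
               tolerance = 1e-6)
})

test_that("the three-variant ensemble follows the 2-of-3 majority", {
  d <- c(6, 6, 6)
  base <- array(0, d); base[2:4, 2:4, 2:4] <- 1
  extra <- base; extra[5, 5, 5] <- 1
  masks <- list(mk_mask(extra), mk_mask(extra), mk_mask(base))
  ens <- ensemble_combine(masks)
  expect_equal(ens$values[5, 5, 5], 1)
  expect_identical(ensemble_combine(lapply(1:3, function(i)
    mk_mask(base)))$values, base)
  expect_equal(sum(ensemble_combine(lapply(1:3, function(i)
    mk_mask(array(0, d))))$values), 0)
  maj <- ensemble_combine(masks, method = "majority")
  expect_identical(maj$values, ens$values)
  expect_error(ensemble_combine(masks[1:2]), "exactly 3")
})
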