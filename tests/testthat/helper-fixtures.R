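# Shared fixture builders and independent brute-force oracles.

mk_vol <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume3d(values, spacing, origin)
}

mk_mask <- function(values, spacing = c(1, 1, 1)) {
  volume3d(array(as.numeric(values > 0), dim(values)), spacing)
}

# A small phantom with one straight vessel and one aneurysm.
small_phantom_spec <- function(volume_mm3 = 100, grid = c(48, 48, 32),
                               spacing = c(0.62, 0.62, 1.0), seed = 7,
                               noise_sd = 8, aneurysms = NULL) {
  if (is.null(aneurysms))
    aneurysms <- list(list(attach = 1L, t = 0.5, volume_mm3 = volume_mm3,
                           eccentricity = 1))
  phantom_spec(
    grid_shape = grid, spacing_mm = spacing,
    vessel_segments = list(list(
      points = rbind(c(4, grid[2] * spacing[2] * 0.3, grid[3] * spacing[3] * 0.5),
                     c(grid[1] * spacing[1] * 0.5, grid[2] * spacing[2] * 0.28,
                       grid[3] * spacing[3] * 0.52),
                     c(grid[1] * spacing[1] - 4, grid[2] * spacing[2] * 0.33,
                       grid[3] * spacing[3] * 0.5)),
      radius = 1.4)),
    aneurysms = aneurysms, noise_sd = noise_sd, seed = seed)
}

# Wrap a plain array as a single-channel stack on an isotropic grid.
array_stack <- function(arr, spacing = 0.5, variant = "Orig",
                        mask = NULL) {
  v <- volume3d(arr, rep(spacing, 3))
  if (is.null(mask)) mask <- array(1, dim(arr))
  structure(list(channels = list(v),
                 mask = volume3d(mask, rep(spacing, 3)),
                 variant_tag = variant),
            class = "channel_stack")
}

tiny_network_config <- function(...) {
  args <- list(channels_in = 1L, segment_size = 19L,
               widths = c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L), fc_width = 4L,
               batch_size = 3L, epochs = 1L, batches_per_epoch = 1L,
               seed = 3L)
  args[names(list(...))] <- list(...)
  do.call(network_config, args)
}

# ---- independent oracles ----------------------------------------------------

# Per-voxel binary STAPLE EM, deliberately naive (no pattern grouping).
staple_oracle <- function(masks, prior = "auto", tol = 1e-6, max_iter = 100,
                          init_p = 0.99, init_q = 0.99) {
  D <- sapply(masks, function(m) as.numeric(m$values > 0))
  J <- ncol(D); n <- nrow(D)
  g <- if (identical(prior, "auto")) mean(colMeans(D)) else prior
  p <- rep(init_p, J); q <- rep(init_q, J)
  W <- rep(g, n)
  eps <- 1e-7
  for (it in seq_len(max_iter)) {
    Wnew <- numeric(n)
    for (i in seq_len(n)) {
      a <- g; b <- 1 - g
      for (j in seq_len(J)) {
        if (D[i, j] == 1) { a <- a * p[j]; b <- b * (1 - q[j]) }
        else { a <- a * (1 - p[j]); b <- b * q[j] }
      }
      Wnew[i] <- a / (a + b)
    }
    delta <- max(abs(Wnew - W)); W <- Wnew
    p <- pmin(pmax(colSums(W * D) / sum(W), eps), 1 - eps)
    q <- pmin(pmax(colSums((1 - W) * (1 - D)) / sum(1 - W), eps), 1 - eps)
    if (delta < tol) break
  }
  list(W = W, p = p, q = q)
}

# Naive 26-connectivity labeling by flood fill over voxel index sets.
label_oracle <- function(arr) {
  d <- dim(arr)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  nxt <- 0L
  for (i in which(arr > 0)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(nbr))) {
        p <- ci + nbr[k, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (arr[j] > 0 && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Exhaustive set-intersection detection matching oracle.
match_oracle <- function(pred_arr, ref_arr, voxel_mm3 = 1) {
  pl <- label_oracle(pred_arr); rl <- label_oracle(ref_arr)
  np <- max(pl); nr <- max(rl)
  pred_sets <- lapply(seq_len(np), function(k) which(pl == k))
  ref_sets <- lapply(seq_len(nr), function(k) which(rl == k))
  assign_to <- rep(NA_integer_, np)
  for (p in seq_len(np)) {
    ov <- vapply(ref_sets, function(rs) length(intersect(pred_sets[[p]], rs)), 0)
    if (np > 0 && nr > 0 && any(ov > 0)) assign_to[p] <- which.max(ov)
  }
  tp <- 0L; fn <- 0L; dscs <- numeric(0)
  for (r in seq_len(nr)) {
    direct <- if (np > 0)
      sum(vapply(pred_sets, function(ps) length(intersect(ps, ref_sets[[r]])), 0))
      else 0
    if (direct >= 1) {
      tp <- tp + 1L
      pu <- unlist(pred_sets[which(assign_to == r)])
      dscs <- c(dscs, 2 * length(intersect(pu, ref_sets[[r]])) /
                  (length(pu) + length(ref_sets[[r]])))
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = sum(is.na(assign_to)), dsc = sort(dscs))
}

# Random blobby binary array for matching trials.
random_blobs <- function(d, n_blobs, seed) {
  set.seed(seed)
  arr <- array(0, d)
  if (n_blobs == 0) return(arr)
  for (k in seq_len(n_blobs)) {
    c0 <- sapply(d, function(n) sample.int(n, 1))
    r <- sample(1:3, 1)
    lo <- pmax(c0 - r, 1); hi <- pmin(c0 + r, d)
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  }
  arr
}
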