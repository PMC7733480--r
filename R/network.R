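#' Configuration of the dual-pathway 3D segmentation network
#'
#' A DeepMedic-style patch network: two identical convolutional pathways
#' process a 3D image segment at native resolution and at a threefold
#' downsampled resolution, centered at the same location. Each pathway has
#' eight 3x3x3 convolutional layers (batch normalization + parametric ReLU,
#' residual connections at layers 4, 6 and 8); the upsampled low-resolution
#' features are concatenated with the native features and passed through two
#' 1x1x1 "fully connected" layers (residual spanning the block, layer 10)
#' and a final two-class classification layer (layer 11) with softmax. The
#' output window per pass is `segment_size - 16` per axis (eight valid 3^3
#' convolutions). Trained with a soft Dice loss.
#'
#' @param channels_in Input channels (1 for Orig/LDim, 3 for Vess).
#' @param segment_size Input segment edge length in voxels (odd, >= 19;
#'   25 or 45 in the studied variants).
#' @param widths Integer length-8, feature maps of the eight pathway layers.
#'   Defaults to a reduced profile sized for CPU runs.
#' @param fc_width Feature maps of the two 1x1x1 layers.
#' @param residual_layers Layers receiving residual connections.
#' @param downsample_factor Downsampling of the context pathway (3).
#' @param batch_size Patches per training batch (15 in the studied setup).
#' @param epochs Training epochs (30 in the studied setup).
#' @param batches_per_epoch Training steps per epoch.
#' @param lr,beta1,beta2,adam_eps Adam optimizer settings (the original
#'   optimizer is not specified; these are recorded defaults).
#' @param bn_momentum,bn_eps Batch-normalization running-average momentum
#'   and variance floor.
#' @param prelu_init Initial slope of the parametric ReLU.
#' @param smooth Additive smoothing of the soft Dice loss.
#' @param fg_fraction Fraction of training segments centered on foreground.
#' @param seed Integer seed for initialization and sampling.
#' @return An object of class `network_config`.
#' @export
network_config <- function(channels_in = 1L, segment_size = 25L,
                           widths = c(4L, 4L, 4L, 4L, 8L, 8L, 8L, 8L),
                           fc_width = 16L,
                           residual_layers = c(4L, 6L, 8L, 10L),
                           downsample_factor = 3L,
                           batch_size = 15L, epochs = 30L,
                           batches_per_epoch = 10L,
                           lr = 3e-3, beta1 = 0.9, beta2 = 0.999,
                           adam_eps = 1e-8,
                           bn_momentum = 0.9, bn_eps = 1e-5,
                           prelu_init = 0.25, smooth = 1,
                           fg_fraction = 0.5, seed = 1L) {
  segment_size <- as.integer(segment_size)
  rf <- 2L * 8L + 1L  # receptive field of the native pathway
  if (segment_size < rf)
    stop(sprintf("segment_size %d is below the receptive field; minimum is %d",
                 segment_size, rf))
  if (segment_size %% 2L == 0L) stop("segment_size must be odd")
  if (length(widths) != 8L) stop("`widths` must have length 8")
  if (downsample_factor < 1L) stop("downsample_factor must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  out_size <- segment_size - 16L
  lo_out <- as.integer(ceiling((out_size + 2L) / 3L))
  structure(list(
    channels_in = as.integer(channels_in), segment_size = segment_size,
    n_layers = 11L, kernel = c(3L, 3L, 3L),
    widths = as.integer(widths), fc_width = as.integer(fc_width),
    residual_layers = as.integer(residual_layers),
    downsample_factor = as.integer(downsample_factor),
    out_size = out_size, lo_out = lo_out, lo_in = lo_out + 16L,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    batches_per_epoch = as.integer(batches_per_epoch),
    lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
    bn_momentum = bn_momentum, bn_eps = bn_eps, prelu_init = prelu_init,
    smooth = smooth, fg_fraction = fg_fraction, seed = as.integer(seed)),
    class = "network_config")
}

# ---- internal tensor helpers -----------------------------------------------

.net_cache <- new.env(parent = emptyenv())

# im2col index matrix for a valid 3^3 convolution on an n^3 grid with Cin
# channels: rows = output voxels (column-major), cols = 27 * Cin.
im2col_idx <- function(n, cin) {
  key <- sprintf("i2c_%d_%d", n, cin)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  bx <- 0:(n - 3L)
  base <- as.vector(outer(as.vector(outer(bx, bx * n, "+")), bx * n * n, "+"))
  k <- 0:2
  offs <- as.vector(outer(as.vector(outer(k, k * n, "+")), k * n * n, "+"))
  offs <- as.vector(outer(offs, (seq_len(cin) - 1L) * n^3, "+"))
  idx <- outer(base, offs, "+") + 1L
  .net_cache[[key]] <- idx
  idx
}

# Row indices (1-based, flat n_src^3) of the centered n_dst^3 crop.
crop_idx <- function(n_src, n_dst) {
  key <- sprintf("crop_%d_%d", n_src, n_dst)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  pad <- (n_src - n_dst) %/% 2L
  b <- pad + 0:(n_dst - 1L)
  idx <- as.vector(outer(as.vector(outer(b, b * n_src, "+")),
                         b * n_src^2, "+")) + 1L
  .net_cache[[key]] <- idx
  idx
}

# Map from an o^3 output window to the lo-resolution m^3 window for a given
# per-axis alignment offset (hi voxel x maps to lo voxel (x + off) %/% 3).
upsample_map <- function(o, m, off) {
  key <- sprintf("ups_%d_%d_%d_%d_%d", o, m, off[1], off[2], off[3])
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  lx <- ((0:(o - 1L)) + off[1]) %/% 3L
  ly <- ((0:(o - 1L)) + off[2]) %/% 3L
  lz <- ((0:(o - 1L)) + off[3]) %/% 3L
  idx <- as.vector(outer(as.vector(outer(lx, ly * m, "+")),
                         lz * m^2, "+")) + 1L
  .net_cache[[key]] <- idx
  idx
}

# valid conv via im2col: x is (vox_in x Cin) for ONE sample, flat column-major
conv3_forward_one <- function(xflat, n_in, cin, W, b) {
  idx <- im2col_idx(n_in, cin)
  col <- xflat[idx]
  dim(col) <- dim(idx)
  out <- col %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, col = col)
}

conv3_backward_one <- function(dout, col, idx, n_in, cin, W) {
  dW <- crossprod(col, dout)
  db <- colSums(dout)
  dcol <- dout %*% t(W)
  dx <- numeric(n_in^3 * cin)
  for (j in seq_len(ncol(idx))) {
    ij <- idx[, j]
    dx[ij] <- dx[ij] + dcol[, j]
  }
  list(dW = dW, db = db, dx = dx)
}

bn_forward <- function(x, gamma, beta, state_rm, state_rv, eps, train) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, ivar, "*")
  } else {
    ivar <- 1 / sqrt(state_rv + eps)
    xhat <- sweep(sweep(x, 2, state_rm), 2, ivar, "*")
    mu <- state_rm; v <- state_rv
  }
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, ivar = ivar, mu = mu, var = v)
}

bn_backward <- function(dy, xhat, ivar, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / n, "*")
  dx <- sweep(t1 - t2, 2, ivar, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

prelu_forward <- function(x, a) {
  neg <- pmin(x, 0)
  y <- pmax(x, 0) + sweep(neg, 2, a, "*")
  list(y = y, x = x)
}

prelu_backward <- function(dy, x, a) {
  pos <- x > 0
  dx <- dy * pos + sweep(dy * !pos, 2, a, "*")
  da <- colSums(dy * pmin(x, 0))
  list(dx = dx, da = da)
}

# initialize one conv/fc block (He init)
init_block <- function(fan_in, cout, prelu_init, with_prelu = TRUE) {
  W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
              fan_in, cout)
  blk <- list(W = W, b = numeric(cout), gamma = rep(1, cout),
              beta = numeric(cout))
  if (with_prelu) blk$a <- rep(prelu_init, cout)
  blk
}

#' Build a dual-pathway segmentation model
#'
#' Initializes all weights deterministically from `config$seed`. The model
#' object carries its config, per-layer parameters for both pathways, the
#' 1x1x1 block, the classification layer, and batch-normalization running
#' statistics.
#'
#' @param config A [network_config()].
#' @return An object of class `aneuseg_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  w <- config$widths
  mk_pathway <- function() {
    layers <- vector("list", 8L)
    cin <- config$channels_in
    for (l in 1:8) {
      layers[[l]] <- init_block(27L * cin, w[l], config$prelu_init)
      cin <- w[l]
    }
    layers
  }
  model <- list(
    config = config,
    pathways = list(hi = mk_pathway(), lo = mk_pathway()),
    fc = list(
      l9 = init_block(2L * w[8], config$fc_width, config$prelu_init),
      l10 = init_block(config$fc_width, config$fc_width, config$prelu_init)
    ),
    cls = list(W = matrix(stats::rnorm(config$fc_width * 2,
                                       sd = sqrt(2 / config$fc_width)),
                          config$fc_width, 2),
               b = numeric(2)),
    state = list()
  )
  # running BN statistics, one pair per normalized layer
  zf <- function(cout) list(rm = numeric(cout), rv = rep(1, cout))
  model$state$pathways <- list(hi = lapply(w, zf), lo = lapply(w, zf))
  model$state$fc <- list(l9 = zf(config$fc_width), l10 = zf(config$fc_width))
  class(model) <- "aneuseg_model"
  model
}

#' Number of trainable parameters of a model
#' @param model An `aneuseg_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  grab <- function(x) if (is.list(x)) sum(vapply(x, grab, 0)) else length(x)
  grab(list(model$pathways, model$fc, model$cls))
}

#' @export
print.aneuseg_model <- function(x, ...) {
  cat(sprintf(paste0("<aneuseg_model> %d-channel, segment %d^3 -> output ",
                     "%d^3, %d parameters\n"),
              x$config$channels_in, x$config$segment_size,
              x$config$out_size, n_parameters(x)))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# One pathway over a batch. x: array (n, n, n, Cin, B). Returns post-activation
# feature matrix (B * out_vox) x C_out plus caches for backward.
pathway_forward <- function(x, layers, bn_state, config, train) {
  n <- dim(x)[1]; cin <- dim(x)[4]; B <- dim(x)[5]
  # per-sample flat vectors
  flats <- lapply(seq_len(B), function(b) as.vector(x[, , , , b]))
  cur_n <- n; cur_c <- cin
  cache <- list()
  post <- NULL
  for (l in 1:8) {
    W <- layers[[l]]$W; bb <- layers[[l]]$b
    idx <- im2col_idx(cur_n, cur_c)
    outs <- vector("list", B); cols <- vector("list", B)
    for (b in seq_len(B)) {
      cf <- conv3_forward_one(flats[[b]], cur_n, cur_c, W, bb)
      outs[[b]] <- cf$out; cols[[b]] <- cf$col
    }
    z <- do.call(rbind, outs)
    bn <- bn_forward(z, layers[[l]]$gamma, layers[[l]]$beta,
                     bn_state[[l]]$rm, bn_state[[l]]$rv, config$bn_eps, train)
    pr <- prelu_forward(bn$y, layers[[l]]$a)
    y <- pr$y
    res_src <- NULL
    if (l %in% config$residual_layers && l <= 8 && l >= 3) {
      src <- cache[[l - 2]]$post           # (B * src_vox) x C_src
      n_src <- cache[[l - 2]]$n_out
      ci <- crop_idx(n_src, cur_n - 2L)
      nc <- min(ncol(src), ncol(y))
      rows <- as.vector(outer(ci, (seq_len(B) - 1L) * n_src^3, "+"))
      y[, seq_len(nc)] <- y[, seq_len(nc)] + src[rows, seq_len(nc), drop = FALSE]
      res_src <- list(layer = l - 2L, rows = rows, nc = nc)
    }
    cache[[l]] <- list(cols = cols, idx = idx, n_in = cur_n, c_in = cur_c,
                       bn = bn, pre = pr$x, post = y, n_out = cur_n - 2L,
                       res = res_src, zrows = nrow(z))
    # next layer input
    cur_n <- cur_n - 2L; cur_c <- ncol(y)
    vox <- cur_n^3
    flats <- lapply(seq_len(B), function(b) {
      as.vector(y[((b - 1L) * vox + 1L):(b * vox), , drop = FALSE])
    })
    post <- y
  }
  list(post = post, cache = cache, B = B)
}

pathway_backward <- function(dpost, fwd, layers, config) {
  B <- fwd$B
  cache <- fwd$cache
  grads <- vector("list", 8L)
  dy <- dpost
  dres <- vector("list", 8L)  # deferred residual gradients into earlier layers
  for (l in 8:1) {
    cc <- cache[[l]]
    if (!is.null(dres[[l]])) dy <- dy + dres[[l]]
    # residual branch out of this layer's output
    if (!is.null(cc$res)) {
      src_l <- cc$res$layer
      nc <- cc$res$nc
      src_vox <- cache[[src_l]]$n_out^3
      dsrc <- matrix(0, B * src_vox, ncol(cache[[src_l]]$post))
      dsrc[cc$res$rows, seq_len(nc)] <- dy[, seq_len(nc), drop = FALSE]
      dres[[src_l]] <- if (is.null(dres[[src_l]])) dsrc else dres[[src_l]] + dsrc
    }
    pr <- prelu_backward(dy, cc$pre, layers[[l]]$a)
    bn <- bn_backward(pr$dx, cc$bn$xhat, cc$bn$ivar, layers[[l]]$gamma)
    dz <- bn$dx
    vox_out <- cc$n_out^3
    dW <- matrix(0, nrow(layers[[l]]$W), ncol(layers[[l]]$W))
    db <- numeric(ncol(layers[[l]]$W))
    dx_flats <- vector("list", B)
    for (b in seq_len(B)) {
      dz_b <- dz[((b - 1L) * vox_out + 1L):(b * vox_out), , drop = FALSE]
      bk <- conv3_backward_one(dz_b, cc$cols[[b]], cc$idx, cc$n_in, cc$c_in,
                               layers[[l]]$W)
      dW <- dW + bk$dW; db <- db + bk$db
      dx_flats[[b]] <- bk$dx
    }
    grads[[l]] <- list(W = dW, b = db, gamma = bn$dgamma, dbeta = bn$dbeta,
                       beta = bn$dbeta, a = pr$da)
    grads[[l]]$dbeta <- NULL
    if (l > 1) {
      vox_in <- cc$n_in^3
      dy <- do.call(rbind, lapply(seq_len(B), function(b) {
        m <- dx_flats[[b]]
        dim(m) <- c(vox_in, cc$c_in)
        m
      }))
    }
  }
  grads
}

# Full forward (and optional backward) over a batch of patch pairs.
# batch: list(xhi (s,s,s,C,B), xlo (li,li,li,C,B), off (B x 3), labels
# (o,o,o,B) or NULL).
net_forward <- function(model, batch, train = FALSE, with_grad = FALSE,
                        update_state = FALSE) {
  cf <- model$config
  # window sizes follow the input shapes (fully convolutional)
  o <- dim(batch$xhi)[1] - 16L
  m <- dim(batch$xlo)[1] - 16L
  B <- dim(batch$xhi)[5]
  fhi <- pathway_forward(batch$xhi, model$pathways$hi,
                         model$state$pathways$hi, cf, train)
  flo <- pathway_forward(batch$xlo, model$pathways$lo,
                         model$state$pathways$lo, cf, train)
  ovox <- o^3; mvox <- m^3
  # upsample + crop the lo features per sample
  up_rows <- integer(B * ovox)
  for (b in seq_len(B)) {
    mp <- upsample_map(o, m, batch$off[b, ])
    up_rows[((b - 1L) * ovox + 1L):(b * ovox)] <- mp + (b - 1L) * mvox
  }
  lo_up <- flo$post[up_rows, , drop = FALSE]
  concat <- cbind(fhi$post, lo_up)
  # 1x1x1 block
  z9 <- sweep(concat %*% model$fc$l9$W, 2, model$fc$l9$b, "+")
  bn9 <- bn_forward(z9, model$fc$l9$gamma, model$fc$l9$beta,
                    model$state$fc$l9$rm, model$state$fc$l9$rv, cf$bn_eps,
                    train)
  pr9 <- prelu_forward(bn9$y, model$fc$l9$a)
  z10 <- sweep(pr9$y %*% model$fc$l10$W, 2, model$fc$l10$b, "+")
  bn10 <- bn_forward(z10, model$fc$l10$gamma, model$fc$l10$beta,
                     model$state$fc$l10$rm, model$state$fc$l10$rv, cf$bn_eps,
                     train)
  pr10 <- prelu_forward(bn10$y, model$fc$l10$a)
  x11 <- pr10$y
  nres <- min(ncol(concat), ncol(x11))
  if (10L %in% cf$residual_layers)
    x11[, seq_len(nres)] <- x11[, seq_len(nres)] +
      concat[, seq_len(nres), drop = FALSE]
  zc <- sweep(x11 %*% model$cls$W, 2, model$cls$b, "+")
  p <- 1 / (1 + exp(zc[, 1] - zc[, 2]))

  out <- list(p = p, B = B)
  if (!is.null(batch$labels)) {
    t <- as.numeric(batch$labels)
    sm <- cf$smooth
    A <- sum(p * t); PP <- sum(p); TT <- sum(t)
    out$loss <- 1 - (2 * A + sm) / (PP + TT + sm)
    out$t <- t
  }
  if (update_state) {
    upd <- function(st, bn) list(
      rm = cf$bn_momentum * st$rm + (1 - cf$bn_momentum) * bn$mu,
      rv = cf$bn_momentum * st$rv + (1 - cf$bn_momentum) * bn$var)
    for (l in 1:8) {
      model$state$pathways$hi[[l]] <- upd(model$state$pathways$hi[[l]],
                                          fhi$cache[[l]]$bn)
      model$state$pathways$lo[[l]] <- upd(model$state$pathways$lo[[l]],
                                          flo$cache[[l]]$bn)
    }
    model$state$fc$l9 <- upd(model$state$fc$l9, bn9)
    model$state$fc$l10 <- upd(model$state$fc$l10, bn10)
    out$state <- model$state
  }
  if (!with_grad) return(out)

  # ---- backward -------------------------------------------------------------
  t <- out$t; sm <- cf$smooth
  A <- sum(p * t); PP <- sum(p); TT <- sum(t)
  denom <- (PP + TT + sm)
  dp <- -(2 * t * denom - (2 * A + sm)) / denom^2
  dz1 <- dp * p * (1 - p)
  dzc <- cbind(-dz1, dz1)
  gcls <- list(W = crossprod(x11, dzc), b = colSums(dzc))
  dx11 <- dzc %*% t(model$cls$W)
  dconcat_res <- NULL
  if (10L %in% cf$residual_layers) {
    dconcat_res <- matrix(0, nrow(dx11), ncol(concat))
    dconcat_res[, seq_len(nres)] <- dx11[, seq_len(nres), drop = FALSE]
  }
  pb10 <- prelu_backward(dx11, pr10$x, model$fc$l10$a)
  bb10 <- bn_backward(pb10$dx, bn10$xhat, bn10$ivar, model$fc$l10$gamma)
  g10 <- list(W = crossprod(pr9$y, bb10$dx), b = colSums(bb10$dx),
              gamma = bb10$dgamma, beta = bb10$dbeta, a = pb10$da)
  dpr9 <- bb10$dx %*% t(model$fc$l10$W)
  pb9 <- prelu_backward(dpr9, pr9$x, model$fc$l9$a)
  bb9 <- bn_backward(pb9$dx, bn9$xhat, bn9$ivar, model$fc$l9$gamma)
  g9 <- list(W = crossprod(concat, bb9$dx), b = colSums(bb9$dx),
             gamma = bb9$dgamma, beta = bb9$dbeta, a = pb9$da)
  dconcat <- bb9$dx %*% t(model$fc$l9$W)
  if (!is.null(dconcat_res)) dconcat <- dconcat + dconcat_res
  chi <- ncol(fhi$post)
  dhi <- dconcat[, seq_len(chi), drop = FALSE]
  dlo_up <- dconcat[, (chi + 1L):ncol(dconcat), drop = FALSE]
  # scatter-add back through the upsampling
  dlo <- rowsum(dlo_up, group = up_rows, reorder = FALSE)
  full <- matrix(0, B * mvox, ncol(dlo_up))
  full[as.integer(rownames(dlo)), ] <- dlo
  ghi <- pathway_backward(dhi, fhi, model$pathways$hi, cf)
  glo <- pathway_backward(full, flo, model$pathways$lo, cf)
  out$grads <- list(pathways = list(hi = ghi, lo = glo),
                    fc = list(l9 = g9, l10 = g10), cls = gcls)
  out
}

# recursive Adam update over matched nested lists of numerics
adam_init <- function(params) {
  rec <- function(x) if (is.list(x)) lapply(x, rec) else x * 0
  list(m = rec(params), v = rec(params), t = 0L)
}

adam_step <- function(params, grads, st, cf) {
  st$t <- st$t + 1L
  b1 <- cf$beta1; b2 <- cf$beta2
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g * g
      p2 <- p - cf$lr * (m2 / corr1) / (sqrt(v2 / corr2) + cf$adam_eps)
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- rec(params, grads, st$m, st$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = st$t))
}

model_params <- function(model) {
  list(pathways = model$pathways, fc = model$fc, cls = model$cls)
}

set_model_params <- function(model, params) {
  model$pathways <- params$pathways
  model$fc <- params$fc
  model$cls <- params$cls
  model
}

# ---- patches ----------------------------------------------------------------

# block-mean downsampling by 3 per axis (anchored at voxel 1; partial edge
# blocks average over the available voxels)
downsample_by3 <- function(arr) {
  d <- dim(arr)
  od <- ceiling(d[1:3] / 3)
  has_c <- length(d) == 4L
  nc <- if (has_c) d[4] else 1L
  out <- array(0, c(od, nc))
  cnt <- array(0, od)
  gx <- (seq_len(d[1]) - 1L) %/% 3L + 1L
  gy <- (seq_len(d[2]) - 1L) %/% 3L + 1L
  gz <- (seq_len(d[3]) - 1L) %/% 3L + 1L
  # accumulate with tensor contractions per axis (sparse-free and fast):
  Mx <- matrix(0, od[1], d[1]); Mx[cbind(gx, seq_len(d[1]))] <- 1
  My <- matrix(0, od[2], d[2]); My[cbind(gy, seq_len(d[2]))] <- 1
  Mz <- matrix(0, od[3], d[3]); Mz[cbind(gz, seq_len(d[3]))] <- 1
  norm <- as.vector(Mx %*% rep(1, d[1]))
  for (c in seq_len(nc)) {
    a <- if (has_c) arr[, , , c] else arr
    a1 <- Mx %*% matrix(a, d[1])                       # od1 x (d2*d3)
    dim(a1) <- c(od[1], d[2], d[3])
    a2 <- apply(a1, c(1, 3), function(v) My %*% v)      # od2 x od1 x d3
    a2 <- aperm(a2, c(2, 1, 3))
    a3 <- apply(a2, c(1, 2), function(v) Mz %*% v)      # od3 x od1 x od2
    a3 <- aperm(a3, c(2, 3, 1))
    w <- outer(outer(rowSums(Mx), rowSums(My)), rowSums(Mz))
    out[, , , c] <- a3 / w
  }
  if (has_c) out else array(out, od)
}

# Extract a zero-padded sub-array: start0 is the 0-based corner, size the
# edge length; arr is (X, Y, Z, C).
extract_patch <- function(arr, start0, size) {
  d <- dim(arr)
  nc <- d[4]
  out <- array(0, c(size, size, size, nc))
  lo_src <- pmax(start0, 0L) + 1L
  hi_src <- pmin(start0 + size, d[1:3])
  if (any(hi_src < lo_src)) return(out)
  lo_dst <- lo_src - start0
  hi_dst <- lo_dst + (hi_src - lo_src)
  out[lo_dst[1]:hi_dst[1], lo_dst[2]:hi_dst[2], lo_dst[3]:hi_dst[3], ] <-
    arr[lo_src[1]:hi_src[1], lo_src[2]:hi_src[2], lo_src[3]:hi_src[3], ,
        drop = FALSE]
  out
}

stack_array <- function(stack) {
  chs <- lapply(stack$channels, function(v) v$values)
  array(unlist(chs), c(dim(chs[[1]]), length(chs)))
}

# Build the patch pair for an output window starting at h0 (0-based).
make_patch <- function(arr, lo_arr, h0, config, labels = NULL) {
  s <- config$segment_size; o <- config$out_size
  li <- config$lo_in
  l0 <- h0 %/% 3L
  pair <- list(
    image_segment = extract_patch(arr, h0 - 8L, s),
    context_segment = extract_patch(lo_arr, l0 - 8L, li),
    off = as.integer(h0 - 3L * l0)
  )
  if (!is.null(labels)) {
    lab <- extract_patch(array(labels, c(dim(labels), 1L)), h0, o)
    pair$label_segment <- array(lab, c(o, o, o))
  }
  class(pair) <- "patch_pair"
  pair
}

#' Sample training patch pairs from a channel stack
#'
#' Half of the segments (per `config$fg_fraction`) are centered on uniformly
#' sampled foreground voxels, the rest on background voxels inside the brain
#' mask. Out-of-volume regions are zero padded. Each pair carries the native
#' segment, the context segment from the threefold-downsampled volume
#' centered at the same location, the label window and the sub-voxel
#' alignment offset between the two pathways.
#'
#' @param stack A `channel_stack` from [build_stack()].
#' @param labels Binary `volume3d` of foreground on the stack grid.
#' @param config A [network_config()].
#' @param n Number of patch pairs.
#' @param seed Integer seed.
#' @return List of `patch_pair` objects.
#' @export
sample_patches <- function(stack, labels, config, n, seed = 1L) {
  stopifnot(inherits(stack, "channel_stack"))
  stop_if_grid_mismatch(stack$channels[[1]], labels, "stack and labels")
  arr <- stack_array(stack)
  lo_arr <- downsample_by3(arr)
  d <- dim(arr)[1:3]
  fg <- which(labels$values > 0)
  bg <- which(stack$mask$values > 0 & labels$values == 0)
  if (!length(bg)) bg <- which(labels$values == 0)
  nf <- round(n * config$fg_fraction)
  if (nf > 0 && !length(fg))
    stop("no foreground voxels available but a foreground fraction > 0 was requested")
  set.seed(seed)
  centers <- c(if (nf > 0) fg[sample.int(length(fg), nf, replace = TRUE)],
               bg[sample.int(length(bg), n - nf, replace = TRUE)])
  half <- (config$out_size - 1L) %/% 2L
  lapply(centers, function(ci) {
    cidx <- as.integer(arrayInd(ci, d)) - 1L
    h0 <- cidx - half
    make_patch(arr, lo_arr, h0, config, labels$values)
  })
}

#' Randomly flip a patch pair along its axes
#'
#' Each of the three axes is flipped independently with probability 0.5;
#' image, context and label segments flip consistently and the pathway
#' alignment offset is mirrored accordingly.
#'
#' @param pair A `patch_pair`.
#' @param seed Integer seed.
#' @param flips Optional logical length-3 to force a specific flip pattern.
#' @param config The [network_config()] the pair was built for.
#' @return A `patch_pair`.
#' @export
augment_flips <- function(pair, seed = 1L, flips = NULL,
                          config = NULL) {
  if (is.null(flips)) {
    set.seed(seed)
    flips <- stats::runif(3) < 0.5
  }
  o <- dim(pair$label_segment)[1]
  m3 <- dim(pair$context_segment)[1] - 16L  # lo output voxels per axis
  rev_axis <- function(a, ax) {
    idx <- rep(list(quote(expr = )), length(dim(a)))
    idx[[ax]] <- rev(seq_len(dim(a)[ax]))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (ax in 1:3) {
    if (!flips[ax]) next
    pair$image_segment <- rev_axis(pair$image_segment, ax)
    pair$context_segment <- rev_axis(pair$context_segment, ax)
    if (!is.null(pair$label_segment))
      pair$label_segment <- array(rev_axis(array(pair$label_segment,
                                                 c(dim(pair$label_segment), 1L)),
                                           ax),
                                  dim(pair$label_segment))
    pair$off[ax] <- 3L * m3 - o - pair$off[ax]
  }
  pair
}

batch_from_pairs <- function(pairs, config) {
  B <- length(pairs)
  s <- config$segment_size; li <- config$lo_in; o <- config$out_size
  nc <- config$channels_in
  xhi <- array(0, c(s, s, s, nc, B))
  xlo <- array(0, c(li, li, li, nc, B))
  off <- matrix(0L, B, 3)
  labels <- if (!is.null(pairs[[1]]$label_segment))
    array(0, c(o, o, o, B)) else NULL
  for (b in seq_len(B)) {
    xhi[, , , , b] <- pairs[[b]]$image_segment
    xlo[, , , , b] <- pairs[[b]]$context_segment
    off[b, ] <- pairs[[b]]$off
    if (!is.null(labels)) labels[, , , b] <- pairs[[b]]$label_segment
  }
  list(xhi = xhi, xlo = xlo, off = off, labels = labels)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`, differentiable in `pred`. Bounded in [0, 1] for probabilistic
#' predictions (with `smooth >= 0`).
#'
#' @param pred Numeric array of probabilities in [0, 1].
#' @param target Binary array of the same shape.
#' @param smooth Additive smoothing constant.
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ")
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
    stop("pred must contain probabilities in [0, 1]")
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Train one cross-validation fold
#'
#' Runs `epochs x batches_per_epoch` Adam steps on flip-augmented patch
#' pairs sampled 50/50 from foreground and background centers of the
#' training cases, with batch normalization in training mode and the soft
#' Dice loss. Fully seeded: the same config and cases give the same model.
#'
#' @param cases List of `list(stack = channel_stack, labels = volume3d)`.
#' @param config A [network_config()].
#' @param verbose Print per-epoch mean loss.
#' @return A trained `aneuseg_model` with a `loss_log` data.frame
#'   (epoch, step, loss) attached.
#' @export
train_fold <- function(cases, config, verbose = FALSE) {
  if (!length(cases)) stop("need at least one training case")
  model <- build_model(config)
  opt <- adam_init(model_params(model))
  log <- list()
  set.seed(config$seed + 1L)
  step_seeds <- sample.int(.Machine$integer.max %/% 2,
                           config$epochs * config$batches_per_epoch)
  k <- 0L
  for (ep in seq_len(config$epochs)) {
    for (st in seq_len(config$batches_per_epoch)) {
      k <- k + 1L
      set.seed(step_seeds[k])
      ci <- sample.int(length(cases), 1)
      pairs <- sample_patches(cases[[ci]]$stack, cases[[ci]]$labels, config,
                              config$batch_size,
                              seed = step_seeds[k] %% 100000L)
      pairs <- lapply(seq_along(pairs), function(i)
        augment_flips(pairs[[i]], seed = step_seeds[k] %% 100000L + i))
      batch <- batch_from_pairs(pairs, config)
      fw <- net_forward(model, batch, train = TRUE, with_grad = TRUE,
                        update_state = TRUE)
      if (!is.finite(fw$loss))
        stop(sprintf("training diverged at epoch %d step %d: loss is %s",
                     ep, st, format(fw$loss)))
      model$state <- fw$state
      upd <- adam_step(model_params(model), fw$grads, opt, config)
      model <- set_model_params(model, upd$params)
      opt$m <- upd$state$m; opt$v <- upd$state$v; opt$t <- upd$state$t
      log[[k]] <- data.frame(epoch = ep, step = st, loss = fw$loss)
    }
    if (verbose) {
      ep_losses <- vapply(log[(k - config$batches_per_epoch + 1L):k],
                          function(d) d$loss, 0)
      message(sprintf("epoch %d/%d  mean dice loss %.4f", ep, config$epochs,
                      mean(ep_losses)))
    }
  }
  model$loss_log <- do.call(rbind, log)
  model
}

#' Dense prediction of a whole volume
#'
#' Tiles the volume into non-overlapping output windows with sufficient
#' input context (zero padding beyond the volume) so that every voxel
#' receives exactly one prediction. Batch normalization uses the running
#' statistics, so the output is independent of tile batching.
#'
#' @param model A trained `aneuseg_model`.
#' @param stack A `channel_stack` whose channel count matches the model.
#' @param tile_batch Tiles per forward pass.
#' @return A `probability_map` (`volume3d` with values in [0, 1]).
#' @export
predict_volume <- function(model, stack, tile_batch = 24L) {
  stopifnot(inherits(model, "aneuseg_model"), inherits(stack, "channel_stack"))
  cf <- model$config
  if (length(stack$channels) != cf$channels_in)
    stop(sprintf("stack has %d channel(s) but the model expects %d",
                 length(stack$channels), cf$channels_in))
  arr <- stack_array(stack)
  lo_arr <- downsample_by3(arr)
  d <- dim(arr)[1:3]
  o <- cf$out_size
  starts <- lapply(d, function(n) seq(0L, by = o,
                                      length.out = ceiling(n / o)))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  padded <- vapply(starts, function(s) max(s) + o, 0)
  out <- array(0, padded)
  idx <- seq_len(nrow(grid))
  for (chunk in split(idx, ceiling(idx / tile_batch))) {
    pairs <- lapply(chunk, function(i)
      make_patch(arr, lo_arr, as.integer(unlist(grid[i, ])), cf))
    # label-free batch
    batch <- batch_from_pairs(pairs, cf)
    fw <- net_forward(model, batch, train = FALSE, with_grad = FALSE)
    pm <- matrix(fw$p, ncol = length(chunk))
    for (j in seq_along(chunk)) {
      h0 <- as.integer(unlist(grid[chunk[j], ]))
      out[h0[1] + 1:o, h0[2] + 1:o, h0[3] + 1:o] <-
        array(pm[, j], c(o, o, o))
    }
  }
  template <- stack$channels[[1]]
  probability_map(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                      drop = FALSE],
                  template,
                  provenance = list(variant_tag = stack$variant_tag))
}

#' Binarize a probability map
#' @param p A `probability_map` (or any `volume3d` with values in [0, 1]).
#' @param threshold Scalar in [0, 1].
#' @return A `segmentation_mask`.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "volume3d"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  segmentation_mask(array(as.numeric(p$values >= threshold), dim(p$values)), p)
}
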