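#' Parameters of the multi-scale Hessian vesselness filter
#'
#' Configures a Frangi-type bright-on-dark tubular-structure filter: the
#' per-voxel response is the maximum over `n_scales` log-spaced Gaussian
#' smoothing scales (sigma, in voxel units) of an eigenvalue-based measure
#' discriminating tubes from plates and blobs.
#'
#' @param scale_range Length-2 numeric, min/max scale in voxels (0 < min < max).
#' @param n_scales Number of log-spaced scales (>= 2).
#' @param alpha Plate/line discrimination weight (> 0).
#' @param beta Blob discrimination weight (> 0).
#' @param c Structureness weight, or `"auto"` for half of the maximum
#'   Frobenius norm of the scale-normalized Hessian over the whole scale
#'   sweep. The auto rule makes the response invariant under affine
#'   intensity rescaling while keeping the per-scale responses comparable,
#'   so the maximizing scale tracks the vessel radius.
#' @return An object of class `vesselness_params`.
#' @export
vesselness_params <- function(scale_range = c(0.5, 5), n_scales = 5,
                              alpha = 0.5, beta = 0.5, c = "auto") {
  if (!(scale_range[1] > 0 && scale_range[1] < scale_range[2]))
    stop("scale_range must satisfy 0 < min < max")
  if (n_scales < 2) stop("n_scales must be >= 2")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0))
    stop("c must be a positive number or \"auto\"")
  structure(list(scale_range = as.numeric(scale_range),
                 n_scales = as.integer(n_scales),
                 alpha = alpha, beta = beta, c = c),
            class = "vesselness_params")
}

#' Surrogate brain mask from intensity bands and morphology
#'
#' Keeps voxels in the soft-tissue band (above an air threshold, below a bone
#' threshold), takes the largest 26-connected component, morphologically
#' closes it and fills internal holes. The skull shell (above the bone
#' threshold) is excluded; intracranial vessels are retained.
#'
#' @param vol A `volume3d`.
#' @param air_threshold Intensities at or below this are air (default 20).
#' @param bone_threshold Intensities at or above this are bone (default 500).
#' @param closing_radius Radius (voxels) of the ball used for closing.
#' @return A binary `volume3d` mask.
#' @export
compute_brain_mask <- function(vol, air_threshold = 20, bone_threshold = 500,
                               closing_radius = 2) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$values)
  tissue <- vol$values > air_threshold & vol$values < bone_threshold
  if (!any(tissue))
    stop(sprintf(paste0("no brain tissue found: no voxels between the air ",
                        "threshold (%g) and bone threshold (%g)"),
                 air_threshold, bone_threshold))
  lab <- cpp_label_components(as.vector(tissue), d, 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m <- array(lab == keep, d)
  # closing: dilate then erode (erosion as complement dilation)
  if (closing_radius > 0) {
    m <- cpp_binary_dilate(as.vector(m), d, closing_radius)
    m <- !cpp_binary_dilate(as.vector(!m), d, closing_radius)
    m <- array(m, d)
  }
  # never re-include bone
  m <- m & vol$values < bone_threshold
  # fill holes: background components not touching the volume border
  bg <- cpp_label_components(as.vector(!m), d, 6L)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  touching <- unique(bg[border & bg > 0])
  m[bg > 0 & !(bg %in% touching)] <- TRUE
  # keep a single component after closing/filling
  lab2 <- cpp_label_components(as.vector(m), d, 26L)
  counts2 <- tabulate(lab2[lab2 > 0])
  m <- array(lab2 == which.max(counts2), d)
  volume3d(array(as.numeric(m), d), vol$spacing, vol$origin)
}

#' Multi-scale Hessian vesselness
#'
#' Bright-on-dark tubular-structure enhancement: at each of `n_scales`
#' log-spaced scales the volume is Gaussian-smoothed (sigma in voxel units),
#' the scale-normalized Hessian eigenvalues \eqn{|\lambda_1| \le |\lambda_2|
#' \le |\lambda_3|} are computed per voxel, and the response combines the
#' plate (\eqn{R_A = |\lambda_2|/|\lambda_3|}), blob (\eqn{R_B = |\lambda_1| /
#' \sqrt{|\lambda_2 \lambda_3|}}) and structureness (Frobenius norm) terms.
#' Voxels whose two largest-magnitude eigenvalues are not both negative get
#' zero. The output is the per-voxel maximum over scales, bounded in [0, 1].
#'
#' @param vol A `volume3d`, background already zeroed by a brain mask.
#' @param params A [vesselness_params()].
#' @return A `volume3d` with values in [0, 1].
#' @export
vesselness <- function(vol, params = vesselness_params()) {
  stopifnot(inherits(vol, "volume3d"), inherits(params, "vesselness_params"))
  d <- dim(vol$values)
  if (params$scale_range[2] * 3 > min(d) / 2)
    stop(sprintf(paste0("maximum scale %.3g voxels needs filter support ",
                        "%.3g > half the smallest grid extent (%d voxels)"),
                 params$scale_range[2], params$scale_range[2] * 3,
                 min(d)))
  scales <- exp(seq(log(params$scale_range[1]), log(params$scale_range[2]),
                    length.out = params$n_scales))
  if (identical(params$c, "auto")) {
    # fix c across the sweep: half the global max Frobenius Hessian norm
    smax <- 0
    for (s in scales) {
      r <- cpp_vesselness_scale(as.vector(vol$values), d, s,
                                params$alpha, params$beta, -1)
      smax <- max(smax, r$smax)
    }
    cval <- smax / 2
    if (cval <= 0) return(volume3d(array(0, d), vol$spacing, vol$origin))
  } else cval <- params$c
  best <- array(0, d)
  for (s in scales) {
    r <- cpp_vesselness_scale(as.vector(vol$values), d, s,
                              params$alpha, params$beta, cval)
    best <- pmax(best, array(r$response, d))
  }
  volume3d(best, vol$spacing, vol$origin)
}

#' Resample a volume to isotropic spacing
#'
#' Continuous volumes are trilinearly interpolated, label volumes use
#' nearest-neighbour so mask values stay binary. The output grid is
#' co-centered with the input so the world extent is preserved to within one
#' voxel.
#'
#' @param vol A `volume3d`.
#' @param target_mm Target isotropic spacing in mm (default 0.5).
#' @param mode `"continuous"` (trilinear) or `"label"` (nearest-neighbour).
#' @return A `volume3d` with spacing `rep(target_mm, 3)`.
#' @export
resample_isotropic <- function(vol, target_mm = 0.5,
                               mode = c("continuous", "label")) {
  stopifnot(inherits(vol, "volume3d"))
  mode <- match.arg(mode)
  if (target_mm <= 0) stop("`target_mm` must be > 0")
  d <- dim(vol$values)
  out_d <- pmax(1L, as.integer(round(d * vol$spacing / target_mm)))
  out_sp <- rep(target_mm, 3)
  # co-center the grids
  out_origin <- vol$origin +
    ((d - 1) * vol$spacing - (out_d - 1) * out_sp) / 2
  vals <- cpp_resample(as.vector(vol$values), d, vol$spacing, vol$origin,
                       out_d, out_sp, out_origin, mode == "label")
  volume3d(array(vals, out_d), out_sp, out_origin)
}

#' Percentile intensity normalization for CTA
#'
#' Linearly maps the 5th percentile of the masked intensities to 0 and the
#' 95th to 1, clipping to [0, 1]; background (outside the mask) stays 0.
#'
#' @param vol A `volume3d`.
#' @param mask Optional binary `volume3d`; defaults to nonzero voxels.
#' @param probs Length-2 percentile pair (default `c(0.05, 0.95)`).
#' @return A `volume3d` with values in [0, 1].
#' @export
normalize_cta <- function(vol, mask = NULL, probs = c(0.05, 0.95)) {
  stopifnot(inherits(vol, "volume3d"))
  inside <- if (is.null(mask)) vol$values != 0 else mask$values > 0
  v <- vol$values[inside]
  if (length(unique(v)) < 2) {
    warning("constant masked region; normalize_cta returns all zeros")
    return(volume3d(array(0, dim(vol$values)), vol$spacing, vol$origin))
  }
  q <- stats::quantile(v, probs, names = FALSE, type = 7)
  out <- array(0, dim(vol$values))
  out[inside] <- pmin(pmax((vol$values[inside] - q[1]) / (q[2] - q[1]), 0), 1)
  volume3d(out, vol$spacing, vol$origin)
}

#' Z-score intensity normalization
#'
#' Subtracts the mean and divides by the standard deviation of the masked
#' voxels; after the transform the masked region has mean 0 and sd 1.
#'
#' @inheritParams normalize_cta
#' @return A `volume3d`.
#' @export
normalize_zscore <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  inside <- if (is.null(mask)) array(TRUE, dim(vol$values)) else mask$values > 0
  v <- vol$values[inside]
  s <- sqrt(mean((v - mean(v))^2))  # population sd: two points {1,3} -> {-1,1}
  if (!is.finite(s) || s == 0) {
    warning("zero variance; normalize_zscore returns all zeros")
    return(volume3d(array(0, dim(vol$values)), vol$spacing, vol$origin))
  }
  out <- array(0, dim(vol$values))
  out[inside] <- (v - mean(v)) / s
  volume3d(out, vol$spacing, vol$origin)
}

#' Build the network input channel stack for one variant
#'
#' Runs the fixed preprocessing chain: brain mask, (for `Vess`) two
#' vesselness maps at the configured scale ranges on the native grid,
#' isotropic resampling of every channel and the mask to `target_mm`, then
#' percentile normalization of the CTA channel and z-score normalization of
#' the vesselness channels. `Orig` and `LDim` yield one channel, `Vess`
#' yields three (CTA + two vesselness maps).
#'
#' @param vol Raw CTA-like `volume3d`.
#' @param variant One of `"Orig"`, `"Vess"`, `"LDim"`.
#' @param target_mm Isotropic grid spacing after standardization (mm).
#' @param scale_ranges List of two length-2 vectors: vesselness scale ranges
#'   in voxels for the small- and large-scale channels.
#' @param mask_args List of arguments passed to [compute_brain_mask()].
#' @return An object of class `channel_stack`: list with `channels` (list of
#'   `volume3d`), `mask` (binary `volume3d` on the same grid) and
#'   `variant_tag`.
#' @export
build_stack <- function(vol, variant = c("Orig", "Vess", "LDim"),
                        target_mm = 0.5,
                        scale_ranges = list(c(0.5, 5), c(5, 15)),
                        mask_args = list()) {
  variant <- match.arg(variant)
  mask <- do.call(compute_brain_mask, c(list(vol), mask_args))
  masked <- vol
  masked$values <- vol$values * mask$values
  mask_r <- resample_isotropic(mask, target_mm, mode = "label")
  cta_r <- resample_isotropic(masked, target_mm, mode = "continuous")
  cta_n <- normalize_cta(cta_r, mask = mask_r)
  channels <- list(cta_n)
  if (variant == "Vess") {
    for (sr in scale_ranges) {
      vmap <- vesselness(masked, vesselness_params(scale_range = sr))
      vmap_r <- resample_isotropic(vmap, target_mm, mode = "continuous")
      channels[[length(channels) + 1]] <- normalize_zscore(vmap_r,
                                                           mask = mask_r)
    }
  }
  structure(list(channels = channels, mask = mask_r, variant_tag = variant),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> variant %s, %d channel(s), grid %s @ %s mm\n",
              x$variant_tag, length(x$channels),
              paste(dim(x$channels[[1]]$values), collapse = "x"),
              paste(signif(x$channels[[1]]$spacing, 3), collapse = "x")))
  invisible(x)
}
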