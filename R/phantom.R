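#' Specification of a synthetic head-CTA phantom
#'
#' Describes a digital phantom that emulates the gross appearance of a head
#' CTA: bright tubular vessels on darker parenchyma, saccular aneurysm
#' protrusions of controllable volume attached to a vessel wall, a
#' high-intensity skull shell, optional hemorrhage regions of intermediate
#' intensity, anisotropic voxel spacing and additive Gaussian noise.
#' Intensities are arbitrary HU-like values; only their ordering
#' (parenchyma < hemorrhage < vessel ~ aneurysm < skull) matters downstream.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing_mm Numeric length-3, voxel size in mm; each in [0.3, 2].
#' @param vessel_segments List of vessel descriptions, each a list with
#'   `points` (n x 3 matrix of centerline control points, mm), `radius`
#'   (mm, > 0) and optional `intensity`.
#' @param aneurysms List of aneurysm descriptions, each a list with
#'   `attach` (index of the vessel segment to attach to), `t` (position
#'   along that centerline in [0, 1]), `volume_mm3` (target volume, > 0),
#'   `eccentricity` (ratio of the semi-axis along the attachment normal to
#'   the transverse semi-axes; 1 = sphere), optional `side` (+1/-1, which
#'   side of the vessel the sac sits on) and optional `intensity`.
#' @param skull List with `thickness_mm` and `intensity`, or `NULL` for no
#'   skull shell.
#' @param hemorrhage_regions List of lists with `center` (mm), `radius_mm`,
#'   and optional `intensity`.
#' @param intensities Named list of default tissue intensities
#'   (`parenchyma`, `hemorrhage`, `vessel`, `aneurysm`, `skull`).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed controlling the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 32),
                         spacing_mm = c(0.62, 0.62, 1.0),
                         vessel_segments = list(),
                         aneurysms = list(),
                         skull = list(thickness_mm = 2, intensity = 1000),
                         hemorrhage_regions = list(),
                         intensities = list(parenchyma = 40, hemorrhage = 65,
                                            vessel = 250, aneurysm = 250,
                                            skull = 1000),
                         noise_sd = 8,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("`grid_shape` must be 3 integers >= 8")
  if (any(spacing_mm < 0.3) || any(spacing_mm > 2.0))
    stop("`spacing_mm` components must lie in [0.3, 2.0] mm")
  for (vs in vessel_segments) {
    if (is.null(vs$radius) || vs$radius <= 0) stop("vessel radius must be > 0")
    if (!is.matrix(vs$points) || ncol(vs$points) != 3)
      stop("vessel `points` must be an n x 3 matrix (mm)")
  }
  for (an in aneurysms) {
    if (is.null(an$volume_mm3) || an$volume_mm3 <= 0)
      stop("aneurysm target volume must be > 0 mm^3")
  }
  for (hr in hemorrhage_regions) {
    if (is.null(hr$radius_mm) || hr$radius_mm <= 0)
      stop("hemorrhage radius must be > 0")
  }
  ints <- intensities
  if (!is.null(skull) && is.null(skull$intensity)) skull$intensity <- ints$skull
  if (ints$vessel <= ints$parenchyma || ints$aneurysm <= ints$parenchyma)
    stop("vessel/aneurysm intensity must exceed parenchyma intensity")
  if (!is.null(skull) && skull$intensity <= ints$vessel)
    stop("skull intensity must exceed vessel intensity")
  if (length(hemorrhage_regions) &&
      !(ints$hemorrhage > ints$parenchyma && ints$hemorrhage < ints$vessel))
    stop("hemorrhage intensity must lie strictly between parenchyma and vessel")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 vessel_segments = vessel_segments, aneurysms = aneurysms,
                 skull = skull, hemorrhage_regions = hemorrhage_regions,
                 intensities = ints, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Densify a polyline of control points with cubic spline interpolation
# (per-coordinate natural splines over cumulative chord length).
densify_centerline <- function(points, step_mm = 0.4) {
  if (nrow(points) == 1) return(points)
  d <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  if (max(d) == 0) return(points[1, , drop = FALSE])
  tt <- seq(0, max(d), by = step_mm)
  if (tt[length(tt)] < max(d)) tt <- c(tt, max(d))
  out <- sapply(1:3, function(k) {
    if (nrow(points) > 2) stats::spline(d, points[, k], xout = tt)$y
    else stats::approx(d, points[, k], xout = tt)$y
  })
  matrix(out, ncol = 3)
}

# World coordinates of all voxel centers (nvox x 3), column-major order.
voxel_centers <- function(grid_shape, spacing, origin) {
  gx <- origin[1] + (seq_len(grid_shape[1]) - 1) * spacing[1]
  gy <- origin[2] + (seq_len(grid_shape[2]) - 1) * spacing[2]
  gz <- origin[3] + (seq_len(grid_shape[3]) - 1) * spacing[3]
  cbind(rep(gx, times = grid_shape[2] * grid_shape[3]),
        rep(rep(gy, each = grid_shape[1]), times = grid_shape[3]),
        rep(gz, each = grid_shape[1] * grid_shape[2]))
}

# Point on, and unit normal to, a densified centerline at parameter t in [0,1].
centerline_frame <- function(dense, t) {
  i <- 1 + t * (nrow(dense) - 1)
  i0 <- max(1, min(nrow(dense) - 1, floor(i)))
  frac <- i - i0
  p <- dense[i0, ] * (1 - frac) + dense[i0 + 1, ] * frac
  tangent <- dense[min(i0 + 1, nrow(dense)), ] - dense[i0, ]
  tn <- sqrt(sum(tangent^2))
  tangent <- if (tn > 0) tangent / tn else c(1, 0, 0)
  # any unit vector orthogonal to the tangent
  ref <- if (abs(tangent[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  normal <- ref - sum(ref * tangent) * tangent
  normal <- normal / sqrt(sum(normal^2))
  list(point = p, tangent = tangent, normal = normal)
}

# Rasterize an ellipsoid: center, orthonormal axes (columns of R), semi-axes.
ellipsoid_mask <- function(centers, center, axes, semi) {
  d <- sweep(centers, 2, center)
  u <- d %*% axes
  (u[, 1] / semi[1])^2 + (u[, 2] / semi[2])^2 + (u[, 3] / semi[3])^2 <= 1
}

#' Generate a synthetic phantom case
#'
#' Renders the vessels (tubes along cubic-interpolated centerlines), attaches
#' each aneurysm as an ellipsoid tangent to its vessel wall (penetrating the
#' lumen slightly so the two fuse, with the overlap kept well under 20% of the
#' aneurysm volume), adds skull shell and hemorrhage regions, then additive
#' Gaussian noise. Ground-truth aneurysm components exclude the vessel lumen.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_case`: list with `image`,
#'   `aneurysm_mask`, `vessel_mask` (all `volume3d` on a common grid) and
#'   `aneurysm_truth`, a data.frame with `component_id` and `volume_mm3`
#'   (true rasterized volume of each aneurysm component).
#' @examples
#' sp <- phantom_spec(vessel_segments = list(list(
#'   points = rbind(c(2, 15, 15), c(28, 15, 15)), radius = 1.5)))
#' case <- generate_phantom(sp)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- c(0, 0, 0)
  vv <- prod(sp)
  nvox <- prod(gs)
  ints <- spec$intensities
  centers <- voxel_centers(gs, sp, origin)

  vessel <- rep(FALSE, nvox)
  dense_list <- list()
  for (vs in spec$vessel_segments) {
    dense <- densify_centerline(vs$points)
    dense_list[[length(dense_list) + 1]] <- dense
    dmin <- cpp_min_dist_polyline(gs, sp, origin, dense)
    vessel <- vessel | (as.vector(dmin) <= vs$radius)
  }

  aneu <- rep(0L, nvox)  # component labels
  truth <- list()
  for (k in seq_along(spec$aneurysms)) {
    an <- spec$aneurysms[[k]]
    if (an$volume_mm3 < vv)
      stop(sprintf(
        "aneurysm %d target volume %.3f mm^3 is smaller than one voxel (%.3f mm^3)",
        k, an$volume_mm3, vv))
    vi <- if (is.null(an$attach)) 1L else an$attach
    if (vi > length(dense_list)) stop("aneurysm `attach` refers to no vessel")
    fr <- centerline_frame(dense_list[[vi]], if (is.null(an$t)) 0.5 else an$t)
    ecc <- if (is.null(an$eccentricity)) 1 else an$eccentricity
    side <- if (is.null(an$side)) 1 else sign(an$side)
    # semi-axes: a transverse (twice), c = ecc * a along the attachment normal
    a <- (3 * an$volume_mm3 / (4 * pi * ecc))^(1 / 3)
    cc <- ecc * a
    r_v <- spec$vessel_segments[[vi]]$radius
    # center placed so the ellipsoid penetrates the lumen by 20% of c:
    # the spherical-cap overlap is ~3% of the ellipsoid volume.
    center <- fr$point + side * fr$normal * (r_v + 0.8 * cc)
    axes <- cbind(fr$tangent, pracma_cross(fr$normal, fr$tangent), fr$normal)
    inside <- ellipsoid_mask(centers, center, axes, c(a, a, cc))
    comp <- inside & !vessel
    if (any(comp & (aneu > 0L)))
      stop(sprintf("aneurysm %d overlaps a previously defined aneurysm", k))
    if (!any(comp))
      stop(sprintf("aneurysm %d rasterized to zero voxels", k))
    aneu[comp] <- k
    truth[[k]] <- data.frame(component_id = k,
                             volume_mm3 = sum(comp) * vv)
  }

  img <- rep(ints$parenchyma, nvox)
  if (!is.null(spec$skull)) {
    # ellipsoidal shell fitted to the grid extent; rendered before the soft
    # tissue so vessels/aneurysms grazing the shell keep their intensity
    mid <- (gs - 1) * sp / 2
    semi <- pmax(gs * sp * 0.46, 1)
    d <- sweep(centers, 2, mid)
    lev <- sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 +
                  (d[, 3] / semi[3])^2)
    half_t <- spec$skull$thickness_mm / (2 * mean(semi))
    shell <- abs(lev - 1) <= half_t
    img[shell] <- spec$skull$intensity
    img[lev > 1 + half_t] <- 0  # air outside the skull
  }
  for (hr in spec$hemorrhage_regions) {
    hi <- if (is.null(hr$intensity)) ints$hemorrhage else hr$intensity
    d <- sqrt(rowSums(sweep(centers, 2, hr$center)^2))
    img[d <= hr$radius_mm] <- hi
  }
  img[vessel] <- ints$vessel
  img[aneu > 0L] <- ints$aneurysm

  set.seed(spec$seed)
  if (spec$noise_sd > 0) img <- img + stats::rnorm(nvox, 0, spec$noise_sd)

  dim(img) <- gs
  am <- array(as.numeric(aneu > 0L), gs)
  vm <- array(as.numeric(vessel), gs)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(component_id = integer(), volume_mm3 = numeric())
  structure(list(
    image = volume3d(img, sp, origin),
    aneurysm_mask = volume3d(am, sp, origin),
    vessel_mask = volume3d(vm, sp, origin),
    aneurysm_labels = volume3d(array(as.numeric(aneu), gs), sp, origin),
    aneurysm_truth = truth_df,
    spec = spec
  ), class = "phantom_case")
}

# cross product (avoid pulling a geometry package for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> grid %s, %d aneurysm component(s), vessel voxels %d\n",
              paste(dim(x$image$values), collapse = "x"),
              nrow(x$aneurysm_truth), sum(x$vessel_mask$values)))
  invisible(x)
}

#' Generate a cohort of phantom cases
#'
#' Each case derives its own seed deterministically from the master seed.
#' Aneurysm target volumes are drawn uniformly in `volume_range`; with
#' probability `multiplicity_prob` a case carries a second aneurysm attached
#' to the opposite side of the vessel. Attachment positions are jittered
#' along the vessel so cases differ geometrically; a draw that produces an
#' invalid geometry (colliding sacs) is redrawn deterministically.
#'
#' @param n Number of cases (>= 1).
#' @param base_spec A [phantom_spec()] with at least one vessel segment; its
#'   aneurysm list is replaced per case.
#' @param volume_range Length-2 numeric, min/max aneurysm volume in mm^3.
#' @param seed Master integer seed.
#' @param multiplicity_prob Probability that a case has 2 aneurysms.
#' @return List of `phantom_case` objects.
#' @export
make_cohort <- function(n, base_spec, volume_range = c(20, 500), seed = 1L,
                        multiplicity_prob = 0.2) {
  if (n < 1) stop("`n` must be >= 1")
  if (volume_range[1] > volume_range[2])
    stop("volume_range: min exceeds max")
  if (!length(base_spec$vessel_segments))
    stop("base_spec must contain at least one vessel segment")
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max %/% 2, n)
  lapply(seq_len(n), function(i) {
    # draw geometry; on a rejected configuration (e.g. two aneurysms that
    # collide) redraw deterministically from the next derived seed
    for (attempt in 0:9) {
      set.seed(case_seeds[i] + attempt)
      k <- 1L + stats::rbinom(1, 1, multiplicity_prob)
      vols <- stats::runif(k, volume_range[1], volume_range[2])
      tpos <- if (k == 1) stats::runif(1, 0.35, 0.65) else c(
        stats::runif(1, 0.2, 0.35), stats::runif(1, 0.65, 0.8))
      aneus <- lapply(seq_len(k), function(j)
        list(attach = 1L, t = tpos[j], volume_mm3 = vols[j],
             eccentricity = stats::runif(1, 0.8, 1.3),
             side = if (j %% 2 == 0) -1 else 1))
      sp <- base_spec
      sp$aneurysms <- aneus
      sp$seed <- case_seeds[i] + attempt
      case <- tryCatch(generate_phantom(sp), error = function(e) e)
      if (!inherits(case, "error")) return(case)
    }
    stop("could not generate a valid phantom for case ", i, ": ",
         conditionMessage(case))
  })
}

#' Write a phantom case to disk
#'
#' Writes `image.nii.gz`, `aneurysm_mask.nii.gz`, `vessel_mask.nii.gz` and
#' `aneurysm_truth.csv` (component_id, volume_mm3) into `dir`.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$image, file.path(dir, "image.nii.gz"))
  write_volume(case$aneurysm_mask, file.path(dir, "aneurysm_mask.nii.gz"))
  write_volume(case$vessel_mask, file.path(dir, "vessel_mask.nii.gz"))
  utils::write.csv(case$aneurysm_truth,
                   file.path(dir, "aneurysm_truth.csv"), row.names = FALSE)
  invisible(dir)
}
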