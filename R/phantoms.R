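# Synthetic CT phantoms with analytically known surface areas. Voxelization is
# by centre sampling (a voxel is tissue iff its centre lies inside the solid):
# no partial-volume anti-aliasing, so any smoothing effect seen downstream is
# attributable to the measurement pipeline, not the generator.

.THOMSEN_P <- 1.6075

#' Analytic surface area of a phantom shape
#'
#' sphere `4 pi r^2`; cube `6 a^2`; cylinder `2 pi r (r + h)`; ellipsoid via
#' the Thomsen approximation `4 pi ((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p)`,
#' `p = 1.6075` (max error about 1.06%).
#'
#' @param shape one of `"sphere"`, `"cube"`, `"cylinder"`, `"ellipsoid"`.
#' @param dimensions named list/vector: sphere `r`; cube `a`; cylinder `r`,
#'   `h`; ellipsoid `a`, `b`, `c` (semi-axes). All mm.
#' @return Surface area in cm^2.
#' @export
analyticSurface <- function(shape, dimensions) {
  d <- as.list(dimensions)
  mm2 <- switch(shape,
    sphere = 4 * pi * d$r^2,
    cube = 6 * d$a^2,
    cylinder = 2 * pi * d$r * (d$r + d$h),
    ellipsoid = {
      p <- .THOMSEN_P
      4 * pi * (((d$a * d$b)^p + (d$a * d$c)^p + (d$b * d$c)^p) / 3)^(1 / p)
    },
    stop("unknown shape", call. = FALSE))
  mm2 / 100
}

# signed "inside" predicate at physical coordinates (mm), centred on `centre`
.inside_shape <- function(shape, dimensions, X, Y, Z, centre) {
  d <- as.list(dimensions)
  x <- X - centre[1]; y <- Y - centre[2]; z <- Z - centre[3]
  switch(shape,
    sphere = x^2 + y^2 + z^2 <= d$r^2,
    cube = pmax(abs(x), abs(y), abs(z)) <= d$a / 2,
    cylinder = (x^2 + y^2 <= d$r^2) & (abs(z) <= d$h / 2),
    ellipsoid = (x / d$a)^2 + (y / d$b)^2 + (z / d$c)^2 <= 1,
    stop("unknown shape", call. = FALSE))
}

.shape_halfextent <- function(shape, dimensions) {
  d <- as.list(dimensions)
  switch(shape,
    sphere = rep(d$r, 3),
    cube = rep(d$a / 2, 3),
    cylinder = c(d$r, d$r, d$h / 2),
    ellipsoid = c(d$a, d$b, d$c),
    stop("unknown shape", call. = FALSE))
}

#' Generate a synthetic CT phantom with analytic surface truth
#'
#' Builds a [CTVolume-class] containing a geometric solid of `tissue_hu`
#' (default 40 HU, soft tissue) in `air_hu` air (default -1000 HU), sampled at
#' voxel centres on a grid with `margin_mm` of air margin (at least 3 voxels
#' regardless of spacing), optionally
#' with an internal concentric air cavity, a sub-voxel origin offset and
#' seeded Gaussian HU noise. The `body_composite` shape is a body-like
#' assembly (cylindrical torso, embedded sphere head, two cylinder legs joined
#' at the torso's lower cap) whose junctions are planar cuts, so the analytic
#' truth is an exact sum of parts minus circle/spherical-cap corrections.
#'
#' @param shape `"sphere"`, `"cube"`, `"cylinder"`, `"ellipsoid"` or
#'   `"body_composite"`.
#' @param dimensions shape parameters in mm (see [analyticSurface()]); for
#'   `body_composite`: `torso_r`, `torso_h`, `head_r`, `head_embed` (depth of
#'   the head centre above the torso top cap is `head_r - head_embed`; embed
#'   must be in `(0, head_r)`), `leg_r`, `leg_h`.
#' @param spacing_mm voxel size, scalar or `(x, y, z)`, mm (default 1).
#' @param tissue_hu,air_hu HU values (defaults 40, -1000).
#' @param cavity optional list `list(shape=, dimensions=)` of a concentric
#'   internal air inclusion.
#' @param origin_offset_vox length-3 sub-voxel shift of the solid relative to
#'   the grid, in voxel units.
#' @param noise_sd_hu additive Gaussian noise SD (0 = none).
#' @param margin_mm air margin around the solid, mm (default 8; clipped to at
#'   least 3 voxels so downstream morphology never reaches the border).
#' @param seed RNG seed for the noise.
#' @return List: `ct` ([CTVolume-class]), `analytic_surface_cm2`, `spec` (echo).
#' @export
makePhantom <- function(shape, dimensions, spacing_mm = 1, tissue_hu = 40,
                        air_hu = -1000, cavity = NULL,
                        origin_offset_vox = c(0, 0, 0), noise_sd_hu = 0,
                        margin_mm = 8, seed = 1) {
  sp <- rep(as.numeric(spacing_mm), length.out = 3)
  if (any(unlist(dimensions) <= 0)) stop("phantom out of bounds", call. = FALSE)
  if (margin_mm <= 0) stop("phantom out of bounds", call. = FALSE)
  margin_vox <- pmax(3L, as.integer(ceiling(margin_mm / sp)))
  if (shape == "body_composite")
    return(.make_body_composite(dimensions, sp, tissue_hu, air_hu, cavity,
                                origin_offset_vox, noise_sd_hu, margin_vox,
                                margin_mm, seed))
  he <- .shape_halfextent(shape, dimensions)
  dims <- as.integer(ceiling(2 * he / sp) + 2 * margin_vox + 1)
  centre <- ((dims - 1) / 2 + origin_offset_vox) * sp
  cx <- (seq_len(dims[1]) - 1) * sp[1]
  cy <- (seq_len(dims[2]) - 1) * sp[2]
  cz <- (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(cx, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dim = dims)
  inside <- .inside_shape(shape, dimensions, X, Y, Z, centre)
  if (!is.null(cavity))
    inside <- inside & !.inside_shape(cavity$shape, cavity$dimensions,
                                      X, Y, Z, centre)
  vox <- array(ifelse(inside, tissue_hu, air_hu), dim = dims)
  if (noise_sd_hu > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vox <- vox + stats::rnorm(length(vox), 0, noise_sd_hu)
    vox <- pmin(pmax(vox, -1024), 3071)
  }
  list(ct = CTVolume(vox, spacing = sp),
       analytic_surface_cm2 = analyticSurface(shape, dimensions),
       spec = list(shape = shape, dimensions = as.list(dimensions),
                   spacing_mm = sp, tissue_hu = tissue_hu, air_hu = air_hu,
                   cavity = cavity, origin_offset_vox = origin_offset_vox,
                   noise_sd_hu = noise_sd_hu, margin_mm = margin_mm,
                   seed = seed))
}

# body-like composite with exactly computable surface: cylinder torso (axis z),
# sphere head embedded through the top cap, two parallel cylinder legs joined
# at the bottom cap. All junctions are planar circles.
.make_body_composite <- function(dimensions, sp, tissue_hu, air_hu, cavity,
                                 origin_offset_vox, noise_sd_hu, margin_vox,
                                 margin_mm, seed) {
  d <- as.list(dimensions)
  stopifnot(d$head_embed > 0, d$head_embed < d$head_r,
            2 * d$leg_r < d$torso_r,
            d$head_r^2 - (d$head_r - d$head_embed)^2 <= d$torso_r^2)
  # head centre sits (head_r - head_embed) above the top cap
  hc_z <- d$torso_h / 2 + (d$head_r - d$head_embed)
  rho2 <- d$head_r^2 - (d$head_r - d$head_embed)^2  # junction circle radius^2
  leg_dx <- d$torso_r / 2                           # legs at +/- torso_r/2
  he <- c(max(d$torso_r, leg_dx + d$leg_r),
          max(d$torso_r, d$leg_r),
          d$torso_h / 2 + max(d$head_r + (d$head_r - d$head_embed), 0) +
            d$leg_h)  # generous z half-extent
  dims <- as.integer(ceiling(2 * he / sp) + 2 * margin_vox + 1)
  centre <- ((dims - 1) / 2 + origin_offset_vox) * sp
  cx <- (seq_len(dims[1]) - 1) * sp[1]
  cy <- (seq_len(dims[2]) - 1) * sp[2]
  cz <- (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(cx, times = dims[2] * dims[3]), dim = dims) - centre[1]
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dim = dims) - centre[2]
  Z <- array(rep(cz, each = dims[1] * dims[2]), dim = dims) - centre[3]
  torso <- (X^2 + Y^2 <= d$torso_r^2) & (abs(Z) <= d$torso_h / 2)
  head <- X^2 + Y^2 + (Z - hc_z)^2 <= d$head_r^2
  leg1 <- ((X - leg_dx)^2 + Y^2 <= d$leg_r^2) &
    (Z <= -d$torso_h / 2) & (Z >= -d$torso_h / 2 - d$leg_h)
  leg2 <- ((X + leg_dx)^2 + Y^2 <= d$leg_r^2) &
    (Z <= -d$torso_h / 2) & (Z >= -d$torso_h / 2 - d$leg_h)
  inside <- torso | head | leg1 | leg2
  vox <- array(ifelse(inside, tissue_hu, air_hu), dim = dims)
  if (!is.null(cavity)) {
    # internal inclusion (e.g. lung-like air) centred in the torso; recovered
    # by cavity filling downstream, so the analytic outer surface is unchanged
    inc <- .inside_shape(cavity$shape, cavity$dimensions, X, Y, Z, c(0, 0, 0))
    hu_inc <- if (is.null(cavity$hu)) air_hu else cavity$hu
    vox[inc & inside] <- hu_inc
  }
  if (noise_sd_hu > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vox <- vox + stats::rnorm(length(vox), 0, noise_sd_hu)
    vox <- pmin(pmax(vox, -1024), 3071)
  }
  # analytic truth (mm^2):
  #   torso lateral + bottom cap - 2 leg circles + top cap - head junction disc
  #   + head sphere - spherical cap below the junction plane
  #   + legs: lateral + far cap each
  cap_h <- d$head_embed                       # height of the submerged cap
  area <- 2 * pi * d$torso_r * d$torso_h +
    (pi * d$torso_r^2 - 2 * pi * d$leg_r^2) +
    (pi * d$torso_r^2 - pi * rho2) +
    (4 * pi * d$head_r^2 - 2 * pi * d$head_r * cap_h) +
    2 * (2 * pi * d$leg_r * d$leg_h + pi * d$leg_r^2)
  list(ct = CTVolume(vox, spacing = sp),
       analytic_surface_cm2 = area / 100,
       spec = list(shape = "body_composite", dimensions = d, spacing_mm = sp,
                   tissue_hu = tissue_hu, air_hu = air_hu,
                   origin_offset_vox = origin_offset_vox,
                   noise_sd_hu = noise_sd_hu, margin_mm = margin_mm,
                   seed = seed))
}

#' Synthetic test-retest acquisition
#'
#' Produces a rigidly transformed, re-noised copy of a CT volume: rotation
#' about the z axis through the volume centre, sub-voxel translation, trilinear
#' resampling, plus fresh seeded HU noise — a stand-in "retest" scan.
#'
#' @param ct a [CTVolume-class].
#' @param shift_vox length-3 translation in voxel units.
#' @param rotation_deg rotation about z, degrees.
#' @param noise_sd_hu Gaussian HU noise SD added after resampling.
#' @param seed RNG seed.
#' @return A [CTVolume-class] with the same grid.
#' @export
makeTestRetest <- function(ct, shift_vox = c(0, 0, 0), rotation_deg = 0,
                           noise_sd_hu = 0, seed = 1) {
  d <- dim(voxels(ct))
  if (any(abs(shift_vox) >= d / 2)) stop("out of field", call. = FALSE)
  v <- .cpp_resample_rigid(as.vector(voxels(ct)), d, rotation_deg,
                           as.numeric(shift_vox), fill = -1000)
  v <- array(v, dim = d)
  if (noise_sd_hu > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd_hu)
  }
  v <- pmin(pmax(v, -1024), 3071)
  CTVolume(v, spacing = spacing(ct), origin = origin(ct))
}

#' Synthetic subject cohort
#'
#' Heights and weights are drawn from a correlated bivariate normal
#' (Cholesky construction) and truncated by rejection to the stated bounds.
#' Defaults emulate an adult oncology population: H ~ N(1.70, 0.09^2) m on
#' [1.51, 1.92], W ~ N(75, 15^2) kg on [42, 115], correlation 0.6.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param mean_h,sd_h,h_bounds height distribution (m).
#' @param mean_w,sd_w,w_bounds weight distribution (kg).
#' @param correlation height-weight correlation.
#' @return data.frame with columns `id`, `height_m`, `weight_kg`.
#' @export
makeCohort <- function(n, seed = 1, mean_h = 1.70, sd_h = 0.09,
                       h_bounds = c(1.51, 1.92), mean_w = 75, sd_w = 15,
                       w_bounds = c(42, 115), correlation = 0.6) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # truncation attenuates the correlation of the accepted sample (~6% under
  # the default bounds); inflate the latent correlation so the delivered
  # sample correlation matches the requested value
  rho <- min(correlation / 0.94, 0.999)
  H <- numeric(0); W <- numeric(0)
  while (length(H) < n) {
    m <- max(2L * (n - length(H)), 32L)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    h <- mean_h + sd_h * z1
    w <- mean_w + sd_w * z2
    ok <- h >= h_bounds[1] & h <= h_bounds[2] & w >= w_bounds[1] & w <= w_bounds[2]
    H <- c(H, h[ok]); W <- c(W, w[ok])
  }
  data.frame(id = sprintf("S%03d", seq_len(n)), height_m = H[seq_len(n)],
             weight_kg = W[seq_len(n)])
}

#' Write a phantom to NIfTI with a JSON truth sidecar
#'
#' @param phantom result of [makePhantom()].
#' @param path output NIfTI path; the sidecar is `<path>.json`.
#' @return Invisibly, the NIfTI path.
#' @export
writePhantom <- function(phantom, path) {
  img <- .as_nifti(phantom$ct@voxels, spacing(phantom$ct), origin(phantom$ct))
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(
    list(analytic_surface_cm2 = phantom$analytic_surface_cm2,
         spec = phantom$spec),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
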