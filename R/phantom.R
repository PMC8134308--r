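# Synthetic ankle phantoms with exact ground-truth standard-plane frames.
#
# The phantom template is deliberately minimal: two parallel high-intensity
# tubes of unequal radius (tibia / fibula surrogates), a transverse plateau
# slab terminating the larger tube, and a sub-plateau ellipsoid (talus
# surrogate). Its canonical frame is exactly known, so rendering a rotated /
# scaled / mirrored copy gives a volume whose standard-plane frame is the
# correspondingly transformed canonical frame, with no annotation error.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- trilinear / nearest resampling ---------------------------------------

# snap continuous indices that are numerically on the lattice, so identity
# transforms reproduce inputs bit-exactly
snap_index <- function(ci) {
  r <- round(ci)
  ci[abs(ci - r) < 1e-9] <- r[abs(ci - r) < 1e-9]
  ci
}

# sample `values` (3D array on `grid`) at world points (n x 3); outside -> 0
sample_trilinear <- function(values, grid, pts_mm) {
  ci <- snap_index(world_to_voxel(pts_mm, grid))
  s <- grid$shape
  i0 <- floor(ci)
  f <- ci - i0
  out <- numeric(nrow(ci))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (if (cx) f[, 1] else 1 - f[, 1]) *
           (if (cy) f[, 2] else 1 - f[, 2]) *
           (if (cz) f[, 3] else 1 - f[, 3])
    ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
    ok <- wgt > 0 & ix >= 0 & iy >= 0 & iz >= 0 & ix < s[1] & iy < s[2] & iz < s[3]
    if (any(ok)) {
      lin <- ix[ok] + s[1] * (iy[ok] + s[2] * iz[ok]) + 1
      out[ok] <- out[ok] + wgt[ok] * values[lin]
    }
  }
  out
}

# nearest-neighbor sampling for label volumes; outside -> 0
sample_nearest <- function(values, grid, pts_mm) {
  ci <- round(snap_index(world_to_voxel(pts_mm, grid)))
  s <- grid$shape
  out <- numeric(nrow(ci))
  ok <- ci[, 1] >= 0 & ci[, 2] >= 0 & ci[, 3] >= 0 &
        ci[, 1] < s[1] & ci[, 2] < s[2] & ci[, 3] < s[3]
  if (any(ok)) {
    lin <- ci[ok, 1] + s[1] * (ci[ok, 2] + s[2] * ci[ok, 3]) + 1
    out[ok] <- values[lin]
  }
  out
}

# ---- phantom template ------------------------------------------------------

# canonical right-ankle template, frame = identity (n_sag = +x, n_ax = +y,
# n_cor = +z, right-handed), intersection point at the origin = lowest
# central point of the plateau slab; all sizes in mm.
#
# The template needs at least TWO distinct off-axis landmarks at different
# azimuths (here the fibula and a medial-malleolus surrogate): with a single
# one, a mirrored (left) ankle is indistinguishable from a rotated right
# ankle up to the talus aspect ratio, making azimuth and laterality nearly
# unidentifiable from the image. Two landmarks fix the chirality, which no
# rotation can undo.
.template <- list(
  tibia = list(radius = 8, lo = 3, hi = 45, value = 1.0),
  plateau = list(radius = 14, lo = 0, hi = 3, value = 1.0),
  fibula = list(center = c(12, 6), radius = 4, lo = -5, hi = 45, value = 0.85),
  malleolus = list(center = c(-10, -2), radius = 5, lo = -10, hi = 1, value = 0.95),
  talus = list(center = c(0, -10, 0), semi = c(12, 7, 10), value = 0.7)
)

# intensity of the canonical template at canonical coordinates C (n x 3)
template_intensity <- function(C) {
  tp <- .template
  x <- C[, 1]; y <- C[, 2]; z <- C[, 3]
  v <- numeric(nrow(C))
  r2 <- x^2 + z^2
  v <- pmax(v, tp$tibia$value * (r2 <= tp$tibia$radius^2 & y >= tp$tibia$lo & y <= tp$tibia$hi))
  v <- pmax(v, tp$plateau$value * (r2 <= tp$plateau$radius^2 & y >= tp$plateau$lo & y <= tp$plateau$hi))
  rf2 <- (x - tp$fibula$center[1])^2 + (z - tp$fibula$center[2])^2
  v <- pmax(v, tp$fibula$value * (rf2 <= tp$fibula$radius^2 & y >= tp$fibula$lo & y <= tp$fibula$hi))
  rm2 <- (x - tp$malleolus$center[1])^2 + (z - tp$malleolus$center[2])^2
  v <- pmax(v, tp$malleolus$value *
              (rm2 <= tp$malleolus$radius^2 & y >= tp$malleolus$lo & y <= tp$malleolus$hi))
  e <- ((x - tp$talus$center[1]) / tp$talus$semi[1])^2 +
       ((y - tp$talus$center[2]) / tp$talus$semi[2])^2 +
       ((z - tp$talus$center[3]) / tp$talus$semi[3])^2
  pmax(v, tp$talus$value * (e <= 1))
}

canonical_frame <- function(laterality = "right") {
  sx <- if (laterality == "left") -1 else 1
  orthonormalize_frame(cbind(c(sx, 0, 0), c(0, 1, 0), c(0, 0, 1)), c(0, 0, 0))
}

# ---- PhantomSpec / PhantomSample ------------------------------------------

#' Specification for a synthetic ankle phantom
#'
#' Defaults emulate the study conditions: per-axis rotations uniform in
#' +-45 degrees, isotropic scale in \[0.8, 1.2\], additive Gaussian intensity
#' noise, and (for bilateral samples) one left and one right ankle with
#' well-separated, non-overlapping placements. The default desk-scale grid is
#' 64^3 voxels at 1.5 mm (96 mm extent) for one ankle and 96 x 64 x 64 at
#' 1.5 mm for two, so that two intersection points fit with > 60 mm
#' separation and >= 20 mm boundary margin.
#'
#' @param n_ankles 1 (unilateral) or 2 (bilateral).
#' @param grid a [volume_grid()]; if `NULL` a desk-scale default is used.
#' @param rotation_range_deg half-range of the per-axis rotation (default 45).
#' @param scale_range isotropic scale range (default `c(0.8, 1.2)`).
#' @param noise_sd sd of additive Gaussian intensity noise on a template of
#'   unit peak intensity (default 0.05).
#' @param mask_radius_mm,mask_height_mm geometry of the ground-truth plane
#'   cylinder masks (defaults 25 and 2 mm).
#' @param seed integer; all randomness flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_ankles = 1, grid = NULL, rotation_range_deg = 45,
                         scale_range = c(0.8, 1.2), noise_sd = 0.05,
                         mask_radius_mm = 25, mask_height_mm = 2, seed = 1L) {
  if (!n_ankles %in% c(1L, 2L)) stop("n_ankles must be 1 or 2")
  if (is.null(grid)) {
    grid <- if (n_ankles == 1) volume_grid(c(64, 64, 64), rep(1.5, 3))
            else volume_grid(c(96, 64, 64), rep(1.5, 3))
  }
  if (!(length(scale_range) == 2L && scale_range[1] <= scale_range[2] && scale_range[1] > 0))
    stop("scale_range must be a non-decreasing positive pair")
  stopifnot(rotation_range_deg >= 0, noise_sd >= 0)
  structure(list(n_ankles = as.integer(n_ankles), grid = grid,
                 rotation_range_deg = rotation_range_deg,
                 scale_range = scale_range, noise_sd = noise_sd,
                 mask_radius_mm = mask_radius_mm, mask_height_mm = mask_height_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic ankle phantom with exact ground truth
#'
#' Renders one or two ankle templates (see package vignette) into a volume by
#' evaluating the analytically transformed template at every voxel center (no
#' resampling), then adds Gaussian noise. The returned ground-truth frames
#' are the *exactly* transformed canonical frames, and the ground-truth
#' sphere / plane-cylinder masks are rasterized from them. Bilateral samples
#' contain one left and one right ankle in random left-right image order with
#' non-overlapping placements (> 60 mm center separation). Output is
#' bit-reproducible given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: `volume` ([scalar_volume()]),
#'   `frames` (list of [plane_frame()]), `lateralities`, `sphere_masks`,
#'   `plane_masks` (list of [plane_labels()]), `transforms` (per-ankle list
#'   of the exact generator pose: `R`, `scale`, `t`, `laterality`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  extent <- grid$shape * grid$spacing_mm
  margin <- 25
  if (any(extent < 2 * margin + 1))
    stop("grid too small for the required placement margins")
  with_seed(spec$seed, {
    n <- spec$n_ankles
    lats <- if (n == 1) sample(c("left", "right"), 1) else sample(c("left", "right"))
    placements <- vector("list", n)
    for (attempt in 1:50) {
      pts <- vector("list", n)
      ok <- TRUE
      for (i in seq_len(n)) {
        lo <- grid$origin_mm + margin
        hi <- grid$origin_mm + extent - grid$spacing_mm - margin
        if (n == 2) {
          # split the long axis so the two ankles cannot collide
          mid <- grid$origin_mm[1] + extent[1] / 2
          if (i == 1) hi[1] <- min(hi[1], mid - 31) else lo[1] <- max(lo[1], mid + 31)
        }
        if (any(hi < lo)) { ok <- FALSE; break }
        pts[[i]] <- lo + runif(3) * (hi - lo)
      }
      if (ok && n == 2 && sqrt(sum((pts[[1]] - pts[[2]])^2)) <= 60) ok <- FALSE
      if (ok) { placements <- pts; break }
      if (attempt == 50) stop("placement failure: margins cannot be met on this grid")
    }
    W <- grid_coords_mm(grid)
    vol <- numeric(nrow(W))
    frames <- vector("list", n)
    transforms <- vector("list", n)
    for (i in seq_len(n)) {
      ang <- deg2rad(runif(3, -spec$rotation_range_deg, spec$rotation_range_deg))
      sc <- runif(1, spec$scale_range[1], spec$scale_range[2])
      R <- euler_xyz(ang[1], ang[2], ang[3])
      t <- placements[[i]]
      # canonical coords of every voxel: c = (1/s) R^T (w - t), then mirror x
      C <- (sweep(W, 2L, t, "-") %*% R) / sc
      if (lats[i] == "left") C[, 1] <- -C[, 1]
      vol <- pmax(vol, template_intensity(C))
      M <- frame_matrix(canonical_frame(lats[i]))
      frames[[i]] <- orthonormalize_frame(R %*% M, t)
      transforms[[i]] <- list(R = R, scale = sc, t = t, laterality = lats[i])
    }
    if (spec$noise_sd > 0) vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
    volume <- scalar_volume(array(vol, dim = grid$shape), grid)
    sphere_masks <- lapply(frames, function(f) make_sphere_mask(f$intersection_mm, grid, 5))
    plane_masks <- lapply(frames, function(f)
      make_plane_cylinder_masks(f, grid, spec$mask_radius_mm, spec$mask_height_mm))
    structure(list(volume = volume, frames = frames, lateralities = lats,
                   sphere_masks = sphere_masks, plane_masks = plane_masks,
                   transforms = transforms, spec = spec),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d ankle(s) [%s] on a %d x %d x %d grid @ %g mm\n",
              length(x$frames), paste(x$lateralities, collapse = ", "),
              x$volume$grid$shape[1], x$volume$grid$shape[2], x$volume$grid$shape[3],
              x$volume$grid$spacing_mm[1]))
  for (i in seq_along(x$frames))
    cat(sprintf("  ankle %d: intersection (%.1f, %.1f, %.1f) mm\n", i,
                x$frames[[i]]$intersection_mm[1], x$frames[[i]]$intersection_mm[2],
                x$frames[[i]]$intersection_mm[3]))
  invisible(x)
}

# ---- augmentation ----------------------------------------------------------

#' Online augmentation transform for volume + targets (+ frames)
#'
#' Applies one sampled spatial transform — per-axis rotations uniform in
#' `+-rotation_range_deg`, one isotropic scale drawn from `scale_range`, an
#' optional axis mirror (probability 1/2 when `mirror = TRUE`), and a random
#' crop to `crop_size^3` — identically to the image (trilinear interpolation),
#' every label target (nearest-neighbor), and any ground-truth frames
#' (transformed analytically, not by resampling). The transform is centered
#' on the volume's physical center. Pass explicit `angles_deg`, `scale`,
#' `mirror_axis` and `crop_offset` to override sampling (identity parameters
#' return the inputs unchanged).
#'
#' @param volume a [scalar_volume()].
#' @param targets list of integer label arrays sharing the volume's grid.
#' @param frames optional list of [plane_frame()] ground truths.
#' @param seed integer seed for the sampled parameters.
#' @param rotation_range_deg,scale_range,mirror augmentation ranges
#'   (defaults +-45 degrees, \[0.8, 1.2\], mirror enabled).
#' @param crop_size output cube side in voxels (default: full volume, no crop).
#' @param angles_deg,scale,mirror_axis,crop_offset explicit transform
#'   parameters overriding the sampled ones (`mirror_axis` in 0:3, 0 = none;
#'   `crop_offset` 0-based voxel triple).
#' @return list with transformed `volume`, `targets`, `frames`, and the
#'   realized `transform` parameters.
#' @export
augment <- function(volume, targets = list(), frames = list(), seed = 1L,
                    rotation_range_deg = 45, scale_range = c(0.8, 1.2),
                    mirror = TRUE, crop_size = NULL,
                    angles_deg = NULL, scale = NULL, mirror_axis = NULL,
                    crop_offset = NULL) {
  stopifnot(inherits(volume, "scalar_volume"))
  grid <- volume$grid
  if (is.null(crop_size)) crop_size <- min(grid$shape)
  if (any(crop_size > grid$shape)) stop("crop_size exceeds the volume shape")
  with_seed(seed, {
    if (is.null(angles_deg)) angles_deg <- runif(3, -rotation_range_deg, rotation_range_deg)
    if (is.null(scale)) scale <- runif(1, scale_range[1], scale_range[2])
    if (is.null(mirror_axis)) mirror_axis <- if (mirror && runif(1) < 0.5) 1L else 0L
    maxoff <- grid$shape - crop_size
    if (is.null(crop_offset))
      crop_offset <- vapply(maxoff, function(m) if (m > 0) sample.int(m + 1L, 1L) - 1L else 0L,
                            integer(1))
  })
  ang <- deg2rad(angles_deg)
  R <- euler_xyz(ang[1], ang[2], ang[3])
  Mr <- diag(3)
  if (mirror_axis > 0) Mr[mirror_axis, mirror_axis] <- -1
  A <- scale * R %*% Mr                      # forward linear map about the center
  Cc <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm / 2
  out_shape <- rep(as.integer(crop_size), 3L)
  out_grid <- volume_grid(out_shape, grid$spacing_mm,
                          grid$origin_mm + crop_offset * grid$spacing_mm)
  Wout <- grid_coords_mm(out_grid)
  # input sample position: A^-1 (w - C) + C
  Ainv <- Mr %*% t(R) / scale
  Pin <- sweep(sweep(Wout, 2L, Cc, "-") %*% t(Ainv), 2L, Cc, "+")
  vout <- sample_trilinear(volume$values, grid, Pin)
  new_vol <- scalar_volume(array(vout, dim = out_shape), out_grid)
  new_targets <- lapply(targets, function(tg) {
    stopifnot(all(dim(tg) == grid$shape))
    array(as.integer(sample_nearest(tg, grid, Pin)), dim = out_shape)
  })
  new_frames <- lapply(frames, function(f) {
    p <- as.numeric(A %*% (f$intersection_mm - Cc) + Cc)
    orthonormalize_frame(R %*% Mr %*% frame_matrix(f), p)
  })
  list(volume = new_vol, targets = new_targets, frames = new_frames,
       transform = list(angles_deg = angles_deg, scale = scale,
                        mirror_axis = mirror_axis, crop_offset = crop_offset))
}

# ---- preprocessing ---------------------------------------------------------

# intensity normalization to zero mean / unit variance; constant volumes
# come back as all zeros with attr(,"constant") = TRUE and a warning
normalize_intensity <- function(values) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    warning("constant volume: normalization returns zeros")
    out <- array(0, dim = dim(values))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (values - m) / s
}

#' Downsample and intensity-normalize a volume
#'
#' Trilinear downsampling to `target_shape` voxels per axis with the spacing
#' rescaled so the physical extent is preserved (e.g. 512^3 at 0.3 mm becomes
#' 160^3 at 0.96 mm), followed by normalization to zero mean and unit
#' variance over all voxels. A constant input yields a zero volume with a
#' warning and `attr(values, "constant") = TRUE`.
#'
#' @param volume a [scalar_volume()].
#' @param target_shape integer, output voxels per axis (scalar or triple);
#'   `NULL` keeps the grid and only normalizes intensities.
#' @return A [scalar_volume()].
#' @export
preprocess <- function(volume, target_shape = NULL) {
  stopifnot(inherits(volume, "scalar_volume"))
  grid <- volume$grid
  if (is.null(target_shape))
    return(scalar_volume(normalize_intensity(volume$values), grid))
  target_shape <- as.integer(rep(target_shape, length.out = 3L))
  stopifnot(all(target_shape >= 1L))
  new_spacing <- grid$spacing_mm * grid$shape / target_shape
  # cell-aligned: both grids tile the same physical extent
  new_origin <- grid$origin_mm + (new_spacing - grid$spacing_mm) / 2
  out_grid <- volume_grid(target_shape, new_spacing, new_origin)
  vals <- sample_trilinear(volume$values, grid, grid_coords_mm(out_grid))
  scalar_volume(normalize_intensity(array(vals, dim = target_shape)), out_grid)
}
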