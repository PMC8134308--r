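# Stage 2: crop an ROI around each detection, segment the three plane
# cylinders, and recover the standard-plane frame by per-class PCA. The
# smallest-eigenvalue eigenvector of each cylinder's voxel cloud is the plane
# normal; the mean of the three per-class centroids is the intersection point.

#' Crop a cubic region of interest around a detection
#'
#' The crop is centered on the voxel nearest `center_mm`; parts outside the
#' parent volume are zero-padded and recorded in `pad_mask`. The cropped
#' grid's origin is set so that world coordinates of cropped voxels equal
#' those of the corresponding parent voxels exactly.
#'
#' @param volume the parent [scalar_volume()].
#' @param center_mm world center (mm); must lie inside the parent grid.
#' @param size_voxels cube side (>= 16).
#' @return An object of class `roi_crop`: `volume` (the cropped
#'   [scalar_volume()]), `offset_voxels` (0-based, possibly negative),
#'   `parent_grid`, `pad_mask` (TRUE where zero-padded).
#' @export
crop_roi <- function(volume, center_mm, size_voxels) {
  stopifnot(inherits(volume, "scalar_volume"))
  size_voxels <- as.integer(size_voxels)
  if (size_voxels < 16L) stop("size_voxels must be >= 16")
  grid <- volume$grid
  ci <- world_to_voxel(as.numeric(center_mm), grid)
  if (any(ci < -0.5) || any(ci > grid$shape - 0.5))
    stop("crop center lies outside the parent grid")
  cv <- round(ci)
  start <- as.integer(cv - size_voxels %/% 2)        # 0-based, may be negative
  vals <- array(0, dim = rep(size_voxels, 3L))
  pad <- array(TRUE, dim = rep(size_voxels, 3L))
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + size_voxels - 1L, grid$shape - 1L)
  if (all(src_hi >= src_lo)) {
    dst <- lapply(1:3, function(a) (src_lo[a]:src_hi[a]) - start[a] + 1L)
    src <- lapply(1:3, function(a) (src_lo[a]:src_hi[a]) + 1L)
    vals[dst[[1]], dst[[2]], dst[[3]]] <- volume$values[src[[1]], src[[2]], src[[3]]]
    pad[dst[[1]], dst[[2]], dst[[3]]] <- FALSE
  }
  g <- volume_grid(rep(size_voxels, 3L), grid$spacing_mm,
                   grid$origin_mm + start * grid$spacing_mm)
  structure(list(volume = scalar_volume(vals, g), offset_voxels = start,
                 parent_grid = grid, pad_mask = pad),
            class = "roi_crop")
}

#' Plane parameters of one cylinder class by PCA
#'
#' Principal component analysis of the world-mm coordinates of the foreground
#' voxels (eigendecomposition of the covariance of centered coordinates). For
#' a flat cylinder the two largest eigenvalues span the disc and the
#' eigenvector of the smallest eigenvalue is the plane normal; the centroid
#' is the unweighted mean of the foreground coordinates. The normal's sign is
#' fixed by flipping it to a non-negative dot product with `reference_dir`
#' when given. A warning is raised when `(lambda2 - lambda3) / lambda1 <
#' 0.05` (near-degenerate mask, normal unreliable).
#'
#' @param class_mask binary/logical 3D array.
#' @param grid its [volume_grid()].
#' @param reference_dir optional direction for sign disambiguation.
#' @param min_voxels minimum foreground count (default 50).
#' @return list with `normal` (unit triple), `centroid_mm`, `eigenvalues`
#'   (descending triple), `n_voxels`, `degenerate` (logical).
#' @export
derive_plane_params <- function(class_mask, grid, reference_dir = NULL,
                                min_voxels = 50L) {
  stopifnot(inherits(grid, "volume_grid"), all(dim(class_mask) == grid$shape))
  sel <- which(class_mask != 0)
  if (length(sel) < min_voxels)
    stop(sprintf("too few foreground voxels for PCA: %d < %d", length(sel), min_voxels))
  X <- grid_coords_mm(grid)[sel, , drop = FALSE]
  centroid <- colMeans(X)
  Xc <- sweep(X, 2L, centroid, "-")
  S <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(S, symmetric = TRUE)           # eigenvalues descending
  normal <- eg$vectors[, 3]
  if (!is.null(reference_dir) && sum(normal * reference_dir) < 0) normal <- -normal
  degenerate <- (eg$values[2] - eg$values[3]) / eg$values[1] < 0.05
  if (degenerate)
    warning("eigenvalue degeneracy: lambda2 close to lambda3, plane normal unreliable")
  list(normal = unit(normal), centroid_mm = centroid, eigenvalues = eg$values,
       n_voxels = length(sel), degenerate = degenerate)
}

#' Recover a standard-plane frame from a plane label volume
#'
#' Runs [derive_plane_params()] on each of the three cylinder classes, takes
#' the intersection point as the unweighted mean of the three per-class
#' centroids (robust to unequal class sizes after the intersection-omission
#' rule; set `intersection = "pooled"` for the pooled-voxel mean instead),
#' disambiguates normal signs against `reference` (a [plane_frame()], or the
#' canonical world axes when absent), and orthonormalizes the three raw
#' normals into a frame.
#'
#' @param labels a [plane_labels()] volume.
#' @param reference optional [plane_frame()] for sign disambiguation.
#' @param min_voxels per-class minimum foreground count.
#' @param intersection `"centroid_mean"` (default) or `"pooled"`.
#' @return An object of class `plane_estimate`: `frame`,
#'   `per_class_voxel_counts`, `eigenvalue_triples`, `degenerate_classes`.
#' @export
estimate_frame <- function(labels, reference = NULL, min_voxels = 50L,
                           intersection = c("centroid_mean", "pooled")) {
  stopifnot(inherits(labels, "plane_labels"))
  intersection <- match.arg(intersection)
  cls_names <- c("sagittal", "axial", "coronal")
  missing <- which(vapply(1:3, function(k) sum(labels$labels == k), 0) == 0)
  if (length(missing) > 0)
    stop(sprintf("missing plane class(es): %s", paste(cls_names[missing], collapse = ", ")))
  ref_dirs <- if (is.null(reference)) diag(3) else frame_matrix(reference)
  pars <- lapply(1:3, function(k)
    derive_plane_params(labels$labels == k, labels$grid,
                        reference_dir = ref_dirs[, k], min_voxels = min_voxels))
  p <- if (intersection == "centroid_mean") {
    rowMeans(vapply(pars, `[[`, numeric(3), "centroid_mm"))
  } else {
    sel <- which(labels$labels > 0)
    colMeans(grid_coords_mm(labels$grid)[sel, , drop = FALSE])
  }
  N <- vapply(pars, `[[`, numeric(3), "normal")
  frame <- orthonormalize_frame(N, p)
  structure(list(frame = frame,
                 per_class_voxel_counts = vapply(pars, `[[`, 0, "n_voxels"),
                 eigenvalue_triples = lapply(pars, `[[`, "eigenvalues"),
                 degenerate_classes = vapply(pars, `[[`, FALSE, "degenerate")),
            class = "plane_estimate")
}

#' @export
print.plane_estimate <- function(x, ...) {
  cat("<plane_estimate>\n")
  print(x$frame)
  cat(sprintf("  class voxels: sag %d, ax %d, cor %d%s\n",
              x$per_class_voxel_counts[1], x$per_class_voxel_counts[2],
              x$per_class_voxel_counts[3],
              if (any(x$degenerate_classes)) "  [degenerate eigenstructure]" else ""))
  invisible(x)
}

# Orient the signs of an estimated frame against the anatomy in the volume:
# n_ax is flipped toward the tibial shaft (higher intensity along the ray
# from the intersection point), then the (n_sag, n_cor) sign combination is
# chosen so the fibula surrogate sits at positive sagittal and coronal
# offsets. Sign conventions fixed this way make handedness equal laterality.
orient_frame_to_anatomy <- function(frame, volume) {
  p <- frame$intersection_mm
  ray_score <- function(dirn, ts) {
    pts <- cbind(p[1] + ts * dirn[1], p[2] + ts * dirn[2], p[3] + ts * dirn[3])
    mean(sample_trilinear(volume$values, volume$grid, pts))
  }
  ts <- seq(6, 20, by = 2)
  n_ax <- if (ray_score(frame$n_ax, ts) >= ray_score(-frame$n_ax, ts))
    frame$n_ax else -frame$n_ax
  # expected fibula offsets in frame coordinates (template: +12 sag, +6 cor,
  # parallel to the shaft), bracketing the 0.8-1.2 scale range
  as_ <- c(10, 12, 14); bs <- c(5, 6, 7); hs <- seq(2, 18, by = 4)
  gridpts <- expand.grid(a = as_, b = bs, h = hs)
  combo_score <- function(u, v) {
    pts <- t(p + outer(u, gridpts$a) + outer(v, gridpts$b) + outer(n_ax, gridpts$h))
    mean(sample_trilinear(volume$values, volume$grid, pts))
  }
  best <- NULL; best_score <- -Inf
  for (su in c(1, -1)) for (sv in c(1, -1)) {
    sc <- combo_score(su * frame$n_sag, sv * frame$n_cor)
    if (sc > best_score) { best_score <- sc; best <- c(su, sv) }
  }
  plane_frame(p, best[1] * frame$n_sag, n_ax, best[2] * frame$n_cor)
}

#' Stage-2 driver: segment an ROI and recover its frame
#'
#' Applies `segmenter` to the (intensity-normalized) ROI volume and passes
#' the predicted label volume to [estimate_frame()]. Because the ROI grid
#' carries exact world coordinates, the returned frame is already expressed
#' in parent-volume world coordinates.
#'
#' @param roi a [crop_roi()] result.
#' @param segmenter function mapping a [scalar_volume()] to a
#'   [plane_labels()] on the same grid (a trained net via
#'   [unet_plane_segmenter()], or an oracle from [oracle_plane_segmenter()]).
#' @param reference optional [plane_frame()] for sign disambiguation; when
#'   absent the signs are oriented against the anatomy itself (axial normal
#'   toward the shaft, fibula at positive sagittal/coronal offsets), which
#'   makes the recovered handedness equal the anatomical laterality.
#' @param min_voxels per-class minimum foreground count.
#' @param normalize intensity-normalize the ROI before segmentation
#'   (default TRUE, matching the training-time preprocessing).
#' @return A `plane_estimate`.
#' @export
estimate_planes <- function(roi, segmenter, reference = NULL, min_voxels = 50L,
                            normalize = TRUE) {
  stopifnot(inherits(roi, "roi_crop"))
  vol <- roi$volume
  if (normalize)
    vol <- scalar_volume(suppressWarnings(normalize_intensity(vol$values)), vol$grid)
  labels <- segmenter(vol)
  stopifnot(inherits(labels, "plane_labels"))
  est <- estimate_frame(labels, reference = reference, min_voxels = min_voxels)
  if (is.null(reference)) est$frame <- orient_frame_to_anatomy(est$frame, vol)
  est
}

#' Oracle plane segmenter from ground-truth frames
#'
#' Test double standing in for the trained plane segmenter: rasterizes the
#' ground-truth cylinder masks of the sample ankle nearest to the ROI being
#' segmented, with optional seeded label noise ([flip_mask_labels()]).
#'
#' @param sample a [generate_phantom()] result.
#' @param noise_rate fraction of labeled voxels flipped (default 0).
#' @param seed noise seed.
#' @param radius_mm,height_mm cylinder geometry (defaults from the sample
#'   spec).
#' @return A segmenter function for [estimate_planes()].
#' @export
oracle_plane_segmenter <- function(sample, noise_rate = 0, seed = 1L,
                                   radius_mm = NULL, height_mm = NULL) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (is.null(radius_mm)) radius_mm <- sample$spec$mask_radius_mm
  if (is.null(height_mm)) height_mm <- sample$spec$mask_height_mm
  function(vol) {
    ctr <- vol$grid$origin_mm + (vol$grid$shape - 1) * vol$grid$spacing_mm / 2
    d <- vapply(sample$frames, function(f) sum((f$intersection_mm - ctr)^2), 0)
    frame <- sample$frames[[which.min(d)]]
    pl <- make_plane_cylinder_masks(frame, vol$grid, radius_mm, height_mm)
    if (noise_rate > 0)
      pl <- plane_labels(flip_mask_labels(pl$labels, noise_rate, seed), vol$grid)
    pl
  }
}
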