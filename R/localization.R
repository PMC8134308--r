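# Stage 1: tibia-plateau localization. Overlapping patches are pushed through
# a sphere-landmark segmenter, per-voxel predictions are mean-fused, and the
# fused probabilities weight a k-means clustering whose centers are the
# detected plateau landmarks.

#' Extract overlapping cubic patches on a stride lattice
#'
#' Offsets per axis are `0, stride, 2*stride, ...` with a final offset
#' clamped so the last patch ends exactly at the volume boundary; every voxel
#' is therefore covered at least once and no patch is padded. Each patch
#' carries a grid whose origin is the world position of its first voxel, so a
#' predictor can relate patch content to world coordinates.
#'
#' @param volume a [scalar_volume()].
#' @param patch_size cube side in voxels; must not exceed any grid dimension.
#' @param stride stride in voxels (>= 1).
#' @return List of patches, each a list with `volume` (a [scalar_volume()] of
#'   shape `patch_size^3`) and `offset` (0-based voxel triple into the parent).
#' @export
extract_patches <- function(volume, patch_size, stride) {
  stopifnot(inherits(volume, "scalar_volume"), stride >= 1)
  s <- volume$grid$shape
  patch_size <- as.integer(patch_size)
  if (any(patch_size > s)) stop("patch_size exceeds the volume shape")
  axis_offsets <- function(n) {
    last <- n - patch_size
    off <- seq(0L, last, by = as.integer(stride))
    if (off[length(off)] != last) off <- c(off, last)
    off
  }
  ox <- axis_offsets(s[1]); oy <- axis_offsets(s[2]); oz <- axis_offsets(s[3])
  out <- vector("list", length(ox) * length(oy) * length(oz))
  i <- 0L
  for (z in oz) for (y in oy) for (x in ox) {
    i <- i + 1L
    vals <- volume$values[x + seq_len(patch_size), y + seq_len(patch_size),
                          z + seq_len(patch_size), drop = FALSE]
    g <- volume_grid(rep(patch_size, 3L), volume$grid$spacing_mm,
                     volume$grid$origin_mm + c(x, y, z) * volume$grid$spacing_mm)
    out[[i]] <- list(volume = scalar_volume(vals, g), offset = c(x, y, z))
  }
  out
}

#' Per-voxel probability map
#'
#' @param values 3D array with entries in \[0, 1\].
#' @param grid a [volume_grid()].
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"), all(dim(values) == grid$shape))
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop("probability values must lie in [0, 1]")
  structure(list(values = values, grid = grid), class = "prob_map")
}

#' Fuse overlapping patch predictions by per-voxel mean
#'
#' Every output voxel value is the arithmetic mean of all patch predictions
#' covering it. Accumulation uses compensated (Kahan) summation so the fused
#' map is exactly independent of patch order.
#'
#' @param patch_preds list of elements `list(values = 3D array in [0,1],
#'   offset = 0-based voxel triple)`.
#' @param out_grid the parent [volume_grid()]; every voxel must be covered by
#'   at least one patch.
#' @return A [prob_map()].
#' @export
fuse_predictions <- function(patch_preds, out_grid) {
  stopifnot(inherits(out_grid, "volume_grid"))
  s <- out_grid$shape
  acc <- array(0, dim = s)
  comp <- array(0, dim = s)
  cnt <- array(0L, dim = s)
  for (p in patch_preds) {
    d <- dim(p$values)
    off <- as.integer(p$offset)
    if (any(off < 0L) || any(off + d > s)) stop("patch does not fit in the output grid")
    ix <- off[1] + seq_len(d[1]); iy <- off[2] + seq_len(d[2]); iz <- off[3] + seq_len(d[3])
    # Kahan update on the covered block
    y <- p$values - comp[ix, iy, iz]
    t <- acc[ix, iy, iz] + y
    comp[ix, iy, iz] <- (t - acc[ix, iy, iz]) - y
    acc[ix, iy, iz] <- t
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  if (any(cnt == 0L)) stop("uncovered voxel(s): patches must cover the full grid")
  prob_map(acc / cnt, out_grid)
}

#' Weighted k-means on the supra-threshold voxels of a probability map
#'
#' Clusters the world-mm coordinates of all voxels whose fused probability
#' exceeds `weight_floor`, using the probabilities as weights: assignment by
#' nearest center (Euclidean, ties to the lower center index), update
#' `center = sum(w x) / sum(w)` over assigned voxels. Initialization is
#' deterministic farthest-point seeding from the weight-maximum voxel, so
#' results are reproducible; for `k = 1` the result is the closed-form
#' weighted centroid.
#'
#' @param map a [prob_map()].
#' @param k number of clusters (1 or 2 = number of ankles).
#' @param weight_floor voxels with probability <= this are excluded
#'   (default 0.05).
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with attribute `converged = FALSE`.
#' @return List of detections, each
#'   `list(center_mm, total_weight, member_voxel_count)`, sorted by
#'   descending `total_weight` then by x-coordinate.
#' @export
weighted_kmeans <- function(map, k, weight_floor = 0.05, max_iter = 100L) {
  stopifnot(inherits(map, "prob_map"), k %in% c(1L, 2L))
  sel <- which(map$values > weight_floor)
  if (length(sel) < k)
    stop(sprintf("insufficient foreground: %d voxel(s) above the weight floor, need >= %d",
                 length(sel), k))
  W <- grid_coords_mm(map$grid)[sel, , drop = FALSE]
  w <- as.numeric(map$values[sel])
  # farthest-point seeding from the weight maximum (ties: lowest index)
  centers <- matrix(0, k, 3)
  centers[1, ] <- W[which.max(w), ]
  if (k == 2L) {
    d1 <- rowSums(sweep(W, 2L, centers[1, ], "-")^2)
    centers[2, ] <- W[which.max(d1), ]
  }
  assign_nearest <- function(centers) {
    D <- vapply(seq_len(nrow(centers)),
                function(j) rowSums(sweep(W, 2L, centers[j, ], "-")^2),
                numeric(nrow(W)))
    max.col(-D, ties.method = "first")
  }
  converged <- FALSE
  asg <- assign_nearest(centers)
  for (it in seq_len(max_iter)) {
    new_centers <- centers
    for (j in seq_len(k)) {
      m <- asg == j
      if (any(m)) new_centers[j, ] <- colSums(W[m, , drop = FALSE] * w[m]) / sum(w[m])
    }
    new_asg <- assign_nearest(new_centers)
    done <- max(abs(new_centers - centers)) < 1e-12 && all(new_asg == asg)
    centers <- new_centers
    asg <- new_asg
    if (done) { converged <- TRUE; break }
  }
  det <- lapply(seq_len(k), function(j) {
    m <- asg == j
    list(center_mm = centers[j, ], total_weight = sum(w[m]),
         member_voxel_count = sum(m))
  })
  ord <- order(-vapply(det, `[[`, numeric(1), "total_weight"),
               vapply(det, function(d) d$center_mm[1], numeric(1)))
  out <- det[ord]
  attr(out, "converged") <- converged
  if (!converged) warning("weighted k-means did not converge; returning last iterate")
  out
}

#' Localize the tibia plateau(s) in a volume
#'
#' The full stage-1 chain: [extract_patches()] -> `predictor` per patch ->
#' [fuse_predictions()] -> [weighted_kmeans()] with `k = n_ankles`. If the
#' two returned centers are closer than `merge_mm` (default 40 mm) they are
#' treated as duplicate detections of one ankle, merged by total weight, and
#' a single detection is returned with a warning.
#'
#' @param volume a [scalar_volume()] (already preprocessed as desired).
#' @param predictor function mapping a patch [scalar_volume()] to a 3D array
#'   of foreground probabilities of the same shape (a trained localizer via
#'   [unet_predictor()], or an oracle from [oracle_sphere_predictor()]).
#' @param n_ankles 1 or 2.
#' @param patch_size,stride sliding-window geometry (defaults 64 and 32).
#' @param weight_floor passed to [weighted_kmeans()].
#' @param merge_mm duplicate-merge distance for `n_ankles = 2`.
#' @return List of detections as in [weighted_kmeans()].
#' @export
localize <- function(volume, predictor, n_ankles, patch_size = 64, stride = 32,
                     weight_floor = 0.05, merge_mm = 40) {
  patches <- extract_patches(volume, patch_size, stride)
  preds <- lapply(patches, function(p)
    list(values = predictor(p$volume), offset = p$offset))
  fused <- fuse_predictions(preds, volume$grid)
  det <- weighted_kmeans(fused, k = as.integer(n_ankles), weight_floor = weight_floor)
  if (n_ankles == 2L) {
    dmm <- sqrt(sum((det[[1]]$center_mm - det[[2]]$center_mm)^2))
    if (dmm < merge_mm) {
      wsum <- det[[1]]$total_weight + det[[2]]$total_weight
      merged <- list(center_mm = (det[[1]]$center_mm * det[[1]]$total_weight +
                                  det[[2]]$center_mm * det[[2]]$total_weight) / wsum,
                     total_weight = wsum,
                     member_voxel_count = det[[1]]$member_voxel_count +
                                          det[[2]]$member_voxel_count)
      warning(sprintf("duplicate detections %.1f mm apart merged; only one ankle found", dmm))
      det <- list(merged)
    }
  }
  det
}

#' Oracle patch predictor from ground-truth sphere masks
#'
#' Test double standing in for a trained localizer: returns, for any patch,
#' the ground-truth sphere-mask voxels (union over the sample's ankles) as
#' probabilities, with optional seeded label noise (see [flip_mask_labels()]).
#'
#' @param sample a [generate_phantom()] result.
#' @param noise_rate fraction of mask voxels flipped (default 0).
#' @param seed noise seed.
#' @return A predictor function for [localize()].
#' @export
oracle_sphere_predictor <- function(sample, noise_rate = 0, seed = 1L) {
  stopifnot(inherits(sample, "phantom_sample"))
  mask <- Reduce(function(a, b) pmax(a, b), sample$sphere_masks)
  if (noise_rate > 0) mask <- flip_mask_labels(mask, noise_rate, seed)
  parent <- sample$volume$grid
  function(patch) {
    off <- round(world_to_voxel(patch$grid$origin_mm, parent))
    d <- patch$grid$shape
    array(as.numeric(mask[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
                          off[3] + seq_len(d[3])]), dim = d)
  }
}
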