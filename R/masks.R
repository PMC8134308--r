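# Artificial segmentation targets: the 5 mm sphere landmark and the
# three-cylinder plane "cross" with intersection regions omitted.

#' Rasterize a sphere landmark mask
#'
#' The tibia-plateau landmark is represented as a solid sphere (default
#' radius 5 mm) around the plane intersection point, large enough to survive
#' image interpolation. A voxel is foreground iff the distance from its
#' center to `center_mm` is `<= radius_mm` (inclusive boundary, so surface
#' ties are deterministic). Centers outside the grid yield the clipped, and
#' possibly empty, intersection without error.
#'
#' @param center_mm world center of the sphere (mm).
#' @param grid a [volume_grid()].
#' @param radius_mm sphere radius in mm (default 5).
#' @return Integer 3D array on `grid` with 1 = foreground, 0 = background.
#' @export
make_sphere_mask <- function(center_mm, grid, radius_mm = 5) {
  stopifnot(inherits(grid, "volume_grid"), radius_mm > 0)
  center_mm <- as.numeric(center_mm)
  s <- grid$shape
  dx2 <- (grid$origin_mm[1] + (seq_len(s[1]) - 1) * grid$spacing_mm[1] - center_mm[1])^2
  dy2 <- (grid$origin_mm[2] + (seq_len(s[2]) - 1) * grid$spacing_mm[2] - center_mm[2])^2
  dz2 <- (grid$origin_mm[3] + (seq_len(s[3]) - 1) * grid$spacing_mm[3] - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(as.integer(d2 <= radius_mm^2), dim = s)
}

#' Four-class plane label volume
#'
#' Container for the artificial plane segmentation target: labels 0 =
#' background, 1 = sagittal, 2 = axial, 3 = coronal cylinder. The classes are
#' mutually exclusive by construction; any voxel inside two or more cylinders
#' has been demoted to background (the omission rule).
#'
#' @param labels integer 3D array with values in 0:3.
#' @param grid a [volume_grid()].
#' @return An object of class `plane_labels`.
#' @export
plane_labels <- function(labels, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(labels) || !all(dim(labels) == grid$shape))
    stop("labels must be a 3D array matching grid$shape")
  if (!all(labels %in% 0:3)) stop("labels must take values in 0:3")
  structure(list(labels = labels, grid = grid), class = "plane_labels")
}

#' @export
print.plane_labels <- function(x, ...) {
  cnt <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<plane_labels> %d x %d x %d; voxels: bg %d, sag %d, ax %d, cor %d\n",
              dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
              cnt[1], cnt[2], cnt[3], cnt[4]))
  invisible(x)
}

#' Rasterize the three-cylinder standard-plane mask
#'
#' Each standard plane is thickened to a flat cylinder (disc of radius
#' `radius_mm`, height `height_mm`) centered on the frame's intersection
#' point, so that the plane survives downsampling. Voxel `v` belongs to
#' cylinder `k` iff `|(w - p) . n_k| <= height_mm/2` and the in-plane radial
#' distance `|| (w - p) - ((w - p) . n_k) n_k || <= radius_mm` (both
#' boundaries inclusive), with `w` the voxel center and `p` the intersection
#' point. Because the three cylinders are mutually orthogonal they intersect
#' in a cross; every voxel inside two or more cylinders is demoted to
#' background so the label classes never overlap.
#'
#' @param frame a [plane_frame()] (orthonormal by construction).
#' @param grid a [volume_grid()].
#' @param radius_mm cylinder radius in mm (default 25; 20/25/30 are typical).
#' @param height_mm cylinder height in mm (default 2; 2/3 are typical).
#' @return A [plane_labels()] object.
#' @export
make_plane_cylinder_masks <- function(frame, grid, radius_mm = 25, height_mm = 2) {
  stopifnot(inherits(frame, "plane_frame"), inherits(grid, "volume_grid"))
  if (!(radius_mm > 0 && height_mm > 0 && radius_mm > height_mm / 2))
    stop("need radius_mm > height_mm / 2 > 0")
  W <- grid_coords_mm(grid)
  d <- sweep(W, 2L, frame$intersection_mm, "-")
  dd <- rowSums(d^2)
  N <- frame_matrix(frame)
  inside <- matrix(FALSE, nrow(d), 3L)
  for (k in 1:3) {
    t_k <- d %*% N[, k, drop = FALSE]
    r2 <- pmax(dd - t_k^2, 0)
    inside[, k] <- abs(t_k) <= height_mm / 2 & r2 <= radius_mm^2
  }
  nmember <- rowSums(inside)
  lab <- integer(nrow(d))
  one <- nmember == 1L
  lab[one] <- max.col(inside[one, , drop = FALSE], ties.method = "first")
  plane_labels(array(lab, dim = grid$shape), grid)
}
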