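#' @useDynLib contraplane, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median sd
NULL

# ---- VolumeGrid ------------------------------------------------------------

#' Geometry of a 3D scalar lattice
#'
#' A `volume_grid` fixes the coordinate convention used throughout the
#' package: voxel indices are 0-based integer triples in axis order (x, y, z)
#' matching the on-disk NIfTI array order, the world coordinate of a voxel is
#' the position of its *center* in millimetres, and
#' `world = origin_mm + index * spacing_mm` elementwise.
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param spacing_mm positive real triple, voxel size in mm.
#' @param origin_mm real triple, world position (mm) of the center of voxel
#'   (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be an integer triple with all entries >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a positive real triple")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be a finite real triple")
  structure(list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param index numeric vector of length 3 (one voxel) or an n x 3 matrix of
#'   0-based voxel indices. Out-of-bounds indices are allowed (padding math).
#' @param grid a [volume_grid()].
#' @return World coordinates in mm, same shape as `index`.
#' @export
voxel_to_world <- function(index, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.matrix(index)) {
    sweep(sweep(index, 2L, grid$spacing_mm, "*"), 2L, grid$origin_mm, "+")
  } else {
    grid$origin_mm + as.numeric(index) * grid$spacing_mm
  }
}

#' Convert world coordinates to continuous voxel indices
#'
#' Exact inverse of [voxel_to_world()]; the result is a continuous (fractional)
#' 0-based index. Rounding to the nearest lattice voxel is a separate step the
#' caller performs explicitly where needed.
#'
#' @param point_mm numeric triple or n x 3 matrix of world points (mm).
#' @inheritParams voxel_to_world
#' @return Continuous voxel indices, same shape as `point_mm`.
#' @export
world_to_voxel <- function(point_mm, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.matrix(point_mm)) {
    sweep(sweep(point_mm, 2L, grid$origin_mm, "-"), 2L, grid$spacing_mm, "/")
  } else {
    (as.numeric(point_mm) - grid$origin_mm) / grid$spacing_mm
  }
}

# world coordinates of every voxel center, as an n x 3 matrix in array order
grid_coords_mm <- function(grid) {
  s <- grid$shape
  ix <- rep.int(seq_len(s[1]) - 1L, s[2] * s[3])
  iy <- rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3])
  iz <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  cbind(grid$origin_mm[1] + ix * grid$spacing_mm[1],
        grid$origin_mm[2] + iy * grid$spacing_mm[2],
        grid$origin_mm[3] + iz * grid$spacing_mm[3])
}

# ---- ScalarVolume ----------------------------------------------------------

#' A scalar image volume on a grid
#'
#' @param values 3D numeric array; its dim must equal `grid$shape`.
#' @param grid a [volume_grid()].
#' @return An object of class `scalar_volume` with elements `values`, `grid`.
#' @export
scalar_volume <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(dim(values) == grid$shape))
    stop("dim(values) must equal grid$shape")
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<scalar_volume> %d x %d x %d, spacing (%g, %g, %g) mm, intensity [%.3g, %.3g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$grid$spacing_mm[1], x$grid$spacing_mm[2], x$grid$spacing_mm[3],
              rng[1], rng[2]))
  invisible(x)
}

# ---- StandardPlaneFrame ----------------------------------------------------

#' Standard-plane frame: intersection point plus three orthonormal normals
#'
#' The ankle standard planes are pairwise orthogonal, so the three plane
#' normals plus the common intersection point (middle of the lowermost tibial
#' plafond) form a complete pose. `handedness` is the sign of
#' `det([n_sag n_ax n_cor])`: `+1` right, `-1` left; it flips under mirroring
#' and encodes anatomical laterality under the package's sign convention
#' (`n_ax` points from the plafond toward the proximal tibia).
#'
#' @param intersection_mm world position (mm) of the plane intersection point.
#' @param n_sag,n_ax,n_cor unit plane normals (sagittal, axial, coronal).
#' @return An object of class `plane_frame`.
#' @export
plane_frame <- function(intersection_mm, n_sag, n_ax, n_cor) {
  p <- as.numeric(intersection_mm)
  N <- cbind(as.numeric(n_sag), as.numeric(n_ax), as.numeric(n_cor))
  if (length(p) != 3L || any(!is.finite(p)) || any(!is.finite(N)))
    stop("frame components must be finite real triples")
  lens <- sqrt(colSums(N^2))
  if (any(abs(lens - 1) > 1e-9))
    stop("plane normals must be unit vectors (within 1e-9)")
  dots <- c(abs(sum(N[, 1] * N[, 2])), abs(sum(N[, 1] * N[, 3])), abs(sum(N[, 2] * N[, 3])))
  if (any(dots >= 1e-6))
    stop("plane normals must be pairwise orthogonal (|dot| < 1e-6); use orthonormalize_frame()")
  d <- det(N)
  if (abs(abs(d) - 1) > 1e-6) stop("frame determinant must be +-1")
  structure(list(intersection_mm = p,
                 n_sag = N[, 1], n_ax = N[, 2], n_cor = N[, 3],
                 handedness = if (d > 0) "right" else "left"),
            class = "plane_frame")
}

frame_matrix <- function(frame) cbind(frame$n_sag, frame$n_ax, frame$n_cor)

#' @export
print.plane_frame <- function(x, ...) {
  cat(sprintf("<plane_frame> %s-handed, intersection (%.3f, %.3f, %.3f) mm\n",
              x$handedness, x$intersection_mm[1], x$intersection_mm[2], x$intersection_mm[3]))
  cat(sprintf("  n_sag (%.4f, %.4f, %.4f)\n", x$n_sag[1], x$n_sag[2], x$n_sag[3]))
  cat(sprintf("  n_ax  (%.4f, %.4f, %.4f)\n", x$n_ax[1], x$n_ax[2], x$n_ax[3]))
  cat(sprintf("  n_cor (%.4f, %.4f, %.4f)\n", x$n_cor[1], x$n_cor[2], x$n_cor[3]))
  invisible(x)
}

#' Orthonormalize three raw plane normals into a frame
#'
#' Plane normals derived independently (one PCA per cylinder class) are
#' generically *not* exactly orthogonal. This routine replaces the raw 3x3
#' normal matrix `N` by its nearest orthogonal matrix in the Frobenius sense
#' (the orthogonal polar factor `U V'` of the SVD `N = U D V'`), which treats
#' the three planes symmetrically instead of privileging one as Gram-Schmidt
#' would. Each output column keeps the direction of its input (non-negative
#' dot product); handedness is read off the determinant.
#'
#' @param raw_normals 3x3 matrix whose columns are the raw sagittal, axial and
#'   coronal normals (need not be unit length). Pairwise angles must be within
#'   30 degrees of orthogonal.
#' @param intersection_mm world intersection point (mm) carried into the frame.
#' @return A [plane_frame()].
#' @export
orthonormalize_frame <- function(raw_normals, intersection_mm) {
  N <- as.matrix(raw_normals)
  stopifnot(all(dim(N) == c(3L, 3L)))
  lens <- sqrt(colSums(N^2))
  if (any(lens == 0) || any(!is.finite(N))) stop("raw normals must be nonzero and finite")
  Nu <- sweep(N, 2L, lens, "/")
  for (i in 1:2) for (j in (i + 1):3) {
    cosij <- abs(sum(Nu[, i] * Nu[, j]))
    if (cosij > cos(60 * pi / 180))
      stop(sprintf("degenerate input: raw normals %d and %d are within 30 degrees of parallel", i, j))
  }
  sv <- svd(Nu)
  Q <- sv$u %*% t(sv$v)
  # polar factor of a near-orthogonal matrix keeps each column direction
  if (any(colSums(Q * Nu) < 0))
    stop("orthonormalization flipped a column direction; input too far from orthogonal")
  # renormalize columns against accumulated round-off
  Q <- sweep(Q, 2L, sqrt(colSums(Q^2)), "/")
  plane_frame(intersection_mm, Q[, 1], Q[, 2], Q[, 3])
}

# ---- JSON serialization ----------------------------------------------------

#' Write / read a plane frame as JSON
#'
#' The on-disk record is
#' `{"intersection_mm":[x,y,z],"n_sag":[...],"n_ax":[...],"n_cor":[...],
#' "handedness":"left|right"}` with 9 significant digits.
#'
#' @param frame a [plane_frame()] (or for `frames_to_json` a list of them).
#' @param path file path.
#' @return `read_frame_json` returns a `plane_frame`; writers return the path
#'   invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(frame_to_list(frame), path, auto_unbox = TRUE, digits = 9)
  invisible(path)
}

frame_to_list <- function(frame) {
  stopifnot(inherits(frame, "plane_frame"))
  list(intersection_mm = signif(frame$intersection_mm, 9),
       n_sag = signif(frame$n_sag, 9), n_ax = signif(frame$n_ax, 9),
       n_cor = signif(frame$n_cor, 9), handedness = frame$handedness)
}

frame_from_list <- function(x) {
  N <- cbind(as.numeric(x$n_sag), as.numeric(x$n_ax), as.numeric(x$n_cor))
  # rounding to 9 significant digits can nudge columns off exact unit length
  orthonormalize_frame(N, as.numeric(x$intersection_mm))
}

#' @rdname write_frame_json
#' @export
read_frame_json <- function(path) {
  frame_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read / write a scalar volume as NIfTI-1
#'
#' Spacing and origin are taken from (written to) the header affine. Only
#' axis-aligned, positively oriented affines (diagonal 3x3 part with positive
#' entries) are supported; oblique or flipped affines are rejected with a
#' clear error rather than silently reinterpreted.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param volume a [scalar_volume()]; for `write_label_nifti` an integer label
#'   array on `grid` written as uint8.
#' @param grid a [volume_grid()] (label writer only).
#' @param labels integer 3D array (label writer only).
#' @return `read_volume_nifti` returns a `scalar_volume`; writers return the
#'   path invisibly.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  A <- aff[1:3, 1:3]
  offdiag <- A - diag(diag(A))
  if (max(abs(offdiag)) > 1e-4 * max(abs(A)))
    stop("oblique NIfTI affine: only axis-aligned volumes are supported")
  if (any(diag(A) <= 0))
    stop("flipped NIfTI affine: only positively oriented axis-aligned volumes are supported")
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  scalar_volume(vals, volume_grid(dim(vals), diag(A), aff[1:3, 4]))
}

nifti_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$spacing_mm)
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`sform<-`(img, structure(nifti_affine(volume$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume_nifti
#' @export
write_label_nifti <- function(labels, grid, path) {
  stopifnot(is.array(labels), all(dim(labels) == grid$shape))
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)))
  img <- RNifti::`sform<-`(img, structure(nifti_affine(grid), code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# ---- shared small helpers --------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# rotation matrices about world axes; euler_xyz applies x then y then z
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
euler_xyz <- function(ax, ay, az) rot_z(az) %*% rot_y(ay) %*% rot_x(ax)

# transform a frame rigidly: p -> R p + t, normals -> R n
transform_frame <- function(frame, R, t = c(0, 0, 0)) {
  N <- R %*% frame_matrix(frame)
  orthonormalize_frame(N, as.numeric(R %*% frame$intersection_mm + t))
}
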