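# Stage 3: mirror the two per-ankle frames to a common laterality and
# extract comparable MPR slices at the three clinical viewing levels
# (talar dome -6 mm, plateau 0 mm, incisura +10 mm along the axial normal).

#' Mirror a frame through a world coordinate plane
#'
#' Reflects the intersection point and all three normals through the world
#' plane `axis = 0`. Handedness (and hence laterality) flips; applying the
#' same mirror twice restores the original frame exactly.
#'
#' @param frame a [plane_frame()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return The mirrored [plane_frame()].
#' @export
mirror_frame <- function(frame, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  p <- frame$intersection_mm; p[a] <- -p[a]
  # sign flips preserve orthonormality exactly, so the frame is rebuilt
  # directly and the double mirror is an exact involution
  N <- frame_matrix(frame); N[a, ] <- -N[a, ]
  plane_frame(p, N[, 1], N[, 2], N[, 3])
}

# reflect a frame through its own sagittal plane (through its intersection
# point): used to flip one side's laterality in place for side-by-side
# comparison; n_sag negates, the other normals and the point are unchanged
mirror_frame_local <- function(frame) {
  plane_frame(frame$intersection_mm, -frame$n_sag, frame$n_ax, frame$n_cor)
}

#' Resample an oblique 2D slice from a volume
#'
#' Samples the plane through `intersection + offset_mm * n_plane` spanned by
#' the frame's other two axes (axial plane: spanned by `n_sag`, `n_cor`;
#' sagittal: by `n_cor`, `n_ax`; coronal: by `n_sag`, `n_ax`), with trilinear
#' interpolation and zero outside the volume. In-plane pixel (i, j) maps to
#' `center + (i - c) * pixel_mm * u + (j - c) * pixel_mm * v`, so axis
#' orientation is fixed by the frame's axis order and signs.
#'
#' @param volume a [scalar_volume()].
#' @param frame a [plane_frame()].
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param offset_mm signed offset along the plane normal (mm).
#' @param extent_mm slice side length (default 60 mm).
#' @param pixel_mm in-plane sampling step (default 0.5 mm).
#' @return A 2D numeric matrix with attributes `pixel_mm` and `center_mm`.
#' @export
resample_slice <- function(volume, frame, plane = c("axial", "sagittal", "coronal"),
                           offset_mm = 0, extent_mm = 60, pixel_mm = 0.5) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(frame, "plane_frame"),
            pixel_mm > 0, extent_mm > 0)
  plane <- match.arg(plane)
  ax <- switch(plane,
               axial = list(n = frame$n_ax, u = frame$n_sag, v = frame$n_cor),
               sagittal = list(n = frame$n_sag, u = frame$n_cor, v = frame$n_ax),
               coronal = list(n = frame$n_cor, u = frame$n_sag, v = frame$n_ax))
  center <- frame$intersection_mm + offset_mm * ax$n
  npx <- as.integer(round(extent_mm / pixel_mm)) + 1L
  coord <- (seq_len(npx) - (npx + 1) / 2) * pixel_mm
  iu <- rep(coord, times = npx)
  iv <- rep(coord, each = npx)
  pts <- cbind(center[1] + iu * ax$u[1] + iv * ax$v[1],
               center[2] + iu * ax$u[2] + iv * ax$v[2],
               center[3] + iu * ax$u[3] + iv * ax$v[3])
  slice <- matrix(sample_trilinear(volume$values, volume$grid, pts), npx, npx)
  attr(slice, "pixel_mm") <- pixel_mm
  attr(slice, "center_mm") <- center
  slice
}

#' Laterality of a frame
#'
#' Under the package's sign conventions (axial normal toward the proximal
#' tibia, sagittal/coronal normals completing the declared frame) the
#' anatomical laterality equals the frame's handedness, so classification is
#' deterministic.
#'
#' @param frame a [plane_frame()].
#' @return `"left"` or `"right"`.
#' @export
classify_laterality <- function(frame) {
  stopifnot(inherits(frame, "plane_frame"))
  frame$handedness
}

#' Side-by-side axial comparison view at a clinical level
#'
#' Takes the two per-ankle frames of a bilateral volume and resamples the
#' axial slice of each ankle at the level's offset along its *own* axial
#' normal (`lower` = -6 mm / talar dome, `plateau` = 0, `upper` = +10 mm /
#' incisura) plus a common signed `correction_mm`. Because the frame sign
#' conventions are anchored to the anatomy (fibula at positive sagittal and
#' coronal offsets on both sides), the left frame is itself the mirror image
#' of a right frame, and sampling each ankle in its own frame renders both
#' sides in the same anatomical orientation — the mirroring to a common
#' laterality is carried by the frames. `display_side = "left"` flips the
#' in-plane sagittal axis of both slices to the left-ankle convention. Both
#' slices share pixel size and extent and can be compared pixel by pixel.
#'
#' @param volume the bilateral [scalar_volume()].
#' @param frames list of exactly two [plane_frame()]s with opposite
#'   lateralities.
#' @param level `"plateau"`, `"lower"` or `"upper"`.
#' @param correction_mm common axial-position correction applied to both
#'   sides (default 0).
#' @param display_side orientation both slices are rendered in
#'   (default `"right"`).
#' @param extent_mm,pixel_mm slice geometry (defaults 60 mm at 0.5 mm).
#' @param level_offsets_mm named offsets for the three levels.
#' @return An object of class `comparison_view` with `left_slice`,
#'   `right_slice` (by anatomical laterality), `level`, `offset_mm`,
#'   `correction_mm`.
#' @export
build_comparison <- function(volume, frames, level = c("plateau", "lower", "upper"),
                             correction_mm = 0, display_side = c("right", "left"),
                             extent_mm = 60, pixel_mm = 0.5,
                             level_offsets_mm = c(lower = -6, plateau = 0, upper = 10)) {
  level <- match.arg(level)
  display_side <- match.arg(display_side)
  if (length(frames) != 2L) stop("build_comparison needs exactly two frames")
  lats <- vapply(frames, classify_laterality, "")
  if (lats[1] == lats[2])
    stop(sprintf("same-laterality error: both frames classified as %s", lats[1]))
  offset <- unname(level_offsets_mm[level]) + correction_mm
  slice_of <- function(frame) {
    # left-display convention: mirror the in-plane sagittal axis of both
    # sides (an in-frame reflection through the ankle's own sagittal plane)
    f <- if (display_side == "left") mirror_frame_local(frame) else frame
    resample_slice(volume, f, "axial", offset_mm = offset,
                   extent_mm = extent_mm, pixel_mm = pixel_mm)
  }
  slices <- lapply(frames, slice_of)
  names(slices) <- lats
  structure(list(left_slice = slices[["left"]], right_slice = slices[["right"]],
                 level = level, offset_mm = offset, correction_mm = correction_mm,
                 display_side = display_side, pixel_mm = pixel_mm,
                 extent_mm = extent_mm),
            class = "comparison_view")
}

#' @export
print.comparison_view <- function(x, ...) {
  cat(sprintf("<comparison_view> level %s (offset %+.1f mm), %s-side display, %d x %d px @ %g mm\n",
              x$level, x$offset_mm, x$display_side,
              nrow(x$left_slice), ncol(x$left_slice), x$pixel_mm))
  invisible(x)
}

#' @export
plot.comparison_view <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(x$left_slice, x$right_slice)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  for (side in c("left", "right")) {
    sl <- x[[paste0(side, "_slice")]]
    graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl, zlim = rng,
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    xlab = "", ylab = "", main = paste(side, "-", x$level), ...)
  }
  invisible(x)
}
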