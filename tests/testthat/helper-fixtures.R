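# Shared fixtures, all built in code.

# uniformly random right-handed orthonormal frame at p
rand_frame <- function(p = c(0, 0, 0)) {
  A <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(A))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  orthonormalize_frame(q, p)
}

# random rotation matrix
rand_rotation <- function() {
  A <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(A))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

identity_frame <- function(p = c(0, 0, 0))
  orthonormalize_frame(diag(3), p)

# brute-force sphere membership count: explicit per-voxel scalar loop,
# independent of the vectorized implementation
brute_sphere_count <- function(center, grid, radius) {
  s <- grid$shape
  cnt <- 0L
  for (k in seq_len(s[3])) for (j in seq_len(s[2])) for (i in seq_len(s[1])) {
    w <- grid$origin_mm + c(i - 1, j - 1, k - 1) * grid$spacing_mm
    if (sqrt(sum((w - center)^2)) <= radius) cnt <- cnt + 1L
  }
  cnt
}

# brute-force cylinder-cross labeling: per-voxel scalar evaluation of the
# membership predicate with the omission rule; returns per-label counts
brute_cylinder_counts <- function(frame, grid, radius, height) {
  s <- grid$shape
  N <- cbind(frame$n_sag, frame$n_ax, frame$n_cor)
  cnt <- integer(4)
  for (k in seq_len(s[3])) for (j in seq_len(s[2])) for (i in seq_len(s[1])) {
    w <- grid$origin_mm + c(i - 1, j - 1, k - 1) * grid$spacing_mm
    d <- w - frame$intersection_mm
    member <- logical(3)
    for (c in 1:3) {
      t_c <- sum(d * N[, c])
      r_c <- sqrt(max(sum(d^2) - t_c^2, 0))
      member[c] <- abs(t_c) <= height / 2 && r_c <= radius
    }
    lab <- if (sum(member) == 1L) which(member) else 0L
    cnt[lab + 1L] <- cnt[lab + 1L] + 1L
  }
  cnt
}

# small phantom grids used throughout the tests
desk_grid32 <- function() volume_grid(c(32, 32, 32), rep(3, 3))

angle_deg <- function(a, b) {
  d <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, d)) * 180 / pi
}
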