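# Sliding-window patching, mean fusion and weighted k-means.

test_that("patch offsets tile the volume with boundary clamping", {
  g <- function(n) scalar_volume(array(0, dim = rep(n, 3)), volume_grid(rep(n, 3)))
  p64 <- extract_patches(g(64), 64, 32)
  expect_length(p64, 1L)
  expect_equal(p64[[1]]$offset, c(0, 0, 0))
  p96 <- extract_patches(g(96), 64, 32)
  expect_length(p96, 8L)
  offs <- unique(sapply(p96, function(p) p$offset[1]))
  expect_setequal(offs, c(0, 32))
  p100 <- extract_patches(g(100), 64, 32)
  expect_length(p100, 27L)
  offs <- sort(unique(sapply(p100, function(p) p$offset[1])))
  expect_equal(offs, c(0, 32, 36))
  # brute-force coverage check: every voxel covered at least once
  cov <- array(0L, dim = rep(100, 3))
  for (p in p100) {
    ix <- lapply(p$offset, function(o) o + 1:64)
    cov[ix[[1]], ix[[2]], ix[[3]]] <- cov[ix[[1]], ix[[2]], ix[[3]]] + 1L
  }
  expect_true(all(cov >= 1L))
  expect_error(extract_patches(g(32), 64, 32), "exceeds")
})

test_that("fusion averages overlapping patches and matches a brute-force oracle", {
  og <- volume_grid(c(96, 64, 64))
  two <- list(list(values = array(0.2, dim = c(64, 64, 64)), offset = c(0, 0, 0)),
              list(values = array(0.6, dim = c(64, 64, 64)), offset = c(32, 0, 0)))
  fused <- fuse_predictions(two, og)$values
  expect_true(all(abs(fused[33:64, , ] - 0.4) < 1e-15))
  expect_true(all(abs(fused[1:32, , ] - 0.2) < 1e-15))
  expect_true(all(abs(fused[65:96, , ] - 0.6) < 1e-15))

  set.seed(33)
  og2 <- volume_grid(c(40, 40, 40))
  preds <- lapply(1:50, function(i) {
    off <- sapply(1:3, function(a) sample(0:24, 1))
    list(values = array(runif(16^3), dim = rep(16, 3)), offset = off)
  })
  # ensure full coverage with a coarse tiling
  for (x in c(0, 16, 24)) for (y in c(0, 16, 24)) for (z in c(0, 16, 24))
    preds[[length(preds) + 1]] <- list(values = array(0.5, dim = rep(16, 3)),
                                       offset = c(x, y, z))
  fused <- fuse_predictions(preds, og2)
  acc <- array(0, dim = c(40, 40, 40)); cnt <- array(0L, dim = c(40, 40, 40))
  for (p in preds) {
    ix <- lapply(p$offset, function(o) o + 1:16)
    acc[ix[[1]], ix[[2]], ix[[3]]] <- acc[ix[[1]], ix[[2]], ix[[3]]] + p$values
    cnt[ix[[1]], ix[[2]], ix[[3]]] <- cnt[ix[[1]], ix[[2]], ix[[3]]] + 1L
  }
  expect_lt(max(abs(fused$values - acc / cnt)), 1e-12)
  # permutation invariance is exact thanks to compensated summation
  fused2 <- fuse_predictions(rev(preds), og2)
  expect_identical(fused$values, fused2$values)
  expect_error(fuse_predictions(preds[1:3], og2), "uncovered")
})

test_that("weighted k-means with k = 1 is the closed-form weighted centroid", {
  set.seed(14)
  g <- volume_grid(c(20, 20, 20), rep(2, 3))
  vals <- array(runif(8000), dim = g$shape)
  m <- prob_map(vals, g)
  det <- weighted_kmeans(m, k = 1, weight_floor = 0.3)
  sel <- which(vals > 0.3)
  W <- contraplane:::grid_coords_mm(g)[sel, ]
  w <- vals[sel]
  expect_equal(det[[1]]$center_mm, colSums(W * w) / sum(w), tolerance = 1e-12)
  # uniform weight scaling leaves the center unchanged
  det2 <- weighted_kmeans(prob_map(vals * 0.5, g), k = 1, weight_floor = 0.15)
  sel2 <- which(vals * 0.5 > 0.15)
  expect_identical(sel2, sel)
  expect_equal(det2[[1]]$center_mm, det[[1]]$center_mm, tolerance = 1e-12)
})

test_that("two separated blobs are recovered as their per-blob centroids", {
  g <- volume_grid(c(60, 30, 30), rep(2, 3))
  W <- contraplane:::grid_coords_mm(g)
  c1 <- c(20, 30, 30); c2 <- c(100, 30, 30)   # 80 mm apart
  vals <- array(exp(-rowSums(sweep(W, 2, c1, "-")^2) / 50) +
                exp(-rowSums(sweep(W, 2, c2, "-")^2) / 50), dim = g$shape)
  m <- prob_map(pmin(vals, 1), g)
  det <- weighted_kmeans(m, k = 2, weight_floor = 0.05)
  # brute force: the only stable 2-partition separates the blobs at x = 60
  sel <- which(m$values > 0.05)
  Ws <- contraplane:::grid_coords_mm(g)[sel, ]; w <- m$values[sel]
  left <- Ws[, 1] < 60
  cents <- rbind(colSums(Ws[left, ] * w[left]) / sum(w[left]),
                 colSums(Ws[!left, ] * w[!left]) / sum(w[!left]))
  got <- do.call(rbind, lapply(det, `[[`, "center_mm"))
  got <- got[order(got[, 1]), ]
  expect_lt(max(abs(got - cents[order(cents[, 1]), ])), 1e-6)
})

test_that("duplicate detections on a single blob are merged by localize", {
  s <- generate_phantom(phantom_spec(1, seed = 9))
  pred <- oracle_sphere_predictor(s)
  expect_warning(
    det <- localize(s$volume, pred, n_ankles = 2, patch_size = 32, stride = 16),
    "merged")
  expect_length(det, 1L)
  expect_lt(sqrt(sum((det[[1]]$center_mm - s$frames[[1]]$intersection_mm)^2)), 3)
})

test_that("oracle localization finds unilateral and bilateral ankles", {
  s1 <- generate_phantom(phantom_spec(1, seed = 17))
  det <- localize(s1$volume, oracle_sphere_predictor(s1), n_ankles = 1,
                  patch_size = 32, stride = 16)
  err <- sqrt(sum((det[[1]]$center_mm - s1$frames[[1]]$intersection_mm)^2))
  expect_lt(err, 1.5)   # within one voxel (1.5 mm)

  s2 <- generate_phantom(phantom_spec(2, seed = 18))
  det2 <- localize(s2$volume, oracle_sphere_predictor(s2), n_ankles = 2,
                   patch_size = 32, stride = 16)
  expect_length(det2, 2L)
  for (d in det2) {
    errs <- sapply(s2$frames, function(f) sqrt(sum((d$center_mm - f$intersection_mm)^2)))
    expect_lt(min(errs), 3)   # within two voxels of its matched truth
  }
  expect_error(
    localize(s1$volume, function(p) array(0, dim = p$grid$shape), n_ankles = 1,
             patch_size = 32, stride = 16),
    "insufficient foreground")
})
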