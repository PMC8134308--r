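# A small, configurable 3D encoder-decoder segmentation network in the
# original U-Net spirit: two (conv 3x3x3 -> instance norm -> ReLU) blocks per
# resolution level, 2x max-pool down, trilinear up with skip concatenation,
# and a 1x1x1 output convolution. Convolutions are im2col gathers (C++) plus
# BLAS matrix products; everything else is plain R, so training is fully
# deterministic given a seed.

#' Segmenter network configuration
#'
#' @param in_shape input cube side in voxels; must be divisible by
#'   `2^depth`.
#' @param n_out output channels: 2 for the sphere localizer, 4 for the plane
#'   segmenter (background + three cylinder classes).
#' @param base_channels encoder width at the top level (default 8,
#'   desk-scale).
#' @param depth number of resolution levels (default 3).
#' @param seed weight-initialization seed.
#' @return list of class `segmenter_config`.
#' @export
segmenter_config <- function(in_shape = 32, n_out = 4, base_channels = 8,
                             depth = 3, seed = 1L) {
  stopifnot(in_shape %% (2^depth) == 0, n_out >= 2, base_channels >= 1, depth >= 2)
  structure(list(in_shape = as.integer(in_shape), n_out = as.integer(n_out),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "segmenter_config")
}

#' Training configuration
#'
#' Defaults follow the study recipe at desk scale: Adam with initial
#' learning rate 3e-4, cross-entropy + soft-Dice loss weighted 1:1, online
#' augmentation (per-axis rotation +-45 degrees, isotropic scale 0.8-1.2,
#' mirroring, random crop), batch size 4 volumes (plane segmenter) or 16
#' patches (localizer), 20 epochs.
#'
#' @param lr Adam learning rate.
#' @param batch_size samples per optimization step.
#' @param epochs training epochs.
#' @param loss_weights `c(ce, dice)` weighting of the two loss terms.
#' @param augment logical, apply online augmentation.
#' @param rotation_range_deg,scale_range augmentation ranges.
#' @param seed training seed (shuffling, augmentation, patch sampling).
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 3e-4, batch_size = 4, epochs = 20,
                         loss_weights = c(ce = 1, dice = 1), augment = TRUE,
                         rotation_range_deg = 45, scale_range = c(0.8, 1.2),
                         seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_weights = loss_weights,
                 augment = isTRUE(augment), rotation_range_deg = rotation_range_deg,
                 scale_range = scale_range, seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter initialization ---------------------------------------------

he_init <- function(k, cin, cout) {
  array(rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), dim = c(k * cin, cout))
}

unet_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)

# weights: named list; each conv layer holds W (27*cin x cout as a matrix,
# or cin x cout for the 1x1x1 output), b, and instance-norm gain g / bias be
unet_init <- function(cfg) {
  ch <- unet_channels(cfg)
  with_seed(cfg$seed, {
    w <- list()
    conv <- function(cin, cout) list(W = he_init(27, cin, cout), b = numeric(cout),
                                     g = rep(1, cout), be = numeric(cout))
    cin <- 1L
    for (l in seq_len(cfg$depth)) {
      w[[sprintf("enc%da", l)]] <- conv(cin, ch[l])
      w[[sprintf("enc%db", l)]] <- conv(ch[l], ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(cfg$depth - 1L))) {
      w[[sprintf("dec%da", l)]] <- conv(ch[l + 1] + ch[l], ch[l])
      w[[sprintf("dec%db", l)]] <- conv(ch[l], ch[l])
    }
    w[["out"]] <- list(W = he_init(1, ch[1], cfg$n_out), b = numeric(cfg$n_out))
    w
  })
}

# ---- layers ----------------------------------------------------------------

NORM_EPS <- 1e-5

# column-wise scale / shift without sweep()'s aperm overhead
col_scale <- function(m, v) m * rep(v, each = nrow(m))
col_shift <- function(m, v) m + rep(v, each = nrow(m))

conv_block_fw <- function(x, lay) {
  dims <- dim(x)
  n <- prod(dims[1:3])
  Xcol <- cp_im2col(x, as.integer(dims))
  z <- col_shift(Xcol %*% lay$W, lay$b)
  mu <- colMeans(z)
  zc <- col_shift(z, -mu)
  istd <- 1 / sqrt(colMeans(zc^2) + NORM_EPS)
  xhat <- col_scale(zc, istd)
  y <- col_shift(col_scale(xhat, lay$g), lay$be)
  y[y < 0] <- 0
  list(y = array(y, dim = c(dims[1:3], ncol(lay$W))),
       cache = list(Xcol = Xcol, xhat = xhat, istd = istd, relu = y > 0,
                    dims = dims))
}

conv_block_bw <- function(dy, lay, cache) {
  n <- nrow(cache$xhat)
  dy <- matrix(dy, nrow = n)
  dy[!cache$relu] <- 0
  dg <- colSums(dy * cache$xhat)
  dbe <- colSums(dy)
  dxh <- col_scale(dy, lay$g)
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xhat)
  dz <- col_scale(col_shift(dxh, -m1) - col_scale(cache$xhat, m2), cache$istd)
  dW <- crossprod(cache$Xcol, dz)
  db <- colSums(dz)
  dXcol <- dz %*% t(lay$W)
  dx <- cp_col2im(dXcol, as.integer(cache$dims))
  list(dx = dx, grads = list(W = dW, b = db, g = dg, be = dbe))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# forward pass; returns logits (D,H,W,n_out) and caches for backward
unet_fw <- function(weights, cfg, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- list()
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) {
      mp <- cp_maxpool_fw(x, as.integer(dim(x)))
      caches[[sprintf("pool%d", l)]] <- list(idx = mp$idx, dims = dim(x))
      x <- mp$y
    }
    fa <- conv_block_fw(x, weights[[sprintf("enc%da", l)]])
    caches[[sprintf("enc%da", l)]] <- fa$cache
    fb <- conv_block_fw(fa$y, weights[[sprintf("enc%db", l)]])
    caches[[sprintf("enc%db", l)]] <- fb$cache
    x <- fb$y
    if (l < cfg$depth) skips[[l]] <- x
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    up <- cp_upsample_fw(x, as.integer(dim(x)))
    caches[[sprintf("updims%d", l)]] <- dim(x)
    x <- cat_channels(skips[[l]], up)
    fa <- conv_block_fw(x, weights[[sprintf("dec%da", l)]])
    caches[[sprintf("dec%da", l)]] <- fa$cache
    fb <- conv_block_fw(fa$y, weights[[sprintf("dec%db", l)]])
    caches[[sprintf("dec%db", l)]] <- fb$cache
    x <- fb$y
  }
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4])
  logits <- col_shift(xm %*% weights$out$W, weights$out$b)
  caches[["out"]] <- list(xm = xm, dims = d)
  list(logits = array(logits, dim = c(d[1:3], cfg$n_out)), caches = caches)
}

# Backward pass. Decoder levels are traversed top-down (l = 1 ... depth-1),
# peeling off the skip-branch gradient at each level and pushing the
# upsample-branch gradient one level deeper; the encoder is then walked from
# the bottleneck back up, adding each level's stored skip gradient.
unet_bw <- function(weights, cfg, caches, dlogits) {
  grads <- list()
  oc <- caches[["out"]]
  dl <- matrix(dlogits, nrow(oc$xm))
  grads$out <- list(W = crossprod(oc$xm, dl), b = colSums(dl))
  dd <- array(dl %*% t(weights$out$W), dim = oc$dims)   # grad at d_1
  dskips <- vector("list", cfg$depth - 1L)
  for (l in seq_len(cfg$depth - 1L)) {
    bb <- conv_block_bw(dd, weights[[sprintf("dec%db", l)]], caches[[sprintf("dec%db", l)]])
    grads[[sprintf("dec%db", l)]] <- bb$grads
    ba <- conv_block_bw(bb$dx, weights[[sprintf("dec%da", l)]], caches[[sprintf("dec%da", l)]])
    grads[[sprintf("dec%da", l)]] <- ba$grads
    dcat <- ba$dx
    ch_skip <- ncol(weights[[sprintf("enc%db", l)]]$W)
    dskips[[l]] <- dcat[, , , seq_len(ch_skip), drop = FALSE]
    dup <- dcat[, , , ch_skip + seq_len(dim(dcat)[4] - ch_skip), drop = FALSE]
    dd <- cp_upsample_bw(dup, as.integer(caches[[sprintf("updims%d", l)]]))
  }
  # dd now holds the gradient at the bottleneck output e_depth
  for (l in rev(seq_len(cfg$depth))) {
    dy <- if (l == cfg$depth) dd else dskips[[l]] + dd
    bb <- conv_block_bw(dy, weights[[sprintf("enc%db", l)]], caches[[sprintf("enc%db", l)]])
    grads[[sprintf("enc%db", l)]] <- bb$grads
    ba <- conv_block_bw(bb$dx, weights[[sprintf("enc%da", l)]], caches[[sprintf("enc%da", l)]])
    grads[[sprintf("enc%da", l)]] <- ba$grads
    if (l > 1L) {
      pc <- caches[[sprintf("pool%d", l)]]
      dd <- cp_maxpool_bw(ba$dx, pc$idx, as.integer(pc$dims))
    }
  }
  grads
}

# ---- loss ------------------------------------------------------------------

# numerically stable per-voxel softmax over the channel dimension
softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  mx <- do.call(pmax, as.data.frame(m))
  e <- exp(m - mx)
  array(e / rowSums(e), dim = d)
}

#' Combined cross-entropy and soft-Dice loss
#'
#' `loss = ce_w * CE + dice_w * (1 - mean over foreground classes of soft
#' Dice)`, where per class `c` the soft Dice is
#' `(2 sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)` with `eps = 1e-5`,
#' and CE is the mean over voxels of `-log p` at the target class (clamped).
#' The Dice mean runs over the foreground classes only, which is what lets
#' the combination cope with the extreme foreground/background imbalance of
#' sphere and cylinder targets.
#'
#' @param pred_probs 4D array (D, H, W, K) of per-class probabilities
#'   summing to 1 per voxel.
#' @param target integer 3D array of class labels in `0:(K-1)`.
#' @param loss_weights `c(ce, dice)` term weights (default 1:1).
#' @return Non-negative scalar loss.
#' @export
soft_dice_ce_loss <- function(pred_probs, target, loss_weights = c(ce = 1, dice = 1)) {
  d <- dim(pred_probs)
  if (length(d) != 4L || !all(dim(target) == d[1:3]))
    stop("shape mismatch between pred_probs and target")
  K <- d[4]
  n <- prod(d[1:3])
  P <- matrix(pred_probs, n, K)
  tgt <- as.integer(target)
  if (min(tgt) < 0L || max(tgt) >= K) stop("target labels out of range")
  p_at <- P[cbind(seq_len(n), tgt + 1L)]
  ce <- -mean(log(pmax(p_at, 1e-12)))
  eps <- 1e-5
  dice <- vapply(seq_len(K - 1L), function(c) {
    t_c <- as.numeric(tgt == c)
    (2 * sum(P[, c + 1L] * t_c) + eps) / (sum(P[, c + 1L]) + sum(t_c) + eps)
  }, 0)
  unname(loss_weights[1] * ce + loss_weights[2] * (1 - mean(dice)))
}

# loss + gradient wrt logits, for training
loss_and_grad <- function(logits, target, loss_weights = c(ce = 1, dice = 1)) {
  d <- dim(logits)
  K <- d[4]
  n <- prod(d[1:3])
  probs <- softmax_channels(logits)
  P <- matrix(probs, n, K)
  tgt <- as.integer(target)
  Tm <- matrix(0, n, K)
  Tm[cbind(seq_len(n), tgt + 1L)] <- 1
  ce <- -mean(log(pmax(P[cbind(seq_len(n), tgt + 1L)], 1e-12)))
  eps <- 1e-5
  dice_vals <- numeric(K - 1L)
  dLdp <- matrix(0, n, K)
  for (c in seq_len(K - 1L)) {
    pc <- P[, c + 1L]; tc <- Tm[, c + 1L]
    num <- 2 * sum(pc * tc) + eps
    den <- sum(pc) + sum(tc) + eps
    dice_vals[c] <- num / den
    # d(1 - mean dice)/dp_c
    dLdp[, c + 1L] <- -(2 * tc * den - num) / den^2 / (K - 1L)
  }
  loss <- unname(loss_weights[1] * ce + loss_weights[2] * (1 - mean(dice_vals)))
  # chain through softmax: dlogit = p * (dLdp - rowSums(dLdp * p))
  dDice <- P * (dLdp - rowSums(dLdp * P))
  dCE <- (P - Tm) / n
  dlogits <- loss_weights[1] * dCE + loss_weights[2] * dDice
  list(loss = loss, dlogits = array(dlogits, dim = d),
       ce = ce, dice = mean(dice_vals))
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(weights) {
  rapply(weights, function(x) list(m = x * 0, v = x * 0), how = "list",
         classes = c("matrix", "array", "numeric"))
}

adam_step <- function(weights, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      g <- grads[[ln]][[pn]]
      st <- state[[ln]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      weights[[ln]][[pn]] <- weights[[ln]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[ln]][[pn]] <- st
    }
  }
  list(weights = weights, state = state)
}

# ---- training --------------------------------------------------------------

#' Train a segmenter on phantom samples
#'
#' Seeded end-to-end training with online augmentation. For
#' `task = "planes"` each draw is a whole (augmented) volume with its
#' 4-class cylinder target; for `task = "localizer"` each draw is a randomly
#' placed patch of side `seg_cfg$in_shape` with its binary sphere target
#' (patches sampled uniformly from the volume). Inputs are
#' intensity-normalized after augmentation, exactly as at inference time.
#' Training aborts with diagnostics if the loss turns non-finite.
#'
#' @param samples list of [generate_phantom()] results (>= 8 recommended).
#' @param seg_cfg a [segmenter_config()].
#' @param trn_cfg a [train_config()].
#' @param task `"planes"` or `"localizer"`.
#' @param verbose print one line per epoch.
#' @return Object of class `unet_fit`: `weights`, `seg_cfg`, `trn_cfg`,
#'   `task`, `history` (per-epoch mean loss).
#' @export
train_segmenter <- function(samples, seg_cfg, trn_cfg = train_config(),
                            task = c("planes", "localizer"), verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(length(samples) >= 2L)
  weights <- unet_init(seg_cfg)
  state <- adam_init(weights)
  history <- numeric(trn_cfg$epochs)
  t_step <- 0L
  with_seed(trn_cfg$seed, {
    for (ep in seq_len(trn_cfg$epochs)) {
      ord <- sample(seq_along(samples))
      ep_loss <- 0; ep_n <- 0L
      batches <- split(ord, ceiling(seq_along(ord) / trn_cfg$batch_size))
      for (bt in batches) {
        grads_acc <- NULL
        bloss <- 0
        for (si in bt) {
          s <- samples[[si]]
          tgt_full <- if (task == "planes") s$plane_masks[[1]]$labels
                      else Reduce(pmax, s$sphere_masks)
          if (trn_cfg$augment) {
            aug <- augment(s$volume, targets = list(tgt_full),
                           seed = sample.int(.Machine$integer.max, 1L),
                           rotation_range_deg = trn_cfg$rotation_range_deg,
                           scale_range = trn_cfg$scale_range,
                           crop_size = seg_cfg$in_shape)
            x <- aug$volume$values; tgt <- aug$targets[[1]]
          } else {
            off <- vapply(s$volume$grid$shape - seg_cfg$in_shape,
                          function(m) if (m > 0) sample.int(m + 1L, 1L) - 1L else 0L, 0L)
            ix <- lapply(1:3, function(a) off[a] + seq_len(seg_cfg$in_shape))
            x <- s$volume$values[ix[[1]], ix[[2]], ix[[3]]]
            tgt <- tgt_full[ix[[1]], ix[[2]], ix[[3]]]
          }
          x <- suppressWarnings(normalize_intensity(x))
          fw <- unet_fw(weights, seg_cfg, x)
          lg <- loss_and_grad(fw$logits, tgt, trn_cfg$loss_weights)
          if (!is.finite(lg$loss))
            stop(sprintf("divergence: non-finite loss at epoch %d (step %d)", ep, t_step))
          gr <- unet_bw(weights, seg_cfg, fw$caches, lg$dlogits)
          grads_acc <- if (is.null(grads_acc)) gr else
            mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                   grads_acc, gr, SIMPLIFY = FALSE)
          bloss <- bloss + lg$loss
        }
        nb <- length(bt)
        grads_acc <- lapply(grads_acc, function(g) lapply(g, function(x) x / nb))
        t_step <- t_step + 1L
        upd <- adam_step(weights, grads_acc, state, trn_cfg$lr, t_step)
        weights <- upd$weights; state <- upd$state
        ep_loss <- ep_loss + bloss; ep_n <- ep_n + nb
      }
      history[ep] <- ep_loss / ep_n
      if (verbose)
        message(sprintf("epoch %3d/%d  loss %.4f", ep, trn_cfg$epochs, history[ep]))
    }
  })
  structure(list(weights = weights, seg_cfg = seg_cfg, trn_cfg = trn_cfg,
                 task = task, history = history),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %s segmenter, %d-level U-Net (base %d), input %d^3\n",
              x$task, x$seg_cfg$depth, x$seg_cfg$base_channels, x$seg_cfg$in_shape))
  cat(sprintf("  %d epochs; loss %.4f -> %.4f\n", length(x$history),
              x$history[1], x$history[length(x$history)]))
  invisible(x)
}

# ---- inference wrappers ----------------------------------------------------

#' Wrap a trained fit as a stage-1 patch predictor or stage-2 segmenter
#'
#' `unet_predictor` returns a function mapping a patch [scalar_volume()] to
#' the foreground-probability array (softmax channel 2), for [localize()].
#' `unet_plane_segmenter` returns a function mapping an ROI volume to a
#' [plane_labels()] via per-voxel argmax, for [estimate_planes()]. Both
#' normalize intensities exactly as during training.
#'
#' @param fit a [train_segmenter()] result.
#' @return A closure.
#' @export
unet_predictor <- function(fit) {
  stopifnot(inherits(fit, "unet_fit"))
  function(patch) {
    x <- suppressWarnings(normalize_intensity(patch$values))
    probs <- softmax_channels(unet_fw(fit$weights, fit$seg_cfg, x)$logits)
    array(probs[, , , 2L], dim = dim(patch$values))
  }
}

#' @rdname unet_predictor
#' @export
unet_plane_segmenter <- function(fit) {
  stopifnot(inherits(fit, "unet_fit"))
  function(vol) {
    x <- suppressWarnings(normalize_intensity(vol$values))
    probs <- softmax_channels(unet_fw(fit$weights, fit$seg_cfg, x)$logits)
    d <- dim(probs)
    lab <- max.col(matrix(probs, prod(d[1:3]), d[4]), ties.method = "first") - 1L
    plane_labels(array(lab, dim = d[1:3]), vol$grid)
  }
}

# ---- checkpoint I/O --------------------------------------------------------

#' Save / load a trained segmenter as JSON
#'
#' Checkpoints are plain JSON: flattened weights with full precision plus the
#' segmenter / training configs and seeds, so a run can be reproduced and
#' audited from the file alone.
#'
#' @param fit a `unet_fit`.
#' @param path file path (`.json`).
#' @return `load_unet` returns the restored `unet_fit`; `save_unet` the path.
#' @export
save_unet <- function(fit, path) {
  stopifnot(inherits(fit, "unet_fit"))
  ser <- list(task = fit$task,
              seg_cfg = unclass(fit$seg_cfg), trn_cfg = unclass(fit$trn_cfg),
              history = fit$history,
              weights = lapply(fit$weights, function(l)
                lapply(l, function(p) list(dim = dim(p) %||% length(p),
                                           data = as.numeric(p)))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(ser$weights, function(l)
    lapply(l, function(p) {
      d <- as.integer(p$dim)
      if (length(d) > 1L) array(p$data, dim = d) else as.numeric(p$data)
    }))
  seg_cfg <- do.call(segmenter_config, as.list(ser$seg_cfg))
  trn_args <- as.list(ser$trn_cfg)
  trn_cfg <- do.call(train_config, trn_args)
  structure(list(weights = weights, seg_cfg = seg_cfg, trn_cfg = trn_cfg,
                 task = ser$task, history = as.numeric(ser$history)),
            class = "unet_fit")
}

# ---- label noise (oracle degradation) --------------------------------------

#' Seeded label-flip noise for oracle masks
#'
#' Emulates segmentation error on a ground-truth mask: for each foreground
#' class, a fraction `rate` of its voxels (rounded) is flipped to background
#' and an equal count of background voxels within `max_offset` voxels of that
#' class is flipped on. Counts are exact and reproducible given the seed.
#'
#' @param labels integer 3D label array (0 = background).
#' @param rate flip fraction in \[0, 0.5).
#' @param seed integer.
#' @param max_offset neighborhood radius (in voxels) for the flipped-on
#'   voxels.
#' @return The noised label array.
#' @export
flip_mask_labels <- function(labels, rate, seed = 1L, max_offset = 3L) {
  stopifnot(rate >= 0, rate < 0.5)
  if (rate == 0) return(labels)
  d <- dim(labels)
  out <- labels
  with_seed(seed, {
    for (cls in sort(unique(labels[labels > 0L]))) {
      idx <- which(labels == cls)
      n_flip <- round(rate * length(idx))
      if (n_flip == 0L) next
      off_sel <- sample(idx, n_flip)
      out[off_sel] <- 0L
      # candidate on-flips: jittered copies of class voxels that land on
      # original background
      coords <- arrayInd(idx, d)
      added <- 0L
      guard <- 0L
      while (added < n_flip && guard < 100L) {
        guard <- guard + 1L
        take <- sample(nrow(coords), min(4L * (n_flip - added), nrow(coords)),
                       replace = TRUE)
        jit <- matrix(sample(seq(-max_offset, max_offset),
                             3L * length(take), replace = TRUE), ncol = 3L)
        cand <- coords[take, , drop = FALSE] + jit
        ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
              cand[, 1] <= d[1] & cand[, 2] <= d[2] & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand) == 0L) next
        lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1))
        lin <- lin[labels[lin] == 0L & out[lin] == 0L]
        if (length(lin) == 0L) next
        lin <- lin[seq_len(min(length(lin), n_flip - added))]
        out[lin] <- cls
        added <- added + length(lin)
      }
    }
  })
  out
}
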