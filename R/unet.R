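#' Configuration for the 3D U-Net aorta segmenter
#'
#' An encoder-decoder with 3x3x3 convolutions, batch normalization and ReLU,
#' the number of filters doubling at each depth level while the grid is
#' halved by 2x2x2 max pooling; nearest-neighbour upsampling and skip
#' concatenation on the decoder path; a per-voxel linear head with softmax
#' over background/aorta. Trained with Adam on voxelwise cross entropy,
#' with window-jitter (random linear intensity rescale) and additive-noise
#' augmentation, on patches drawn from volumes resampled to a uniform
#' working resolution.
#'
#' @param depth number of resolution levels (>= 2). Depth 5 is the
#'   clinical-scale recipe; depth 3 is plenty for desk-scale phantoms.
#' @param base_filters filters at the finest level; doubled per level.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param val_fraction fraction of cases held out for validation.
#' @param patches_per_case random patches drawn per case per epoch.
#' @param patch_vox cubic patch edge in voxels at the working resolution
#'   (must be divisible by `2^(depth-1)`).
#' @param resample_mm isotropic working resolution (mm).
#' @param window_jitter max relative intensity rescale for augmentation.
#' @param noise_aug_max_hu max additive Gaussian noise SD (HU).
#' @param seed integer seed for split, init, patch sampling, augmentation.
#' @return An `aq_segmenter_config` list.
#' @export
segmenter_config <- function(depth = 5, base_filters = 8,
                             learning_rate = 1e-4, epochs = 20,
                             val_fraction = 0.2, patches_per_case = 2,
                             patch_vox = 32, resample_mm = 2,
                             window_jitter = 0.2, noise_aug_max_hu = 20,
                             seed = 1L) {
  stopifnot(depth >= 2, base_filters >= 1, learning_rate > 0, epochs >= 1,
            val_fraction > 0, val_fraction < 1,
            patch_vox %% 2^(depth - 1) == 0)
  structure(list(depth = depth, base_filters = base_filters,
                 learning_rate = learning_rate, epochs = epochs,
                 val_fraction = val_fraction,
                 patches_per_case = patches_per_case, patch_vox = patch_vox,
                 resample_mm = resample_mm, window_jitter = window_jitter,
                 noise_aug_max_hu = noise_aug_max_hu, seed = as.integer(seed)),
            class = "aq_segmenter_config")
}

# HU normalization used by the network.
.unet_norm <- function(hu) (hu + 100) / 600

.he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

.new_conv <- function(cin, cout) {
  list(W = .he_init(27 * cin * cout, 27 * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rm = numeric(cout), rv = rep(1, cout), cin = cin, cout = cout)
}

.unet_init <- function(cfg) {
  d <- cfg$depth; f <- cfg$base_filters
  ch <- f * 2^(0:(d - 1))
  enc <- vector("list", d)
  enc[[1]] <- .new_conv(1, ch[1])
  for (i in 2:d) enc[[i]] <- .new_conv(ch[i - 1], ch[i])
  dec <- vector("list", d - 1)
  for (i in seq_len(d - 1))   # decoder level i merges upsampled ch[i+1] + skip ch[i]
    dec[[i]] <- .new_conv(ch[i + 1] + ch[i], ch[i])
  head_W <- matrix(.he_init(ch[1] * 2, ch[1]), ch[1], 2)
  list(enc = enc, dec = dec, head_W = head_W, head_b = numeric(2), ch = ch)
}

# conv + batchnorm + relu forward. training=TRUE uses batch statistics and
# returns a cache; training=FALSE uses running statistics.
.cbr_fwd <- function(layer, x, dims, training, momentum = 0.1, eps = 1e-5) {
  z <- .cpp_conv3d_fwd(x, layer$W, layer$b, dims, layer$cin, layer$cout)
  nvox <- prod(dims)
  zm <- matrix(z, nvox, layer$cout)
  if (training) {
    mu <- colMeans(zm)
    va <- colMeans(zm^2) - mu^2
    layer$rm <- (1 - momentum) * layer$rm + momentum * mu
    layer$rv <- (1 - momentum) * layer$rv + momentum * va
  } else {
    mu <- layer$rm; va <- layer$rv
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(zm, 2, mu, "-"), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  relu <- y > 0
  y[!relu] <- 0
  list(out = as.numeric(y), layer = layer,
       cache = if (training) list(x = x, zm = zm, xhat = xhat, mu = mu,
                                  inv = inv, relu = relu, dims = dims) else NULL)
}

# backward through relu+bn+conv; returns grads and gx.
.cbr_bwd <- function(layer, cache, gy) {
  nvox <- prod(cache$dims)
  g <- matrix(gy, nvox, layer$cout)
  g[!cache$relu] <- 0
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  gxhat <- sweep(g, 2, layer$gamma, "*")
  # batchnorm backward (per channel over nvox elements)
  t1 <- sweep(gxhat, 2, colMeans(gxhat), "-")
  t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), "*")
  gz <- sweep(t1 - t2, 2, cache$inv, "*")
  bw <- .cpp_conv3d_bwd(cache$x, layer$W, as.numeric(gz), cache$dims,
                        layer$cin, layer$cout)
  list(gx = bw$gx, gW = bw$gw, gb = bw$gb, ggamma = ggamma, gbeta = gbeta)
}

# Full forward pass. Returns per-voxel class probabilities (nvox x 2) and,
# when training, the caches needed for backprop.
.unet_fwd <- function(net, x, dims, training = FALSE) {
  d <- length(net$enc)
  caches <- list(enc = vector("list", d), dec = vector("list", d - 1),
                 pool = vector("list", d - 1), dims = vector("list", d))
  acts <- vector("list", d)
  cur <- x; cdims <- dims
  for (i in seq_len(d)) {
    caches$dims[[i]] <- cdims
    fw <- .cbr_fwd(net$enc[[i]], cur, cdims, training)
    net$enc[[i]] <- fw$layer
    caches$enc[[i]] <- fw$cache
    acts[[i]] <- fw$out
    if (i < d) {
      pl <- .cpp_maxpool3d(fw$out, cdims, net$ch[i])
      caches$pool[[i]] <- list(amax = pl$amax, n_in = length(fw$out))
      cur <- pl$y; cdims <- pl$dims
    }
  }
  up <- acts[[d]]
  for (i in rev(seq_len(d - 1))) {
    updims <- caches$dims[[i + 1]]
    upx <- .cpp_upsample3d(up, updims, net$ch[i + 1])
    cat_x <- c(upx, acts[[i]])
    fw <- .cbr_fwd(net$dec[[i]], cat_x, caches$dims[[i]], training)
    net$dec[[i]] <- fw$layer
    caches$dec[[i]] <- fw$cache
    up <- fw$out
  }
  nvox <- prod(dims)
  feat <- matrix(up, nvox, net$ch[1])
  logits <- sweep(feat %*% net$head_W, 2, net$head_b, "+")
  mx <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mx); e2 <- exp(logits[, 2] - mx)
  p <- e2 / (e1 + e2)
  list(net = net, prob = p, feat = feat,
       caches = if (training) caches else NULL)
}

# Backward pass from voxelwise cross-entropy; labels in {0,1} per voxel.
# Returns list of gradients in the same shape as the network params.
.unet_bwd <- function(net, fwd, labels) {
  d <- length(net$enc)
  nvox <- length(labels)
  # d loss / d logits with softmax CE
  gl <- cbind((1 - fwd$prob) - (1 - labels), fwd$prob - labels) / nvox
  gW_head <- t(fwd$feat) %*% gl
  gb_head <- colSums(gl)
  gfeat <- gl %*% t(net$head_W)
  g <- as.numeric(gfeat)
  grads <- list(enc = vector("list", d), dec = vector("list", d - 1),
                head_W = gW_head, head_b = gb_head)
  caches <- fwd$caches
  gskip <- vector("list", d)
  for (i in seq_len(d - 1)) {
    bw <- .cbr_bwd(net$dec[[i]], caches$dec[[i]], g)
    grads$dec[[i]] <- bw[c("gW", "gb", "ggamma", "gbeta")]
    nup <- prod(caches$dims[[i]]) * net$ch[i + 1]
    gup <- bw$gx[seq_len(nup)]
    gskip[[i]] <- bw$gx[(nup + 1):length(bw$gx)]
    g <- .cpp_upsample3d_bwd(gup, caches$dims[[i + 1]], net$ch[i + 1])
  }
  # g now flows into the bottleneck encoder output
  for (i in rev(seq_len(d))) {
    gy <- if (i == d) g else {
      gp <- .cpp_maxpool3d_bwd(g, caches$pool[[i]]$amax,
                               caches$pool[[i]]$n_in)
      gp + gskip[[i]]
    }
    bw <- .cbr_bwd(net$enc[[i]], caches$enc[[i]], gy)
    grads$enc[[i]] <- bw[c("gW", "gb", "ggamma", "gbeta")]
    g <- bw$gx
  }
  grads
}

# Adam state/update over the flattened parameter list.
.adam_step <- function(par, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
}

.unet_flatten <- function(net) {
  d <- length(net$enc)
  ps <- list()
  for (i in seq_len(d)) ps <- c(ps, net$enc[[i]][c("W", "b", "gamma", "beta")])
  for (i in seq_len(d - 1)) ps <- c(ps, net$dec[[i]][c("W", "b", "gamma", "beta")])
  c(ps, list(as.numeric(net$head_W), net$head_b))
}

.unet_unflatten <- function(net, ps) {
  d <- length(net$enc); j <- 0
  nxt <- function() { j <<- j + 1; ps[[j]] }
  for (i in seq_len(d)) {
    net$enc[[i]]$W <- nxt(); net$enc[[i]]$b <- nxt()
    net$enc[[i]]$gamma <- nxt(); net$enc[[i]]$beta <- nxt()
  }
  for (i in seq_len(d - 1)) {
    net$dec[[i]]$W <- nxt(); net$dec[[i]]$b <- nxt()
    net$dec[[i]]$gamma <- nxt(); net$dec[[i]]$beta <- nxt()
  }
  net$head_W <- matrix(nxt(), ncol = 2); net$head_b <- nxt()
  net
}

.grads_flatten <- function(grads) {
  d <- length(grads$enc)
  gs <- list()
  for (i in seq_len(d)) gs <- c(gs, grads$enc[[i]][c("gW", "gb", "ggamma", "gbeta")])
  for (i in seq_len(d - 1)) gs <- c(gs, grads$dec[[i]][c("gW", "gb", "ggamma", "gbeta")])
  c(gs, list(as.numeric(grads$head_W), grads$head_b))
}

# Draw one training patch (input, labels) from a resampled case.
.draw_patch <- function(vol, msk, cfg) {
  d <- dim(vol)
  ps <- cfg$patch_vox
  fg <- which(msk)
  if (length(fg) && runif(1) < 0.8) {
    c0 <- arrayInd(fg[sample.int(length(fg), 1)], d)
  } else {
    c0 <- cbind(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
  }
  lo <- pmin(pmax(as.integer(c0) - ps %/% 2, 1L), pmax(d - ps + 1L, 1L))
  hi <- lo + ps - 1L
  x <- array(-50, rep(ps, 3))       # background HU pad
  y <- array(FALSE, rep(ps, 3))
  si <- pmin(hi, d)
  x[1:(si[1] - lo[1] + 1), 1:(si[2] - lo[2] + 1), 1:(si[3] - lo[3] + 1)] <-
    vol[lo[1]:si[1], lo[2]:si[2], lo[3]:si[3]]
  y[1:(si[1] - lo[1] + 1), 1:(si[2] - lo[2] + 1), 1:(si[3] - lo[3] + 1)] <-
    msk[lo[1]:si[1], lo[2]:si[2], lo[3]:si[3]]
  # augmentation: window jitter + additive noise
  x <- x * runif(1, 1 - cfg$window_jitter, 1 + cfg$window_jitter)
  x <- x + rnorm(length(x), 0, runif(1, 0, cfg$noise_aug_max_hu))
  list(x = .unet_norm(as.numeric(x)), y = as.numeric(y))
}

#' Train the 3D U-Net aorta segmenter
#'
#' Cases are resampled to the working resolution, split deterministically
#' into training and validation sets under the config seed, and the network
#' is trained with Adam on voxelwise cross entropy over randomly drawn,
#' augmented cubic patches (foreground-biased sampling). The per-epoch loss
#' log and the final validation Dice (computed at the working resolution)
#' are returned with the model.
#'
#' @param cases list of cases, each `list(volume = <aq_volume>,
#'   mask = <aq_mask>)` (a `truth` element carrying `$mask` also works).
#' @param cfg an [segmenter_config()].
#' @param cutoff probability cutoff used for the validation Dice.
#' @param verbose print per-epoch progress.
#' @return An `aq_unet` model with elements `net`, `cfg`, `loss_log`
#'   (per-epoch mean patch loss), `val_dice` (per validation case) and
#'   `split` (case indices).
#' @export
train_segmenter <- function(cases, cfg = segmenter_config(), cutoff = 0.5,
                            verbose = FALSE) {
  stopifnot(length(cases) >= 2)
  getm <- function(cs) if (!is.null(cs$mask)) cs$mask else cs$truth$mask
  set.seed(cfg$seed)
  vols <- lapply(cases, function(cs)
    resample_isotropic(cs$volume, cfg$resample_mm)$voxels)
  msks <- lapply(cases, function(cs)
    resample_isotropic(getm(cs), cfg$resample_mm)$voxels)
  n <- length(cases)
  n_val <- max(1L, round(cfg$val_fraction * n))
  perm <- sample.int(n)
  val_idx <- sort(perm[seq_len(n_val)])
  tr_idx <- sort(perm[(n_val + 1):n])
  net <- .unet_init(cfg)
  ps <- .unet_flatten(net)
  ad <- lapply(ps, function(p) list(m = 0 * p, v = 0 * p, t = 0))
  pdims <- rep(cfg$patch_vox, 3)
  loss_log <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    losses <- c()
    tr_seq <- rep(tr_idx, cfg$patches_per_case)
    tr_seq <- tr_seq[sample.int(length(tr_seq))]
    for (ci in tr_seq) {
      pt <- .draw_patch(vols[[ci]], msks[[ci]], cfg)
      fw <- .unet_fwd(net, pt$x, pdims, training = TRUE)
      net <- fw$net
      eps <- 1e-12
      loss <- -mean(pt$y * log(fw$prob + eps) +
                      (1 - pt$y) * log(1 - fw$prob + eps))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      losses <- c(losses, loss)
      grads <- .grads_flatten(.unet_bwd(net, fw, pt$y))
      ps <- .unet_flatten(net)
      for (j in seq_along(ps)) {
        up <- .adam_step(ps[[j]], grads[[j]], ad[[j]], cfg$learning_rate)
        ps[[j]] <- up$par; ad[[j]] <- up$st
      }
      net <- .unet_unflatten(net, ps)
    }
    loss_log[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs, loss_log[ep]))
  }
  model <- structure(list(net = net, cfg = cfg,
                          loss_log = loss_log, split = list(
                            train = tr_idx, val = val_idx)),
                     class = "aq_unet")
  val_dice <- vapply(val_idx, function(ci) {
    sg <- segment(model, aq_volume(vols[[ci]], rep(cfg$resample_mm, 3)),
                  cutoff = cutoff, resample = FALSE)
    dice(sg$mask, aq_mask(msks[[ci]], rep(cfg$resample_mm, 3)))
  }, numeric(1))
  model$val_dice <- val_dice
  model
}

#' @export
print.aq_unet <- function(x, ...) {
  cat(sprintf("<aq_unet> depth %d, base %d filters, %d epochs trained\n",
              x$cfg$depth, x$cfg$base_filters, length(x$loss_log)))
  if (!is.null(x$val_dice))
    cat(sprintf("  validation Dice: mean %.3f over %d cases\n",
                mean(x$val_dice), length(x$val_dice)))
  invisible(x)
}

#' Segment a volume with a trained U-Net
#'
#' The volume is resampled to the model's working resolution, pushed through
#' the network in one fully-convolutional pass (grid padded to a multiple of
#' the pooling factor), and the aorta probability map is thresholded at
#' `cutoff` followed by largest-connected-component selection and hole
#' filling.
#'
#' @param model an `aq_unet`.
#' @param v an `aq_volume` of HU values.
#' @param cutoff inclusion probability cutoff in (0, 1).
#' @param resample resample the input to the model's working resolution
#'   first (set `FALSE` if `v` is already at that resolution).
#' @return List with `prob` (an `aq_volume` probability map on the working
#'   raster) and `mask` (an `aq_mask` on the same raster).
#' @export
segment <- function(model, v, cutoff = 0.5, resample = TRUE) {
  stopifnot(inherits(model, "aq_unet"), cutoff > 0, cutoff < 1)
  w <- if (resample) resample_isotropic(v, model$cfg$resample_mm) else v
  d <- dim(w$voxels)
  fac <- 2^(model$cfg$depth - 1)
  pd <- as.integer(ceiling(d / fac) * fac)
  x <- array(-50, pd)
  x[1:d[1], 1:d[2], 1:d[3]] <- w$voxels
  fw <- .unet_fwd(model$net, .unet_norm(as.numeric(x)), pd, training = FALSE)
  prob <- array(fw$prob, pd)[1:d[1], 1:d[2], 1:d[3]]
  pm <- aq_volume(prob, w$spacing, w$origin)
  bin <- prob >= cutoff
  if (!any(bin)) stop("no aorta found: probability map below cutoff everywhere")
  mk <- fill_holes(largest_component(aq_mask(bin, w$spacing, w$origin)))
  list(prob = pm, mask = mk)
}
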