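#' Configuration of the nucleus-center detection network
#'
#' A small 3D U-Net-style encoder-decoder for heatmap regression, in which
#' every convolution input is concatenated with three channels holding the
#' normalized absolute voxel coordinates (x, y, z in `[0, 1]` over the full
#' stack). This deliberately breaks translation equivariance: detection
#' quality in these stacks depends on depth (z), and because coordinates are
#' normalized over the full stack rather than per patch, the depth signal
#' survives patch-wise training. Pooling halves y and x only; the z axis is
#' too coarse (few slices) to be downsampled.
#'
#' @param depth Number of resolution levels (>= 1).
#' @param base_filters Filters at the top level; doubled at each level down.
#' @param patch_xy Side of the square xy training column in pixels (full z
#'   extent is always used); must be at least 16 and divisible by
#'   `2^(depth - 1)`.
#' @param epochs Training epochs.
#' @param batch_size Patches per gradient step.
#' @param learning_rate Adam learning rate; a vector is recycled to one
#'   rate per epoch (e.g. a step decay).
#' @param steps_per_epoch Gradient steps per epoch; defaults to
#'   `ceiling(n_pairs / batch_size)`.
#' @param seed Integer seed for weight initialisation and patch sampling.
#' @return A `detector_config` object.
#' @export
detector_config <- function(depth = 3, base_filters = 16, patch_xy = 64,
                            epochs = 10, batch_size = 4, learning_rate = 1e-3,
                            steps_per_epoch = NULL, seed = 1L) {
  stopifnot(depth >= 1, base_filters >= 1, patch_xy >= 16,
            epochs >= 1, batch_size >= 1, all(learning_rate > 0))
  if (patch_xy %% 2^(depth - 1) != 0) {
    stop("detector_config: patch_xy must be divisible by 2^(depth - 1)", call. = FALSE)
  }
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 patch_xy = as.integer(patch_xy), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 steps_per_epoch = steps_per_epoch, seed = as.integer(seed)),
            class = "detector_config")
}

#' Build an untrained detection network
#'
#' Initialises the weights (He-normal, deterministic given `cfg$seed`) of the
#' CoordConv encoder-decoder described in [detector_config()]. The network
#' maps a `(ny, nx, nz)` image to a heatmap of identical shape.
#'
#' @param cfg A [detector_config()].
#' @return An object of class `nuc_detector`.
#' @export
build_detector <- function(cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  with_preserved_rng({
    set.seed(cfg$seed)
    weights <- list()
    he_conv <- function(cin, cout, kz) {
      taps <- 9L * kz * cin
      matrix(stats::rnorm(taps * cout, 0, sqrt(2 / taps)), taps, cout)
    }
    filt <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1)
    cin_prev <- 1L
    for (l in seq_len(cfg$depth)) {
      kz <- level_kz(l)
      weights[[sprintf("enc%d_w1", l)]] <- he_conv(cin_prev + 3L, filt[l], kz)
      weights[[sprintf("enc%d_b1", l)]] <- numeric(filt[l])
      weights[[sprintf("enc%d_w2", l)]] <- he_conv(filt[l] + 3L, filt[l], kz)
      weights[[sprintf("enc%d_b2", l)]] <- numeric(filt[l])
      cin_prev <- filt[l]
    }
    for (l in rev(seq_len(cfg$depth - 1))) {
      kz <- level_kz(l)
      weights[[sprintf("dec%d_w1", l)]] <- he_conv(filt[l + 1] + filt[l] + 3L, filt[l], kz)
      weights[[sprintf("dec%d_b1", l)]] <- numeric(filt[l])
      weights[[sprintf("dec%d_w2", l)]] <- he_conv(filt[l] + 3L, filt[l], kz)
      weights[[sprintf("dec%d_b2", l)]] <- numeric(filt[l])
    }
    # final 1x1x1 linear projection to one output channel
    weights[["out_w"]] <- matrix(stats::rnorm(filt[1] + 3L, 0, sqrt(2 / (filt[1] + 3))),
                                 filt[1] + 3L, 1L)
    weights[["out_b"]] <- 0
    structure(list(cfg = cfg, weights = weights, history = numeric()),
              class = "nuc_detector")
  })
}

#' @export
print.nuc_detector <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<nuc_detector> depth %d, base %d filters, %s parameters, %d epochs trained\n",
              x$cfg$depth, x$cfg$base_filters, format(np, big.mark = ","),
              length(x$history)))
  invisible(x)
}

# normalized absolute-coordinate channels for a patch of a full stack.
# offset = (y0, x0) of the patch in full-resolution pixels (0-based);
# pool = xy downsampling factor of this level.
coord_channels <- function(ny, nx, nz, full_shape, offset, pool) {
  yc <- (offset[1] + (seq_len(ny) - 1) * pool) / max(full_shape[1] - 1, 1)
  xc <- (offset[2] + (seq_len(nx) - 1) * pool) / max(full_shape[2] - 1, 1)
  zc <- (seq_len(nz) - 1) / max(full_shape[3] - 1, 1)
  out <- array(0, dim = c(ny, nx, nz, 3))
  out[, , , 1] <- array(rep(xc, each = ny), dim = c(ny, nx, nz))
  out[, , , 2] <- array(yc, dim = c(ny, nx, nz))
  out[, , , 3] <- array(rep(zc, each = ny * nx), dim = c(ny, nx, nz))
  out
}

cat_coords <- function(x, coords) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3], d[4] + 3L))
  out[, , , seq_len(d[4])] <- x
  out[, , , d[4] + 1:3] <- coords
  out
}

# z-extent of the conv kernels per resolution level: in-plane (3x3x1) at the
# full-resolution level where the z-step dwarfs the pixel size, full 3x3x3
# from level 2 down, which is where cross-slice context is aggregated
level_kz <- function(l) if (l == 1L) 1L else 3L

conv_block_fwd <- function(x, coords, w, b, kz, relu = TRUE, keep_cols = TRUE) {
  xc <- cat_coords(x, coords)
  cv <- conv3d_fwd(xc, dim(xc), w, b, kz, keep_cols)
  a <- if (relu) pmax(cv$y, 0) else cv$y
  list(a = a, cols = cv$cols, y = cv$y, kz = kz, in_dims = dim(xc))
}

conv_block_bwd <- function(cache, w, ga, relu = TRUE, need_gx = TRUE) {
  g <- if (relu) ga * (cache$y > 0) else ga
  cin <- if (need_gx) cache$in_dims[4] - 3L else 0L
  bw <- conv3d_bwd(cache$cols, cache$in_dims, w, g, cache$kz, cin)
  list(gx = bw$gx, gw = bw$gw, gb = bw$gb)
}

upsample2_xy <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

downsum2_xy <- function(g) {
  d <- dim(g)
  g[seq(1, d[1], 2), , , , drop = FALSE] + g[seq(2, d[1], 2), , , , drop = FALSE] ->
    tmp
  tmp[, seq(1, d[2], 2), , , drop = FALSE] + tmp[, seq(2, d[2], 2), , , drop = FALSE]
}

# forward pass on one patch; returns prediction (ny,nx,nz) and the cache
# needed for backprop. full_shape = (ny, nx, nz) of the full stack,
# offset = (y0, x0) of the patch.
detector_forward <- function(model, patch, full_shape, offset = c(0L, 0L),
                             train = TRUE) {
  cfg <- model$cfg
  w <- model$weights
  d <- dim(patch)
  x <- array(patch, dim = c(d, 1L))
  cache <- list()
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    pool <- 2^(l - 1)
    dl <- dim(x)
    co <- coord_channels(dl[1], dl[2], dl[3], full_shape, offset, pool)
    kz <- level_kz(l)
    c1 <- conv_block_fwd(x, co, w[[sprintf("enc%d_w1", l)]], w[[sprintf("enc%d_b1", l)]],
                         kz, keep_cols = train)
    c2 <- conv_block_fwd(c1$a, co, w[[sprintf("enc%d_w2", l)]], w[[sprintf("enc%d_b2", l)]],
                         kz, keep_cols = train)
    cache[[sprintf("enc%d", l)]] <- list(c1 = c1, c2 = c2, coords = co)
    skips[[l]] <- c2$a
    if (l < cfg$depth) {
      p <- pool2_fwd(c2$a, dim(c2$a))
      cache[[sprintf("pool%d", l)]] <- list(arg = p$arg, xdims = dim(c2$a))
      x <- p$y
    } else {
      x <- c2$a
    }
  }
  for (l in rev(seq_len(cfg$depth - 1))) {
    up <- upsample2_xy(x)
    skip <- skips[[l]]
    xc <- array(0, dim = c(dim(skip)[1:3], dim(up)[4] + dim(skip)[4]))
    xc[, , , seq_len(dim(up)[4])] <- up
    xc[, , , dim(up)[4] + seq_len(dim(skip)[4])] <- skip
    co <- cache[[sprintf("enc%d", l)]]$coords
    kz <- level_kz(l)
    c1 <- conv_block_fwd(xc, co, w[[sprintf("dec%d_w1", l)]], w[[sprintf("dec%d_b1", l)]],
                         kz, keep_cols = train)
    c2 <- conv_block_fwd(c1$a, co, w[[sprintf("dec%d_w2", l)]], w[[sprintf("dec%d_b2", l)]],
                         kz, keep_cols = train)
    cache[[sprintf("dec%d", l)]] <- list(c1 = c1, c2 = c2, n_up = dim(up)[4])
    x <- c2$a
  }
  # 1x1x1 linear output layer on (features + coords)
  co <- cache[["enc1"]]$coords
  xc <- cat_coords(x, co)
  dl <- dim(xc)
  flat <- matrix(xc, ncol = dl[4])
  pred <- array(flat %*% w$out_w + w$out_b, dim = dl[1:3])
  cache[["out"]] <- list(flat = flat, in_dims = dl)
  list(pred = pred, cache = cache)
}

detector_backward <- function(model, cache, gpred) {
  cfg <- model$cfg
  w <- model$weights
  grads <- list()
  oc <- cache[["out"]]
  gflat <- matrix(gpred, ncol = 1L)
  grads$out_w <- crossprod(oc$flat, gflat)
  grads$out_b <- sum(gflat)
  gxc <- gflat %*% t(w$out_w)
  nfeat <- oc$in_dims[4] - 3L
  gx <- array(gxc[, seq_len(nfeat)], dim = c(oc$in_dims[1:3], nfeat))

  for (l in seq_len(cfg$depth - 1)) {
    dc <- cache[[sprintf("dec%d", l)]]
    b2 <- conv_block_bwd(dc$c2, w[[sprintf("dec%d_w2", l)]], gx)
    grads[[sprintf("dec%d_w2", l)]] <- b2$gw
    grads[[sprintf("dec%d_b2", l)]] <- b2$gb
    b1 <- conv_block_bwd(dc$c1, w[[sprintf("dec%d_w1", l)]], b2$gx)
    grads[[sprintf("dec%d_w1", l)]] <- b1$gw
    grads[[sprintf("dec%d_b1", l)]] <- b1$gb
    n_up <- dc$n_up
    gup <- b1$gx[, , , seq_len(n_up), drop = FALSE]
    gskip <- b1$gx[, , , n_up + seq_len(dim(b1$gx)[4] - n_up), drop = FALSE]
    cache[[sprintf("skip_grad%d", l)]] <- gskip
    gx <- downsum2_xy(gup)
  }
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) {
      pc <- cache[[sprintf("pool%d", l)]]
      gx <- pool2_bwd(pc$arg, gx, pc$xdims)
      gx <- gx + cache[[sprintf("skip_grad%d", l)]]
    }
    ec <- cache[[sprintf("enc%d", l)]]
    b2 <- conv_block_bwd(ec$c2, w[[sprintf("enc%d_w2", l)]], gx)
    grads[[sprintf("enc%d_w2", l)]] <- b2$gw
    grads[[sprintf("enc%d_b2", l)]] <- b2$gb
    b1 <- conv_block_bwd(ec$c1, w[[sprintf("enc%d_w1", l)]], b2$gx,
                         need_gx = l > 1L)
    grads[[sprintf("enc%d_w1", l)]] <- b1$gw
    grads[[sprintf("enc%d_b1", l)]] <- b1$gb
    gx <- b1$gx
  }
  grads
}

#' Train the detection network on image/target pairs
#'
#' Each gradient step samples `batch_size` random square xy-columns (side
#' `patch_xy`, full z extent) from the training volumes, perturbs each
#' image/target pair (see [augment_pair()]) and minimises the weighted mean
#' squared error ([weighted_mse()]) with Adam. Fully deterministic on CPU
#' given `cfg$seed`.
#'
#' @param model A [build_detector()] model.
#' @param images List of 3D image arrays (all the same shape).
#' @param targets List of matching target heatmaps, e.g. from
#'   [make_target_heatmap()].
#' @param cfg Optional [detector_config()] overriding `model$cfg` training
#'   fields.
#' @param augment Apply random perturbations (default `TRUE`).
#' @return The trained model; `$history` holds the mean loss per epoch.
#' @export
train_detector <- function(model, images, targets, cfg = NULL, augment = TRUE) {
  stopifnot(inherits(model, "nuc_detector"),
            is.list(images), is.list(targets), length(images) == length(targets))
  if (!length(images)) stop("train_detector: empty training set", call. = FALSE)
  if (is.null(cfg)) cfg <- model$cfg
  with_preserved_rng({
    set.seed(cfg$seed + 1L)
    n <- length(images)
    full_shape <- dim(images[[1]])
    patch <- min(cfg$patch_xy, full_shape[1], full_shape[2])
    patch <- patch - (patch %% 2^(cfg$depth - 1))
    steps <- if (!is.null(cfg$steps_per_epoch)) cfg$steps_per_epoch
             else ceiling(n / cfg$batch_size)
    adam_m <- lapply(model$weights, function(w) w * 0)
    adam_v <- adam_m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    tstep <- 0
    history <- numeric(cfg$epochs)
    lr_ep <- rep_len(cfg$learning_rate, cfg$epochs)
    aug_seed <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        gacc <- NULL
        loss_acc <- 0
        for (bi in seq_len(cfg$batch_size)) {
          k <- sample.int(n, 1)
          y0 <- sample.int(full_shape[1] - patch + 1L, 1) - 1L
          x0 <- sample.int(full_shape[2] - patch + 1L, 1) - 1L
          img <- images[[k]][y0 + seq_len(patch), x0 + seq_len(patch), , drop = FALSE]
          tgt <- targets[[k]][y0 + seq_len(patch), x0 + seq_len(patch), , drop = FALSE]
          if (augment) {
            aug_seed <- aug_seed + 1L
            a <- augment_pair(img, tgt, seed = cfg$seed * 7919L + aug_seed)
            img <- a$image; tgt <- a$target
          }
          fw <- detector_forward(model, img, full_shape, offset = c(y0, x0))
          loss_acc <- loss_acc + weighted_mse(fw$pred, tgt)
          g <- detector_backward(model, fw$cache, weighted_mse_grad(fw$pred, tgt))
          gacc <- if (is.null(gacc)) g
                  else purrr::map2(gacc, g[names(gacc)], `+`)
        }
        gacc <- lapply(gacc, function(g) g / cfg$batch_size)
        tstep <- tstep + 1
        for (nm in names(model$weights)) {
          g <- gacc[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mh <- adam_m[[nm]] / (1 - b1^tstep)
          vh <- adam_v[[nm]] / (1 - b2^tstep)
          model$weights[[nm]] <- model$weights[[nm]] -
            lr_ep[ep] * mh / (sqrt(vh) + eps)
        }
        ep_loss <- ep_loss + loss_acc / cfg$batch_size
      }
      history[ep] <- ep_loss / steps
    }
    model$history <- c(model$history, history)
    model
  })
}

#' Predict a heatmap for a full image stack
#'
#' Applies the network tile-wise (xy tiles of the training patch size with an
#' overlap margin whose borders are discarded) so that arbitrarily large
#' stacks can be processed with bounded memory. Coordinate channels always
#' hold the absolute position of each tile within the full stack.
#'
#' @param model A trained [build_detector()] model.
#' @param image A 3D array `(ny, nx, nz)`.
#' @param margin Overlap margin in pixels discarded at inner tile borders.
#' @param tta Average the predictions over the four in-plane flip variants
#'   (test-time augmentation). The network is trained under random flips
#'   with unflipped coordinate channels, so flipping the image, predicting,
#'   and unflipping the prediction is consistent by construction; averaging
#'   suppresses spurious background bumps.
#' @return A heatmap array of the same shape.
#' @export
predict_heatmap <- function(model, image, margin = 8L, tta = FALSE) {
  if (tta) {
    nx <- dim(image)[2]; ny <- dim(image)[1]
    acc <- predict_heatmap(model, image, margin)
    fx <- predict_heatmap(model, image[, nx:1, , drop = FALSE], margin)
    acc <- acc + fx[, nx:1, , drop = FALSE]
    fy <- predict_heatmap(model, image[ny:1, , , drop = FALSE], margin)
    acc <- acc + fy[ny:1, , , drop = FALSE]
    fxy <- predict_heatmap(model, image[ny:1, nx:1, , drop = FALSE], margin)
    acc <- acc + fxy[ny:1, nx:1, , drop = FALSE]
    return(acc / 4)
  }
  cfg <- model$cfg
  d <- dim(image)
  patch <- min(cfg$patch_xy, d[1], d[2])
  patch <- patch - (patch %% 2^(cfg$depth - 1))
  out <- array(0, dim = d)
  starts <- function(nfull) {
    if (patch >= nfull) return(0L)
    s <- seq(0L, nfull - patch, by = patch - 2L * margin)
    unique(pmin(s, nfull - patch))
  }
  for (y0 in starts(d[1])) for (x0 in starts(d[2])) {
    tile <- image[y0 + seq_len(patch), x0 + seq_len(patch), , drop = FALSE]
    pr <- detector_forward(model, tile, d, offset = c(y0, x0), train = FALSE)$pred
    # keep only the interior of interior tiles
    ys <- if (y0 > 0) margin + 1L else 1L
    ye <- if (y0 + patch < d[1]) patch - margin else patch
    xs <- if (x0 > 0) margin + 1L else 1L
    xe <- if (x0 + patch < d[2]) patch - margin else patch
    out[y0 + ys:ye, x0 + xs:xe, ] <- pr[ys:ye, xs:xe, , drop = FALSE]
  }
  out
}

#' Save / load a detector model as JSON
#'
#' @param model A `nuc_detector`.
#' @param path File path.
#' @return `save_detector()` returns `path` invisibly; `load_detector()` the
#'   model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "nuc_detector"))
  obj <- list(cfg = unclass(model$cfg),
              history = model$history,
              weights = lapply(model$weights, function(w) {
                list(dim = dim(w), values = as.numeric(w))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- obj$cfg
  cfg <- detector_config(cfgl$depth, cfgl$base_filters, cfgl$patch_xy,
                         cfgl$epochs, cfgl$batch_size, cfgl$learning_rate,
                         if (is.null(cfgl$steps_per_epoch)) NULL else cfgl$steps_per_epoch,
                         cfgl$seed)
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$values, w$dim[1], w$dim[2]) else w$values
  })
  structure(list(cfg = cfg, weights = weights,
                 history = as.numeric(obj$history)),
            class = "nuc_detector")
}
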