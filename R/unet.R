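# Four-class U-Net: encoder-decoder with skip connections, two 3x3 conv+ReLU
# per stage, 2x2 max pooling, 2x2 transposed-convolution upsampling, dropout
# at the deepest encoder stage and the bridge, and a 1x1 per-pixel classifier.
# Trained from scratch with softmax cross-entropy and Adam.

#' U-Net configuration
#'
#' Defaults are the study-scale hyperparameters: four resolution levels
#' (46 layers under the reported counting convention), 128x128 training
#' patches, 4 classes, Adam with learning rate 1e-3, mini-batch 64, 15
#' epochs, base width 64. Every field can be overridden for desk-scale runs.
#'
#' @param depth number of resolution levels (`depth - 1` max-poolings).
#' @param in_patch training patch side, px; must be divisible by
#'   `2^(depth-1)`.
#' @param n_classes number of output classes.
#' @param base_channels feature channels at the first level; doubled per
#'   level.
#' @param epochs training epochs.
#' @param learning_rate Adam initial learning rate.
#' @param batch_size mini-batch size.
#' @param dropout dropout probability at the deepest encoder stage and
#'   bridge.
#' @param seed RNG seed for weight initialisation, shuffling and dropout.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 4, in_patch = 128, n_classes = 4,
                        base_channels = 64, epochs = 15,
                        learning_rate = 1e-3, batch_size = 64,
                        dropout = 0.5, seed = 1) {
  if (n_classes < 2) stop("configuration error: n_classes must be >= 2")
  if (depth < 2) stop("configuration error: depth must be >= 2")
  if (in_patch %% 2^(depth - 1) != 0)
    stop("configuration error: in_patch must be divisible by 2^(depth-1)")
  structure(list(depth = as.integer(depth), in_patch = as.integer(in_patch),
                 n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 seed = as.integer(seed)),
            class = "unet_config")
}

stage_channels <- function(config) config$base_channels * 2^(seq_len(config$depth) - 1L)

he_conv3 <- function(cin, cout) {
  list(W = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout),
       b = numeric(cout))
}
he_upconv <- function(cin, cout) {
  list(W = matrix(rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))), 4 * cin, cout),
       b = numeric(cout))
}

#' Build an untrained U-Net
#'
#' @param config a [unet_config()].
#' @return An object of class `unet` with randomly initialised (He) weights;
#'   see [summary.unet()] for the layer table.
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  ch <- stage_channels(config)
  L <- config$depth
  params <- with_seed(config$seed, {
    # drawn under the config seed so identical configs give identical nets
    p <- list()
    cin <- 1L
    for (l in seq_len(L - 1)) {
      p[[sprintf("enc%d_conv1", l)]] <- he_conv3(cin, ch[l])
      p[[sprintf("enc%d_conv2", l)]] <- he_conv3(ch[l], ch[l])
      cin <- ch[l]
    }
    p$bridge_conv1 <- he_conv3(cin, ch[L])
    p$bridge_conv2 <- he_conv3(ch[L], ch[L])
    for (l in rev(seq_len(L - 1))) {
      up_in <- if (l == L - 1) ch[L] else ch[l + 1]
      p[[sprintf("dec%d_up", l)]] <- he_upconv(up_in, ch[l])
      p[[sprintf("dec%d_conv1", l)]] <- he_conv3(2 * ch[l], ch[l])
      p[[sprintf("dec%d_conv2", l)]] <- he_conv3(ch[l], ch[l])
    }
    p$final <- list(W = matrix(rnorm(ch[1] * config$n_classes, 0,
                                     sqrt(2 / ch[1])),
                               ch[1], config$n_classes),
                    b = numeric(config$n_classes))
    p
  })
  structure(list(params = params, config = config, trained = FALSE,
                 loss_trace = numeric(0)),
            class = "unet")
}

#' Layer table of a U-Net
#'
#' Enumerates the network under the counting convention in which the input,
#' every convolution, ReLU, dropout, max-pooling, transposed convolution,
#' concatenation, the softmax and the final pixel-classification stage each
#' count as one layer; the default 4-level network has 46.
#'
#' @param config a [unet_config()].
#' @return data.frame with columns `layer`, `type`, `stage`.
#' @export
unet_layers <- function(config = unet_config()) {
  L <- config$depth
  rows <- list(c("input", "input"))
  add <- function(type, stage) rows[[length(rows) + 1L]] <<- c(type, stage)
  for (l in seq_len(L - 1)) {
    s <- sprintf("encoder-%d", l)
    add("conv 3x3", s); add("relu", s); add("conv 3x3", s); add("relu", s)
    if (l == L - 1) add("dropout", s)
    add("maxpool 2x2", s)
  }
  add("conv 3x3", "bridge"); add("relu", "bridge")
  add("conv 3x3", "bridge"); add("relu", "bridge"); add("dropout", "bridge")
  for (l in rev(seq_len(L - 1))) {
    s <- sprintf("decoder-%d", l)
    add("transposed conv 2x2", s); add("relu", s); add("concat skip", s)
    add("conv 3x3", s); add("relu", s); add("conv 3x3", s); add("relu", s)
  }
  add("conv 1x1", "output"); add("softmax", "output")
  add("pixel classification", "output")
  m <- do.call(rbind, rows)
  data.frame(layer = seq_len(nrow(m)), type = m[, 1], stage = m[, 2],
             stringsAsFactors = FALSE)
}

conv_block <- function(x, p1, p2, train, drop_p = 0) {
  c1 <- conv3_forward(x, p1$W, p1$b); r1 <- relu_forward(c1$out)
  c2 <- conv3_forward(r1$out, p2$W, p2$b); r2 <- relu_forward(c2$out)
  dr <- dropout_forward(r2$out, drop_p, train)
  list(out = dr$out, cache = list(c1 = c1$cache, r1 = r1$cache,
                                  c2 = c2$cache, r2 = r2$cache,
                                  dr = dr$cache))
}

conv_block_backward <- function(cache, dout) {
  d <- dropout_backward(cache$dr, dout)
  d <- relu_backward(cache$r2, d)
  b2 <- conv3_backward(cache$c2, d)
  d <- relu_backward(cache$r1, b2$dx)
  b1 <- conv3_backward(cache$c1, d)
  list(dx = b1$dx, g1 = list(W = b1$dW, b = b1$db),
       g2 = list(W = b2$dW, b = b2$db))
}

unet_forward <- function(params, x, config, train = FALSE) {
  L <- config$depth
  caches <- list(enc = vector("list", L - 1), dec = vector("list", L - 1))
  skips <- vector("list", L - 1)
  h <- x
  for (l in seq_len(L - 1)) {
    drop_p <- if (l == L - 1) config$dropout else 0
    blk <- conv_block(h, params[[sprintf("enc%d_conv1", l)]],
                      params[[sprintf("enc%d_conv2", l)]], train, drop_p)
    skips[[l]] <- blk$out
    pl <- pool_forward(blk$out)
    caches$enc[[l]] <- list(blk = blk$cache, pool = pl$cache)
    h <- pl$out
  }
  br <- conv_block(h, params$bridge_conv1, params$bridge_conv2, train,
                   config$dropout)
  caches$bridge <- br$cache
  h <- br$out
  for (l in rev(seq_len(L - 1))) {
    p <- params[[sprintf("dec%d_up", l)]]
    up <- upconv_forward(h, p$W, p$b)
    ur <- relu_forward(up$out)
    cc <- concat_forward(ur$out, skips[[l]])
    blk <- conv_block(cc$out, params[[sprintf("dec%d_conv1", l)]],
                      params[[sprintf("dec%d_conv2", l)]], train, 0)
    caches$dec[[l]] <- list(up = up$cache, ur = ur$cache, cc = cc$cache,
                            blk = blk$cache)
    h <- blk$out
  }
  fin <- conv1_forward(h, params$final$W, params$final$b)
  caches$final <- fin$cache
  list(logits = fin$out, caches = caches)
}

unet_backward <- function(params, caches, dlogits, config) {
  L <- config$depth
  grads <- list()
  bf <- conv1_backward(caches$final, dlogits)
  grads$final <- list(W = bf$dW, b = bf$db)
  d <- bf$dx
  dskips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    cb <- conv_block_backward(caches$dec[[l]]$blk, d)
    grads[[sprintf("dec%d_conv1", l)]] <- cb$g1
    grads[[sprintf("dec%d_conv2", l)]] <- cb$g2
    sp <- concat_backward(caches$dec[[l]]$cc, cb$dx)
    dskips[[l]] <- sp$db
    du <- relu_backward(caches$dec[[l]]$ur, sp$da)
    bu <- upconv_backward(caches$dec[[l]]$up, du)
    grads[[sprintf("dec%d_up", l)]] <- list(W = bu$dW, b = bu$db)
    d <- bu$dx
  }
  cb <- conv_block_backward(caches$bridge, d)
  grads$bridge_conv1 <- cb$g1
  grads$bridge_conv2 <- cb$g2
  d <- cb$dx
  for (l in rev(seq_len(L - 1))) {
    dpool <- pool_backward(caches$enc[[l]]$pool, d)
    cb <- conv_block_backward(caches$enc[[l]]$blk, dpool + dskips[[l]])
    grads[[sprintf("enc%d_conv1", l)]] <- cb$g1
    grads[[sprintf("enc%d_conv2", l)]] <- cb$g2
    d <- cb$dx
  }
  grads
}

flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) { out[[paste0(nm, ".W")]] <- p[[nm]]$W
                         out[[paste0(nm, ".b")]] <- p[[nm]]$b }
  out
}
unflatten_params <- function(f) {
  nms <- unique(sub("\\.(W|b)$", "", names(f)))
  setNames(lapply(nms, function(nm)
    list(W = f[[paste0(nm, ".W")]], b = f[[paste0(nm, ".b")]])), nms)
}

batch_tensor <- function(images) {
  # [p, p, n] 0-255 -> [p, p, n, 1] in [0, 1]
  d <- dim(images)
  array(images / 255, c(d[1], d[2], d[3], 1L))
}

#' Train a U-Net on patch pairs
#'
#' Mini-batch softmax cross-entropy training with Adam for the configured
#' number of epochs. All randomness (weight init, shuffling, dropout) flows
#' from `config$seed`, so identical data and config reproduce the loss trace.
#'
#' @param pairs a `patch_set` (see [extract_pairs()]) or a list with
#'   `images` and `labels` arrays `[p, p, n]`.
#' @param config a [unet_config()].
#' @param model optionally, an existing [build_unet()] model to continue.
#' @param verbose print per-epoch mean loss.
#' @return A trained object of class `unet` carrying `loss_trace` (per-epoch
#'   mean loss) and `batch_losses`.
#' @export
unet_train <- function(pairs, config = unet_config(), model = NULL,
                       verbose = FALSE) {
  n <- if (inherits(pairs, "patch_set")) n_pairs(pairs)
       else dim(pairs$images)[3]
  if (n < 1) stop("data error: no training pairs")
  if (is.null(model)) model <- build_unet(config)
  params <- model$params
  with_seed(config$seed + 1L, {
    flat <- flatten_params(params)
    state <- adam_init(flat)
    epoch_losses <- numeric(config$epochs)
    batch_losses <- list()
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      bl <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        if (inherits(pairs, "patch_set")) {
          mat <- materialize_pairs(pairs, idx)
          x <- batch_tensor(mat$images); y <- mat$labels
        } else {
          x <- batch_tensor(pairs$images[, , idx, drop = FALSE])
          y <- pairs$labels[, , idx, drop = FALSE]
        }
        params <- unflatten_params(flat)
        fw <- unet_forward(params, x, config, train = TRUE)
        ce <- softmax_ce(fw$logits, y)
        bl[bi] <- ce$loss
        grads <- unet_backward(params, fw$caches, ce$grad, config)
        upd <- adam_step(flat, flatten_params(grads), state,
                         config$learning_rate)
        flat <- upd$params; state <- upd$state
      }
      epoch_losses[ep] <- mean(bl)
      batch_losses[[ep]] <- bl
      if (verbose)
        message(sprintf("epoch %d/%d: mean loss %.4f", ep, config$epochs,
                        epoch_losses[ep]))
    }
    model$params <- unflatten_params(flat)
    model$trained <- TRUE
    model$loss_trace <- epoch_losses
    model$batch_losses <- batch_losses
  })
  model
}

argmax_classes <- function(logits) {
  d <- dim(logits)
  lm <- logits; dim(lm) <- c(prod(d[1:3]), d[4])
  cls <- max.col(lm, ties.method = "first") - 1L   # ties -> lowest class code
  dim(cls) <- d[1:3]
  cls
}

#' Classify a stack of patches
#'
#' @param model trained `unet`.
#' @param images array `[p, p, n]` of intensities 0-255 (p divisible by
#'   `2^(depth-1)`).
#' @return Integer array `[p, p, n]` of class codes.
#' @export
predict_patches <- function(model, images) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  fw <- unet_forward(model$params, batch_tensor(images), model$config,
                     train = FALSE)
  argmax_classes(fw$logits)
}

reflect_index <- function(n, lo, hi) {
  # indices lo..hi mapped into 1..n by mirror folding (period 2n-2)
  idx <- lo:hi
  if (n == 1L) return(rep(1L, length(idx)))
  per <- 2L * n - 2L
  m <- (idx - 1L) %% per
  ifelse(m < n, m + 1L, per - m + 1L)
}

#' Segment a full slice by tiled inference
#'
#' Runs the fixed-size network over overlapping tiles (stride = half tile)
#' with reflective padding and mosaics each tile's central region, so slices
#' of arbitrary size — including ones smaller than a tile — get a full-size
#' class map.
#'
#' @param model trained `unet`.
#' @param slice 2D intensity matrix.
#' @param tile tile side (default the training patch size).
#' @param tile_batch tiles per forward pass.
#' @return Integer matrix of class codes, same shape as `slice`.
#' @export
predict_slice <- function(model, slice, tile = model$config$in_patch,
                          tile_batch = 16L) {
  x <- as_slice(slice)
  H <- nrow(x); W <- ncol(x)
  s <- tile %/% 2L; margin <- tile %/% 4L
  ntr <- ceiling(H / s); ntc <- ceiling(W / s)
  Hp <- (ntr - 1L) * s + tile; Wp <- (ntc - 1L) * s + tile
  xp <- x[reflect_index(H, 1L - margin, Hp - margin),
          reflect_index(W, 1L - margin, Wp - margin)]
  out <- matrix(0L, H, W)
  tiles <- expand.grid(r = seq_len(ntr), c = seq_len(ntc))
  for (start in seq(1L, nrow(tiles), by = tile_batch)) {
    batch <- tiles[start:min(start + tile_batch - 1L, nrow(tiles)), ]
    imgs <- array(0, c(tile, tile, nrow(batch)))
    for (j in seq_len(nrow(batch))) {
      r0 <- (batch$r[j] - 1L) * s; c0 <- (batch$c[j] - 1L) * s
      imgs[, , j] <- xp[r0 + seq_len(tile), c0 + seq_len(tile)]
    }
    cls <- predict_patches(model, imgs)
    for (j in seq_len(nrow(batch))) {
      r0 <- (batch$r[j] - 1L) * s; c0 <- (batch$c[j] - 1L) * s
      rs <- (r0 + 1L):min(r0 + s, H); cs <- (c0 + 1L):min(c0 + s, W)
      out[rs, cs] <- cls[margin + seq_along(rs), margin + seq_along(cs), j]
    }
  }
  out
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("U-Net: %d levels, %d layers, base width %d, %d classes%s\n",
              cfg$depth, nrow(unet_layers(cfg)), cfg$base_channels,
              cfg$n_classes,
              if (x$trained) sprintf(", trained (%d epochs, final loss %.4f)",
                                     length(x$loss_trace),
                                     x$loss_trace[length(x$loss_trace)])
              else ", untrained"))
  invisible(x)
}

#' Summarise a U-Net
#'
#' @param object a `unet`.
#' @param ... unused.
#' @return The layer table (invisibly) after printing it with the parameter
#'   count.
#' @export
summary.unet <- function(object, ...) {
  lt <- unet_layers(object$config)
  npar <- sum(vapply(flatten_params(object$params), length, numeric(1)))
  print.unet(object)
  cat(sprintf("  %d trainable parameters\n", npar))
  print(lt)
  invisible(lt)
}

#' Predict method for U-Net models
#'
#' @param object trained `unet`.
#' @param newdata 2D slice (tiled inference) or `[p, p, n]` patch array.
#' @param ... unused.
#' @return Class-code matrix or array matching `newdata`.
#' @export
predict.unet <- function(object, newdata, ...) {
  if (!object$trained) warning("predicting with an untrained network")
  if (is.matrix(newdata) && !all(dim(newdata) %% 2^(object$config$depth - 1) == 0))
    return(predict_slice(object, newdata))
  if (is.matrix(newdata) && any(dim(newdata) != object$config$in_patch))
    return(predict_slice(object, newdata))
  predict_patches(object, newdata)
}

#' Plot the training loss trace
#'
#' @param x trained `unet`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.unet <- function(x, ...) {
  if (!length(x$loss_trace)) stop("model has no loss trace; train it first")
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "mean cross-entropy loss", ...)
  invisible(x)
}
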