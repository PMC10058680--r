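# Shared fixtures (memoised: built once per test run) and independent
# brute-force oracles used to check the package's implementations.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# noise-free multi-cell phantom with an ROI crop on the central cell
fx_small <- function() fixture("small", {
  spec <- phantom_spec(frame_size = 256, n_slices = 20, n_cells = 4,
                       noise_sigma = 0, seed = 1)
  phantom_roi_and_frame(spec, 128)
})

# default-noise phantom for post-processing / io fixtures
fx_noisy <- function() fixture("noisy", {
  generate_phantom(phantom_spec(frame_size = 256, n_slices = 4, n_cells = 4,
                                seed = 2))
})

# study-scale noise-free ROI (512 px, 40 slices) and its nucleus segmentation
fx_ip_roi <- function() fixture("ip_roi", {
  spec <- phantom_spec(frame_size = 1024, n_slices = 40, n_cells = 4,
                       noise_sigma = 0, seed = 1)
  r <- phantom_roi_and_frame(spec, 512)
  r$frame <- NULL   # keep only the ROI: the full frame is ~0.5 GB of arrays
  r
})

fx_ip_nucleus <- function() fixture("ip_nucleus", {
  segment_nucleus_volume(fx_ip_roi()$roi$image)
})

# a tiny trained network for shape/method tests
fx_tiny_unet <- function() fixture("tiny_unet", {
  ph <- fx_noisy()
  ps <- extract_pairs(ph$image, ph$labels, "1:4", patch = 16)
  cfg <- unet_config(depth = 3, in_patch = 16, base_channels = 4,
                     epochs = 2, batch_size = 8, seed = 5)
  unet_train(materialize_pairs(ps, 1:24), cfg)
})

# ---- oracles ----------------------------------------------------------------

oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] && gt[i, j]) tp <- tp + 1L
    else if (pred[i, j] && !gt[i, j]) fp <- fp + 1L
    else if (!pred[i, j] && gt[i, j]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_window_count <- function(len, patch, stride) {
  n <- 0L
  for (off in 0:(len - patch)) if (off %% stride == 0L) n <- n + 1L
  n
}

# 4-connected component labelling by explicit flood fill
oracle_label <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- nxt
      while (nrow(queue)) {
        q <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r <- q[1] + d[1]; c <- q[2] + d[2]
          if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
              m[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- nxt
            queue <- rbind(queue, c(r, c))
          }
        }
      }
    }
  }
  lab
}

oracle_fill_holes <- function(m) {
  comp <- oracle_label(!m)
  border_ids <- setdiff(unique(c(comp[1, ], comp[nrow(m), ],
                                 comp[, 1], comp[, ncol(m)])), 0L)
  hole <- comp > 0L & !matrix(comp %in% border_ids, nrow(m), ncol(m))
  m | hole
}

oracle_dilate <- function(m, brush) {
  r0 <- (nrow(brush) + 1L) %/% 2L; c0 <- (ncol(brush) + 1L) %/% 2L
  out <- matrix(FALSE, nrow(m), ncol(m))
  offs <- which(brush > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1] - r0; dc <- offs[k, 2] - c0
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    out[rs, cs] <- out[rs, cs] | m[rs - dr, cs - dc]
  }
  out
}

oracle_erode <- function(m, brush) !oracle_dilate(!m, brush)

oracle_clean_class <- function(m, closing_radius, min_area) {
  m <- oracle_fill_holes(m)
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, "disc")
  m <- oracle_erode(oracle_dilate(m, brush), brush)
  lab <- oracle_label(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    for (id in which(areas < min_area)) m[lab == id] <- FALSE
  }
  m
}

# random blob mask with an empty border margin (keeps morphology away from
# image edges, where border conventions could differ between implementations)
random_blob_mask <- function(n = 64, margin = 10, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  sm <- EBImage::filter2(z, helaseg:::gaussian_kernel(3), boundary = "circular")
  m <- sm > stats::quantile(sm, 0.7)
  m[c(seq_len(margin), n - seq_len(margin) + 1L), ] <- FALSE
  m[, c(seq_len(margin), n - seq_len(margin) + 1L)] <- FALSE
  m
}

polygon_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(idx)
  poly <- idx[h, , drop = FALSE]
  abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
            poly[, 2] * c(poly[-1, 1], poly[1, 1]))) / 2
}
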