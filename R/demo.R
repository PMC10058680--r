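# End-to-end demonstration: phantom -> image-processing segmentation ->
# training strategies -> U-Net -> post-processing -> evaluation, at a scale
# that runs on one CPU in minutes.

#' Run the whole framework on a small phantom
#'
#' Generates a multi-cell phantom with ground truth, segments the ROI with
#' the image-processing algorithm, builds reduced-scale training strategies,
#' optionally trains a small U-Net per strategy, post-processes and evaluates
#' everything per slice, and writes CSV metrics and overlay/metric figures.
#' A single seed fans out deterministically to the phantom and training
#' seeds (seed, seed+1, ...), so one value reproduces the whole report.
#'
#' @param seed global seed.
#' @param out_dir report directory (created if needed).
#' @param train train U-Nets (`FALSE` gives an image-processing-only
#'   report).
#' @param strategies which training strategies to exercise.
#' @param frame_size,n_slices,n_cells phantom scale.
#' @param patch patch side for training pairs (divisible by 8).
#' @param max_pairs cap on training pairs per strategy (subsampled
#'   deterministically).
#' @param epochs,base_channels reduced U-Net budget.
#' @return A report list: `pair_counts`, `ip_metrics`, per-strategy
#'   `unet_metrics`, and the output paths. Also written as CSV files under
#'   `out_dir`.
#' @export
run_demo <- function(seed = 7, out_dir = file.path(tempdir(), "helaseg_demo"),
                     train = TRUE,
                     strategies = c("s1_single36k", "s3_multi135k",
                                    "s4_auto135k", "s5_union270k"),
                     frame_size = 256, n_slices = 24, n_cells = 4,
                     patch = 32, max_pairs = 150, epochs = 3,
                     base_channels = 8) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ", as.numeric(
    difftime(Sys.time(), t0, units = "secs"))), sprintf(...))

  log_stage("phantom: frame %d, %d slices, %d cells, seed %d",
            frame_size, n_slices, n_cells, seed)
  spec <- phantom_spec(frame_size = frame_size, n_slices = n_slices,
                       n_cells = n_cells, seed = seed)
  ph <- phantom_roi_and_frame(spec, crop_size = frame_size %/% 2)
  roi <- ph$roi
  gt_single <- single_nucleus_labels(roi$labels, roi$cell_id, ph$center_cell)

  log_stage("image-processing segmentation of the %dpx ROI", frame_size %/% 2)
  nuc3 <- segment_nucleus_volume(roi$image)
  ip_labels <- array(0L, dim(nuc3)); ip_labels[nuc3] <- 3L
  ip_eval <- evaluate_volume(ip_labels, roi$labels,
                             csv = file.path(out_dir, "ip_metrics.csv"),
                             plot = file.path(out_dir, "ip_metrics.png"))

  mid <- ceiling(n_slices / 2)
  rng_central <- sprintf("%d:2:%d", max(1, mid - 6), min(n_slices, mid + 6))
  rng_all <- sprintf("1:2:%d", n_slices)
  inputs <- list(roi_volume = roi$image, roi_labels = roi$labels,
                 roi_labels_single = gt_single, frames = ph$frame$image)
  frame_mid <- unique(round(seq(mid - 2, mid + 2, length.out = 3)))

  sets <- list()
  for (s in strategies) {
    strat <- switch(s,
      s1_single36k = training_strategy("s1_single36k", slice_range = rng_central),
      s2_multi36k = training_strategy("s2_multi36k", slice_range = rng_central),
      s3_multi135k = training_strategy("s3_multi135k", slice_range = rng_all),
      s4_auto135k = training_strategy("s4_auto135k", frame_slices = frame_mid,
                                      n_cells_per_frame = min(3L, n_cells),
                                      crop_size = frame_size %/% 2),
      s5_union270k = training_strategy("s5_union270k", slice_range = rng_all,
                                       frame_slices = frame_mid,
                                       n_cells_per_frame = min(3L, n_cells),
                                       crop_size = frame_size %/% 2))
    sets[[s]] <- suppressMessages(
      build_training_set(strat, inputs, patch = patch))
    log_stage("strategy %s: %d pairs", s, n_pairs(sets[[s]]))
  }
  pair_counts <- vapply(sets, n_pairs, integer(1))

  report <- list(seed = seed, pair_counts = pair_counts,
                 ip_metrics = ip_eval$summaries, out_dir = out_dir)

  if (train) {
    eval_slices <- unique(c(mid - 1, mid, mid + 1))
    unet_metrics <- list()
    for (s in names(sets)) {
      idx <- seq_len(n_pairs(sets[[s]]))
      if (length(idx) > max_pairs)
        idx <- with_seed(seed + 2L, sample(idx, max_pairs))
      mat <- materialize_pairs(sets[[s]], idx)
      cfg <- unet_config(in_patch = patch, base_channels = base_channels,
                         epochs = epochs, batch_size = 16,
                         seed = seed + 1L)
      log_stage("training %s on %d pairs (%d epochs)", s, length(idx), epochs)
      model <- unet_train(mat, cfg)
      pred <- array(0L, c(dim(roi$labels)[1:2], length(eval_slices)))
      for (j in seq_along(eval_slices))
        pred[, , j] <- postprocess_labels(
          predict_slice(model, roi$image[, , eval_slices[j]]))
      ev <- evaluate_volume(pred,
                            unclass(roi$labels)[, , eval_slices, drop = FALSE])
      unet_metrics[[s]] <- ev$summaries
      log_stage("%s: central-slice mean Jaccard %.3f", s,
                ev$summaries$mean_jaccard[1])
      write.csv(ev$per_slice,
                file.path(out_dir, sprintf("unet_%s_metrics.csv", s)),
                row.names = FALSE)
    }
    report$unet_metrics <- unet_metrics
  }

  k <- mid
  write_overlay_png(ip_labels[, , k],
                    file.path(out_dir, "ip_overlay_central.png"),
                    image = roi$image[, , k])
  write.csv(data.frame(strategy = names(pair_counts),
                       pairs = as.integer(pair_counts)),
            file.path(out_dir, "report.csv"), row.names = FALSE)
  log_stage("done; report in %s", out_dir)
  report
}
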