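# Scaled-down training-strategy experiment: does a network trained on
# patches from many cells (with automatically generated labels) segment
# held-out cells at least as well as one trained on the same number of
# patches from a single cell (with manual labels)?

crop_around <- function(arr, center, crop) {
  d <- dim(arr)
  rs <- crop_window(round(center[1]), crop, d[1])
  cs <- crop_window(round(center[2]), crop, d[2])
  list(rows = rs, cols = cs)
}

#' Compare many-cell automatic training against single-cell manual training
#'
#' Generates a multi-cell phantom frame, builds two training sets of equal
#' size — one with patches from several cells labelled automatically by the
#' image-processing algorithm, one with patches from a single cell labelled
#' by ground truth — trains one small U-Net on each, and evaluates the
#' nucleus Jaccard on cells held out from both training sets.
#'
#' @param seed seed for the phantom and both trainings.
#' @param frame_size,n_slices,n_cells phantom frame scale.
#' @param crop_size crop side around each cell, px.
#' @param patch patch side for training pairs (divisible by 8).
#' @param train_cells cells contributing to the many-cell set.
#' @param single_cell the cell providing the single-cell set.
#' @param holdout_cells cells used only for evaluation.
#' @param epochs,base_channels,batch_size U-Net training budget.
#' @return List with `jaccard_multi`, `jaccard_single` (mean nucleus Jaccard
#'   over held-out cells), `n_pairs` per set, and the per-cell Jaccards.
#' @export
compare_training_sources <- function(seed = 1, frame_size = 512,
                                     n_slices = 8, n_cells = 6,
                                     crop_size = 128, patch = 64,
                                     train_cells = 1:4, single_cell = 1L,
                                     holdout_cells = 5:6, epochs = 12,
                                     base_channels = 8, batch_size = 8) {
  spec <- phantom_spec(frame_size = frame_size, n_slices = n_slices,
                       n_cells = n_cells, seed = seed)
  ph <- generate_phantom(spec)
  img <- unclass(ph$image); lab <- unclass(ph$labels)
  k0 <- ceiling(n_slices / 2)

  pairs_from_crop <- function(cell, slices, labeller) {
    w <- crop_around(img, ph$centers[cell, ], crop_size)
    sub_img <- img[w$rows, w$cols, slices, drop = FALSE]
    sub_lab <- switch(labeller,
      manual = lab[w$rows, w$cols, slices, drop = FALSE],
      automatic = unclass(segment_cell_roi(sub_img)))
    extract_pairs(volume_stack(sub_img), label_volume(sub_lab),
                  seq_along(slices), patch = patch,
                  source = sprintf("%s_c%d", labeller, cell))
  }

  multi <- Reduce(concat_pairs, lapply(train_cells, function(i)
    pairs_from_crop(i, k0:(k0 + 1L), "automatic")))
  single <- pairs_from_crop(single_cell,
                            seq_len(2L * length(train_cells)), "manual")
  stopifnot(n_pairs(multi) == n_pairs(single))

  cfg <- unet_config(in_patch = patch, base_channels = base_channels,
                     epochs = epochs, batch_size = batch_size, seed = seed)
  m_multi <- unet_train(materialize_pairs(multi), cfg)
  m_single <- unet_train(materialize_pairs(single), cfg)

  eval_model <- function(model) {
    vapply(holdout_cells, function(cell) {
      w <- crop_around(img, ph$centers[cell, ], crop_size)
      pred <- predict_slice(model, img[w$rows, w$cols, k0])
      gt <- lab[w$rows, w$cols, k0] == 3L &
        ph$cell_id[w$rows, w$cols, k0] == cell
      volume_jaccard(pred == 3L, gt)
    }, numeric(1))
  }
  jm <- eval_model(m_multi)
  js <- eval_model(m_single)
  list(jaccard_multi = mean(jm), jaccard_single = mean(js),
       per_cell_multi = jm, per_cell_single = js,
       n_pairs = n_pairs(multi))
}
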