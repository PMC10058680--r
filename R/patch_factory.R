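# Training-pair construction: sliding 128x128 windows with 50% overlap over
# selected slices, under five strategies differing in slice range, ground-
# truth source (manual, automatic, union) and ground-truth variant.

#' Sliding-window grid offsets along one axis
#'
#' Offsets are 0-based: `0, stride, ...`, keeping only windows that fit
#' entirely (`offset + patch <= length`); partial trailing windows are
#' dropped. A 2000 px side at patch 128 / stride 64 yields 30 offsets.
#'
#' @param length axis length in px.
#' @param patch window size in px.
#' @param stride step between windows in px.
#' @return Integer vector of 0-based offsets.
#' @export
grid_positions <- function(length, patch, stride) {
  if (patch > length) stop("parameter error: patch larger than the axis")
  if (stride < 1) stop("parameter error: stride must be >= 1")
  seq.int(0L, by = as.integer(stride), length.out = (length - patch) %/% stride + 1L)
}

#' Enumerate aligned image/label patch pairs over a stack
#'
#' Builds the full 2D grid of patch windows on each listed slice. The result
#' is a lazy `patch_set`: a manifest of window origins plus references to the
#' source volumes; pixel data are materialised on demand with
#' [materialize_pairs()].
#'
#' @param volume `VolumeStack`.
#' @param labels `LabelVolume`, congruent with `volume`.
#' @param slice_range slice-range text (see [parse_slice_range()]) or integer
#'   vector of 1-based slice indices.
#' @param patch patch side in px.
#' @param overlap fractional window overlap; 0.5 gives stride `patch/2`.
#' @param source free-text provenance tag stored per pair.
#' @return A `patch_set` with elements `manifest` (data.frame: `slice`,
#'   `row`, `col` 0-based offsets, `source`, `strategy`), `volume`, `labels`,
#'   `patch`.
#' @export
extract_pairs <- function(volume, labels, slice_range, patch = 128L,
                          overlap = 0.5, source = "manual") {
  if (!all(dim(volume) == dim(labels)))
    stop("dimension error: volume and labels are not congruent")
  slices <- parse_slice_range(slice_range)
  if (any(slices < 1L | slices > dim(volume)[3]))
    stop("bounds error: slice index outside the stack")
  stride <- as.integer(round(patch * (1 - overlap)))
  ro <- grid_positions(dim(volume)[1], patch, stride)
  co <- grid_positions(dim(volume)[2], patch, stride)
  g <- expand.grid(row = ro, col = co, slice = slices)
  manifest <- data.frame(slice = g$slice, row = g$row, col = g$col,
                         source = source, strategy = NA_character_,
                         stringsAsFactors = FALSE)
  structure(list(manifest = manifest, volume = volume, labels = labels,
                 patch = as.integer(patch)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d pairs of %dx%d patches (%s)\n",
              nrow(x$manifest), x$patch, x$patch,
              paste(unique(x$manifest$source), collapse = "+")))
  invisible(x)
}

#' Number of pairs in a patch set
#' @param pairs a `patch_set`.
#' @return Integer pair count.
#' @export
n_pairs <- function(pairs) nrow(pairs$manifest)

#' Materialise patch pixel data
#'
#' @param pairs a `patch_set`.
#' @param idx which pairs (row indices of the manifest); default all.
#' @return List with `images` and `labels`, arrays `[patch, patch, n]`, and
#'   the corresponding `manifest` rows.
#' @export
materialize_pairs <- function(pairs, idx = seq_len(n_pairs(pairs))) {
  p <- pairs$patch
  n <- length(idx)
  imgs <- array(0, c(p, p, n)); labs <- array(0L, c(p, p, n))
  vol <- pairs$volume
  for (j in seq_len(n)) {
    m <- pairs$manifest[idx[j], ]
    rs <- (m$row + 1L):(m$row + p); cs <- (m$col + 1L):(m$col + p)
    src <- if (is.list(vol)) vol[[m$source]] else vol
    lsrc <- if (is.list(pairs$labels)) pairs$labels[[m$source]] else pairs$labels
    imgs[, , j] <- src[rs, cs, m$slice]
    labs[, , j] <- lsrc[rs, cs, m$slice]
  }
  list(images = imgs, labels = labs, manifest = pairs$manifest[idx, ])
}

concat_pairs <- function(a, b) {
  stopifnot(a$patch == b$patch)
  va <- if (is.list(a$volume)) a$volume else setNames(list(a$volume),
                                                     unique(a$manifest$source))
  vb <- if (is.list(b$volume)) b$volume else setNames(list(b$volume),
                                                     unique(b$manifest$source))
  la <- if (is.list(a$labels)) a$labels else setNames(list(a$labels),
                                                     unique(a$manifest$source))
  lb <- if (is.list(b$labels)) b$labels else setNames(list(b$labels),
                                                     unique(b$manifest$source))
  structure(list(manifest = rbind(a$manifest, b$manifest),
                 volume = c(va, vb), labels = c(la, lb), patch = a$patch),
            class = "patch_set")
}

#' Named training strategies
#'
#' The five recipes differ in slice range, ground-truth source and variant:
#' \describe{
#'   \item{s1_single36k}{manual GT, single-nucleus variant, alternate central
#'     slices (101:2:180 at full scale).}
#'   \item{s2_multi36k}{manual GT, multi-nuclei variant, same slices.}
#'   \item{s3_multi135k}{manual GT, multi-nuclei, every other slice of the
#'     whole stack (1:2:300).}
#'   \item{s4_auto135k}{automatic GT from the image-processing algorithm on
#'     cell crops detected in full frames (10 cells x 15 frames).}
#'   \item{s5_union270k}{union of s3 and s4.}
#' }
#'
#' @param name strategy name.
#' @param slice_range override the recipe's slice range (needed when the
#'   stack is smaller than the full-scale study).
#' @param frame_slices for s4/s5: 1-based indices of the frames to crop from.
#' @param n_cells_per_frame for s4/s5: seeds per frame.
#' @param crop_size for s4/s5: crop side in px.
#' @return A `training_strategy` list.
#' @export
training_strategy <- function(name = c("s1_single36k", "s2_multi36k",
                                       "s3_multi135k", "s4_auto135k",
                                       "s5_union270k"),
                              slice_range = NULL, frame_slices = NULL,
                              n_cells_per_frame = 10L, crop_size = 2000L) {
  name <- match.arg(name)
  defaults <- list(
    s1_single36k = list(slice_range = "101:2:180", gt_source = "manual",
                        gt_variant = "single-nucleus"),
    s2_multi36k = list(slice_range = "101:2:180", gt_source = "manual",
                       gt_variant = "multi-nuclei"),
    s3_multi135k = list(slice_range = "1:2:300", gt_source = "manual",
                        gt_variant = "multi-nuclei"),
    s4_auto135k = list(slice_range = "230:10:370", gt_source = "automatic",
                       gt_variant = "multi-nuclei"),
    s5_union270k = list(slice_range = NULL, gt_source = "union",
                        gt_variant = "multi-nuclei"))
  rec <- defaults[[name]]
  structure(list(name = name,
                 slice_range = if (is.null(slice_range)) rec$slice_range
                               else slice_range,
                 gt_source = rec$gt_source, gt_variant = rec$gt_variant,
                 frame_slices = frame_slices,
                 n_cells_per_frame = as.integer(n_cells_per_frame),
                 crop_size = as.integer(crop_size)),
            class = "training_strategy")
}

#' Pair-count arithmetic of a strategy at full study scale
#'
#' Pure window arithmetic: pairs = slices x (grid per side)^2 for the
#' manual-GT strategies, crops x cells x frames x (grid per side)^2 for the
#' automatic one, and the sum of both for the union.
#'
#' @param name strategy name (see [training_strategy()]).
#' @param roi_side ROI slice side, px.
#' @param patch,stride window geometry, px.
#' @param n_frames,n_cells frames and seeds per frame of the automatic
#'   strategy.
#' @param crop_size crop side of the automatic strategy, px.
#' @return Integer pair count.
#' @export
strategy_pair_count <- function(name, roi_side = 2000L, patch = 128L,
                                stride = 64L, n_frames = 15L, n_cells = 10L,
                                crop_size = 2000L) {
  g_roi <- length(grid_positions(roi_side, patch, stride))
  g_crop <- length(grid_positions(crop_size, patch, stride))
  strat <- training_strategy(name)
  manual <- function(s) {
    slices <- length(parse_slice_range(training_strategy(s)$slice_range))
    slices * g_roi^2
  }
  switch(strat$name,
         s1_single36k = manual("s1_single36k"),
         s2_multi36k = manual("s2_multi36k"),
         s3_multi135k = manual("s3_multi135k"),
         s4_auto135k = n_frames * n_cells * g_crop^2,
         s5_union270k = manual("s3_multi135k") + n_frames * n_cells * g_crop^2)
}

crop_window <- function(center, crop, limit) {
  half <- crop %/% 2
  r0 <- min(max(center - half, 1L), limit - crop + 1L)
  r0:(r0 + crop - 1L)
}

build_auto_pairs <- function(frames, strategy, patch, overlap, params) {
  crop <- strategy$crop_size
  d <- dim(frames)
  slices <- if (is.null(strategy$frame_slices)) seq_len(d[3])
            else strategy$frame_slices
  sets <- list()
  for (k in slices) {
    seeds <- suppressWarnings(
      detect_cells(frames[, , k], n = strategy$n_cells_per_frame,
                   crop_size = crop, params = params))
    if (nrow(seeds) < strategy$n_cells_per_frame)
      message(sprintf("frame %d: only %d of %d cells detected",
                      k, nrow(seeds), strategy$n_cells_per_frame))
    for (i in seq_len(nrow(seeds))) {
      rs <- crop_window(seeds$row[i], crop, d[1])
      cs <- crop_window(seeds$col[i], crop, d[2])
      img <- frames[rs, cs, k, drop = FALSE]
      auto <- segment_cell_roi(img[, , 1], params)
      tag <- sprintf("auto_f%d_c%d", k, i)
      ps <- extract_pairs(volume_stack(img), auto, 1L, patch = patch,
                          overlap = overlap, source = tag)
      ps$volume <- setNames(list(ps$volume), tag)
      ps$labels <- setNames(list(ps$labels), tag)
      sets[[length(sets) + 1L]] <- ps
    }
  }
  if (!length(sets)) stop("configuration error: no cells detected in any frame")
  Reduce(concat_pairs, sets)
}

#' Build the training-pair set of a strategy
#'
#' @param strategy a [training_strategy()].
#' @param inputs list with, as the strategy requires: `roi_volume`,
#'   `roi_labels` (multi-nuclei manual GT), `roi_labels_single`
#'   (single-nucleus variant), `frames` (full-frame `VolumeStack` for the
#'   automatic strategy).
#' @param patch,overlap window geometry.
#' @param params [ip_params()] for the automatic labelling.
#' @return A `patch_set`; its manifest records provenance per pair.
#' @export
build_training_set <- function(strategy, inputs, patch = 128L, overlap = 0.5,
                               params = ip_params()) {
  stopifnot(inherits(strategy, "training_strategy"))
  out <- switch(
    strategy$gt_source,
    manual = {
      labs <- if (strategy$gt_variant == "single-nucleus") {
        if (is.null(inputs$roi_labels_single))
          stop("configuration error: single-nucleus GT variant missing")
        inputs$roi_labels_single
      } else {
        if (is.null(inputs$roi_labels))
          stop("configuration error: multi-nuclei GT missing")
        inputs$roi_labels
      }
      extract_pairs(inputs$roi_volume, labs, strategy$slice_range,
                    patch = patch, overlap = overlap, source = "manual")
    },
    automatic = {
      if (is.null(inputs$frames))
        stop("configuration error: full frames required for automatic GT")
      build_auto_pairs(inputs$frames, strategy, patch, overlap, params)
    },
    union = {
      s3 <- training_strategy("s3_multi135k",
                              slice_range = strategy$slice_range)
      s4 <- training_strategy("s4_auto135k",
                              frame_slices = strategy$frame_slices,
                              n_cells_per_frame = strategy$n_cells_per_frame,
                              crop_size = strategy$crop_size)
      concat_pairs(build_training_set(s3, inputs, patch, overlap, params),
                   build_training_set(s4, inputs, patch, overlap, params))
    })
  out$manifest$strategy <- strategy$name
  out
}

#' Write a patch set to disk as paired PNGs plus a CSV manifest
#'
#' @param pairs a `patch_set`.
#' @param dir output directory.
#' @return The manifest data.frame (with file columns), invisibly.
#' @export
write_pairs <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat <- materialize_pairs(pairs)
  man <- pairs$manifest
  man$file_image <- sprintf("pair_%06d_img.png", seq_len(nrow(man)))
  man$file_label <- sprintf("pair_%06d_lab.png", seq_len(nrow(man)))
  for (j in seq_len(nrow(man))) {
    png::writePNG(mat$images[, , j] / 255, file.path(dir, man$file_image[j]))
    png::writePNG(mat$labels[, , j] / 255, file.path(dir, man$file_label[j]))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
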