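# Per-slice evaluation against ground truth: confusion counts, accuracy
# (TP+TN)/(TP+TN+FP+FN) and Jaccard TP/(TP+FP+FN) on the binary nucleus mask,
# with slice-range aggregation and optional CSV/plot export.

#' Pixel confusion counts of two binary masks
#'
#' @param pred,gt congruent logical masks (prediction and ground truth).
#' @return Named integer vector `(TP, TN, FP, FN)`; the four counts always
#'   sum to the pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("dimension error: masks are not congruent")
  p <- as.logical(pred); g <- as.logical(gt)
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  c(TP = tp, TN = length(p) - tp - fp - fn, FP = fp, FN = fn)
}

slice_metrics_row <- function(slice, cc) {
  denom_j <- cc["TP"] + cc["FP"] + cc["FN"]
  data.frame(slice = slice, TP = cc["TP"], TN = cc["TN"], FP = cc["FP"],
             FN = cc["FN"],
             accuracy = (cc["TP"] + cc["TN"]) / sum(cc),
             jaccard = if (denom_j == 0) NA_real_ else cc["TP"] / denom_j,
             row.names = NULL)
}

binary_class_mask <- function(labels, positive) {
  if (identical(positive, "nucleus")) labels == 3L
  else if (identical(positive, "nucleus+envelope")) labels >= 2L
  else labels == as.integer(positive)
}

#' Per-slice accuracy and Jaccard of a predicted label volume
#'
#' Metrics are computed on the binary nucleus mask (nucleus class versus all
#' others; the envelope is excluded from the positive set by default).
#' Slices where both prediction and ground truth are empty get an undefined
#' (`NA`) Jaccard and accuracy 1; undefined slices are excluded from range
#' means, while slices with a non-empty ground truth but empty prediction
#' score 0.
#'
#' @param pred,gt congruent `LabelVolume`s (or 3D arrays of class codes).
#' @param positive `"nucleus"` (default), `"nucleus+envelope"`, or a class
#'   code.
#' @param ranges named list of slice-range strings to average over; ranges
#'   extending beyond the stack are dropped. Defaults to all slices plus the
#'   study's central ranges when the stack is deep enough.
#' @param csv,plot optional output paths for a per-slice CSV and an
#'   accuracy/Jaccard-versus-slice PNG.
#' @return List with `per_slice` (data.frame: slice, TP, TN, FP, FN,
#'   accuracy, jaccard) and `summaries` (data.frame: range, mean_accuracy,
#'   mean_jaccard, n_slices).
#' @export
evaluate_volume <- function(pred, gt, positive = "nucleus", ranges = NULL,
                            csv = NULL, plot = NULL) {
  pa <- unclass(pred); ga <- unclass(gt)
  if (length(dim(pa)) == 2L) dim(pa) <- c(dim(pa), 1L)
  if (length(dim(ga)) == 2L) dim(ga) <- c(dim(ga), 1L)
  if (!all(dim(pa) == dim(ga)))
    stop("dimension error: prediction and ground truth differ in shape")
  nz <- dim(pa)[3]
  per <- do.call(rbind, lapply(seq_len(nz), function(k)
    slice_metrics_row(k, confusion_counts(
      binary_class_mask(pa[, , k], positive),
      binary_class_mask(ga[, , k], positive)))))
  if (is.null(ranges)) {
    ranges <- list(all = sprintf("1:%d", nz))
    if (nz >= 300) ranges <- c(ranges,
                               list(`150:200` = "150:200", `60:150` = "60:150"))
  }
  summaries <- do.call(rbind, lapply(names(ranges), function(nm) {
    sl <- tryCatch(parse_slice_range(ranges[[nm]]), error = function(e) NULL)
    if (is.null(sl) || any(sl > nz)) return(NULL)
    sub <- per[per$slice %in% sl, ]
    data.frame(range = nm,
               mean_accuracy = mean(sub$accuracy),
               mean_jaccard = mean(sub$jaccard, na.rm = TRUE),
               n_slices = nrow(sub))
  }))
  if (!is.null(csv)) write.csv(per, csv, row.names = FALSE)
  if (!is.null(plot)) {
    grDevices::png(plot, width = 900, height = 450)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2))
    graphics::plot(per$slice, per$accuracy, type = "l", ylim = c(0, 1),
                   xlab = "slice", ylab = "accuracy")
    graphics::plot(per$slice, per$jaccard, type = "l", ylim = c(0, 1),
                   xlab = "slice", ylab = "Jaccard index")
  }
  list(per_slice = per, summaries = summaries)
}

#' Per-class Jaccard indices of two label volumes
#'
#' @param pred,gt congruent label volumes or matrices.
#' @return Named numeric vector of Jaccard indices for the four classes
#'   (NA where a class is absent from both).
#' @export
class_jaccard <- function(pred, gt) {
  pa <- as.integer(unclass(pred)); ga <- as.integer(unclass(gt))
  out <- vapply(CLASS_CODES, function(k) {
    inter <- sum(pa == k & ga == k)
    un <- sum(pa == k | ga == k)
    if (un == 0) NA_real_ else inter / un
  }, numeric(1))
  setNames(out, names(CLASS_CODES))
}

#' Volume-wise Jaccard of a binary mask pair
#'
#' @param pred,gt congruent logical arrays.
#' @return `TP / (TP + FP + FN)` pooled over all voxels.
#' @export
volume_jaccard <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  denom <- cc["TP"] + cc["FP"] + cc["FN"]
  unname(if (denom == 0) NA_real_ else cc["TP"] / denom)
}
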