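# Class-wise cleanup of predicted label maps: per-class hole filling, disk
# closing and small-region removal, an envelope-repair step bridging nucleus
# and cell, and aggregation back to a total 4-class labelling.

as_mask <- function(x) {
  m <- as.logical(x)
  dim(m) <- dim(x)[1:2]
  m
}

bin_op <- function(x) matrix(as.logical(x), nrow(x), ncol(x))

#' Post-processing parameters
#'
#' @param closing_radius disk radius (px) of the per-class closing.
#' @param min_area components smaller than this (strictly) are removed;
#'   `NULL` scales `min_area_frac` with the slice area (3200 px on a
#'   2000x2000 slice).
#' @param min_area_frac fraction of the slice area used when `min_area` is
#'   `NULL` (default 0.08\%).
#' @param envelope_dilation_radius dilation radius (px) of the
#'   envelope-repair step; defaults to `closing_radius`.
#' @return A `postprocess_params` list.
#' @export
postprocess_params <- function(closing_radius = 3, min_area = NULL,
                               min_area_frac = 8e-4,
                               envelope_dilation_radius = closing_radius) {
  stopifnot(closing_radius >= 0, envelope_dilation_radius >= 0,
            min_area_frac >= 0, is.null(min_area) || min_area >= 0)
  structure(list(closing_radius = closing_radius, min_area = min_area,
                 min_area_frac = min_area_frac,
                 envelope_dilation_radius = envelope_dilation_radius),
            class = "postprocess_params")
}

resolved_min_area <- function(params, dims) {
  if (!is.null(params$min_area)) return(params$min_area)
  round(params$min_area_frac * prod(dims[1:2]))
}

#' Clean one binary class mask
#'
#' Hole filling, closing with a disk structural element, then removal of
#' connected components with area strictly below `min_area`.
#'
#' @param mask logical matrix.
#' @param params [postprocess_params()].
#' @param fill_holes apply the hole-filling step.
#' @return Cleaned logical matrix.
#' @export
clean_class <- function(mask, params = postprocess_params(),
                        fill_holes = TRUE) {
  m <- bin_op(mask)
  if (!any(m)) return(m)
  if (fill_holes) m <- bin_op(EBImage::fillHull(m))
  if (params$closing_radius > 0)
    m <- bin_op(EBImage::closing(m, disc_brush(params$closing_radius)))
  min_area <- resolved_min_area(params, dim(m))
  if (min_area > 0) {
    lab <- EBImage::bwlabel(m)
    nl <- max(lab)
    if (nl > 0) {
      areas <- tabulate(lab[lab > 0], nbins = nl)
      drop <- which(areas < min_area)
      if (length(drop)) {
        flag <- logical(nl + 1L)
        flag[drop + 1L] <- TRUE
        m[matrix(flag[lab + 1L], nrow(m), ncol(m))] <- FALSE
      }
    }
  }
  m
}

#' Repair small discontinuities of the nuclear envelope
#'
#' Dilates the nucleus and cell masks and adds their overlap to the envelope,
#' closing small gaps where nucleus and cell (almost) touch.
#'
#' @param nucleus,cell,envelope congruent logical masks.
#' @param params [postprocess_params()].
#' @return Repaired envelope mask.
#' @export
repair_envelope <- function(nucleus, cell, envelope,
                            params = postprocess_params()) {
  r <- params$envelope_dilation_radius
  if (r == 0 || !any(nucleus) || !any(cell)) return(bin_op(envelope))
  br <- disc_brush(r)
  bin_op(envelope) |
    (bin_op(EBImage::dilate(bin_op(nucleus), br)) &
     bin_op(EBImage::dilate(bin_op(cell), br)))
}

#' Post-process a predicted 4-class label map
#'
#' Each class is cleaned separately (the background without hole filling,
#' since its holes are the cells), the envelope is repaired from the dilated
#' nucleus/cell overlap, and the cleaned masks are aggregated with precedence
#' nucleus > envelope > cell > background; pixels claimed by no cleaned mask
#' keep their original class, so the output is a total labelling.
#'
#' @param labels 2D (or one-slice 3D) class map over the 4-code alphabet.
#' @param params [postprocess_params()].
#' @return Integer class map of the same 2D shape.
#' @export
postprocess_labels <- function(labels, params = postprocess_params()) {
  if (length(dim(labels)) == 3L) {
    if (dim(labels)[3] != 1L) {
      out <- unclass(labels)
      for (k in seq_len(dim(labels)[3]))
        out[, , k] <- postprocess_labels(out[, , k], params)
      return(label_volume(out))
    }
    labels <- labels[, , 1L]
  }
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  bg <- clean_class(lab == 0L, params, fill_holes = FALSE)
  cell <- clean_class(lab == 1L, params)
  nuc <- clean_class(lab == 3L, params)
  env <- repair_envelope(nuc, cell, lab == 2L, params)
  out <- lab
  out[bg] <- 0L
  out[cell] <- 1L
  out[env] <- 2L
  out[nuc] <- 3L
  out
}
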