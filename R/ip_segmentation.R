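# Traditional image-processing segmentation: per-slice Canny edges ->
# edge-complement superpixels -> morphological region selection, propagated
# outward from the central slice; plus background segmentation, distance-
# transform cell detection and automatic 4-class labelling of cell crops.

#' Parameters of the image-processing segmentation algorithm
#'
#' Defaults are stated for a 2000x2000 region of interest; the area-like
#' parameters (`min_area`, `min_hole`) and the prior dilation radius scale
#' with the actual slice side when left `NULL`.
#'
#' @param sigma Gaussian low-pass sigma (px) applied before edge detection.
#' @param low_frac Canny low hysteresis threshold as a fraction of the high
#'   threshold; the high threshold is the Otsu split of the gradient
#'   magnitudes.
#' @param min_area discard superpixels smaller than this (px); `NULL` scales
#'   500 px at side 2000 by `(side/2000)^2`.
#' @param prior_dilate dilation radius (px) applied to the neighbouring
#'   slice's mask before the overlap test, a tolerance for slice-to-slice
#'   misalignment. Default 0: a region is kept when most of it lies inside
#'   the previous mask itself; any positive radius progressively admits the
#'   bands adjacent to the nucleus and makes the propagated mask creep
#'   outward.
#' @param prior_overlap keep a region when its overlap with the dilated prior
#'   exceeds this fraction of the region's area.
#' @param min_width_px discard candidate regions thinner than this half-width
#'   (they vanish under a disk erosion of this radius): thin strips between
#'   parallel edge lines — the dark envelope band, double-edge slivers — are
#'   boundary artifacts, not nucleus interior.
#' @param close_radius disk radius (px) of the closing that smooths the
#'   selected nucleus region.
#' @param edge_compensation_px dilation (px) applied to the selected region
#'   before smoothing: superpixels are the complement of the drawn edge
#'   lines, so each region is eroded by about the edge width relative to the
#'   true partition; this restores it.
#' @param bg_sigma Gaussian sigma (px) of the smoothing before the Otsu
#'   background threshold.
#' @param min_hole_frac holes in the background mask smaller than this
#'   fraction of the slice area are absorbed into the background
#'   (1e4 px on an 8192x8192 frame).
#' @param envelope_px width (px) of the nuclear-envelope band grown outward
#'   from the nucleus mask when building automatic labels.
#' @return An `ip_params` list.
#' @export
ip_params <- function(sigma = 2, low_frac = 0.4, min_area = NULL,
                      prior_dilate = NULL, prior_overlap = 0.5,
                      min_width_px = 3,
                      close_radius = 5, edge_compensation_px = 2,
                      bg_sigma = 8, min_hole_frac = 1e4 / 8192^2,
                      envelope_px = 5) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, low_frac = low_frac, min_area = min_area,
                 prior_dilate = prior_dilate, prior_overlap = prior_overlap,
                 min_width_px = min_width_px,
                 close_radius = close_radius,
                 edge_compensation_px = edge_compensation_px,
                 bg_sigma = bg_sigma,
                 min_hole_frac = min_hole_frac, envelope_px = envelope_px),
            class = "ip_params")
}

scaled_min_area <- function(p, d) {
  if (!is.null(p$min_area)) return(p$min_area)
  side <- sqrt(prod(d[1:2]))
  max(4, round(500 * (side / 2000)^2))
}

scaled_prior_dilate <- function(p, d) {
  if (!is.null(p$prior_dilate)) return(p$prior_dilate)
  0L
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

as_slice <- function(x) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L) stop("expected a single 2D slice")
    x <- x[, , 1L]
  }
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Gaussian low-pass denoising of one slice
#'
#' @param slice 2D intensity matrix.
#' @param sigma Gaussian sigma in px; 0 returns the input unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
denoise <- function(slice, sigma = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  x <- as_slice(slice)
  if (sigma == 0) return(x)
  EBImage::filter2(x, gaussian_kernel(sigma), boundary = "replicate")
}

shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantised gradient
#' direction, and hysteresis linking. The high threshold is derived
#' automatically as the Otsu split of the gradient-magnitude distribution and
#' the low threshold as `low_frac` times the high one.
#'
#' @param slice 2D intensity matrix (already denoised).
#' @param low_frac low/high hysteresis threshold ratio.
#' @return Logical edge map of the same shape.
#' @export
detect_edges <- function(slice, low_frac = 0.4) {
  x <- as_slice(slice)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gc <- EBImage::filter2(x, sx, boundary = "replicate")      # d/d(col)
  gr <- EBImage::filter2(x, t(sx), boundary = "replicate")   # d/d(row)
  mag <- sqrt(gc^2 + gr^2)
  mx <- max(mag)
  if (mx < 1e-9) return(matrix(FALSE, nrow(x), ncol(x)))

  # non-maximum suppression against the bilinearly interpolated magnitude one
  # step along the gradient direction on either side (single-pixel ridges)
  safe <- pmax(mag, 1e-12)
  ur <- gr / safe; uc <- gc / safe
  wr <- abs(ur); wc <- abs(uc)
  sr <- ifelse(ur >= 0, 1L, -1L); sc <- ifelse(uc >= 0, 1L, -1L)
  Sp0 <- shift_mat(mag, 1, 0); Sn0 <- shift_mat(mag, -1, 0)
  S0p <- shift_mat(mag, 0, 1); S0n <- shift_mat(mag, 0, -1)
  Spp <- shift_mat(mag, 1, 1); Spn <- shift_mat(mag, 1, -1)
  Snp <- shift_mat(mag, -1, 1); Snn <- shift_mat(mag, -1, -1)
  pick <- function(dr, dc) {
    A <- ifelse(dr > 0, Sp0, Sn0)                       # (sign_r, 0)
    B <- ifelse(dc > 0, S0p, S0n)                       # (0, sign_c)
    C <- ifelse(dr > 0, ifelse(dc > 0, Spp, Spn),
                ifelse(dc > 0, Snp, Snn))               # (sign_r, sign_c)
    (1 - wr) * (1 - wc) * mag + (1 - wr) * wc * B +
      wr * (1 - wc) * A + wr * wc * C
  }
  nms <- mag >= pick(sr, sc) & mag >= pick(-sr, -sc) & mag > 0

  high <- EBImage::otsu(mag / mx, range = c(0, 1)) * mx
  low <- low_frac * high
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  weak <- nms & mag >= low
  # hysteresis: keep weak chains connected (8-ish connectivity via a 3x3
  # dilation bridge) to at least one strong pixel
  lab <- EBImage::bwlabel(EBImage::dilate(weak, matrix(1L, 3, 3)))
  lab[!weak] <- 0
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  flag <- logical(max(lab) + 1L)
  flag[keep_ids + 1L] <- TRUE
  weak & flag[lab + 1L]
}

#' Superpixels as connected components of the edge complement
#'
#' @param edges logical edge map.
#' @return Integer matrix of region labels (contiguous from 1); edge pixels
#'   carry label 0.
#' @export
superpixels_from_edges <- function(edges) {
  lab <- EBImage::bwlabel(!edges)
  storage.mode(lab) <- "integer"
  matrix(lab, nrow(edges), ncol(edges))
}

region_centroids <- function(spx, ids) {
  idx <- which(spx > 0)
  lab <- spx[idx]
  rows <- ((idx - 1L) %% nrow(spx)) + 1L
  cols <- ((idx - 1L) %/% nrow(spx)) + 1L
  cbind(rowsum(rows, lab)[as.character(ids), 1] / tabulate(lab)[ids],
        rowsum(cols, lab)[as.character(ids), 1] / tabulate(lab)[ids])
}

#' Select the nucleus region among superpixels
#'
#' Discards regions smaller than `min_area` or touching the image border;
#' with a `prior` (the neighbouring slice's nucleus mask) keeps every region
#' whose overlap with the dilated prior exceeds half the region's area,
#' otherwise keeps the region whose centroid is closest to the image centre.
#' The selection is smoothed by a disk closing and hole filling.
#'
#' @param spx superpixel label matrix.
#' @param prior optional logical mask from the neighbouring slice.
#' @param params [ip_params()].
#' @return Logical nucleus mask (all-`FALSE` when no region survives,
#'   signalling that the nucleus is absent at this slice).
#' @export
select_nucleus_region <- function(spx, prior = NULL, params = ip_params()) {
  d <- dim(spx)
  min_area <- scaled_min_area(params, d)
  nreg <- max(spx)
  empty <- matrix(FALSE, d[1], d[2])
  if (nreg == 0L) return(empty)
  areas <- tabulate(spx[spx > 0L], nbins = nreg)
  border <- unique(c(spx[1, ], spx[d[1], ], spx[, 1], spx[, d[2]]))
  ok <- setdiff(which(areas >= min_area), border)
  if (!length(ok)) return(empty)
  if (params$min_width_px > 0) {
    flag <- logical(nreg + 1L)
    flag[ok + 1L] <- TRUE
    cand <- flag[spx + 1L]
    dim(cand) <- d
    core <- EBImage::erode(cand, disc_brush(params$min_width_px))
    thick <- unique(spx[core > 0])
    ok <- intersect(ok, thick)
    if (!length(ok)) return(empty)
  }

  if (!is.null(prior)) {
    if (!any(prior)) return(empty)
    pd <- scaled_prior_dilate(params, d)
    dp <- if (pd > 0) bin_op(EBImage::dilate(bin_op(prior), disc_brush(pd)))
          else bin_op(prior)
    ov <- tabulate(spx[dp & spx > 0L], nbins = nreg)
    chosen <- ok[ov[ok] > params$prior_overlap * areas[ok]]
  } else {
    # the central region: the one containing the image-centre pixel when it
    # survives the filters, else the surviving region of nearest centroid
    at_center <- spx[ceiling(d[1] / 2), ceiling(d[2] / 2)]
    if (at_center %in% ok) {
      chosen <- at_center
    } else {
      cen <- region_centroids(spx, ok)
      dist2 <- (cen[, 1] - (d[1] + 1) / 2)^2 + (cen[, 2] - (d[2] + 1) / 2)^2
      chosen <- ok[which.min(dist2)]
    }
  }
  if (!length(chosen)) return(empty)
  flag <- logical(nreg + 1L)
  flag[chosen + 1L] <- TRUE
  mask <- flag[spx + 1L]
  dim(mask) <- d
  if (params$edge_compensation_px > 0)
    mask <- EBImage::dilate(mask, disc_brush(params$edge_compensation_px))
  mask <- EBImage::closing(mask, disc_brush(params$close_radius))
  matrix(as.logical(EBImage::fillHull(mask)), d[1], d[2])
}

segment_nucleus_slice <- function(slice, prior, params) {
  sm <- denoise(slice, params$sigma)
  edges <- detect_edges(sm, params$low_frac)
  spx <- superpixels_from_edges(edges)
  select_nucleus_region(spx, prior, params)
}

#' Segment the nucleus through a region-of-interest stack
#'
#' Runs the per-slice pipeline (denoise, Canny edges, superpixels, region
#' selection) starting at the central slice and propagating outward, each
#' slice's mask serving as the prior of its neighbour. Disjoint nucleus
#' fragments are retained through the prior-overlap rule.
#'
#' @param roi `VolumeStack` (one cell roughly centred).
#' @param params [ip_params()].
#' @return Logical 3D nucleus mask of the ROI's shape.
#' @export
segment_nucleus_volume <- function(roi, params = ip_params()) {
  d <- dim(roi)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("dimension error: expected a non-empty 3D stack")
  out <- array(FALSE, d)
  k0 <- ceiling(d[3] / 2)
  out[, , k0] <- segment_nucleus_slice(roi[, , k0], NULL, params)
  if (k0 < d[3]) for (k in (k0 + 1L):d[3]) {
    prior <- out[, , k - 1L]
    out[, , k] <- if (any(prior))
      segment_nucleus_slice(roi[, , k], prior, params) else FALSE
  }
  if (k0 > 1L) for (k in (k0 - 1L):1L) {
    prior <- out[, , k + 1L]
    out[, , k] <- if (any(prior))
      segment_nucleus_slice(roi[, , k], prior, params) else FALSE
  }
  out
}

#' Segment the bright smooth background of a frame
#'
#' Otsu threshold of the heavily smoothed slice, keeping the bright side;
#' holes smaller than `min_hole_frac` of the slice are absorbed.
#'
#' @param frame 2D intensity matrix.
#' @param params [ip_params()].
#' @return Logical background mask.
#' @export
segment_background <- function(frame, params = ip_params()) {
  x <- as_slice(frame)
  sm <- denoise(x, params$bg_sigma)
  rng <- range(sm)
  # a (near-)uniform slice has no foreground/background contrast to split:
  # call it background only if it is bright (resin sits in the upper half of
  # the 8-bit range), else it is the interior of one large cell
  if (stats::sd(sm) < 2)
    return(matrix(mean(sm) > 127.5, nrow(x), ncol(x)))
  th <- EBImage::otsu((sm - rng[1]) / diff(rng), range = c(0, 1))
  bg <- (sm - rng[1]) / diff(rng) > th
  # absorb small holes (non-background islands not touching the border)
  min_hole <- max(1, round(params$min_hole_frac * length(x)))
  lab <- EBImage::bwlabel(!bg)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    small <- setdiff(which(areas < min_hole), border)
    if (length(small)) {
      flag <- logical(max(lab) + 1L)
      flag[small + 1L] <- TRUE
      bg[flag[lab + 1L]] <- TRUE
    }
  }
  bg
}

#' Detect the most salient cells of a frame
#'
#' Distance transform of the background complement; local maxima are ranked
#' by distance value (regions furthest from background) and returned after
#' minimum-separation suppression. Ties are broken by (row, col) order.
#'
#' @param frame 2D intensity matrix.
#' @param n number of seeds requested.
#' @param min_sep minimum seed separation in px; defaults to half of
#'   `crop_size` when given, else an eighth of the slice side.
#' @param crop_size side of the crops the seeds are meant for.
#' @param params [ip_params()].
#' @return data.frame with columns `row`, `col`, `salience`; fewer than `n`
#'   rows (with a warning) when the frame has fewer salient maxima.
#' @export
detect_cells <- function(frame, n = 10, min_sep = NULL, crop_size = NULL,
                         params = ip_params()) {
  x <- as_slice(frame)
  if (is.null(min_sep))
    min_sep <- if (!is.null(crop_size)) crop_size / 2 else round(nrow(x) / 8)
  fg <- !segment_background(x, params)
  if (!any(fg))
    return(data.frame(row = integer(), col = integer(), salience = numeric()))
  D <- as.matrix(EBImage::distmap(fg))
  rowg <- row(D); colg <- col(D)
  seeds <- list()
  while (length(seeds) < n) {
    v <- max(D)
    if (v <= 0) break
    cand <- which(D == v)
    r <- ((cand - 1L) %% nrow(D)) + 1L
    c <- ((cand - 1L) %/% nrow(D)) + 1L
    o <- order(r, c)[1L]
    seeds[[length(seeds) + 1L]] <- c(r[o], c[o], v)
    D[(rowg - r[o])^2 + (colg - c[o])^2 <= min_sep^2] <- 0
  }
  if (length(seeds) < n)
    warning("only ", length(seeds), " of ", n, " requested cell seeds found")
  out <- do.call(rbind, seeds)
  if (is.null(out)) return(data.frame(row = integer(), col = integer(),
                                      salience = numeric()))
  data.frame(row = as.integer(out[, 1]), col = as.integer(out[, 2]),
             salience = out[, 3])
}

#' Automatic four-class labelling of a cell-centred crop
#'
#' The nucleus comes from the superpixel pipeline (with 3D propagation for
#' stacks); the nuclear envelope is a band of width `envelope_px` grown
#' outward from the nucleus boundary; the cell class is the foreground
#' connected component containing the crop centre minus nucleus and envelope;
#' everything else is background.
#'
#' @param roi `VolumeStack`, 3D array or single 2D slice.
#' @param params [ip_params()].
#' @return `LabelVolume` of the crop's shape (single slices give one-slice
#'   volumes).
#' @export
segment_cell_roi <- function(roi, params = ip_params()) {
  arr <- if (is.matrix(roi)) array(roi, c(dim(roi), 1L)) else unclass(roi)
  d <- dim(arr)
  nuc3 <- segment_nucleus_volume(volume_stack(pmin(pmax(arr, 0), 255)), params)
  out <- array(0L, d)
  brush <- disc_brush(params$envelope_px)
  for (k in seq_len(d[3])) {
    slice <- arr[, , k]
    fg <- !segment_background(slice, params)
    nuc <- nuc3[, , k]
    lab <- EBImage::bwlabel(fg)
    id <- 0L
    if (any(nuc)) {
      ids <- lab[nuc]
      ids <- ids[ids > 0]
      if (length(ids)) id <- as.integer(names(sort(table(ids), decreasing = TRUE))[1])
    }
    if (id == 0L) id <- lab[ceiling(d[1] / 2), ceiling(d[2] / 2)]
    cellmask <- if (id > 0L) lab == id else matrix(FALSE, d[1], d[2])
    sl <- matrix(0L, d[1], d[2])
    sl[cellmask] <- 1L
    if (any(nuc)) {
      env <- EBImage::dilate(nuc, brush) & !nuc
      sl[env] <- 2L
      sl[nuc] <- 3L
    }
    out[, , k] <- sl
  }
  label_volume(out)
}
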