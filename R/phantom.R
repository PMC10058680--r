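# Synthetic EM phantoms: multiple darker cells on a bright smooth background,
# each with a star-convex nucleus wrapped in a thin dark envelope ring, with
# exact 4-class ground truth. Nuclei shrink toward the first and last slices
# (spherical-cap z-profile) so extreme slices reproduce the small-irregular-
# nucleus regime where edge-based segmentation degrades.

#' Specification of a synthetic EM phantom
#'
#' @param frame_size pixels per side of each (square) slice.
#' @param n_slices number of slices.
#' @param n_cells number of non-overlapping cells.
#' @param nucleus_radius_px length-2 `(mean, jitter_sd)` of the nucleus radius
#'   at the cell's central slice, in px.
#' @param envelope_thickness_px width of the nuclear-envelope ring (px).
#' @param invagination_amplitude radial perturbation of the nucleus boundary as
#'   a fraction of the radius, in `[0, 1)`; values around 0.3-0.4 produce
#'   clearly non-convex (invaginated) nuclei.
#' @param intensity_means length-4 `(background, cytoplasm, envelope, nucleus)`
#'   mean intensities in `[0, 255]`; background must be the brightest.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param texture_amplitude amplitude of the smooth, mean-preserving cytoplasm
#'   texture (0 disables it).
#' @param n_mitochondria dark ellipsoids per cell imitating mitochondria; their
#'   darkening is mean-compensated inside the cytoplasm so class means are
#'   preserved.
#' @param cell_intensity_jitter standard deviation of per-cell offsets added
#'   to the cytoplasm, envelope and nucleus means (not the background):
#'   neighbouring cells in EM differ visibly in shading, which is what makes
#'   training on patches from many cells generalise better than training on
#'   one cell. 0 makes all cells identically shaded.
#' @param seed RNG seed; all randomness in the generator flows from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(frame_size = 512, n_slices = 60, n_cells = 4,
                         nucleus_radius_px = c(frame_size / 12, frame_size / 72),
                         envelope_thickness_px = 5,
                         invagination_amplitude = 0.15,
                         intensity_means = c(background = 200, cytoplasm = 110,
                                             envelope = 40, nucleus = 150),
                         noise_sigma = 5, texture_amplitude = 4,
                         n_mitochondria = 3, cell_intensity_jitter = 8,
                         seed = 1) {
  stopifnot(frame_size >= 32, n_slices >= 1, n_cells >= 1,
            envelope_thickness_px >= 1,
            invagination_amplitude >= 0, invagination_amplitude < 1,
            length(intensity_means) == 4,
            all(intensity_means >= 0 & intensity_means <= 255),
            noise_sigma >= 0)
  if (intensity_means[1] <= max(intensity_means[2:3]))
    stop("background mean must be strictly brighter than cytoplasm and envelope")
  structure(list(frame_size = as.integer(frame_size),
                 n_slices = as.integer(n_slices),
                 n_cells = as.integer(n_cells),
                 nucleus_radius_px = as.numeric(nucleus_radius_px),
                 envelope_thickness_px = as.integer(envelope_thickness_px),
                 invagination_amplitude = invagination_amplitude,
                 intensity_means = as.numeric(intensity_means),
                 noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 n_mitochondria = as.integer(n_mitochondria),
                 cell_intensity_jitter = cell_intensity_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate a deterministic run with its own RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Star-convex radial boundary: r0 * (1 + A * f(theta)) with f a random
# low-order Fourier series normalized to max |f| = 1.
radial_profile <- function(amplitude, harmonics = 3:6) {
  a <- rnorm(length(harmonics))
  phi <- runif(length(harmonics), 0, 2 * pi)
  f <- function(theta) {
    s <- 0
    for (i in seq_along(harmonics))
      s <- s + a[i] * cos(harmonics[i] * theta + phi[i])
    s
  }
  th <- seq(0, 2 * pi, length.out = 720)
  m <- max(abs(f(th)))
  function(theta) 1 + amplitude * f(theta) / m
}

place_cells <- function(spec, cell_radius) {
  fs <- spec$frame_size
  if (cell_radius[1] * 2 > fs)
    stop("placement error: cells too large for the frame")
  # sequential rejection sampling, restarting the whole configuration when a
  # cell gets boxed in by earlier draws
  for (restart in 1:100) {
    centers <- matrix(NA_real_, spec$n_cells, 2)
    centers[1, ] <- c(fs / 2, fs / 2)  # designated central cell for ROI crops
    stuck <- FALSE
    for (i in seq_len(spec$n_cells)[-1]) {
      placed <- FALSE
      for (try in 1:200) {
        p <- runif(2, 1 + cell_radius[i], fs - cell_radius[i])
        d <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                             rep(p, each = i - 1))^2))
        if (all(d > cell_radius[i] + cell_radius[seq_len(i - 1)] + 4)) {
          centers[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed) { stuck <- TRUE; break }
    }
    if (!stuck) return(centers)
  }
  stop("placement error: could not place ", spec$n_cells,
       " non-overlapping cells in a ", fs, "px frame")
}

#' Generate a synthetic EM phantom volume with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` ([volume_stack()]), `labels` ([label_volume()]),
#'   `cell_id` (integer array, which cell each non-background voxel belongs
#'   to), `centers` (cell centroids, `[row, col]`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  fs <- spec$frame_size; nz <- spec$n_slices; nc <- spec$n_cells
  thick <- spec$envelope_thickness_px
  r0 <- pmax(6, spec$nucleus_radius_px[1] +
               rnorm(nc, 0, spec$nucleus_radius_px[2]))
  nuc_prof <- lapply(seq_len(nc),
                     function(i) radial_profile(spec$invagination_amplitude))
  cell_prof <- lapply(seq_len(nc), function(i) radial_profile(0.08))
  # cytoplasm boundary must everywhere clear nucleus + envelope
  cell_r <- r0 * (1 + spec$invagination_amplitude) + thick + pmax(8, 0.45 * r0)
  centers <- place_cells(spec, cell_r)
  # spherical-cap z-profile; z-centres jittered so neighbours peak off-phase
  zc <- (nz + 1) / 2 + rnorm(nc, 0, nz / 12)
  ze <- nz * runif(nc, 0.42, 0.52)

  labels <- array(0L, dim = c(fs, fs, nz))
  cell_id <- array(0L, dim = c(fs, fs, nz))
  env_brush <- EBImage::makeBrush(2L * thick + 1L, "disc")

  # per-cell static polar geometry over the bounding box
  geom <- lapply(seq_len(nc), function(i) {
    R <- ceiling(cell_r[i]) + 2
    rows <- max(1, round(centers[i, 1]) - R):min(fs, round(centers[i, 1]) + R)
    cols <- max(1, round(centers[i, 2]) - R):min(fs, round(centers[i, 2]) + R)
    dy <- outer(rows - centers[i, 1], rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - centers[i, 2])
    rho <- sqrt(dy^2 + dx^2)
    theta <- atan2(dx, dy)
    cellmask <- rho <= cell_r[i] / (1 + 0.08) * cell_prof[[i]](theta)
    list(rows = rows, cols = cols, rho = rho, theta = theta,
         cellmask = cellmask)
  })

  for (k in seq_len(nz)) {
    sl <- matrix(0L, fs, fs); cid <- matrix(0L, fs, fs)
    for (i in seq_len(nc)) {
      g <- geom[[i]]
      sl[g$rows, g$cols][g$cellmask] <- 1L
      cid[g$rows, g$cols][g$cellmask] <- i
      zscale2 <- 1 - ((k - zc[i]) / ze[i])^2
      if (zscale2 <= 0) next
      rn <- r0[i] * sqrt(zscale2) * nuc_prof[[i]](g$theta)
      nuc <- g$rho <= rn & g$cellmask
      if (!any(nuc)) next
      env <- EBImage::dilate(nuc, env_brush) & !nuc & g$cellmask
      loc <- sl[g$rows, g$cols]
      loc[env] <- 2L; loc[nuc] <- 3L
      sl[g$rows, g$cols] <- loc
    }
    labels[, , k] <- sl
    cell_id[, , k] <- cid
  }

  img <- render_phantom_image(spec, labels, cell_id, geom, centers, zc)
  list(image = volume_stack(img), labels = label_volume(labels),
       cell_id = cell_id, centers = centers, spec = spec)
}

render_phantom_image <- function(spec, labels, cell_id, geom, centers, zc) {
  fs <- spec$frame_size; nz <- spec$n_slices
  mu <- spec$intensity_means
  img <- array(0, dim = dim(labels))
  for (k in seq_len(nz)) img[, , k] <- mu[labels[, , k] + 1L]

  # per-cell shading offsets (cytoplasm, envelope, nucleus; background fixed)
  if (spec$cell_intensity_jitter > 0) {
    off <- matrix(rnorm(3L * spec$n_cells, 0, spec$cell_intensity_jitter),
                  3L, spec$n_cells)
    for (i in seq_len(spec$n_cells))
      for (cls in 1:3) {
        sel <- labels == cls & cell_id == i
        if (any(sel)) img[sel] <- img[sel] + off[cls, i]
      }
  }

  # mitochondria: dark ellipsoids in the cytoplasm, persistent across slices
  if (spec$n_mitochondria > 0) {
    for (i in seq_len(spec$n_cells)) {
      g <- geom[[i]]
      for (m in seq_len(spec$n_mitochondria)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0.75, 0.92) * max(g$rho[g$cellmask])
        mrow <- centers[i, 1] + rad * cos(ang)
        mcol <- centers[i, 2] + rad * sin(ang)
        ax <- runif(2, 3, 7); mth <- runif(1, 0, pi)
        mz <- round(runif(1, 1, nz)); mzr <- round(runif(1, 2, 5))
        dy <- g$rho * 0 + outer(g$rows - mrow, rep(1, length(g$cols)))
        dx <- outer(rep(1, length(g$rows)), g$cols - mcol)
        u <- dy * cos(mth) + dx * sin(mth)
        v <- -dy * sin(mth) + dx * cos(mth)
        ell <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
        for (k in max(1, mz - mzr):min(nz, mz + mzr)) {
          cyto <- labels[g$rows, g$cols, k] == 1L
          hit <- ell & cyto
          if (!any(hit)) next
          loc <- img[g$rows, g$cols, k]
          delta <- numeric(length(loc)); dim(delta) <- dim(loc)
          delta[hit] <- -0.35 * mu[2]
          delta[cyto] <- delta[cyto] - mean(delta[cyto])  # preserve class mean
          img[g$rows, g$cols, k] <- loc + delta
        }
      }
    }
  }

  # smooth mean-preserving cytoplasm texture
  if (spec$texture_amplitude > 0) {
    kern <- gaussian_kernel(3)
    for (k in seq_len(nz)) {
      cyto <- labels[, , k] == 1L
      if (!any(cyto)) next
      tex <- EBImage::filter2(matrix(rnorm(fs * fs), fs, fs), kern,
                              boundary = "circular")
      tex <- tex / stats::sd(tex) * spec$texture_amplitude
      tex[!cyto] <- 0
      tex[cyto] <- tex[cyto] - mean(tex[cyto])
      img[, , k] <- img[, , k] + tex
    }
  }

  if (spec$noise_sigma > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sigma)
  pmin(pmax(round(img), 0), 255)
}

#' Generate a phantom frame plus an ROI crop centred on one cell
#'
#' Mirrors the study layout of a large multi-cell frame from which a region of
#' interest is cropped around the centroid of one designated cell.
#'
#' @param spec a [phantom_spec()].
#' @param crop_size side of the square ROI crop, px.
#' @return List with `frame` (image, labels, cell_id), `roi` (image, labels,
#'   cell_id), `offset` (`[row, col]` of the ROI's first pixel in the frame)
#'   and `center_cell` (index of the designated cell).
#' @export
phantom_roi_and_frame <- function(spec, crop_size = spec$frame_size %/% 2) {
  ph <- generate_phantom(spec)
  ctr <- round(ph$centers[1, ])
  half <- crop_size %/% 2
  r0 <- ctr[1] - half; c0 <- ctr[2] - half
  if (r0 < 0 || c0 < 0 || r0 + crop_size > spec$frame_size ||
      c0 + crop_size > spec$frame_size)
    stop("bounds error: crop of ", crop_size, " px exceeds the frame")
  rows <- (r0 + 1):(r0 + crop_size); cols <- (c0 + 1):(c0 + crop_size)
  roi <- list(image = volume_stack(unclass(ph$image)[rows, cols, , drop = FALSE]),
              labels = label_volume(unclass(ph$labels)[rows, cols, , drop = FALSE]),
              cell_id = ph$cell_id[rows, cols, , drop = FALSE])
  list(frame = ph, roi = roi, offset = c(row = r0 + 1L, col = c0 + 1L),
       center_cell = 1L)
}

#' Reduce a multi-nuclei ground truth to the single-nucleus variant
#'
#' The single-nucleus variant labels only the designated cell's nucleus and
#' envelope; other cells' nuclei and envelopes are relabelled as cell.
#'
#' @param labels `LabelVolume`.
#' @param cell_id integer array of per-voxel cell membership (from
#'   [generate_phantom()]).
#' @param center_cell which cell keeps its nucleus.
#' @return `LabelVolume` of the single-nucleus variant.
#' @export
single_nucleus_labels <- function(labels, cell_id, center_cell = 1L) {
  out <- unclass(labels)
  other <- (out == 2L | out == 3L) & cell_id != center_cell
  out[other] <- 1L
  label_volume(out, attr(labels, "voxel_size"))
}
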