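test_that("denoising is a smoothing fixed point on constants and reduces noise", {
  const <- matrix(42, 32, 32)
  expect_equal(denoise(const, 2), const)
  expect_equal(denoise(const, 0), const)
  expect_error(denoise(const, -1), "sigma")
  set.seed(3)
  wn <- matrix(rnorm(64 * 64, 128, 20), 64, 64)
  expect_lt(var(as.vector(denoise(wn, 2))), var(as.vector(wn)))
})

test_that("edge detection behaves canonically on flat and step images", {
  expect_false(any(detect_edges(matrix(7, 32, 32))))
  step <- cbind(matrix(0, 64, 32), matrix(200, 64, 32))
  es <- detect_edges(step)
  hits <- which(es, arr.ind = TRUE)
  expect_lte(diff(range(hits[, 2])), 1)          # a single vertical line
  expect_equal(length(unique(hits[, 1])), 64)    # full height
})

test_that("edges trace the phantom envelope boundaries", {
  r <- fx_small()
  sl <- r$roi$image[, , 10]
  ed <- detect_edges(denoise(sl, 2))
  env <- r$roi$labels[, , 10] == 2 & r$roi$cell_id[, , 10] == 1
  bnd <- env & !(EBImage::erode(env, matrix(1L, 3, 3)) > 0)
  D <- as.matrix(EBImage::distmap(!ed))
  expect_gte(mean(D[bnd] <= 2), 0.9)
})

test_that("superpixels partition the edge complement", {
  none <- superpixels_from_edges(matrix(FALSE, 16, 16))
  expect_equal(max(none), 1L)
  wall <- matrix(FALSE, 16, 16); wall[, 8] <- TRUE
  expect_equal(max(superpixels_from_edges(wall)), 2L)
  r <- fx_small()
  spx <- superpixels_from_edges(detect_edges(denoise(r$roi$image[, , 10], 2)))
  nuc <- r$roi$labels[, , 10] == 3 & r$roi$cell_id[, , 10] == 1
  expect_gte(max(table(spx[nuc & spx > 0])) / sum(nuc), 0.8)
})

test_that("nucleus selection applies the area, border and centrality filters", {
  spx <- matrix(1L, 32, 32)            # border-touching background region
  spx[10:24, 10:24] <- 2L              # large central region
  spx[2, 2] <- 3L                      # tiny region
  m <- select_nucleus_region(spx, params = ip_params(min_area = 4,
                                                     min_width_px = 1,
                                                     edge_compensation_px = 0,
                                                     close_radius = 1))
  expect_true(all(m[11:23, 11:23]))
  expect_false(any(m[1:8, ]))
  # all regions touching the border -> empty mask, not an error
  all_border <- matrix(1L, 16, 16); all_border[, 9:16] <- 2L
  expect_false(any(select_nucleus_region(all_border)))
})

test_that("nucleus selection recovers the phantom nucleus on the central slice", {
  r <- fx_small()
  spx <- superpixels_from_edges(detect_edges(denoise(r$roi$image[, , 10], 2)))
  m <- select_nucleus_region(spx)
  gt <- r$roi$labels[, , 10] == 3 & r$roi$cell_id[, , 10] == 1
  expect_gte(volume_jaccard(m, gt), 0.8)
})

test_that("volume propagation tracks the nucleus and stops beyond it", {
  r <- fx_small()
  nuc3 <- segment_nucleus_volume(r$roi$image)
  gt <- unclass(r$roi$labels) == 3 & r$roi$cell_id == 1
  expect_gte(volume_jaccard(nuc3, gt), 0.8)
  # slices with no ground-truth nucleus give empty masks
  empty_gt <- which(apply(gt, 3, sum) == 0)
  for (k in empty_gt) expect_false(any(nuc3[, , k]))
  # single-slice stack equals the per-slice result without a prior
  one <- segment_nucleus_volume(volume_stack(r$roi$image[, , 10]))
  direct <- select_nucleus_region(
    superpixels_from_edges(detect_edges(denoise(r$roi$image[, , 10], 2))))
  expect_identical(one[, , 1], direct)
  expect_error(segment_nucleus_volume(volume_stack(matrix(0L, 4, 4))[, , 0,
                                                                     drop = FALSE]),
               "dimension")
})

test_that("propagated masks overlap their inward neighbour and are deterministic", {
  r <- fx_small()
  nuc3 <- segment_nucleus_volume(r$roi$image)
  k0 <- ceiling(dim(nuc3)[3] / 2)
  for (k in seq_len(dim(nuc3)[3])[-k0]) {
    inward <- if (k > k0) nuc3[, , k - 1] else nuc3[, , k + 1]
    if (any(nuc3[, , k])) expect_gt(sum(nuc3[, , k] & inward), 0)
  }
  expect_identical(nuc3, segment_nucleus_volume(r$roi$image))
})

test_that("segmentation degrades monotonically with noise", {
  js <- vapply(c(0, 5, 10, 20), function(ns) {
    spec <- phantom_spec(frame_size = 256, n_slices = 20, n_cells = 4,
                         noise_sigma = ns, seed = 1)
    rr <- phantom_roi_and_frame(spec, 128)
    volume_jaccard(segment_nucleus_volume(rr$roi$image),
                   unclass(rr$roi$labels) == 3 & rr$roi$cell_id == 1)
  }, numeric(1))
  expect_true(all(diff(js) <= 0))
})

test_that("background segmentation isolates the bright smooth background", {
  r <- fx_small()
  fr <- r$frame$image[, , 10]
  bg <- segment_background(fr)
  expect_gte(volume_jaccard(bg, r$frame$labels[, , 10] == 0), 0.9)
  expect_true(all(segment_background(matrix(200, 64, 64))))
  # frame fully covered by one dark textured cell -> (near-)empty mask
  dark <- matrix(110, 64, 64)
  expect_lt(mean(segment_background(dark + matrix(rnorm(64 * 64, 0, 4),
                                                  64, 64))), 0.5)
})

test_that("cell detection seeds match the phantom cell centres", {
  ph <- generate_phantom(phantom_spec(frame_size = 512, n_slices = 2,
                                      n_cells = 5, seed = 3))
  seeds <- detect_cells(ph$image[, , 1], n = 5, crop_size = 170)
  expect_equal(nrow(seeds), 5)
  expect_true(all(diff(seeds$salience) <= 0))   # ranked by salience
  d <- as.matrix(dist(rbind(as.matrix(seeds[, c("row", "col")]), ph$centers)))
  nearest <- apply(d[1:5, 6:10], 1, min)
  # every seed falls inside a cell (within its ~73 px outer radius), so a
  # crop centred on it covers that cell
  expect_true(all(nearest < 75))
  assigned <- apply(d[1:5, 6:10], 1, which.min)
  expect_equal(sort(unname(assigned)), 1:5)     # each seed a distinct cell
  # degenerate inputs
  expect_equal(nrow(detect_cells(matrix(200, 64, 64), n = 3)), 0)
  expect_warning(detect_cells(ph$image[, , 1], n = 10, crop_size = 600),
                 "requested")
})

test_that("automatic crop labelling produces all four classes with a closed ring", {
  ph <- generate_phantom(phantom_spec(frame_size = 512, n_slices = 8,
                                      n_cells = 5, noise_sigma = 0, seed = 3))
  ctr <- round(ph$centers[1, ])
  rs <- (ctr[1] - 85):(ctr[1] + 84); cs <- (ctr[2] - 85):(ctr[2] + 84)
  auto <- segment_cell_roi(ph$image[rs, cs, 4])
  expect_setequal(unique(as.vector(auto)), 0:3)
  env <- auto[, , 1] == 2
  filled <- EBImage::fillHull(env) > 0
  expect_true(all(filled[auto[, , 1] == 3]))    # ring encloses the nucleus
  gt <- ph$labels[rs, cs, 4]
  gt[ph$cell_id[rs, cs, 4] != 1] <- 0L          # like-with-like: central cell
  cj <- class_jaccard(auto[, , 1], gt)
  expect_gte(cj[["nucleus"]], 0.8)
  expect_gte(cj[["cell"]], 0.8)
  # an all-background crop yields an all-background label
  flat <- matrix(200, 96, 96)
  expect_true(all(segment_cell_roi(flat) == 0))
})
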