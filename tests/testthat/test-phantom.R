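test_that("phantoms are deterministic and carry all four classes", {
  spec <- phantom_spec(frame_size = 128, n_slices = 6, n_cells = 1, seed = 3)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(unclass(a$labels), unclass(b$labels))
  expect_setequal(unique(as.vector(a$labels)), 0:3)
})

test_that("the envelope ring exactly separates nucleus from cytoplasm", {
  ph <- generate_phantom(phantom_spec(frame_size = 128, n_slices = 6,
                                      n_cells = 1, noise_sigma = 0, seed = 3))
  for (k in c(2, 3, 4)) {
    lab <- ph$labels[, , k]
    nuc <- lab == 3
    if (!any(nuc)) next
    # no nucleus pixel 4-adjacent to a cytoplasm or background pixel
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      shifted <- helaseg:::shift_mat(lab == 1 | lab == 0, d[1], d[2]) > 0
      expect_false(any(nuc & shifted))
    }
    # envelope voxels lie within the ring width of the nucleus
    D <- as.matrix(EBImage::distmap(!nuc))
    expect_lte(max(D[lab == 2]), 5 + 1.5)
  }
})

test_that("class means are recovered exactly from a noise-free phantom", {
  spec <- phantom_spec(frame_size = 128, n_slices = 8, n_cells = 1,
                       noise_sigma = 0, texture_amplitude = 0,
                       n_mitochondria = 0, cell_intensity_jitter = 0, seed = 2)
  ph <- generate_phantom(spec)
  for (k in 0:3)
    expect_equal(mean(ph$image[ph$labels == k]), spec$intensity_means[k + 1])
})

test_that("invaginations make the nucleus boundary non-convex", {
  mk <- function(amp) {
    ph <- generate_phantom(phantom_spec(frame_size = 192, n_slices = 5,
                                        n_cells = 1, noise_sigma = 0,
                                        invagination_amplitude = amp,
                                        seed = 4))
    m <- ph$labels[, , 3] == 3
    polygon_hull_area(m) / sum(m)
  }
  expect_gt(mk(0.4), 1.05)        # convex hull clearly exceeds the region
  expect_lt(mk(0.05), 1.02)       # near-circular nucleus stays convex
})

test_that("nuclei shrink toward the first and last slices", {
  r <- fx_small()
  a <- sapply(seq_len(dim(r$roi$labels)[3]), function(k)
    sum(r$roi$labels[, , k] == 3 & r$roi$cell_id[, , k] == 1))
  peak <- which.max(a)
  expect_true(all(diff(a[seq_len(peak)]) >= 0))
  expect_true(all(diff(a[peak:length(a)]) <= 0))
  expect_lt(a[1], max(a) / 2)
})

test_that("cells that cannot be placed raise a placement error", {
  expect_error(generate_phantom(phantom_spec(frame_size = 96, n_slices = 2,
                                             n_cells = 12, seed = 1)),
               "placement")
})

test_that("the ROI crop is consistent with the frame and sees neighbours", {
  r <- fx_small()
  off <- r$offset; n <- dim(r$roi$labels)[1]
  rows <- off[1]:(off[1] + n - 1); cols <- off[2]:(off[2] + n - 1)
  expect_identical(as.vector(r$roi$labels),
                   as.vector(unclass(r$frame$labels)[rows, cols, ]))
  # parts of neighbouring cells' nuclei appear inside the ROI
  expect_gt(sum(r$roi$labels == 3 & r$roi$cell_id != 1), 0)
  ncomp <- sapply(seq_len(dim(r$roi$labels)[3]), function(k)
    max(EBImage::bwlabel(r$roi$labels[, , k] == 3)))
  expect_gt(max(ncomp), 1)
  expect_error(phantom_roi_and_frame(phantom_spec(frame_size = 128,
                                                  n_slices = 2, n_cells = 1,
                                                  seed = 1),
                                     200), "bounds")
})

test_that("single-nucleus variant keeps only the designated cell's nucleus", {
  r <- fx_small()
  single <- single_nucleus_labels(r$roi$labels, r$roi$cell_id, 1L)
  expect_false(any(single == 3 & r$roi$cell_id != 1))
  expect_false(any(single == 2 & r$roi$cell_id != 1))
  # relabelled voxels became cell, everything else unchanged
  changed <- unclass(single) != unclass(r$roi$labels)
  expect_true(all(single[changed] == 1))
  expect_true(all((r$roi$labels[changed] == 2) | (r$roi$labels[changed] == 3)))
})
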