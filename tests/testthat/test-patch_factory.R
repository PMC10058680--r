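test_that("grid offsets match brute-force window enumeration", {
  expect_length(grid_positions(2000, 128, 64), 30)
  expect_length(grid_positions(128, 128, 64), 1)
  expect_length(grid_positions(8192, 128, 64), 127)
  expect_equal(grid_positions(10, 4, 2), c(0L, 2L, 4L, 6L))
  for (len in c(17, 32, 100)) for (patch in c(4, 8)) for (stride in c(2, 3, 4))
    expect_length(grid_positions(len, patch, stride),
                  oracle_window_count(len, patch, stride))
  expect_error(grid_positions(64, 128, 64), "patch")
  expect_error(grid_positions(64, 32, 0), "stride")
})

test_that("pair extraction enumerates the full grid per listed slice", {
  ph <- fx_noisy()
  ps <- extract_pairs(ph$image, ph$labels, "1:2:4", patch = 64)
  g <- length(grid_positions(256, 64, 32))
  expect_equal(n_pairs(ps), 2 * g^2)
  one <- extract_pairs(volume_stack(matrix(0L, 128, 128)),
                       label_volume(matrix(0L, 128, 128)), 1L)
  expect_equal(n_pairs(one), 1)
  expect_error(extract_pairs(ph$image, ph$labels, "1:9"), "bounds")
  expect_error(extract_pairs(ph$image,
                             label_volume(array(0L, c(64, 64, 4))), 1L),
               "congruent")
})

test_that("materialised label patches equal the source volume windows", {
  ph <- fx_noisy()
  ps <- extract_pairs(ph$image, ph$labels, 2L, patch = 64)
  idx <- c(1, 5, n_pairs(ps))
  mat <- materialize_pairs(ps, idx)
  for (j in seq_along(idx)) {
    m <- ps$manifest[idx[j], ]
    rs <- (m$row + 1):(m$row + 64); cs <- (m$col + 1):(m$col + 64)
    expect_identical(mat$labels[, , j],
                     matrix(unclass(ph$labels)[rs, cs, m$slice], 64, 64))
    expect_identical(mat$images[, , j],
                     matrix(as.double(unclass(ph$image)[rs, cs, m$slice]),
                            64, 64))
  }
})

test_that("strategy pair counts reproduce the published arithmetic", {
  expect_equal(strategy_pair_count("s1_single36k"), 36000)
  expect_equal(strategy_pair_count("s2_multi36k"), 36000)
  expect_equal(strategy_pair_count("s3_multi135k"), 135000)
  expect_equal(strategy_pair_count("s4_auto135k"), 135000)
  expect_equal(strategy_pair_count("s5_union270k"), 270000)
})

test_that("training sets follow their strategy recipes", {
  r <- fx_small()
  gt_single <- single_nucleus_labels(r$roi$labels, r$roi$cell_id, 1L)
  inputs <- list(roi_volume = r$roi$image, roi_labels = r$roi$labels,
                 roi_labels_single = gt_single, frames = r$frame$image)
  s1 <- build_training_set(training_strategy("s1_single36k",
                                             slice_range = "5:2:15"),
                           inputs, patch = 64)
  g <- length(grid_positions(128, 64, 32))
  expect_equal(n_pairs(s1), 6 * g^2)
  expect_equal(unique(s1$manifest$strategy), "s1_single36k")
  # s1 pairs carry the single-nucleus GT variant
  mat <- materialize_pairs(s1, 1L)
  m1 <- s1$manifest[1, ]
  expect_identical(mat$labels[, , 1],
                   matrix(unclass(gt_single)[(m1$row + 1):(m1$row + 64),
                                             (m1$col + 1):(m1$col + 64),
                                             m1$slice], 64, 64))
  s3 <- build_training_set(training_strategy("s3_multi135k",
                                             slice_range = "1:2:19"),
                           inputs, patch = 64)
  expect_equal(n_pairs(s3), 10 * g^2)
  expect_error(build_training_set(training_strategy("s1_single36k"),
                                  list(roi_volume = r$roi$image,
                                       roi_labels = r$roi$labels)),
               "configuration")
})

test_that("the automatic strategy crops detected cells and the union concatenates", {
  r <- fx_small()
  gt_single <- single_nucleus_labels(r$roi$labels, r$roi$cell_id, 1L)
  inputs <- list(roi_volume = r$roi$image, roi_labels = r$roi$labels,
                 roi_labels_single = gt_single, frames = r$frame$image)
  s4 <- suppressMessages(build_training_set(
    training_strategy("s4_auto135k", frame_slices = 10L,
                      n_cells_per_frame = 3L, crop_size = 128L),
    inputs, patch = 64))
  g <- length(grid_positions(128, 64, 32))
  expect_equal(n_pairs(s4), 3 * g^2)     # 3 cells x 1 frame x g^2
  expect_equal(length(unique(s4$manifest$source)), 3)
  s5 <- suppressMessages(build_training_set(
    training_strategy("s5_union270k", slice_range = "1:2:19",
                      frame_slices = 10L, n_cells_per_frame = 3L,
                      crop_size = 128L),
    inputs, patch = 64))
  expect_equal(n_pairs(s5), 10 * g^2 + 3 * g^2)
  # shortfall: asking for more cells than the frame provides still works
  s4b <- suppressMessages(build_training_set(
    training_strategy("s4_auto135k", frame_slices = 10L,
                      n_cells_per_frame = 6L, crop_size = 200L),
    inputs, patch = 64))
  expect_lt(n_pairs(s4b), 6 * length(grid_positions(200, 64, 32))^2)
})

test_that("patch sets write to disk with a manifest", {
  ph <- fx_noisy()
  ps <- extract_pairs(ph$image, ph$labels, 1L, patch = 128)
  d <- tempfile()
  man <- write_pairs(ps, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(nrow(man), n_pairs(ps))
  img <- png::readPNG(file.path(d, man$file_image[1]))
  lab <- round(png::readPNG(file.path(d, man$file_label[1])) * 255)
  mat <- materialize_pairs(ps, 1L)
  expect_equal(round(img * 255), mat$images[, , 1])
  expect_equal(lab, mat$labels[, , 1])
})
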