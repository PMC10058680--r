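test_that("the default network reports 46 layers over 4 levels", {
  lt <- unet_layers(unet_config())
  expect_equal(nrow(lt), 46)
  expect_equal(sum(lt$type == "maxpool 2x2"), 3)          # 4 resolution levels
  expect_equal(sum(lt$type == "transposed conv 2x2"), 3)
  expect_equal(lt$type[nrow(lt)], "pixel classification")
  expect_error(unet_config(n_classes = 1), "n_classes")
  expect_error(unet_config(in_patch = 100), "divisible")
})

test_that("forward passes honour the shape contract", {
  cfg <- unet_config(base_channels = 4, seed = 1)
  m <- build_unet(cfg)
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  fw <- helaseg:::unet_forward(m$params, x, cfg)
  expect_equal(dim(fw$logits), c(128, 128, 1, 4))
  x64 <- array(runif(64 * 64 * 2), c(64, 64, 2, 1))
  expect_equal(dim(helaseg:::unet_forward(m$params, x64, cfg)$logits),
               c(64, 64, 2, 4))
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- unet_config(depth = 3, in_patch = 8, base_channels = 2, seed = 42,
                     dropout = 0)
  m <- build_unet(cfg)
  set.seed(9)
  # jitter the zero-initialised biases: with b = 0 a position fed only by a
  # dead-ReLU region has pre-activation exactly 0, where the loss sits on the
  # ReLU kink and finite differences straddle the subgradient
  for (nm in names(m$params))
    m$params[[nm]]$b <- rnorm(length(m$params[[nm]]$b), 0, 0.05)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  y <- array(sample(0:3, 8 * 8 * 2, TRUE), c(8, 8, 2))
  fw <- helaseg:::unet_forward(m$params, x, cfg)
  ce <- helaseg:::softmax_ce(fw$logits, y)
  gr <- helaseg:::unet_backward(m$params, fw$caches, ce$grad, cfg)
  loss_at <- function(params)
    helaseg:::softmax_ce(helaseg:::unet_forward(params, x, cfg)$logits, y)$loss
  eps <- 1e-6
  for (nm in c("enc1_conv1", "enc2_conv2", "bridge_conv1", "dec2_up",
               "dec1_conv2", "final")) {
    for (fld in c("W", "b")) {
      th <- m$params[[nm]][[fld]]
      for (i in sample(length(th), min(3, length(th)))) {
        up <- m$params; up[[nm]][[fld]][i] <- th[i] + eps
        dn <- m$params; dn[[nm]][[fld]][i] <- th[i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(gr[[nm]][[fld]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and reproduces its trace under a seed", {
  ph <- fx_noisy()
  ps <- extract_pairs(ph$image, ph$labels, "1:4", patch = 16)
  mat <- materialize_pairs(ps, 1:24)
  cfg <- unet_config(depth = 3, in_patch = 16, base_channels = 4,
                     epochs = 3, batch_size = 8, seed = 5)
  m1 <- unet_train(mat, cfg)
  expect_length(m1$loss_trace, 3)
  expect_lt(m1$loss_trace[3], m1$loss_trace[1])
  m2 <- unet_train(mat, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$final$W, m2$params$final$W)
  expect_error(unet_train(list(images = array(0, c(16, 16, 0)),
                               labels = array(0L, c(16, 16, 0))), cfg),
               "data error")
  # batch_size larger than the pair count degenerates to one batch per epoch
  cfg1 <- unet_config(depth = 3, in_patch = 16, base_channels = 4,
                      epochs = 1, batch_size = 999, seed = 5)
  m3 <- unet_train(materialize_pairs(ps, 1:6), cfg1)
  expect_length(m3$batch_losses[[1]], 1)
})

test_that("predictions are 4-code maps with ties broken toward lower codes", {
  m <- fx_tiny_unet()
  ph <- fx_noisy()
  pred <- predict_patches(m, unclass(ph$image)[1:16, 1:16, 1])
  expect_true(all(pred %in% 0:3))
  z <- array(0, c(4, 4, 1, 4))
  expect_true(all(helaseg:::argmax_classes(z) == 0L))
})

test_that("tiled inference returns full-size class maps for any slice size", {
  m <- fx_tiny_unet()
  ph <- fx_noisy()
  sl <- ph$image[, , 2]
  full <- predict_slice(m, sl)
  expect_equal(dim(full), c(256, 256))
  expect_true(all(full %in% 0:3))
  odd <- predict_slice(m, sl[1:100, 1:90])
  expect_equal(dim(odd), c(100, 90))
  tiny <- predict_slice(m, sl[1:10, 1:7])     # smaller than one tile
  expect_equal(dim(tiny), c(10, 7))
})

test_that("model methods print, summarise and plot", {
  m <- fx_tiny_unet()
  expect_output(print(m), "trained")
  lt <- expect_output(summary(m), "trainable parameters")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
})
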