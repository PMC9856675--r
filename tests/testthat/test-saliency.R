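# a tiny trained decoder shared across saliency tests
saliency_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- blob_images(20, side = 16, seed = 25)
      cfg <- decoder_config(conv_filters = c(4, 8), kernel = 3, fc_units = 16,
                            dropout = 0.1, learning_rate = 0.05, epochs = 10,
                            batch_size = 32, seed = 17)
      dec <- build_decoder(cfg, c(16, 16, 3))
      cache <<- list(decoder = train_decoder(dec, toy$images, toy$labels),
                     toy = toy)
    }
    cache
  }
})

test_that("GradCAM maps are non-negative, input-sized and class-discriminative", {
  fx <- saliency_fixture()
  img1 <- fx$toy$images[1, , , ] # a 'fast' blob (top-left)
  g_fast <- gradcam(fx$decoder, img1, target = "fast")
  g_slow <- gradcam(fx$decoder, img1, target = "slow")
  expect_gte(min(g_fast$map), 0)
  expect_gte(min(g_slow$map), 0)
  expect_equal(dim(g_fast$map), c(16, 16))
  # the map depends on the target class (class-discriminative property);
  # the electrode-level class dependence on planted data is asserted in the
  # chain recovery test
  expect_gt(mean(abs(g_fast$map - g_slow$map)),
            0.05 * (mean(g_fast$map) + mean(g_slow$map)))
  # default target is the predicted class
  g_def <- gradcam(fx$decoder, img1)
  expect_equal(g_def$target, which.max(g_def$probs))
})

test_that("a linear 1x1-conv toy network yields the closed-form GradCAM map", {
  # conv: channels combined by matrix W; head: class score = sum of pixels of
  # each feature channel times class weight. GradCAM weight for channel k is
  # the mean gradient = class weight; map = relu(sum_k w_k A_k).
  H <- 4; W <- 4
  Wconv <- matrix(c(1, 0.5, -0.2, 0.3), 2, 2) # 2 in -> 2 feature channels
  fcW <- matrix(0, H * W * 2, 2)
  fcW[seq_len(H * W), 1] <- 1      # class 1 reads channel 1
  fcW[H * W + seq_len(H * W), 2] <- 0.5
  net <- toy_linear_net(Wconv, fcW)
  init <- rtdecoder:::nn_init(net, c(H, W, 2L))
  dec <- structure(list(layers = init$layers,
                        config = decoder_config(epochs = 0, n_classes = 2),
                        input_shape = c(H, W, 2L), history = NULL,
                        label_order = c("c1", "c2")),
                   class = "trained_decoder")
  dec$layers[[1]]$W <- Wconv
  dec$layers[[3]]$W <- fcW
  withr::with_seed(26, img <- array(runif(H * W * 2), c(H, W, 2)))
  gc <- gradcam(dec, img, target = 1, layer = 1)
  A1 <- img[, , 1] * Wconv[1, 1] + img[, , 2] * Wconv[2, 1]
  A2 <- img[, , 1] * Wconv[1, 2] + img[, , 2] * Wconv[2, 2]
  # class-1 gradient wrt channel 1 map is 1 everywhere, 0 for channel 2
  oracle <- pmax(A1 * 1 + A2 * 0, 0)
  expect_equal(gc$coarse, oracle, tolerance = 1e-9)
})

test_that("guided backprop equals the plain gradient when the guiding mask is all-pass", {
  # strictly positive weights and inputs keep every ELU output and gradient
  # positive, so guiding must not change anything
  H <- 6
  cfg <- decoder_config(conv_filters = 4, kernel = 3, fc_units = 6,
                        dropout = 0, epochs = 0, seed = 31)
  dec <- build_decoder(cfg, c(H, H, 2))
  refs <- rtdecoder:::nn_collect_params(dec$layers)
  for (r in refs) {
    w <- rtdecoder:::nn_get_param(dec$layers, r)
    dec$layers <- rtdecoder:::nn_set_param(dec$layers, r, abs(w) + 0.01)
  }
  dec$label_order <- c("x", "y", "z")
  withr::with_seed(32, img <- array(runif(H * H * 2, 0.1, 1), c(H, H, 2)))
  gb <- guided_backprop(dec, img, target = 1)
  # plain gradient via unguided backward
  x4 <- array(img, c(H, H, 2, 1))
  fw <- rtdecoder:::nn_forward(dec$layers, x4)
  dy <- matrix(c(1, 0, 0), 1)
  plain <- rtdecoder:::nn_backward(dec$layers, fw$caches, dy, guided = FALSE,
                                   need_dw = FALSE)$dx[, , , 1]
  expect_equal(gb$map, plain, tolerance = 1e-12)
})

test_that("guided gradients match finite differences where the mask is all-pass", {
  H <- 6
  cfg <- decoder_config(conv_filters = 4, kernel = 3, fc_units = 6,
                        dropout = 0, epochs = 0, seed = 33)
  dec <- build_decoder(cfg, c(H, H, 2))
  refs <- rtdecoder:::nn_collect_params(dec$layers)
  for (r in refs) {
    w <- rtdecoder:::nn_get_param(dec$layers, r)
    dec$layers <- rtdecoder:::nn_set_param(dec$layers, r, abs(w) + 0.01)
  }
  dec$label_order <- c("x", "y", "z")
  withr::with_seed(34, img <- array(runif(H * H * 2, 0.1, 1), c(H, H, 2)))
  gb <- guided_backprop(dec, img, target = 2)
  logit_of <- function(im) {
    fw <- rtdecoder:::nn_forward(dec$layers, array(im, c(H, H, 2, 1)))
    fw$out[1, 2]
  }
  eps <- 1e-5
  withr::with_seed(35, picks <- sample(length(img), 10))
  for (ii in picks) {
    im2 <- img; im2[ii] <- im2[ii] + eps
    fd <- (logit_of(im2) - logit_of(img)) / eps
    expect_equal(gb$map[ii], fd, tolerance = 1e-4)
  }
})

test_that("guided-gradcam is the elementwise product and keeps three band planes", {
  fx <- saliency_fixture()
  img <- fx$toy$images[3, , , ]
  sm <- guided_gradcam(fx$decoder, img)
  expect_s3_class(sm, "saliency_map")
  expect_equal(dim(sm$guided_gradcam), c(16, 16, 3))
  oracle <- sm$guided * array(sm$gradcam, dim(sm$guided))
  expect_equal(sm$guided_gradcam, oracle, tolerance = 1e-12)
})

test_that("scaling a linear network's input scales its guided map homogeneously", {
  H <- 4
  Wconv <- matrix(abs(rnorm(4)) + 0.1, 2, 2)
  fcW <- matrix(abs(rnorm(H * H * 2 * 2)) + 0.1, H * H * 2, 2)
  net <- toy_linear_net(Wconv, fcW)
  dec <- structure(list(layers = net, config = decoder_config(epochs = 0),
                        input_shape = c(H, H, 2L), label_order = c("p", "q")),
                   class = "trained_decoder")
  withr::with_seed(36, img <- array(runif(H * H * 2, 0.1, 1), c(H, H, 2)))
  g1 <- guided_backprop(dec, img, target = 1)$map
  g2 <- guided_backprop(dec, 3 * img, target = 1)$map
  expect_equal(g2, g1, tolerance = 1e-9) # gradient of a linear map is constant
})

test_that("activation extraction reduces maps to the electrode-band grain", {
  px <- electrode_pixels(project_montage(default_montage()), grid = 32)
  zero <- structure(list(gradcam = matrix(0, 32, 32),
                         guided = array(0, c(32, 32, 3)),
                         guided_gradcam = array(0, c(32, 32, 3)),
                         target = 1, probs = c(fast = 1, medium = 0, slow = 0)),
                    class = "saliency_map")
  tab <- extract_activations(list(zero), px)
  expect_equal(nrow(tab), 64 * 3)
  expect_true(all(tab$activation == 0))
  expect_setequal(unique(tab$band), c("alpha", "beta", "gamma"))

  # delta peak at one electrode: 3x3 mean puts peak/9 there, zero elsewhere
  i <- match("CZ", px$channel)
  delta <- zero
  delta$guided_gradcam[round(px$row[i]), round(px$col[i]), 2] <- 0.9
  tab2 <- extract_activations(list(delta), px)
  at <- tab2$activation[tab2$electrode == "CZ" & tab2$band == "beta"]
  expect_equal(at, 0.9 / 9, tolerance = 1e-12)
  # electrodes whose 3x3 window misses the peak stay zero
  far <- tab2$activation[tab2$electrode == "FPZ"]
  expect_true(all(far == 0))
})

test_that("out-of-range targets and off-image electrodes are rejected", {
  fx <- saliency_fixture()
  img <- fx$toy$images[1, , , ]
  expect_error(gradcam(fx$decoder, img, target = 9), "out of range")
  px <- electrode_pixels(project_montage(default_montage()), grid = 32)
  px$row[1] <- 99
  sm <- guided_gradcam(fx$decoder, img)
  expect_error(extract_activations(list(sm), px), "outside")
})
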