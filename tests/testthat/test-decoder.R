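test_that("the default configuration reproduces the published architecture settings", {
  cfg <- decoder_config()
  expect_equal(cfg$conv_filters, c(52L, 104L, 156L, 208L))
  expect_equal(cfg$kernel, 5L)
  expect_equal(cfg$n_blocks, 4L)
  expect_equal(cfg$fc_units, c(713L, 1019L))
  expect_equal(cfg$dropout, 0.47)
  expect_equal(cfg$optimizer, "adagrad")
  expect_equal(cfg$learning_rate, 0.006)
  expect_equal(cfg$epochs, 165L)
  expect_equal(cfg$val_fraction, 0.25)
  expect_equal(cfg$n_classes, 3L)
  expect_equal(cfg$activation, "elu")
})

test_that("softmax outputs are probabilities summing to one", {
  cfg <- decoder_config(conv_filters = c(4, 8), kernel = 3, fc_units = 8,
                        dropout = 0, epochs = 0, seed = 2)
  dec <- build_decoder(cfg, c(16, 16, 3))
  withr::with_seed(3, imgs <- array(runif(5 * 16 * 16 * 3), c(5, 16, 16, 3)))
  dec$label_order <- c("fast", "medium", "slow")
  p <- predict(dec, imgs)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-5)
  expect_true(all(p >= 0))
})

test_that("trainable parameter count equals the layer-arithmetic closed form", {
  cfg <- decoder_config(conv_filters = c(4, 8), kernel = 3, fc_units = 16,
                        dropout = 0, epochs = 0, seed = 1)
  dec <- build_decoder(cfg, c(16, 16, 3))
  # block 1: conv 3x3x3 -> 4 (112); reduction fb = 2:
  #   b1 3x3x4x2+2 = 74; b2 (1x1x4x2+2) + (3x3x2x2+2) = 48; out ch 2+2+4 = 8
  # block 2 (8x8x8): conv 3x3x8x8+8 = 584; reduction fb = 3:
  #   b1 3x3x8x3+3 = 219; b2 (1x1x8x3+3) + (3x3x3x3+3) = 111; out ch 3+3+8 = 14
  # flatten 4x4x14 = 224; FC 224x16+16 = 3600; head 16x3+3 = 51
  expect_equal(n_params(dec), 112 + 74 + 48 + 584 + 219 + 111 + 3600 + 51)
})

test_that("reduction blocks halve spatial size with ceiling semantics", {
  cfg <- decoder_config(conv_filters = c(4, 4, 4), kernel = 3, fc_units = 4,
                        dropout = 0, epochs = 0, seed = 1)
  dec <- build_decoder(cfg, c(9, 9, 3))
  x <- array(0, c(9, 9, 3, 1))
  fw <- rtdecoder:::nn_forward(dec$layers, x)
  # layer 3, 6, 9 are the reduction outputs: 9 -> 5 -> 3 -> 2
  expect_equal(dim(fw$caches[[3]]$out)[1:2], c(5, 5))
  expect_equal(dim(fw$caches[[6]]$out)[1:2], c(3, 3))
  expect_equal(dim(fw$caches[[9]]$out)[1:2], c(2, 2))
})

test_that("too-deep configurations fail naming the offending block", {
  cfg <- decoder_config(conv_filters = rep(4, 5), kernel = 3, fc_units = 4,
                        dropout = 0, epochs = 0)
  expect_error(build_decoder(cfg, c(8, 8, 3)), "reduction block")
})

test_that("zero-epoch training returns the initialized weights unchanged", {
  cfg <- decoder_config(conv_filters = 4, kernel = 3, fc_units = 4,
                        dropout = 0, epochs = 0, seed = 7)
  dec <- build_decoder(cfg, c(8, 8, 3))
  w0 <- dec$layers[[1]]$W
  withr::with_seed(8, imgs <- array(runif(6 * 8 * 8 * 3), c(6, 8, 8, 3)))
  trained <- train_decoder(dec, imgs, factor(rep(c("a", "b", "c"), 2)))
  expect_identical(trained$layers[[1]]$W, w0)
})

test_that("training on separable blobs reaches the linear-baseline accuracy", {
  toy <- blob_images(40, side = 16, seed = 21)
  # linear-separability oracle: multinomial logistic regression on raw pixels
  skip_if_not_installed("nnet")
  flat <- matrix(toy$images, dim(toy$images)[1])
  ok <- withr::with_seed(1, {
    fit <- nnet::multinom(toy$labels ~ flat[, seq(1, ncol(flat), by = 16)],
                          trace = FALSE, MaxNWts = 5000)
    mean(predict(fit) == toy$labels)
  })
  expect_gte(ok, 0.95) # the blobs really are separable
  cfg <- decoder_config(conv_filters = c(4, 8), kernel = 3, fc_units = 16,
                        dropout = 0.2, optimizer = "adagrad",
                        learning_rate = 0.05, epochs = 20, batch_size = 32,
                        seed = 11)
  dec <- build_decoder(cfg, c(16, 16, 3))
  dec <- train_decoder(dec, toy$images, toy$labels)
  expect_gte(max(dec$history$val_acc), 0.95)
})

test_that("training is deterministic and checkpointing restores the best epoch", {
  toy <- blob_images(15, side = 12, seed = 22)
  cfg <- decoder_config(conv_filters = 4, kernel = 3, fc_units = 8,
                        dropout = 0.1, learning_rate = 0.05, epochs = 6,
                        batch_size = 16, seed = 13)
  d1 <- train_decoder(build_decoder(cfg, c(12, 12, 3)), toy$images, toy$labels)
  d2 <- train_decoder(build_decoder(cfg, c(12, 12, 3)), toy$images, toy$labels)
  expect_identical(d1$history, d2$history)
  expect_identical(d1$layers, d2$layers)
  # restored weights reproduce the minimum validation loss
  expect_equal(d1$best_epoch, which.min(d1$history$val_loss))
})

test_that("single-class input is rejected", {
  cfg <- decoder_config(conv_filters = 4, kernel = 3, fc_units = 4, epochs = 1)
  dec <- build_decoder(cfg, c(8, 8, 3))
  imgs <- array(0, c(4, 8, 8, 3))
  expect_error(train_decoder(dec, imgs, factor(rep("a", 4))), "2 classes")
})

test_that("metrics match hand-computed values on a known confusion table", {
  # truth: 10 a, 10 b, 10 c; predictions confuse 3 a->b and 2 c->a
  truth <- factor(rep(c("a", "b", "c"), each = 10))
  pred <- factor(c(rep("a", 7), rep("b", 3), rep("b", 10), rep("a", 2), rep("c", 8)),
                 levels = levels(truth))
  mt <- rtdecoder:::classification_metrics(truth, pred)
  # by hand: precision a = 7/9, b = 10/13, c = 8/8; recall 0.7, 1.0, 0.8
  expect_equal(mt$per_class$precision, c(7 / 9, 10 / 13, 1))
  expect_equal(mt$per_class$recall, c(0.7, 1, 0.8))
  f1 <- c(2 * (7 / 9) * 0.7 / (7 / 9 + 0.7), 2 * (10 / 13) / (10 / 13 + 1),
          2 * 0.8 / 1.8)
  expect_equal(mt$per_class$f1, f1, tolerance = 1e-12)
  expect_equal(unname(mt$macro["f1"]), mean(f1), tolerance = 1e-12)
  expect_equal(mt$accuracy, 25 / 30)
})

test_that("perfect predictions give unit metrics and an identity confusion matrix", {
  truth <- factor(rep(c("a", "b", "c"), each = 4))
  mt <- rtdecoder:::classification_metrics(truth, truth)
  expect_equal(mt$per_class$precision, rep(1, 3))
  expect_equal(mt$per_class$recall, rep(1, 3))
  expect_equal(unname(mt$macro), c(1, 1, 1))
  expect_equal(unclass(mt$confusion), diag(3), ignore_attr = TRUE)
})
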