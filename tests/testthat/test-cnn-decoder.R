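test_that("the full-scale architecture builds with the stated layer stack", {
  cfg <- cnn_config("full", n = 7)
  expect_equal(cfg$input_shape, c(648L, 692L))
  expect_equal(cfg$filters, c(16L, 32L, 64L))
  expect_equal(cfg$kernels, c(32L, 16L, 8L))
  expect_equal(cfg$strides, c(2L, 1L, 1L))
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(cfg$batch_size, 100L)
  expect_equal(cfg$epochs, 15L)
  geom <- cnn_geometry(cfg)
  expect_length(geom$conv, 3L)
  expect_equal(geom$fc[2], 49L)               # 49-bit output key for 7x7
  expect_equal(geom$conv[[1]]$Hc, 324L)       # stride-2 conv halves 648
  m <- build_decoder(cfg)
  expect_false(m$trained)
  expect_gt(m$n_parameters, 1e6)

  expect_equal(cnn_geometry(cnn_config("full", n = 5))$fc[2], 25L)

  # geometry underflow errors name the offending layer
  bad <- cnn_config("desk", input_shape = c(12L, 12L))
  expect_error(cnn_geometry(bad), "conv layer|max-pool after conv layer")
})

test_that("the architecture config round-trips through serialization", {
  cfg <- cnn_config("desk", n = 7)
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  back <- jsonlite::fromJSON(js)
  for (fld in c("filters", "kernels", "strides", "pools", "pool_strides"))
    expect_equal(as.integer(back[[fld]]), cfg[[fld]])
  expect_equal(back$learning_rate, cfg$learning_rate)
  expect_equal(as.integer(back$input_shape), cfg$input_shape)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  m <- build_decoder(tiny_cnn_config(seed = 5))
  B <- 4
  X <- matrix(runif(400 * B), 400, B)
  TT <- matrix(rbinom(25 * B, 1, 0.4), 25, B)
  loss <- function(mm) mean((silkcode:::cnn_forward(mm, X, train = TRUE)$Y - TT)^2)
  fw <- silkcode:::cnn_forward(m, X, train = TRUE)
  dY <- 2 * (fw$Y - TT) / length(fw$Y)
  gr <- silkcode:::cnn_backward(m, fw$cache, dY)
  eps <- 1e-6
  for (layer in names(gr)) {
    for (pn in setdiff(names(gr[[layer]]), "b")) {  # biases are BN no-ops
      p <- m$params[[layer]][[pn]]
      for (i in sample(length(p), 3)) {
        m2 <- m; m2$params[[layer]][[pn]][i] <- p[i] + eps
        m3 <- m; m3$params[[layer]][[pn]][i] <- p[i] - eps
        num <- (loss(m2) - loss(m3)) / (2 * eps)
        ana <- gr[[layer]][[pn]][i]
        expect_equal(ana, num, tolerance = 1e-3,
                     label = paste("grad", layer, pn, i))
      }
    }
  }
})

test_that("training reduces the loss and is reproducible under a seed", {
  set.seed(1)
  cfg <- tiny_cnn_config(seed = 9, epochs = 4L, batch_size = 10L,
                         learning_rate = 3e-3)
  items <- lapply(1:40, function(i) {
    bits <- rbinom(25, 1, 0.3)
    base <- matrix(0.1, 20, 20)
    for (cell in which(bits == 1)) {
      r <- (cell - 1) %/% 5; cc <- (cell - 1) %% 5
      base[(r * 4 + 1):(r * 4 + 4), (cc * 4 + 1):(cc * 4 + 4)] <- 0.9
    }
    list(raster = base + matrix(rnorm(400, 0, 0.01), 20, 20),
         key = channel_key("ECFP", bits), channel = "ECFP")
  })
  set <- structure(list(items = items, mode = "channel", n = 5L,
                        manifest = list(seed = 1, n_images = 40L,
                                        mode = "channel", config_hash = "x")),
                   class = "labeled_set")
  m1 <- train_decoder(build_decoder(cfg), set)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  expect_true(m1$trained)
  m2 <- train_decoder(build_decoder(cfg), set)
  expect_equal(tail(m2$loss_history, 1), tail(m1$loss_history, 1))
  expect_equal(m1$params$fc2$W, m2$params$fc2$W)

  expect_error(train_decoder(build_decoder(cfg),
                             structure(list(items = list(), mode = "channel",
                                            n = 5L, manifest = list()),
                                       class = "labeled_set")),
               "empty")

  # prediction mechanics: right length, finite scores, threshold monotone
  key <- predict_channel_key(m1, items[[1]]$raster, "EGFP")
  expect_length(key$bits, 25L)
  expect_true(all(is.finite(attr(key, "scores"))))
  ones <- vapply(c(0.9, 0.5, 0.1, -0.5), function(th) {
    m1$decision_threshold <- th
    sum(predict_channel_key(m1, items[[1]]$raster)$bits)
  }, 0)
  expect_true(all(diff(ones) >= 0))
  expect_error(predict_scores(m1, matrix(0, 7, 7)), "expects")

  # forward pass of an all-zero image stays finite
  expect_true(all(is.finite(predict_scores(m1, matrix(0, 20, 20)))))
})

test_that("bit error ratios count mismatched bits over total bits", {
  nl <- fix_noiseless()
  # 10 noiseless images with 2 deliberately flipped truth bits in total:
  # the baseline reader decodes perfectly, so BER = 2 / 490
  set.seed(3)
  items <- lapply(1:10, function(i) {
    m <- random_code(7, seed = 300 + i)
    list(raster = compose_channel_image(m, "EGFP", nl$lib, nl$cfg),
         key = encode_channels(m)$EGFP, channel = "EGFP")
  })
  items[[1]]$key$bits[5] <- 1L - items[[1]]$key$bits[5]
  items[[7]]$key$bits[43] <- 1L - items[[7]]$key$bits[43]
  es <- structure(list(items = items, mode = "channel", n = 7L,
                       manifest = list(seed = 300, n_images = 10L,
                                       mode = "channel", config_hash = "y")),
                  class = "labeled_set")
  rep <- evaluate_ber(nl$layout, es)
  expect_equal(rep$n_bits_total, 490L)
  expect_equal(rep$n_bit_errors, 2L)
  expect_equal(rep$ber, 2 / 490)
  expect_equal(sum(rep$per_channel[, "errors"]), 2)

  # perfect predictions give BER 0
  items[[1]]$key$bits[5] <- 1L - items[[1]]$key$bits[5]
  items[[7]]$key$bits[43] <- 1L - items[[7]]$key$bits[43]
  es$items <- items
  expect_equal(evaluate_ber(nl$layout, es)$ber, 0)
})

test_that("strict evaluation refuses the training set itself", {
  ns <- fix_noisy()
  cfg <- cnn_config("desk", seed = 2, epochs = 1L, batch_size = 10L)
  train <- generate_dataset(10, ns$lib, ns$cfg, seed = 71)
  m <- train_decoder(build_decoder(cfg), train)
  expect_error(evaluate_ber(m, train), "same manifest")
  expect_warning(evaluate_ber(m, train, strict = FALSE), "same manifest")
  ev <- generate_dataset(10, ns$lib, ns$cfg, seed = 72)
  expect_s3_class(evaluate_ber(m, ev), "ber_report")
})
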