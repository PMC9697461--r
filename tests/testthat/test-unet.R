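test_that("elu follows its closed form and has a nonvanishing derivative", {
  expect_equal(elu(0, 1), 0)
  expect_equal(elu(2, 1), 2)
  expect_equal(elu(-1, 1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(c(-2, 0, 3), 0.5), c(0.5 * (exp(-2) - 1), 0, 3))
  # derivative of the negative branch is alpha * exp(x) > 0 everywhere
  d <- activation <- panfrax:::activation_fun("elu", 1)
  g <- d$df(array(c(-50, -1, 0, 2), c(2, 2, 1)))
  expect_true(all(g > 0))
})

test_that("unet construction enforces divisibility and level structure", {
  expect_error(unet_spec(input_size = 100, depth = 4), "divisible")
  spec <- unet_spec(input_size = 32, depth = 3, base_channels = 2)
  model <- panfrax:::with_seed(1, build_unet(spec))
  # channels double per level; head is 1 x 1 single-channel
  expect_equal(model$layers$enc1_a$cout, 2L)
  expect_equal(model$layers$enc2_a$cout, 4L)
  expect_equal(model$layers$bot_a$cout, 8L)
  expect_equal(model$layers$head$cout, 1L)
  expect_equal(model$layers$head$k, 1L)

  # forward pass keeps spatial shape; bottleneck sits at input / 2^(d-1)
  x <- array(runif(32 * 32), c(32, 32, 1))
  fw <- panfrax:::unet_forward(model, x, keep_cache = TRUE)
  expect_identical(dim(fw$logits), c(32L, 32L))
  expect_equal(dim(fw$cache$bot$z1)[1], 8L)   # 32 / 2^2
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  spec <- unet_spec(input_size = 16, depth = 2, base_channels = 2)
  model <- build_unet(spec)
  x <- array(runif(256), c(16, 16, 1))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fw <- panfrax:::unet_forward(model, x, keep_cache = TRUE)
  ls <- panfrax:::seg_loss(fw$logits, y, dice_weight = 1)
  gr <- panfrax:::unet_backward(model, fw$cache, ls$dlogits)
  eps <- 1e-5
  for (nm in c("enc1_a", "bot_b", "dec1_a", "head")) {
    w <- model$layers[[nm]]$w
    i <- nrow(w); j <- ncol(w)
    m2 <- model
    m2$layers[[nm]]$w[i, j] <- w[i, j] + eps
    lp <- panfrax:::seg_loss(panfrax:::unet_forward(m2, x)$logits, y, 1)$loss
    m2$layers[[nm]]$w[i, j] <- w[i, j] - eps
    lm <- panfrax:::seg_loss(panfrax:::unet_forward(m2, x)$logits, y, 1)$loss
    expect_equal(gr[[nm]]$dw[i, j], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training reduces loss, is deterministic, and can memorize", {
  # tiny synthetic task: segment a bright blob on a dark field at 32 x 32
  set.seed(9)
  make_pair <- function() {
    img <- matrix(round(runif(1024, 20, 60)), 32, 32)
    r <- sample(8:24, 1); c <- sample(8:24, 1)
    mask <- matrix(0L, 32, 32)
    mask[(r - 3):(r + 3), (c - 3):(c + 3)] <- 1L
    img[mask == 1] <- round(runif(sum(mask), 180, 220))
    list(image = img, mask = mask)
  }
  pairs <- replicate(6, make_pair(), simplify = FALSE)
  spec <- unet_spec(input_size = 32, depth = 2, base_channels = 4)
  cfg <- train_config(batch_size = 3, learning_rate = 0.005, epochs = 15, seed = 2)
  fit <- train_segmenter(pairs, cfg, spec)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])

  fit2 <- train_segmenter(pairs, cfg, spec)
  expect_identical(fit$loss_history, fit2$loss_history)

  # one-image memorization: training-image Dice >= 0.9
  one <- pairs[1]
  fit1 <- train_segmenter(one, train_config(batch_size = 1, learning_rate = 0.01,
                                            epochs = 60, seed = 3), spec)
  pred <- predict_mask(fit1, one[[1]]$image, 0.5)
  expect_gte(dice_coefficient(pred, one[[1]]$mask), 0.9)

  expect_error(train_segmenter(list(), cfg, spec), "at least one")
})

test_that("swapping the activation changes weights but not shapes", {
  set.seed(9)
  img <- matrix(round(runif(1024, 20, 200)), 32, 32)
  mask <- matrix(0L, 32, 32); mask[10:20, 10:20] <- 1L
  pairs <- list(list(image = img, mask = mask))
  fits <- lapply(c("relu", "leaky_relu", "elu"), function(act) {
    train_segmenter(pairs,
                    train_config(batch_size = 1, learning_rate = 0.01,
                                 epochs = 3, seed = 4),
                    unet_spec(input_size = 32, depth = 2, base_channels = 4,
                              activation = act))
  })
  for (k in 2:3) {
    for (nm in names(fits[[1]]$model$layers)) {
      expect_identical(dim(fits[[1]]$model$layers[[nm]]$w),
                       dim(fits[[k]]$model$layers[[nm]]$w))
    }
    expect_false(identical(fits[[1]]$model$layers$head$w,
                           fits[[k]]$model$layers$head$w))
  }
})

test_that("predict_mask respects thresholds, shape, and resize round-trip", {
  spec <- unet_spec(input_size = 32, depth = 2, base_channels = 2)
  model <- panfrax:::with_seed(5, build_unet(spec))
  img <- matrix(round(runif(32 * 32) * 255), 32, 32)
  expect_equal(sum(predict_mask(model, img, threshold = 1)), 0)
  expect_equal(sum(predict_mask(model, img, threshold = 0)), 32 * 32)
  m <- predict_mask(model, img, 0.5)
  expect_identical(dim(m), dim(img))
  # non-native size: output comes back at the original resolution
  img2 <- matrix(round(runif(48 * 40) * 255), 48, 40)
  expect_identical(dim(predict_mask(model, img2, 0.5)), dim(img2))
})

test_that("dice coefficient matches set algebra", {
  a <- matrix(0L, 8, 8); a[1:4, ] <- 1L
  b <- matrix(0L, 8, 8); b[3:6, ] <- 1L
  expect_equal(dice_coefficient(a, b), 2 * 16 / 64)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
})

test_that("checkpoints round-trip through JSON", {
  set.seed(9)
  img <- matrix(round(runif(1024, 20, 200)), 32, 32)
  mask <- matrix(0L, 32, 32); mask[10:20, 10:20] <- 1L
  fit <- train_segmenter(list(list(image = img, mask = mask)),
                         train_config(batch_size = 1, learning_rate = 0.01,
                                      epochs = 2, seed = 7),
                         unet_spec(input_size = 32, depth = 2, base_channels = 2))
  f <- tempfile(fileext = ".json")
  save_segmenter(fit, f)
  fit2 <- load_segmenter(f)
  expect_equal(fit2$model$layers$head$w, fit$model$layers$head$w, tolerance = 1e-12)
  expect_identical(predict_mask(fit2, img, 0.5), predict_mask(fit, img, 0.5))
  unlink(f)
})
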