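# Scratch-built U-Net: an encoder that halves spatial size per level while
# doubling channels, a decoder that upsamples and concatenates the
# same-level encoder feature (skip connection), and a single-channel
# sigmoid head at input resolution. Convolutions are 3 x 3 with same
# padding; the head is 1 x 1. The activation function is a configuration
# toggle (relu / leaky_relu / elu) rather than a code fork, because the
# choice of activation — ELU in particular, whose derivative never
# vanishes for finite inputs — is the studied design variable.

#' Exponential linear unit
#'
#' `x` for `x >= 0`, `alpha * (exp(x) - 1)` otherwise. Unlike ReLU its
#' derivative (`1` or `alpha * exp(x)`) is nonzero for every finite input,
#' avoiding dead units.
#'
#' @param x Numeric vector/array.
#' @param alpha Positive scale of the negative branch.
#' @return Transformed values, same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  assert_that(alpha > 0, "alpha must be > 0")
  ifelse(x >= 0, x, alpha * (exp(x) - 1))
}

activation_fun <- function(name, alpha = 1) {
  switch(name,
    elu = list(
      f = function(x) { neg <- x < 0; x[neg] <- alpha * (exp(x[neg]) - 1); x },
      df = function(z) { d <- array(1, dim(z)); neg <- z < 0; d[neg] <- alpha * exp(z[neg]); d }),
    relu = list(
      f = function(x) { x[x < 0] <- 0; x },
      df = function(z) { d <- array(1, dim(z)); d[z < 0] <- 0; d }),
    leaky_relu = list(
      f = function(x) { neg <- x < 0; x[neg] <- 0.01 * x[neg]; x },
      df = function(z) { d <- array(1, dim(z)); d[z < 0] <- 0.01; d }),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

#' U-Net architecture specification
#'
#' @param input_size Square input side in pixels; must be divisible by
#'   `2^(depth - 1)`. 512 is the full-scale default; 128 is the desk-scale
#'   test profile.
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels at the first level; doubled per level.
#' @param activation One of `"relu"`, `"leaky_relu"`, `"elu"`.
#' @param elu_alpha ELU negative-branch scale.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(input_size = 512, depth = 5, base_channels = 16,
                      activation = c("elu", "relu", "leaky_relu"),
                      elu_alpha = 1) {
  activation <- match.arg(activation)
  assert_that(depth >= 2, "depth must be >= 2")
  assert_that(input_size %% 2^(depth - 1) == 0,
              sprintf("input_size must be divisible by 2^(depth-1) = %d", 2^(depth - 1)))
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 activation = activation, elu_alpha = elu_alpha),
            class = "unet_spec")
}

conv_layer <- function(cin, cout, k) {
  sd <- sqrt(2 / (k * k * cin))
  list(w = matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

#' Build an untrained U-Net model
#'
#' Weights are He-initialized from the current RNG state; wrap in a fixed
#' seed for reproducible models.
#'
#' @param spec A [unet_spec()].
#' @return An object of class `unet_model` with `spec` and `layers`.
#' @export
build_unet <- function(spec) {
  assert_that(inherits(spec, "unet_spec"), "spec must be a unet_spec")
  d <- spec$depth
  ch <- spec$base_channels * 2^(seq_len(d) - 1)
  layers <- list()
  cin <- 1L
  for (i in seq_len(d - 1)) {
    layers[[sprintf("enc%d_a", i)]] <- conv_layer(cin, ch[i], 3L)
    layers[[sprintf("enc%d_b", i)]] <- conv_layer(ch[i], ch[i], 3L)
    cin <- ch[i]
  }
  layers[["bot_a"]] <- conv_layer(ch[d - 1], ch[d], 3L)
  layers[["bot_b"]] <- conv_layer(ch[d], ch[d], 3L)
  for (i in rev(seq_len(d - 1))) {
    layers[[sprintf("dec%d_up", i)]] <- conv_layer(ch[i + 1], ch[i], 3L)
    layers[[sprintf("dec%d_a", i)]] <- conv_layer(2L * ch[i], ch[i], 3L)
    layers[[sprintf("dec%d_b", i)]] <- conv_layer(ch[i], ch[i], 3L)
  }
  layers[["head"]] <- conv_layer(ch[1], 1L, 1L)
  structure(list(spec = spec, layers = layers), class = "unet_model")
}

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

conv_f <- function(x, layer) conv2d_fwd(x, layer$w, layer$b, layer$k)

# Forward pass; returns logits matrix and (optionally) the cache needed
# for backprop.
unet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  act <- activation_fun(spec$activation, spec$elu_alpha)
  L <- model$layers
  d <- spec$depth
  cache <- list(enc = vector("list", d - 1), dec = vector("list", d - 1))
  skips <- vector("list", d - 1)
  h <- x
  for (i in seq_len(d - 1)) {
    z1 <- conv_f(h, L[[sprintf("enc%d_a", i)]]); a1 <- act$f(z1)
    z2 <- conv_f(a1, L[[sprintf("enc%d_b", i)]]); a2 <- act$f(z2)
    pool <- maxpool2_fwd(a2)
    if (keep_cache) cache$enc[[i]] <- list(x = h, z1 = z1, a1 = a1, z2 = z2,
                                           idx = pool$idx,
                                           H = dim(a2)[1], W = dim(a2)[2])
    skips[[i]] <- a2
    h <- pool$y
  }
  zb1 <- conv_f(h, L$bot_a); ab1 <- act$f(zb1)
  zb2 <- conv_f(ab1, L$bot_b); h2 <- act$f(zb2)
  if (keep_cache) cache$bot <- list(x = h, z1 = zb1, a1 = ab1, z2 = zb2)
  h <- h2
  for (i in rev(seq_len(d - 1))) {
    u <- upsample2_fwd(h)
    zu <- conv_f(u, L[[sprintf("dec%d_up", i)]]); au <- act$f(zu)
    skip <- skips[[i]]
    cat_ <- array(c(au, skip), dim = c(dim(au)[1], dim(au)[2], dim(au)[3] + dim(skip)[3]))
    z1 <- conv_f(cat_, L[[sprintf("dec%d_a", i)]]); a1 <- act$f(z1)
    z2 <- conv_f(a1, L[[sprintf("dec%d_b", i)]]); h <- act$f(z2)
    if (keep_cache) cache$dec[[i]] <- list(u = u, zu = zu, au = au, cat = cat_,
                                           z1 = z1, a1 = a1, z2 = z2)
  }
  logits <- conv_f(h, L$head)
  if (keep_cache) cache$head_in <- h
  list(logits = logits[, , 1], cache = if (keep_cache) cache else NULL)
}

# Backward pass; dlogits is an (H, W) matrix of loss gradients wrt the
# head logits. Returns a named list of gradients matching model$layers.
unet_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  act <- activation_fun(spec$activation, spec$elu_alpha)
  L <- model$layers
  d <- spec$depth
  grads <- list()
  bw <- function(name, x, g) {
    r <- conv2d_bwd(x, L[[name]]$w, g, L[[name]]$k)
    grads[[name]] <<- list(dw = r$dw, db = r$db)
    r$dx
  }
  g <- bw("head", cache$head_in, as_cube(dlogits))
  skip_grads <- vector("list", d - 1)
  for (i in seq_len(d - 1)) {          # decoder applied d-1..1; reverse order
    cc <- cache$dec[[i]]
    g <- bw(sprintf("dec%d_b", i), cc$a1, g * act$df(cc$z2))
    g <- bw(sprintf("dec%d_a", i), cc$cat, g * act$df(cc$z1))
    n_up <- dim(cc$au)[3]
    g_au <- g[, , seq_len(n_up), drop = FALSE]
    skip_grads[[i]] <- g[, , n_up + seq_len(dim(g)[3] - n_up), drop = FALSE]
    g <- bw(sprintf("dec%d_up", i), cc$u, g_au * act$df(cc$zu))
    g <- upsample2_bwd(g)
  }
  cc <- cache$bot
  g <- bw("bot_b", cc$a1, g * act$df(cc$z2))
  g <- bw("bot_a", cc$x, g * act$df(cc$z1))
  for (i in rev(seq_len(d - 1))) {
    cc <- cache$enc[[i]]
    g <- maxpool2_bwd(g, cc$idx, cc$H, cc$W)
    g <- g + skip_grads[[i]]
    g <- bw(sprintf("enc%d_b", i), cc$a1, g * act$df(cc$z2))
    g <- bw(sprintf("enc%d_a", i), cc$x, g * act$df(cc$z1))
  }
  grads
}

# Binary segmentation loss: mean BCE plus a soft-Dice term (weight
# `dice_weight`), evaluated on sigmoid probabilities. Returns the loss and
# the gradient wrt logits.
seg_loss <- function(logits, target, dice_weight = 1, eps = 1e-6) {
  p <- 1 / (1 + exp(-logits))
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  dlog <- (p - target) / n
  s <- sum(p) + sum(target) + eps
  num <- 2 * sum(p * target) + eps
  dice <- num / s
  if (dice_weight > 0) {
    ddice_dp <- (2 * target * s - num) / s^2
    dlog <- dlog + dice_weight * (-ddice_dp) * p * (1 - p)
  }
  list(loss = bce + dice_weight * (1 - dice), bce = bce, dice = dice, dlogits = dlog)
}

#' Training configuration for the segmentation networks
#'
#' Full-scale defaults follow the published recipe (batch size 6, learning
#' rate 1e-4, 300 epochs at 512 x 512); smoke-scale runs override them.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param epochs Training epochs.
#' @param seed Integer seed controlling init and shuffling.
#' @param loss `"bce_dice"` (default) or `"bce"`.
#' @param dice_weight Weight of the soft-Dice term when `loss = "bce_dice"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 6L, learning_rate = 1e-4, epochs = 300L,
                         seed = 1L, loss = c("bce_dice", "bce"),
                         dice_weight = 1) {
  loss <- match.arg(loss)
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss,
                 dice_weight = if (loss == "bce") 0 else dice_weight),
            class = "train_config")
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mw = l$w * 0, vw = l$w * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mw <- beta1 * st$mw + (1 - beta1) * g$dw
    st$vw <- beta2 * st$vw + (1 - beta2) * g$dw^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[nm]]$w <- layers[[nm]]$w - lr * (st$mw / corr1) / (sqrt(st$vw / corr2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[nm]] <- st
  }
  list(layers = layers, state = state)
}

#' Train a U-Net segmenter
#'
#' Trains on (radiograph, binary mask) pairs with Adam; the whole run is a
#' pure function of (pairs, cfg, spec) — weights are initialized and the
#' data shuffled from `cfg$seed`.
#'
#' @param pairs List of `list(image, mask)` — 8-bit image matrix plus 0/1
#'   mask of the same shape, both at `spec$input_size`.
#' @param cfg A [train_config()].
#' @param spec A [unet_spec()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `unet_fit`: `model` (a `unet_model`),
#'   `loss_history` (per-epoch mean loss), `cfg`.
#' @export
train_segmenter <- function(pairs, cfg = train_config(), spec = unet_spec(),
                            verbose = FALSE) {
  assert_that(length(pairs) >= 1, "at least one training pair is required")
  for (p in pairs) {
    assert_that(nrow(p$image) == spec$input_size && ncol(p$image) == spec$input_size,
                "training images must be at spec$input_size")
    check_mask(p$mask, "mask")
  }
  xs <- lapply(pairs, function(p) as_cube(p$image / 255))
  ys <- lapply(pairs, function(p) p$mask)
  with_seed(cfg$seed, {
    model <- build_unet(spec)
    state <- adam_init(model$layers)
    t <- 0L
    history <- numeric(cfg$epochs)
    n <- length(pairs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          fw <- unet_forward(model, xs[[i]], keep_cache = TRUE)
          ls <- seg_loss(fw$logits, ys[[i]], cfg$dice_weight)
          ep_loss <- ep_loss + ls$loss
          gr <- unet_backward(model, fw$cache, ls$dlogits / length(idx))
          if (is.null(acc)) acc <- gr else {
            for (nm in names(gr)) {
              acc[[nm]]$dw <- acc[[nm]]$dw + gr[[nm]]$dw
              acc[[nm]]$db <- acc[[nm]]$db + gr[[nm]]$db
            }
          }
        }
        t <- t + 1L
        upd <- adam_step(model$layers, state, acc, cfg$learning_rate, t)
        model$layers <- upd$layers
        state <- upd$state
      }
      history[epoch] <- ep_loss / n
      if (verbose) message(sprintf("epoch %d/%d loss %.4f", epoch, cfg$epochs, history[epoch]))
    }
    structure(list(model = model, loss_history = history, cfg = cfg),
              class = "unet_fit")
  })
}

#' Predict a binary mask for an image
#'
#' Resizes the image to the model's input size (bilinear), runs the
#' forward pass, thresholds the sigmoid probabilities (strictly above
#' `threshold`), and maps the mask back to the original resolution with
#' nearest-neighbour interpolation.
#'
#' @param model A `unet_model` or `unet_fit`.
#' @param image 8-bit grayscale matrix of any size.
#' @param threshold Probability threshold in [0, 1]; `1` yields an empty
#'   mask, `0` an all-ones mask.
#' @return 0/1 matrix with the input image's shape.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (inherits(model, "unet_fit")) model <- model$model
  assert_that(inherits(model, "unet_model"), "model must be a unet_model or unet_fit")
  check_image(image)
  prob <- predict_prob(model, image)
  out <- (prob > threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

# Sigmoid probability map at the original image resolution.
predict_prob <- function(model, image) {
  s <- model$spec$input_size
  h <- nrow(image); w <- ncol(image)
  x <- if (h == s && w == s) image else resize_image(image, s, s, "bilinear")
  fw <- unet_forward(model, as_cube(x / 255), keep_cache = FALSE)
  prob <- 1 / (1 + exp(-fw$logits))
  if (h == s && w == s) prob else resize_image(prob, h, w, "nearest")
}

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return Dice overlap in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  check_mask(a); check_mask(b)
  check_same_shape(a, b, "masks")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

#' Save / load a trained segmenter as JSON
#'
#' Checkpoints are plain JSON (spec, config, loss history, flattened
#' weights), so they survive text-only storage.
#'
#' @param fit A `unet_fit`.
#' @param path Output file.
#' @return `path` invisibly for save; a `unet_fit` for load.
#' @export
save_segmenter <- function(fit, path) {
  assert_that(inherits(fit, "unet_fit"), "fit must be a unet_fit")
  obj <- list(spec = unclass(fit$model$spec), cfg = unclass(fit$cfg),
              loss_history = fit$loss_history,
              layers = lapply(fit$model$layers, function(l)
                list(w = as.numeric(l$w), b = as.numeric(l$b),
                     k = l$k, cin = l$cin, cout = l$cout)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  assert_that(file.exists(path), sprintf("no such checkpoint: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(unet_spec, obj$spec[c("input_size", "depth", "base_channels",
                                        "activation", "elu_alpha")])
  layers <- lapply(obj$layers, function(l) {
    k <- l$k; cin <- l$cin; cout <- l$cout
    list(w = matrix(l$w, k * k * cin, cout), b = as.numeric(l$b),
         k = k, cin = cin, cout = cout)
  })
  model <- structure(list(spec = spec, layers = layers), class = "unet_model")
  cfg <- do.call(train_config, obj$cfg[c("batch_size", "learning_rate",
                                         "epochs", "seed", "loss")])
  structure(list(model = model, loss_history = as.numeric(obj$loss_history),
                 cfg = cfg), class = "unet_fit")
}
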