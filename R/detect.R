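# Box-detection stage. Two interchangeable box sources feed the fusion
# stage: (a) a detections file in YOLO text format — the stand-in for the
# external LAT-YOLOv4 detector, letting the published fusion behaviour be
# exercised with arbitrary box sources — and (b) a compact single-scale
# grid detector trainable on phantoms in minutes (a convolutional grid
# predicting per-cell objectness, class scores and box offsets).

yolo_fields <- function(line, lineno, path) {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  if (!(length(parts) %in% c(5L, 6L)))
    stop(sprintf("%s line %d: expected 5 or 6 fields, got %d",
                 path, lineno, length(parts)), call. = FALSE)
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals))
    stop(sprintf("%s line %d: non-numeric field", path, lineno), call. = FALSE)
  vals
}

#' Read YOLO-format box annotations
#'
#' Each line is `class_id cx cy w h [confidence]` with coordinates
#' normalized to [0, 1]; class ids 0-5 map to [fracture_classes()].
#' Normalized boxes are converted to half-open pixel rectangles; files
#' without a confidence column get confidence 1 (ground truth).
#'
#' @param path Annotation text file.
#' @param image_size `c(width, height)` in pixels.
#' @return Detections data.frame (klass, x0, y0, x1, y1, confidence).
#' @export
read_annotations <- function(path, image_size) {
  assert_that(file.exists(path), sprintf("no such annotation file: %s", path))
  w <- image_size[1]; h <- image_size[2]
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(klass = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    v <- yolo_fields(lines[i], i, path)
    cid <- v[1]
    if (cid != round(cid) || cid < 0 || cid > 5)
      stop(sprintf("%s line %d: class_id %s outside 0-5", path, i, format(cid)),
           call. = FALSE)
    if (any(v[2:5] < 0) || any(v[2:3] > 1) || any(v[4:5] > 1) || any(v[4:5] <= 0))
      stop(sprintf("%s line %d: coordinates outside [0, 1]", path, i), call. = FALSE)
    conf <- if (length(v) == 6L) v[6] else 1
    data.frame(klass = fracture_classes()[cid + 1L],
               x0 = round(v[2] * w - v[4] * w / 2),
               y0 = round(v[3] * h - v[5] * h / 2),
               x1 = round(v[2] * w + v[4] * w / 2),
               y1 = round(v[3] * h + v[5] * h / 2),
               confidence = conf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$x0 <- pmax(out$x0, 0); out$y0 <- pmax(out$y0, 0)
  out$x1 <- pmin(out$x1, w); out$y1 <- pmin(out$y1, h)
  out
}

#' Write detections in YOLO text format
#'
#' Pixel boxes are normalized by the image size; the confidence is written
#' as an optional 6th column when any detection has confidence below 1.
#' Round-trips with [read_annotations()] to within 1 px.
#'
#' @param dets Detections data.frame.
#' @param path Output text file.
#' @param image_size `c(width, height)` in pixels.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path, image_size) {
  w <- image_size[1]; h <- image_size[2]
  if (is.null(dets) || nrow(dets) == 0) {
    ok <- try(writeLines(character(), path), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("failed to write detections to %s", path), call. = FALSE)
    return(invisible(path))
  }
  cid <- match(dets$klass, fracture_classes()) - 1L
  assert_that(!anyNA(cid), "unknown class label in detections")
  cx <- (dets$x0 + dets$x1) / 2 / w
  cy <- (dets$y0 + dets$y1) / 2 / h
  bw <- (dets$x1 - dets$x0) / w
  bh <- (dets$y1 - dets$y0) / h
  with_conf <- any(dets$confidence < 1)
  lines <- vapply(seq_len(nrow(dets)), function(i) {
    base <- sprintf("%d %.6f %.6f %.6f %.6f", cid[i], cx[i], cy[i], bw[i], bh[i])
    if (with_conf) paste(base, sprintf("%.6f", dets$confidence[i])) else base
  }, character(1))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write detections to %s", path), call. = FALSE)
  invisible(path)
}

#' Grid detector architecture specification
#'
#' A single-scale convolutional grid: three stride-2 (pooled) conv blocks
#' reduce the input by 8x, and a 1 x 1 head predicts, per cell, an
#' objectness logit, six class logits and four box parameters (sigmoid
#' center offsets within the cell and sigmoid width/height fractions).
#'
#' @param input_size Square input side (divisible by 8).
#' @param channels Channel widths of the three conv blocks.
#' @param activation Activation name as in [unet_spec()].
#' @return An object of class `grid_detector_spec`.
#' @export
grid_detector_spec <- function(input_size = 128, channels = c(8, 16, 16),
                               activation = "elu") {
  assert_that(input_size %% 8 == 0, "input_size must be divisible by 8")
  assert_that(length(channels) == 3, "channels must have length 3")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels), activation = activation,
                 grid = as.integer(input_size / 8)),
            class = "grid_detector_spec")
}

build_grid_detector <- function(spec) {
  ch <- spec$channels
  layers <- list(
    c1 = conv_layer(1L, ch[1], 3L),
    c2 = conv_layer(ch[1], ch[2], 3L),
    c3 = conv_layer(ch[2], ch[3], 3L),
    head = conv_layer(ch[3], 11L, 1L))
  structure(list(spec = spec, layers = layers), class = "grid_detector")
}

grid_forward <- function(model, x, keep_cache = FALSE) {
  act <- activation_fun(model$spec$activation)
  L <- model$layers
  cache <- list()
  h <- x
  for (nm in c("c1", "c2", "c3")) {
    z <- conv_f(h, L[[nm]])
    a <- act$f(z)
    pool <- maxpool2_fwd(a)
    if (keep_cache) cache[[nm]] <- list(x = h, z = z, idx = pool$idx,
                                        H = dim(a)[1], W = dim(a)[2])
    h <- pool$y
  }
  out <- conv_f(h, L$head)
  if (keep_cache) cache$head_in <- h
  list(out = out, cache = if (keep_cache) cache else NULL)
}

grid_backward <- function(model, cache, dout) {
  act <- activation_fun(model$spec$activation)
  L <- model$layers
  grads <- list()
  r <- conv2d_bwd(cache$head_in, L$head$w, dout, 1L)
  grads$head <- list(dw = r$dw, db = r$db)
  g <- r$dx
  for (nm in c("c3", "c2", "c1")) {
    cc <- cache[[nm]]
    g <- maxpool2_bwd(g, cc$idx, cc$H, cc$W)
    g <- g * act$df(cc$z)
    r <- conv2d_bwd(cc$x, L[[nm]]$w, g, 3L)
    grads[[nm]] <- list(dw = r$dw, db = r$db)
    g <- r$dx
  }
  grads
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Build per-cell targets for one image's ground-truth boxes.
grid_targets <- function(boxes, spec) {
  G <- spec$grid
  stride <- spec$input_size / G
  obj <- matrix(0, G, G)
  cls <- array(0, c(G, G, 6))
  tb <- array(0, c(G, G, 4))
  if (!is.null(boxes) && nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      cx <- (boxes$x0[i] + boxes$x1[i]) / 2
      cy <- (boxes$y0[i] + boxes$y1[i]) / 2
      gj <- min(G - 1, max(0, floor(cx / stride)))
      gi <- min(G - 1, max(0, floor(cy / stride)))
      obj[gi + 1, gj + 1] <- 1
      cid <- match(boxes$klass[i], fracture_classes())
      cls[gi + 1, gj + 1, ] <- 0
      cls[gi + 1, gj + 1, cid] <- 1
      tb[gi + 1, gj + 1, ] <- c(cx / stride - gj, cy / stride - gi,
                                (boxes$x1[i] - boxes$x0[i]) / spec$input_size,
                                (boxes$y1[i] - boxes$y0[i]) / spec$input_size)
    }
  }
  list(obj = obj, cls = cls, tb = tb)
}

# Detection loss and gradient wrt the 11-channel grid output.
grid_loss <- function(out, tgt, noobj_weight = 0.5) {
  G <- dim(out)[1]
  dout <- array(0, dim(out))
  p_obj <- sigmoid(out[, , 1])
  # positive cells are rare (1-2 per image on a G x G grid); weight them up
  # so the objectness optimum is not "predict background everywhere"
  n_pos <- max(sum(tgt$obj), 1)
  wobj <- ifelse(tgt$obj == 1, G^2 / (8 * n_pos), noobj_weight)
  pc <- pmin(pmax(p_obj, 1e-7), 1 - 1e-7)
  l_obj <- -sum(wobj * (tgt$obj * log(pc) + (1 - tgt$obj) * log(1 - pc))) / G^2
  dout[, , 1] <- wobj * (p_obj - tgt$obj) / G^2
  pos <- which(tgt$obj == 1, arr.ind = TRUE)
  l_cls <- 0; l_box <- 0
  if (nrow(pos) > 0) {
    for (r in seq_len(nrow(pos))) {
      i <- pos[r, 1]; j <- pos[r, 2]
      logits <- out[i, j, 2:7]
      sm <- exp(logits - max(logits)); sm <- sm / sum(sm)
      y <- tgt$cls[i, j, ]
      l_cls <- l_cls - sum(y * log(pmax(sm, 1e-12)))
      dout[i, j, 2:7] <- (sm - y) / nrow(pos)
      tpred <- sigmoid(out[i, j, 8:11])
      diffs <- tpred - tgt$tb[i, j, ]
      l_box <- l_box + sum(diffs^2)
      dout[i, j, 8:11] <- 2 * diffs * tpred * (1 - tpred) * 5 / nrow(pos)
    }
    l_cls <- l_cls / nrow(pos)
    l_box <- l_box / nrow(pos)
  }
  list(loss = l_obj + l_cls + 5 * l_box, dout = dout)
}

#' Train the compact grid detector on phantoms
#'
#' @param pairs List of `list(image, boxes)` — image matrix at the spec's
#'   input size and a ground-truth detections data.frame.
#' @param cfg A [train_config()] (batch size, learning rate, epochs, seed).
#' @param spec A [grid_detector_spec()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `grid_detector_fit`: `model`, `loss_history`.
#' @export
train_detector <- function(pairs, cfg = train_config(), spec = grid_detector_spec(),
                           verbose = FALSE) {
  assert_that(length(pairs) >= 1, "at least one training pair is required")
  xs <- lapply(pairs, function(p) as_cube(p$image / 255))
  tgts <- lapply(pairs, function(p) grid_targets(p$boxes, spec))
  with_seed(cfg$seed, {
    model <- build_grid_detector(spec)
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
          fw <- grid_forward(model, xs[[i]], keep_cache = TRUE)
          ls <- grid_loss(fw$out, tgts[[i]])
          ep_loss <- ep_loss + ls$loss
          gr <- grid_backward(model, fw$cache, ls$dout / length(idx))
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
      if (verbose) message(sprintf("det epoch %d/%d loss %.4f", epoch, cfg$epochs,
                                   history[epoch]))
    }
    structure(list(model = model, loss_history = history, cfg = cfg),
              class = "grid_detector_fit")
  })
}

#' Detect fracture boxes from a model or a detections file
#'
#' When `source` is a file path the parsed content is returned (the
#' stand-in for an external detector); when it is a trained grid detector
#' the network runs on the image and cells whose objectness exceeds
#' `threshold` are decoded into class-labeled boxes.
#'
#' @param source A `grid_detector_fit`/`grid_detector`, or a path to a
#'   YOLO-format detections file.
#' @param image 8-bit grayscale matrix.
#' @param threshold Objectness confidence threshold.
#' @return Detections data.frame (klass, x0, y0, x1, y1, confidence).
#' @export
detect_boxes <- function(source, image, threshold = 0.25) {
  check_image(image)
  if (is.character(source)) {
    return(read_annotations(source, image_size = c(ncol(image), nrow(image))))
  }
  if (inherits(source, "grid_detector_fit")) source <- source$model
  assert_that(inherits(source, "grid_detector"),
              "source must be a grid detector or a detections file path")
  spec <- source$spec
  s <- spec$input_size
  h <- nrow(image); w <- ncol(image)
  x <- if (h == s && w == s) image else resize_image(image, s, s, "bilinear")
  out <- grid_forward(source, as_cube(x / 255))$out
  G <- spec$grid
  stride <- s / G
  rows <- list()
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      conf <- sigmoid(out[i, j, 1])
      if (conf <= threshold) next
      cls <- which.max(out[i, j, 2:7])
      tb <- sigmoid(out[i, j, 8:11])
      cx <- (j - 1 + tb[1]) * stride * w / s
      cy <- (i - 1 + tb[2]) * stride * h / s
      bw <- tb[3] * w; bh <- tb[4] * h
      rows[[length(rows) + 1]] <- data.frame(
        klass = fracture_classes()[cls],
        x0 = max(0, cx - bw / 2), y0 = max(0, cy - bh / 2),
        x1 = min(w, cx + bw / 2), y1 = min(h, cy + bh / 2),
        confidence = conf, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(klass = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  out_df <- do.call(rbind, rows)
  out_df[order(-out_df$confidence), , drop = FALSE]
}

#' Published full-scale training parameters (recorded, not re-implemented)
#'
#' The full-scale recipe behind the emulated system: the external LAT
#' detector trained at 608 x 608 (batch 64, subdivision 16, learning rate
#' 1e-4, 12,000 max batches ~ 711 epochs) and the segmentation U-Net at
#' 512 x 512 (batch 6, learning rate 1e-4, 300 epochs). Recorded as
#' reference metadata; the package's compact detector does not reproduce
#' the external backbone.
#'
#' @return data.frame with one row per module.
#' @export
reference_training_parameters <- function() {
  data.frame(
    module = c("box_detector", "unet"),
    batch_size = c(64L, 6L),
    subdivision = c(16L, NA_integer_),
    resolution = c("608x608", "512x512"),
    learning_rate = c(1e-4, 1e-4),
    epochs = c(711L, 300L),
    stringsAsFactors = FALSE)
}
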