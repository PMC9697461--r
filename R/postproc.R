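# Post-processing: tooth-region hole filling, inversion to a weight map,
# multiplicative suppression of fracture-line pixels inside the tooth row,
# speckle filtering, duplicate-box removal, and box-line fusion.
#
# The suppression stage is the pipeline's false-positive mechanism: the
# tooth-region mask is dilated and hole-filled, inverted into a 0/1 weight
# map, and multiplied into the predicted fracture-line mask, erasing line
# pixels that fall in the tooth row (where interdental seams mimic fracture
# lines).

#' Close holes in a tooth-region mask by dilation and hole filling
#'
#' Dilates with a disc structuring element and then fills enclosed holes,
#' producing the solid tooth-row band used as a suppression weight map.
#' Dilation is extensive (output contains the input) and the operation is
#' idempotent once all holes are closed.
#'
#' @param mask 0/1 matrix.
#' @param se_radius Disc radius in pixels (>= 1).
#' @param iterations Number of dilation passes.
#' @return 0/1 matrix.
#' @export
fill_tooth_region <- function(mask, se_radius = 3, iterations = 2) {
  check_mask(mask)
  assert_that(se_radius >= 1, "se_radius must be >= 1")
  assert_that(iterations >= 1, "iterations must be >= 1")
  if (!any(mask == 1)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, "disc")
  out <- mask
  for (i in seq_len(iterations)) out <- as.matrix(EBImage::dilate(out, brush))
  out <- as.matrix(EBImage::fillHull(out))
  storage.mode(out) <- "integer"
  out
}

#' Invert a binary mask
#'
#' @param mask 0/1 matrix.
#' @return Pixelwise `1 - mask`.
#' @export
invert_mask <- function(mask) {
  check_mask(mask)
  out <- 1L - mask
  storage.mode(out) <- "integer"
  out
}

#' Suppress fracture-line pixels inside the tooth region
#'
#' Multiplies the fracture mask by the inverted (hole-filled) tooth mask:
#' the result is zero wherever the tooth mask is set and unchanged
#' elsewhere, i.e. `frac AND NOT tooth`.
#'
#' @param frac_mask Predicted fracture-line 0/1 matrix.
#' @param tooth_filled Hole-filled tooth-region 0/1 matrix (same shape).
#' @return Suppressed 0/1 matrix.
#' @export
suppress_fracture_in_tooth <- function(frac_mask, tooth_filled) {
  check_mask(frac_mask); check_mask(tooth_filled)
  check_same_shape(frac_mask, tooth_filled, "fracture and tooth masks")
  out <- frac_mask * invert_mask(tooth_filled)
  storage.mode(out) <- "integer"
  out
}

#' Remove small connected components from a mask
#'
#' Components (8-connectivity) smaller than `min_component_size` pixels are
#' removed; thresholded network output needs this speckle filter.
#'
#' @param mask 0/1 matrix.
#' @param min_component_size Minimum surviving component size in pixels.
#' @return Filtered 0/1 matrix.
#' @export
filter_components <- function(mask, min_component_size = 20) {
  check_mask(mask)
  if (min_component_size <= 0 || !any(mask == 1)) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  lab <- as.matrix(EBImage::bwlabel(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_size)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Extract connected line components from a mask
#'
#' @param mask 0/1 matrix.
#' @return List of components, each with `pixels` (n x 2 row/col matrix),
#'   `size`, and `box` (half-open pixel rectangle x0, y0, x1, y1).
#' @export
line_components <- function(mask) {
  check_mask(mask)
  if (!any(mask == 1)) return(list())
  lab <- as.matrix(EBImage::bwlabel(mask))
  lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    list(pixels = idx, size = nrow(idx),
         box = c(x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
                 x1 = max(idx[, 2]), y1 = max(idx[, 1])))
  })
}

#' Intersection-over-union of two pixel boxes
#'
#' Boxes are half-open rectangles `c(x0, y0, x1, y1)`.
#'
#' @param a,b Numeric length-4 boxes.
#' @return IoU in [0, 1].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  uni <- area_a + area_b - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Remove duplicate detection boxes (class-wise greedy NMS)
#'
#' Boxes are visited in descending confidence (ties broken by larger area,
#' then left-to-right by x0); a box is dropped when its IoU with an already
#' kept box of the same class reaches `iou_threshold`. Never increases the
#' box count and is idempotent.
#'
#' @param dets Detections data.frame (klass, x0, y0, x1, y1, confidence).
#' @param iou_threshold Suppression threshold in (0, 1].
#' @return Filtered detections data.frame.
#' @export
remove_duplicate_boxes <- function(dets, iou_threshold = 0.5) {
  assert_that(iou_threshold > 0 && iou_threshold <= 1,
              "iou_threshold must be in (0, 1]")
  if (is.null(dets) || nrow(dets) == 0) return(dets)
  area <- (dets$x1 - dets$x0) * (dets$y1 - dets$y0)
  ord <- order(-dets$confidence, -area, dets$x0)
  keep <- logical(nrow(dets))
  for (i in ord) {
    drop <- FALSE
    for (j in which(keep)) {
      if (dets$klass[j] == dets$klass[i] &&
          box_iou(as.numeric(dets[i, c("x0", "y0", "x1", "y1")]),
                  as.numeric(dets[j, c("x0", "y0", "x1", "y1")])) >= iou_threshold) {
        drop <- TRUE
        break
      }
    }
    if (!drop) keep[i] <- TRUE
  }
  out <- dets[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse box detections with a suppressed fracture-line mask
#'
#' Union semantics: all surviving boxes and all line components are
#' reported; no cross-modality suppression (a line inside a box is kept —
#' the two modalities cover different fracture presentations). Also renders
#' an overlay with boxes as bright rectangles and line components drawn at
#' full intensity.
#'
#' @param boxes Detections data.frame (post duplicate-removal).
#' @param line_mask Suppressed, speckle-filtered 0/1 matrix.
#' @param image Radiograph the mask belongs to (same shape).
#' @return An object of class `detection_result`: `boxes`,
#'   `line_components` (see [line_components()]), `overlay`.
#' @export
fuse_detections <- function(boxes, line_mask, image) {
  check_mask(line_mask); check_image(image)
  check_same_shape(line_mask, image, "line mask and image")
  comps <- line_components(line_mask)
  overlay <- image
  overlay[line_mask == 1] <- 255
  if (!is.null(boxes) && nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      overlay <- draw_box(overlay, as.numeric(boxes[i, c("x0", "y0", "x1", "y1")]))
    }
  }
  structure(list(boxes = boxes, line_components = comps, overlay = overlay),
            class = "detection_result")
}

draw_box <- function(image, box, value = 255) {
  h <- nrow(image); w <- ncol(image)
  r0 <- max(1L, floor(box[2]) + 1L); r1 <- min(h, max(r0, ceiling(box[4])))
  c0 <- max(1L, floor(box[1]) + 1L); c1 <- min(w, max(c0, ceiling(box[3])))
  image[r0, c0:c1] <- value; image[r1, c0:c1] <- value
  image[r0:r1, c0] <- value; image[r0:r1, c1] <- value
  image
}
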