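# Evaluation protocol: TP/FP/FN matching for mixed box + line predictions,
# precision/recall/F1, line-profile statistics, and class-distribution
# summaries. There is no true negative in this protocol: every test image
# contains at least one fracture and "no fracture anywhere" is not a
# meaningful prediction, so specificity/accuracy are undefined by design.

#' Construct an evaluation count triple
#'
#' @param tp,fp,fn Nonnegative counts of true positives (detected
#'   fractures), false positives (misdetections) and false negatives
#'   (undetected fractures).
#' @return An object of class `eval_counts`.
#' @export
eval_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  assert_that(tp >= 0 && fp >= 0 && fn >= 0, "counts must be nonnegative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("eval_counts: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Matching criteria for detection evaluation
#'
#' A predicted box matches a ground-truth fracture when its IoU with the
#' ground-truth box reaches `box_iou_min`. A predicted line component
#' matches when at least `line_overlap_min` of its pixels lie within the
#' ground-truth line dilated by `line_dilate_px`, and conversely at least
#' `line_overlap_min` of the ground-truth line lies within the component
#' dilated by the same radius.
#'
#' @param box_iou_min Box IoU threshold in (0, 1].
#' @param line_dilate_px Dilation tolerance radius for line matching (>= 1).
#' @param line_overlap_min Overlap fraction threshold in (0, 1].
#' @return An object of class `match_criteria`.
#' @export
match_criteria <- function(box_iou_min = 0.5, line_dilate_px = 5,
                           line_overlap_min = 0.5) {
  assert_that(box_iou_min > 0 && box_iou_min <= 1, "box_iou_min must be in (0, 1]")
  assert_that(line_dilate_px >= 1, "line_dilate_px must be >= 1")
  assert_that(line_overlap_min > 0 && line_overlap_min <= 1,
              "line_overlap_min must be in (0, 1]")
  structure(list(box_iou_min = box_iou_min,
                 line_dilate_px = as.integer(line_dilate_px),
                 line_overlap_min = line_overlap_min),
            class = "match_criteria")
}

dilate_mask <- function(mask, radius) {
  if (!any(mask == 1)) return(mask)
  out <- as.matrix(EBImage::dilate(mask, EBImage::makeBrush(2L * radius + 1L, "disc")))
  storage.mode(out) <- "integer"
  out
}

# Does predicted component `comp` (list with $pixels) match the GT line
# raster `gt_mask` under the two-sided dilated-overlap rule?
line_component_matches <- function(comp, gt_mask, criteria) {
  if (!any(gt_mask == 1)) return(FALSE)
  h <- nrow(gt_mask); w <- ncol(gt_mask)
  comp_mask <- matrix(0L, h, w)
  comp_mask[comp$pixels] <- 1L
  gt_dil <- dilate_mask(gt_mask, criteria$line_dilate_px)
  frac_pred <- sum(comp_mask * gt_dil) / comp$size
  comp_dil <- dilate_mask(comp_mask, criteria$line_dilate_px)
  frac_gt <- sum(gt_mask * comp_dil) / sum(gt_mask)
  frac_pred >= criteria$line_overlap_min && frac_gt >= criteria$line_overlap_min
}

# Maximum bipartite matching by augmenting paths on an eligibility matrix
# (rows = predictions, cols = ground truths). Returns the column matched to
# each row (0 = unmatched).
max_bipartite_match <- function(elig) {
  n_pred <- nrow(elig); n_gt <- ncol(elig)
  match_gt <- integer(n_gt)    # gt -> pred
  try_assign <- function(p, seen) {
    for (g in seq_len(n_gt)) {
      if (elig[p, g] && !seen[g]) {
        seen[g] <- TRUE
        res <- if (match_gt[g] == 0L) list(ok = TRUE, seen = seen) else {
          r <- try_assign(match_gt[g], seen)
          list(ok = r$ok, seen = r$seen)
        }
        seen <- res$seen
        if (res$ok) {
          match_gt[g] <<- p
          return(list(ok = TRUE, seen = seen))
        }
      }
    }
    list(ok = FALSE, seen = seen)
  }
  for (p in seq_len(n_pred)) try_assign(p, logical(n_gt))
  match_pred <- integer(n_pred)
  for (g in seq_len(n_gt)) if (match_gt[g] > 0L) match_pred[match_gt[g]] <- g
  match_pred
}

#' Match mixed box + line predictions against ground truth
#'
#' Builds the eligibility graph between predictions and ground-truth
#' fractures (boxes by IoU against the fracture's box; line components by
#' the dilated-overlap rule against the fracture's own line raster, which
#' is empty for displaced fractures) and computes a maximum one-to-one
#' matching, so the reported TP equals the best achievable assignment.
#' Boxes are listed before line components, so at equal matching size boxes
#' consume ground truths first. A ground truth matched by a box whose
#' remaining line-component predictions also overlap only it contributes a
#' single TP, and each such fully-redundant line prediction is consumed
#' rather than counted as a false positive.
#'
#' @param pred A `detection_result` (or a list with `boxes` and
#'   `line_components`).
#' @param gt A `ground_truth`.
#' @param criteria A [match_criteria()].
#' @return An [eval_counts()] with attributes `n_gt` and `n_pred`.
#' @export
match_detections <- function(pred, gt, criteria = match_criteria()) {
  boxes <- pred$boxes
  comps <- pred$line_components
  n_boxes <- if (is.null(boxes)) 0L else nrow(boxes)
  n_comps <- length(comps)
  n_pred <- n_boxes + n_comps
  n_gt <- length(gt$specs)
  h <- nrow(gt$line_mask); w <- ncol(gt$line_mask)

  # per-GT line rasters (empty for displaced fractures, which carry no line
  # label)
  gt_line_masks <- lapply(gt$specs, function(s) {
    m <- matrix(0L, h, w)
    if (s$shape != "displaced") {
      pts <- raster_polyline(s$polyline, h, w)
      if (nrow(pts) > 0) m[pts] <- 1L
      m <- dilate_mask(m, 1L)
    }
    m
  })

  elig <- matrix(FALSE, n_pred, max(n_gt, 1L))
  if (n_gt > 0 && n_pred > 0) {
    for (g in seq_len(n_gt)) {
      gbox <- as.numeric(gt$specs[[g]]$box)
      if (n_boxes > 0) {
        for (b in seq_len(n_boxes)) {
          elig[b, g] <- box_iou(as.numeric(boxes[b, c("x0", "y0", "x1", "y1")]),
                                gbox) >= criteria$box_iou_min
        }
      }
      if (n_comps > 0) {
        for (k in seq_len(n_comps)) {
          elig[n_boxes + k, g] <-
            line_component_matches(comps[[k]], gt_line_masks[[g]], criteria)
        }
      }
    }
  }

  if (n_gt == 0 || n_pred == 0) {
    matched <- integer(n_pred)
  } else {
    matched <- max_bipartite_match(elig)
  }
  tp <- sum(matched > 0L)
  # an unmatched prediction whose only eligible GTs were consumed by the
  # other modality is redundant coverage of a detected fracture, not a
  # misdetection
  fp <- 0L
  for (p in seq_len(n_pred)) {
    if (n_pred == 0) break
    if (matched[p] > 0L) next
    if (n_gt > 0 && any(elig[p, ])) next
    fp <- fp + 1L
  }
  fn <- n_gt - tp
  out <- eval_counts(tp = tp, fp = fp, fn = fn)
  attr(out, "n_gt") <- n_gt
  attr(out, "n_pred") <- n_pred
  out
}

#' Precision (misdetection rate complement)
#'
#' `tp / (tp + fp)`. Undefined (an error) when no predictions exist.
#'
#' @param c An [eval_counts()].
#' @return Precision in [0, 1].
#' @export
precision_score <- function(c) {
  assert_that(c$tp + c$fp > 0, "precision undefined: no predictions (tp + fp = 0)")
  c$tp / (c$tp + c$fp)
}

#' Recall (undetection rate complement)
#'
#' `tp / (tp + fn)`. Undefined (an error) when there is no ground truth.
#'
#' @param c An [eval_counts()].
#' @return Recall in [0, 1].
#' @export
recall_score <- function(c) {
  assert_that(c$tp + c$fn > 0, "recall undefined: no ground truth (tp + fn = 0)")
  c$tp / (c$tp + c$fn)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param p Precision in [0, 1].
#' @param r Recall in [0, 1].
#' @return `2 * p * r / (p + r)`. Undefined (an error) when `p + r = 0`.
#' @export
f1_score <- function(p, r) {
  assert_that(p >= 0 && r >= 0, "precision and recall must be nonnegative")
  assert_that(p + r > 0, "F1 undefined: precision + recall = 0")
  2 * p * r / (p + r)
}

#' Gray-level statistics along a line profile
#'
#' Samples pixels along the Bresenham raster of the segment from `p0` to
#' `p1` (pixel coordinates `c(x, y)`) and reports maximum, minimum, mean
#' and population standard deviation.
#'
#' @param image 8-bit grayscale matrix.
#' @param p0,p1 Segment endpoints `c(x, y)`, inside the image; must differ.
#' @return An object of class `profile_stats`: `maximum`, `minimum`,
#'   `mean`, `std`, `n`, `values`.
#' @export
line_profile <- function(image, p0, p1) {
  check_image(image)
  assert_that(!isTRUE(all.equal(as.numeric(p0), as.numeric(p1))),
              "profile endpoints must differ")
  h <- nrow(image); w <- ncol(image)
  for (p in list(p0, p1)) {
    assert_that(p[1] >= 0 && p[1] <= w && p[2] >= 0 && p[2] <= h,
                "profile endpoints must lie inside the image")
  }
  pts <- bresenham_points(p0[1], p0[2], p1[1], p1[2])
  pts[, 1] <- pmin(pmax(pts[, 1], 1L), h)
  pts[, 2] <- pmin(pmax(pts[, 2], 1L), w)
  vals <- image[pts]
  n <- length(vals)
  mu <- mean(vals)
  structure(list(maximum = max(vals), minimum = min(vals), mean = mu,
                 std = sqrt(sum((vals - mu)^2) / n), n = n, values = vals),
            class = "profile_stats")
}

#' Class distribution summary
#'
#' Percentages are `100 * count / total`, rounded half-up to 3 decimals.
#' Also reports the middle-region share (symphysis + body + angle + ramus)
#' and the side-region share (condyle + coronoid).
#'
#' @param counts 6-vector of per-class fracture counts in
#'   [fracture_classes()] order.
#' @return An object of class `class_distribution`: `counts`, `total`,
#'   `percentages`, `middle_share`, `side_share`.
#' @export
class_distribution <- function(counts) {
  assert_that(length(counts) == 6 && all(counts >= 0), "counts must be 6 nonnegative values")
  total <- sum(counts)
  assert_that(total > 0, "counts must not be all zero")
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  pct <- round_half_up(100 * counts / total, 3)
  structure(list(counts = stats::setNames(as.numeric(counts), fracture_classes()),
                 total = total,
                 percentages = stats::setNames(pct, fracture_classes()),
                 middle_share = round_half_up(100 * sum(counts[1:4]) / total, 3),
                 side_share = round_half_up(100 * sum(counts[5:6]) / total, 3)),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("class_distribution (total", x$total, "fractures)\n")
  print(data.frame(class = names(x$counts), count = x$counts,
                   percentage = x$percentages, row.names = NULL))
  cat(sprintf("middle share %.3f%%  side share %.3f%%\n", x$middle_share, x$side_share))
  invisible(x)
}

#' @export
as.data.frame.profile_stats <- function(x, ...) {
  data.frame(maximum = x$maximum, minimum = x$minimum, mean = x$mean,
             std = x$std, n = x$n)
}

#' Write an evaluation report (JSON + CSV)
#'
#' Aggregates per-image counts, computes precision/recall/F1 at 3 decimals,
#' and writes a JSON report plus a CSV score table (one row per labeled
#' result, columns precision/recall/F1).
#'
#' @param counts_list Named list of [eval_counts()] (one per image or per
#'   module variant).
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @return The aggregate scores, invisibly.
#' @export
write_eval_report <- function(counts_list, path) {
  assert_that(length(counts_list) > 0, "counts_list must be nonempty")
  tp <- sum(vapply(counts_list, `[[`, integer(1), "tp"))
  fp <- sum(vapply(counts_list, `[[`, integer(1), "fp"))
  fn <- sum(vapply(counts_list, `[[`, integer(1), "fn"))
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) f1_score(p, r) else NA_real_
  agg <- c(precision = round(p, 3), recall = round(r, 3), f1 = round(f, 3))
  per_image <- lapply(counts_list, unclass)
  jsonlite::write_json(list(per_image = per_image,
                            aggregate = c(list(tp = tp, fp = fp, fn = fn),
                                          as.list(agg))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  tab <- data.frame(result = names(counts_list),
                    tp = vapply(counts_list, `[[`, integer(1), "tp"),
                    fp = vapply(counts_list, `[[`, integer(1), "fp"),
                    fn = vapply(counts_list, `[[`, integer(1), "fn"))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  invisible(agg)
}
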