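# Full-pipeline orchestration: tooth U-Net -> dilation/hole fill ->
# inversion -> fracture U-Net -> multiplicative suppression -> component
# filtering -> box source -> duplicate-box removal -> box-line fusion ->
# optional evaluation against ground truth.

#' Pipeline configuration
#'
#' Bundles the stage parameters of the combined detector. Any component
#' left `NULL` falls back to its module default.
#'
#' @param mask_threshold Probability threshold for both U-Net masks.
#' @param se_radius,fill_iterations Tooth-region dilation parameters.
#' @param min_component_size Speckle filter threshold (px) for line
#'   components.
#' @param box_iou_dedup IoU threshold of duplicate-box removal.
#' @param box_confidence Confidence threshold of the model box source.
#' @param closing_radius Radius of the morphological closing applied to the
#'   suppressed fracture mask before component extraction (bridges small
#'   breaks so one fracture yields one component); 0 disables.
#' @param criteria A [match_criteria()] for the optional evaluation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mask_threshold = 0.5, se_radius = 3,
                            fill_iterations = 2, min_component_size = 20,
                            box_iou_dedup = 0.5, box_confidence = 0.25,
                            closing_radius = 2,
                            criteria = match_criteria()) {
  structure(list(mask_threshold = mask_threshold, se_radius = se_radius,
                 fill_iterations = fill_iterations,
                 min_component_size = min_component_size,
                 box_iou_dedup = box_iou_dedup,
                 box_confidence = box_confidence,
                 closing_radius = closing_radius,
                 criteria = criteria),
            class = "pipeline_config")
}

close_mask <- function(mask, radius) {
  if (radius < 1 || !any(mask == 1)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
  out <- as.matrix(EBImage::erode(as.matrix(EBImage::dilate(mask, brush)), brush))
  storage.mode(out) <- "integer"
  out
}

#' Run the combined fracture-detection pipeline on one radiograph
#'
#' Stage order: tooth segmentation, tooth-region fill, inversion to a
#' weight map, fracture-line segmentation, multiplicative suppression,
#' closing and component filtering, box source, duplicate-box removal,
#' box-line fusion, and (when ground truth is supplied) evaluation.
#'
#' @param image 8-bit grayscale matrix.
#' @param fracture_model Trained fracture-line `unet_fit`.
#' @param tooth_model Trained tooth-region `unet_fit`.
#' @param box_source A trained `grid_detector_fit`, a detections file path,
#'   a detections data.frame, or `NULL` for line-only operation.
#' @param config A [pipeline_config()].
#' @param gt Optional `ground_truth` for evaluation.
#' @return An object of class `pipeline_result`: the fused
#'   `detection_result` plus intermediate masks, stage log, and (with
#'   `gt`) `counts`/`precision`/`recall`/`f1`.
#' @export
run_pipeline <- function(image, fracture_model, tooth_model, box_source = NULL,
                         config = pipeline_config(), gt = NULL) {
  check_image(image)
  assert_that(inherits(fracture_model, c("unet_fit", "unet_model")),
              "stage fracture-unet: fracture_model must be a trained unet_fit")
  assert_that(inherits(tooth_model, c("unet_fit", "unet_model")),
              "stage tooth-unet: tooth_model must be a trained unet_fit")
  stages <- character()
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0) {
    stages <<- c(stages, sprintf("%s (%.3fs)", name, tic() - t0))
  }

  t0 <- tic()
  tooth_raw <- predict_mask(tooth_model, image, config$mask_threshold)
  log_stage("tooth-unet", t0)

  t0 <- tic()
  tooth_filled <- fill_tooth_region(tooth_raw, config$se_radius, config$fill_iterations)
  weight_map <- invert_mask(tooth_filled)
  log_stage("tooth-fill-invert", t0)

  t0 <- tic()
  frac_raw <- predict_mask(fracture_model, image, config$mask_threshold)
  log_stage("fracture-unet", t0)

  t0 <- tic()
  suppressed <- suppress_fracture_in_tooth(frac_raw, tooth_filled)
  log_stage("suppress", t0)

  t0 <- tic()
  cleaned <- close_mask(suppressed, config$closing_radius)
  cleaned <- filter_components(cleaned, config$min_component_size)
  log_stage("filter", t0)

  t0 <- tic()
  boxes <- if (is.null(box_source)) {
    data.frame(klass = character(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), confidence = numeric(),
               stringsAsFactors = FALSE)
  } else if (is.data.frame(box_source)) {
    box_source
  } else {
    detect_boxes(box_source, image, config$box_confidence)
  }
  log_stage("box-source", t0)

  t0 <- tic()
  boxes <- remove_duplicate_boxes(boxes, config$box_iou_dedup)
  log_stage("dedup", t0)

  t0 <- tic()
  fused <- fuse_detections(boxes, cleaned, image)
  log_stage("fuse", t0)

  result <- list(detection = fused, line_mask = cleaned,
                 tooth_mask = tooth_filled, weight_map = weight_map,
                 fracture_mask_raw = frac_raw, stages = stages)
  if (!is.null(gt)) {
    t0 <- tic()
    counts <- match_detections(fused, gt, config$criteria)
    result$counts <- counts
    result$precision <- if (counts$tp + counts$fp > 0) precision_score(counts) else NA_real_
    result$recall <- if (counts$tp + counts$fn > 0) recall_score(counts) else NA_real_
    result$f1 <- if (!is.na(result$precision) && !is.na(result$recall) &&
                     result$precision + result$recall > 0)
      f1_score(result$precision, result$recall) else NA_real_
    log_stage("evaluate", t0)
    result$stages <- stages
  }
  structure(result, class = "pipeline_result")
}

#' Serialize a pipeline result to JSON
#'
#' Boxes, per-component pixel counts and bounding rectangles, evaluation
#' counts and scores (when present) — everything except the overlay image.
#'
#' @param result A `pipeline_result`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_pipeline_result <- function(result, path) {
  assert_that(inherits(result, "pipeline_result"), "result must be a pipeline_result")
  comps <- lapply(result$detection$line_components, function(cm)
    list(size = cm$size, box = as.numeric(cm$box)))
  obj <- list(boxes = result$detection$boxes, line_components = comps,
              stages = result$stages)
  if (!is.null(result$counts)) {
    obj$counts <- unclass(result$counts)
    obj$precision <- result$precision
    obj$recall <- result$recall
    obj$f1 <- result$f1
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; a nested `criteria`
#' block mirrors [match_criteria()]. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("no such config file: %s", path))
  y <- yaml::read_yaml(path)
  crit_args <- y$criteria
  crit <- if (is.null(crit_args)) match_criteria() else
    do.call(match_criteria, crit_args)
  args <- y[setdiff(names(y), "criteria")]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  assert_that(length(bad) == 0,
              sprintf("unknown pipeline config keys: %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, c(args, list(criteria = crit)))
}
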