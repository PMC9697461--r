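#' @useDynLib panfrax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal validation helpers. All user-facing errors go through stop() with
# a message naming the offending argument.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Six anatomical mandibular fracture classes
#'
#' Class labels in canonical order: symphysis, body, angle and ramus form the
#' "middle" region of the mandible; condyle and coronoid form the "side"
#' region, which appears laterally compressed on a panoramic sweep.
#'
#' @return Character vector of length 6.
#' @export
fracture_classes <- function() {
  c("symphysis", "body", "angle", "ramus", "condyle", "coronoid")
}

#' Fracture morphologies
#'
#' Three rendered morphologies: `oblique_gap` (crack with a radiolucent gap),
#' `shear_step` (brightness step with no gap), and `displaced` (condylar
#' dislocation where bone contours overlap with no visible crack line).
#'
#' @return Character vector of length 3.
#' @export
fracture_shapes <- function() {
  c("oblique_gap", "shear_step", "displaced")
}

is_image_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x))
}

check_image <- function(image, arg = "image") {
  assert_that(is_image_matrix(image), sprintf("`%s` must be a finite numeric matrix", arg))
  assert_that(min(image) >= 0 && max(image) <= 255,
              sprintf("`%s` must hold 8-bit gray values in [0, 255]", arg))
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  assert_that(is.matrix(mask) && all(mask %in% c(0, 1)),
              sprintf("`%s` must be a binary 0/1 matrix", arg))
  invisible(mask)
}

check_same_shape <- function(a, b, what = "inputs") {
  assert_that(identical(dim(a), dim(b)), sprintf("%s must share the same shape", what))
  invisible(TRUE)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Draw from an RNG stream without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
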