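test_that("tooth-region filling is extensive, hole-closing and idempotent", {
  ring <- matrix(0L, 64, 64)
  ring[20:40, 20:40] <- 1L
  ring[29:30, 29:30] <- 0L          # 2 px hole
  filled <- fill_tooth_region(ring, se_radius = 2, iterations = 1)
  expect_true(all(filled[ring == 1] == 1))        # extensive
  expect_equal(filled[29, 29], 1L)                # hole closed
  expect_gte(sum(filled), sum(ring))
  # once holes are closed the result has no interior holes left: hole
  # closure is idempotent (dilation itself is extensive, not idempotent)
  expect_identical(as.integer(as.matrix(EBImage::fillHull(filled))),
                   as.integer(filled))

  empty <- matrix(0L, 32, 32)
  expect_identical(fill_tooth_region(empty, 2, 1), empty)
  expect_error(fill_tooth_region(ring, se_radius = 0), "se_radius")
})

test_that("mask inversion is an involution that partitions pixels", {
  set.seed(3)
  m <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  expect_equal(invert_mask(invert_mask(m)), m, ignore_attr = TRUE)
  expect_equal(sum(invert_mask(matrix(1L, 8, 8))), 0)
  expect_equal(sum(m) + sum(invert_mask(m)), length(m))
})

test_that("suppression equals frac AND NOT fill(tooth) on random mask pairs", {
  # set-algebra oracle over random 64 x 64 masks
  set.seed(11)
  for (k in 1:20) {
    f <- matrix(rbinom(64 * 64, 1, runif(1, 0.05, 0.4)), 64, 64)
    t0 <- matrix(rbinom(64 * 64, 1, runif(1, 0.02, 0.2)), 64, 64)
    tf <- fill_tooth_region(t0, se_radius = 2, iterations = 1)
    got <- suppress_fracture_in_tooth(f, tf)
    oracle <- ifelse(f == 1 & !(tf == 1), 1L, 0L)
    expect_identical(got, oracle)
  }
  # total and null suppression
  ones <- matrix(1L, 16, 16); zeros <- matrix(0L, 16, 16)
  expect_equal(sum(suppress_fracture_in_tooth(ones, ones)), 0)
  expect_identical(suppress_fracture_in_tooth(ones, zeros), ones)
  # a line half inside the tooth band keeps exactly the outside half
  f <- matrix(0L, 32, 32); f[16, 1:32] <- 1L
  t2 <- matrix(0L, 32, 32); t2[1:32, 17:32] <- 1L
  out <- suppress_fracture_in_tooth(f, t2)
  expect_equal(which(out[16, ] == 1), 1:16)
  expect_error(suppress_fracture_in_tooth(f, matrix(0L, 16, 16)), "shape")
})

test_that("component filtering removes only sub-threshold components", {
  m <- matrix(0L, 64, 64)
  m[5, 5] <- 1L                      # 1 px speck
  m[20:40, 20] <- 1L                 # 21 px line
  out <- filter_components(m, 5)
  expect_equal(out[5, 5], 0L)
  expect_equal(sum(out), 21)
  expect_identical(filter_components(m, 0), m)
  lab_before <- max(as.matrix(EBImage::bwlabel(m)))
  lab_after <- max(as.matrix(EBImage::bwlabel(out)))
  expect_lte(lab_after, lab_before)
})

test_that("duplicate-box removal matches a brute-force of the stated rule", {
  # independent oracle: greedy suppression in confidence order with the
  # larger-area then left-to-right tie-break
  nms_oracle <- function(dets, thr) {
    area <- (dets$x1 - dets$x0) * (dets$y1 - dets$y0)
    ord <- order(-dets$confidence, -area, dets$x0)
    kept <- integer()
    for (i in ord) {
      dup <- FALSE
      for (j in kept) {
        if (dets$klass[j] == dets$klass[i]) {
          iou <- box_iou(as.numeric(dets[i, c("x0", "y0", "x1", "y1")]),
                         as.numeric(dets[j, c("x0", "y0", "x1", "y1")]))
          if (iou >= thr) dup <- TRUE
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    sort(kept)
  }

  # two identical boxes -> one survivor; disjoint boxes -> all kept
  two <- data.frame(klass = "body", x0 = c(0, 0), y0 = c(0, 0),
                    x1 = c(10, 10), y1 = c(10, 10), confidence = c(0.9, 0.8))
  expect_equal(nrow(remove_duplicate_boxes(two, 0.5)), 1L)
  disj <- data.frame(klass = "body", x0 = c(0, 50), y0 = c(0, 50),
                     x1 = c(10, 60), y1 = c(10, 60), confidence = c(0.5, 0.5))
  expect_equal(nrow(remove_duplicate_boxes(disj, 0.5)), 2L)

  # chain of three equally confident boxes: the outer two survive
  chain <- data.frame(klass = "angle",
                      x0 = c(0, 6.25, 12.5), y0 = 0,
                      x1 = c(25, 31.25, 37.5), y1 = 10,
                      confidence = 0.7)
  got <- remove_duplicate_boxes(chain, 0.5)
  expect_equal(nrow(got), 2L)
  expect_equal(got$x0, c(0, 12.5))
  expect_equal(sort(rownames(chain)[nms_oracle(chain, 0.5)]), c("1", "3"))

  # fuzz: implementation agrees with the oracle; never grows; idempotent
  set.seed(21)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    d <- data.frame(klass = sample(fracture_classes()[1:3], n, TRUE),
                    x0 = runif(n, 0, 60), y0 = runif(n, 0, 60),
                    confidence = round(runif(n), 2))
    d$x1 <- d$x0 + runif(n, 5, 40); d$y1 <- d$y0 + runif(n, 5, 40)
    got <- remove_duplicate_boxes(d, 0.5)
    expect_equal(nrow(got), length(nms_oracle(d, 0.5)))
    expect_identical(got$x0, d$x0[nms_oracle(d, 0.5)])
    expect_lte(nrow(got), nrow(d))
    expect_identical(remove_duplicate_boxes(got, 0.5), got)
  }
})

test_that("fusion reports both modalities without cross-suppression", {
  img <- desk_phantom(1)$image
  mask <- matrix(0L, 128, 128)
  mask[60:80, 30] <- 1L
  res <- fuse_detections(NULL, mask, img)
  expect_s3_class(res, "detection_result")
  expect_length(res$line_components, 1L)
  expect_true(is.null(res$boxes) || nrow(res$boxes) == 0)

  boxes <- data.frame(klass = "condyle", x0 = 20, y0 = 20, x1 = 50, y1 = 50,
                      confidence = 0.9)
  res2 <- fuse_detections(boxes, matrix(0L, 128, 128), img)
  expect_length(res2$line_components, 0L)
  expect_equal(nrow(res2$boxes), 1L)

  # a line inside a box is kept: both modalities are reported
  mask_in <- matrix(0L, 128, 128); mask_in[25:45, 35] <- 1L
  res3 <- fuse_detections(boxes, mask_in, img)
  expect_equal(nrow(res3$boxes) + length(res3$line_components), 2L)
  expect_identical(dim(res3$overlay), dim(img))
})
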