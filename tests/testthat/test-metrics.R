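square_mask <- function(size, x0, x1, y0, y1) {
  m <- matrix(0L, size, size)
  m[y0:y1, x0:x1] <- 1L
  m
}

test_that("region areas count pixels as defined", {
  a <- square_mask(32, 5, 14, 5, 14) # 100 px
  expect_equal(region_areas(a, a)$overlap, 100)
  expect_equal(region_areas(a, a)$sa, 100)
  b <- square_mask(32, 20, 25, 20, 25)
  expect_equal(region_areas(a, b)$overlap, 0)
  eroded <- square_mask(32, 5, 14, 5, 12) # 80 px inside the 100 px truth
  ra <- region_areas(eroded, a)
  expect_equal(ra$sa, 80)
  expect_equal(ra$oa, 100)
  expect_equal(ra$overlap, 80)
  expect_equal(ra$ba, 32 * 32 - 100)
  expect_error(region_areas(a, matrix(0, 10, 10)), "identical dimensions")
})

test_that("fractional confusion reproduces the worked cases", {
  truth <- square_mask(64, 10, 19, 10, 19) # 100 px
  # exact match
  cf <- fractional_confusion(region_areas(truth, truth))
  expect_equal(unlist(cf), c(tp = 1, fp = 0, tn = 1, fn = 0))
  # under-segmentation: SA inside OA with 80% of its area
  under <- square_mask(64, 10, 19, 10, 17) # 80 px subset
  cf <- fractional_confusion(region_areas(under, truth))
  expect_equal(cf$tp, 0.8)
  expect_equal(cf$fn, 0.2)
  expect_equal(cf$tn, 1)
  expect_equal(cf$fp, 0)
  expect_equal(accuracy(cf$tp, cf$fp, cf$tn, cf$fn), 0.9)
  expect_equal(dice(cf$tp, cf$fp, cf$fn), 1.6 / 1.8)
  expect_equal(overlap_error(cf$tp, cf$fp, cf$fn), 0.2)
  # over-segmentation: spill equal to 10% of (BA - OA)
  ba_minus_oa <- 64 * 64 - 2 * 100
  over <- truth
  over[30:48, 31:50] <- 1L # 19 x 20 = 380 extra pixels
  cf <- fractional_confusion(region_areas(over, truth))
  expect_equal(cf$fp, 380 / ba_minus_oa)
  expect_equal(cf$tn, 1 - 380 / ba_minus_oa)
  expect_equal(cf$tp, 1)
  expect_equal(cf$fn, 0)
})

test_that("strict scalar mode scores by area difference only", {
  truth <- square_mask(64, 10, 19, 10, 19)
  shifted <- square_mask(64, 40, 49, 40, 49) # disjoint but equal area
  cf <- fractional_confusion(region_areas(shifted, truth), mode = "strict")
  expect_equal(cf$tp, 1) # the literal reading: equal areas look perfect
  cf2 <- fractional_confusion(region_areas(shifted, truth)) # set-difference default
  expect_equal(cf2$tp, 0)
})

test_that("metric scalar identities hold at the extremes", {
  expect_equal(accuracy(1, 0, 1, 0), 1)
  expect_equal(accuracy(0, 1, 0, 1), 0)
  expect_equal(dice(1, 0, 0), 1)
  expect_equal(dice(0, 0.5, 0.5), 0)
  expect_equal(overlap_error(1, 0, 0), 0)
  expect_equal(overlap_error(0, 0.5, 0.5), 1)
})

test_that("complementarity TP+FN = 1 and TN+FP = 1 holds for every mask pair", {
  set.seed(11)
  for (k in 1:25) {
    pred <- random_mask()
    truth <- random_mask()
    cf <- fractional_confusion(region_areas(pred, truth))
    expect_equal(cf$tp + cf$fn, 1)
    expect_equal(cf$tn + cf$fp, 1)
    expect_true(all(unlist(cf) >= 0 & unlist(cf) <= 1))
  }
})

test_that("nested predictions give identical fractional and pixelwise Dice", {
  truth <- square_mask(64, 10, 29, 10, 29)
  nested <- square_mask(64, 12, 27, 12, 27)
  frac <- evaluate_masks(nested, truth, mode = "fractional")
  pixw <- evaluate_masks(nested, truth, mode = "pixelwise")
  expect_equal(frac$dice, pixw$dice)
})

test_that("metrics are invariant to simultaneous translation of both masks", {
  pred <- square_mask(64, 10, 19, 10, 17)
  truth <- square_mask(64, 10, 19, 10, 19)
  pred2 <- square_mask(64, 25, 34, 30, 37)
  truth2 <- square_mask(64, 25, 34, 30, 39)
  for (mode in c("fractional", "strict", "pixelwise")) {
    expect_equal(
      evaluate_masks(pred, truth, mode = mode),
      evaluate_masks(pred2, truth2, mode = mode)
    )
  }
})

test_that("empty ground truth is rejected", {
  pred <- square_mask(32, 5, 10, 5, 10)
  expect_error(fractional_confusion(region_areas(pred, matrix(0L, 32, 32))), "OA = 0")
})

test_that("soft ground truth is binarized at the configured support level", {
  pred <- square_mask(32, 5, 14, 5, 14)
  soft <- matrix(0, 32, 32)
  soft[5:14, 5:14] <- 0.8 # above the 75% support level
  soft[16:20, 16:20] <- 0.5 # below: background
  out <- evaluate_masks(pred, soft, truth_threshold = 0.75)
  expect_equal(out$dice, 1)
})

test_that("cumulative error report counts threshold exceedances", {
  expect_equal(
    cumulative_error_report(c(0, 0, 0))$e_le_0.1, 1
  )
  rep3 <- cumulative_error_report(c(0.05, 0.15, 0.25))
  expect_equal(rep3$e_le_0.1, 1 / 3)
  expect_equal(rep3$e_le_0.2, 2 / 3)
  expect_equal(rep3$e_le_0.3, 1)
  expect_equal(rep3$mean_overlap_error, 0.15)
  # monotone in the threshold, and certain at tau = 1
  set.seed(12)
  e <- runif(50)
  r <- cumulative_error_report(e, thresholds = seq(0.1, 1, by = 0.1))
  props <- unlist(r[grep("^e_le_", names(r))])
  expect_false(is.unsorted(props))
  expect_equal(unname(props[length(props)]), 1)
  expect_error(cumulative_error_report(numeric(0)), "no per-image")
  # means of accuracy and dice flow through from a metrics tibble
  tb <- tibble::tibble(overlap_error = c(0.1, 0.3), accuracy = c(0.9, 0.8), dice = c(0.95, 0.85))
  r2 <- cumulative_error_report(tb)
  expect_equal(r2$mean_accuracy, 0.85)
  expect_equal(r2$mean_dice, 0.9)
})
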