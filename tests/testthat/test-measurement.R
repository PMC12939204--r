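test_that("an axis-aligned rectangle measures exactly", {
  cal <- unit_cal(100)
  m <- rect_mask(600, 1100, 50, 549, 50, 1049)   # 500 x 1000 px
  d <- measure_dimensions(binary_mask(m), cal)
  expect_equal(d[["length_cm"]], 10)
  expect_equal(d[["width_cm"]], 5)
  expect_equal(d[["area_cm2"]], 50)
})

test_that("oriented-box dimensions are rotation invariant within 1%", {
  cal <- unit_cal(40)   # 10 x 5 cm rectangle rotated 30 degrees
  th <- 30 * pi / 180
  H <- 500; W <- 560
  ys <- matrix(seq_len(H) - 250, H, W)
  xs <- matrix(seq_len(W) - 280, H, W, byrow = TRUE)
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  m <- abs(xr) <= 200 & abs(yr) <= 100    # 400 x 200 px
  d <- measure_dimensions(binary_mask(m), cal)
  expect_lt(abs(d[["length_cm"]] - 10) / 10, 0.01)
  expect_lt(abs(d[["width_cm"]] - 5) / 5, 0.01)
})

test_that("a disc measures its diameter and area within 1%", {
  cal <- unit_cal(100)
  m <- disc_mask(450, 450, 225, 225, 200)
  d <- measure_dimensions(binary_mask(m), cal)
  expect_lt(abs(d[["length_cm"]] - 4) / 4, 0.01)
  expect_lt(abs(d[["width_cm"]] - 4) / 4, 0.01)
  expect_lt(abs(d[["area_cm2"]] - pi * 4) / (pi * 4), 0.01)
})

test_that("dimensions are translation invariant and error on empty masks", {
  cal <- unit_cal(10)
  a <- rect_mask(100, 100, 10, 40, 20, 80)
  b <- rect_mask(100, 100, 50, 80, 5, 65)
  expect_equal(measure_dimensions(binary_mask(a), cal),
               measure_dimensions(binary_mask(b), cal))
  expect_error(measure_dimensions(binary_mask(matrix(FALSE, 5, 5)), cal),
               "empty")
})

test_that("marbling percentage is the particle share of the ribeye area", {
  none <- data.frame(area_cm2 = numeric())
  expect_equal(marbling_percentage(none, 50), 0)
  parts <- data.frame(area_cm2 = c(7.5, 5))
  expect_equal(marbling_percentage(parts, 50), 25)
  expect_error(marbling_percentage(parts, 0), "positive")
  expect_warning(out <- marbling_percentage(data.frame(area_cm2 = 60), 50),
                 "capped")
  expect_equal(out, 100)
  # monotone nondecreasing in added particles
  expect_gte(marbling_percentage(data.frame(area_cm2 = c(7.5, 5, 1)), 50),
             marbling_percentage(parts, 50))
})

test_that("channel means exclude the background", {
  px <- array(0L, c(10, 10, 3))
  px[, , 1][3:6, 3:6] <- 120L
  px[, , 2][3:6, 3:6] <- 60L
  px[, , 3][3:6, 3:6] <- 60L
  img <- rgb_image(px)
  mask <- binary_mask(rect_mask(10, 10, 3, 6, 3, 6))
  expect_equal(channel_means(img, mask),
               c(mean_r = 120, mean_g = 60, mean_b = 60))
  # with black background included, the red mean would be diluted
  full <- binary_mask(matrix(TRUE, 10, 10))
  expect_lt(channel_means(img, full)[["mean_r"]], 120)
  expect_error(channel_means(img, binary_mask(matrix(FALSE, 10, 10))),
               "empty")
})

test_that("channel means of an exact half/half mixture average the halves", {
  px <- array(0L, c(10, 10, 3))
  px[, , 1][, 1:5] <- 200L
  px[, , 2][, 6:10] <- 200L
  img <- rgb_image(px)
  expect_equal(channel_means(img, binary_mask(matrix(TRUE, 10, 10))),
               c(mean_r = 100, mean_g = 100, mean_b = 0))
})

test_that("red ratio follows its formula and the three ratios partition", {
  expect_equal(red_ratio(100, 100, 100), 1 / 3)
  expect_equal(red_ratio(150, 75, 75), 0.5)
  expect_error(red_ratio(0, 0, 0), "zero")
  expect_error(red_ratio(-1, 2, 3), "nonnegative")
  r <- 123.4; g <- 56.7; b <- 89.1
  expect_equal(red_ratio(r, g, b) + red_ratio(g, b, r) + red_ratio(b, r, g), 1)
})

test_that("measure_sample is deterministic and satisfies its invariants", {
  s <- generate_sample(synthetic_spec(seed = 9, target_marbling_fraction = 0.25))
  ribeye <- segment_ribeye(s$image)
  marbling <- segment_marbling(s$image, ribeye)
  r1 <- measure_sample(s$image, ribeye, marbling, sample_id = "x")
  r2 <- measure_sample(s$image, ribeye, marbling, sample_id = "x")
  expect_identical(r1, r2)
  expect_lte(r1$width_cm, r1$length_cm)
  expect_equal(r1$red_ratio,
               r1$mean_r / (r1$mean_r + r1$mean_g + r1$mean_b))
  expect_gte(r1$marbling_pct, 0)
  expect_lte(r1$marbling_pct, 100)
})

test_that("grade-typical palettes separate the colour-ratio extremes", {
  fx <- panel_fixture()
  truths <- lapply(fx$panel, `[[`, "truth")
  grades <- vapply(truths, `[[`, character(1), "intended_grade")
  a1 <- vapply(truths[grades == "A1"], `[[`, numeric(1), "red_ratio")
  a5 <- vapply(truths[grades == "A5"], `[[`, numeric(1), "red_ratio")
  expect_true(all(a1 > 0.49))
  expect_true(all(a5 < 0.43))
  # fattier, higher-grade samples have the lower red ratio
  expect_lt(max(a5), min(a1))
})

test_that("mask area equals the sum of its unfiltered particle areas", {
  s <- generate_sample(synthetic_spec(seed = 13, target_marbling_fraction = 0.4))
  cal <- s$image$calibration
  marb <- s$truth$marbling_mask
  parts <- particle_analysis(marb, cal, min_size_cm2 = 0)
  expect_equal(sum(parts$area_px), sum(marb$pixels))
})
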