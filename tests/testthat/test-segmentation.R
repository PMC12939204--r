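gray_from_matrix <- function(m) to_grayscale(rgb_image(m), "unweighted")

test_that("grayscale conversion matches the unweighted and luma formulas", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- c(100, 100, 100)
  px[1, 2, ] <- c(255, 0, 0)
  px[1, 3, ] <- c(10, 200, 45)
  img <- rgb_image(px)
  un <- to_grayscale(img, "unweighted")$pixels
  lu <- to_grayscale(img, "luma")$pixels
  expect_identical(un[1, ], c(100L, 85L, 85L))
  expect_identical(lu[1, 1], 100L)
  expect_identical(lu[1, 2], 76L)          # round(0.299 * 255)
  expect_identical(lu[1, 3],
                   as.integer(round(0.299 * 10 + 0.587 * 200 + 0.114 * 45)))
})

test_that("auto contrast stretches the populated range and keeps degenerate input", {
  const <- gray_from_matrix(matrix(77, 10, 10))
  expect_identical(auto_contrast(const)$pixels, const$pixels)

  span <- gray_from_matrix(matrix(rep(50:150, length.out = 101 * 4), 101, 4))
  out <- auto_contrast(span, saturated_fraction = 0)$pixels
  expect_identical(min(out), 0L)
  expect_identical(max(out), 255L)
  expect_identical(out[span$pixels == 50], rep(0L, sum(span$pixels == 50)))
  expect_identical(out[span$pixels == 150], rep(255L, sum(span$pixels == 150)))
})

test_that("auto contrast equals the sort-based oracle on random images", {
  set.seed(11)
  for (rep in 1:8) {
    m <- matrix(sample(0:255, 64 * 64, replace = TRUE,
                       prob = runif(256)^2), 64, 64)
    g <- gray_from_matrix(m)
    for (sat in c(0, 0.0035, 0.02)) {
      got <- auto_contrast(g, sat)$pixels
      want <- oracle_autocontrast(g$pixels, sat)
      expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("auto contrast is monotone in intensity", {
  set.seed(12)
  m <- matrix(sample(0:255, 4096, replace = TRUE), 64, 64)
  g <- gray_from_matrix(m)
  out <- auto_contrast(g, 0.02)$pixels
  ord <- order(as.vector(g$pixels))
  expect_true(all(diff(out[ord]) >= 0))
})

test_that("isodata threshold solves the two-spike case and rejects constants", {
  counts <- rep(0, 256); counts[50 + 1] <- 500; counts[200 + 1] <- 500
  expect_identical(isodata_threshold(counts), 125L)
  expect_error(isodata_threshold(gray_from_matrix(matrix(9, 5, 5))),
               "degenerate")
})

test_that("isodata lands near the optimal split of a known two-class mixture", {
  set.seed(21)
  vals <- c(pmin(255, pmax(0, round(rnorm(4000, 60, 25)))),
            pmin(255, pmax(0, round(rnorm(4000, 190, 25)))))
  labels <- rep(c(0, 1), each = 4000)
  counts <- tabulate(vals + 1L, 256)
  t_pkg <- isodata_threshold(counts)
  # brute-force scan minimizing misassignment of the known mixture
  # (all minimizers count: the optimum can be a plateau)
  miscls <- vapply(0:254, function(t)
    sum(labels == 0 & vals > t) + sum(labels == 1 & vals <= t), numeric(1))
  t_best <- (0:254)[miscls == min(miscls)]
  expect_lte(min(abs(t_pkg - t_best)), 3)
})

test_that("re-thresholding an already binary image reproduces the binarization", {
  set.seed(22)
  m <- matrix(ifelse(runif(900) > 0.6, 255L, 0L), 30, 30)
  g <- gray_from_matrix(m)
  t1 <- isodata_threshold(g)
  bin <- (g$pixels > t1) * 255L
  t2 <- isodata_threshold(gray_from_matrix(bin))
  expect_identical(bin > t2, g$pixels > t1)
})

synthetic_ellipse_ci <- function(fill = 120, bg = 10, speck = FALSE) {
  H <- 220; W <- 300
  m <- matrix(bg, H, W)
  dy <- matrix(seq_len(H) - 100, H, W)
  dx <- matrix(seq_len(W) - 150, H, W, byrow = TRUE)
  ell <- (dx / 90)^2 + (dy / 60)^2 <= 1
  m[ell] <- fill
  if (speck) m[205:208, 285:288] <- 200   # 16 px = 0.1 cm^2 per side at 12.6 px/cm
  ci <- calibrated_image(rgb_image(m), unit_cal(12.6))
  list(ci = ci, truth = ell)
}

test_that("ribeye segmentation recovers a bright ellipse on a dark background", {
  fx <- synthetic_ellipse_ci()
  mask <- segment_ribeye(fx$ci)
  expect_s3_class(mask, "binary_mask")
  expect_lt(abs(sum(mask$pixels) - sum(fx$truth)) / sum(fx$truth), 0.02)
  # single connected region
  expect_identical(max(label_components_8(mask$pixels)), 1L)
})

test_that("ribeye segmentation fails on empty scenes and drops distant specks", {
  flat <- calibrated_image(rgb_image(matrix(10, 50, 50)), unit_cal(10))
  expect_error(segment_ribeye(flat), "segmentation failure")

  fx <- synthetic_ellipse_ci(speck = TRUE)
  mask <- segment_ribeye(fx$ci)
  expect_false(any(mask$pixels[205:208, 285:288]))
})

test_that("marbling segmentation recovers a known fat fraction and respects containment", {
  s <- generate_sample(synthetic_spec(seed = 5, target_marbling_fraction = 0.30))
  ribeye <- segment_ribeye(s$image)
  marb <- segment_marbling(s$image, ribeye)
  frac <- sum(marb$pixels) / sum(ribeye$pixels)
  expect_lt(abs(frac - s$truth$marbling_pct / 100), 0.03)
  expect_false(any(marb$pixels & !ribeye$pixels))   # subset of the ribeye
})

test_that("a uniform lean sample yields an empty marbling mask with a flag", {
  s <- generate_sample(synthetic_spec(seed = 6, target_marbling_fraction = 0))
  ribeye <- segment_ribeye(s$image)
  marb <- segment_marbling(s$image, ribeye)
  expect_false(any(marb$pixels))
  expect_true(length(marb$flags) > 0)
})

test_that("fat fraction recovery holds across a 5-80% sweep", {
  fracs <- seq(0.05, 0.80, length.out = 50)
  errs <- vapply(seq_along(fracs), function(i) {
    s <- generate_sample(synthetic_spec(seed = 1000 + i, px_per_cm = 18,
                                        target_marbling_fraction = fracs[i]))
    ribeye <- segment_ribeye(s$image)
    marb <- segment_marbling(s$image, ribeye)
    100 * sum(marb$pixels) / sum(ribeye$pixels) - s$truth$marbling_pct
  }, numeric(1))
  expect_lte(max(abs(errs)), 3)
})

test_that("cropping to the mask preserves calibration and measurements", {
  fx <- synthetic_ellipse_ci()
  mask <- segment_ribeye(fx$ci)
  before <- measure_dimensions(mask, fx$ci$calibration)
  cr <- crop_to_mask(fx$ci, mask, margin_px = 0L)
  idx <- which(mask$pixels, arr.ind = TRUE)
  expect_identical(dim(cr$mask$pixels),
                   c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L))
  after <- measure_dimensions(cr$mask, cr$image$calibration)
  expect_equal(after, before)

  # margin larger than the frame clamps to the full frame
  cr2 <- crop_to_mask(fx$ci, mask, margin_px = 10000L)
  expect_identical(dim(cr2$mask$pixels), dim(mask$pixels))
  expect_error(crop_to_mask(fx$ci, binary_mask(matrix(FALSE, 5, 5))), "empty")
})
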