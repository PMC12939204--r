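#' Grid-paper area count
#'
#' Manual grid-paper area protocol: `N1` fully covered cells, `N2` cells
#' more than half covered (cells at half coverage or less are ignored), cell
#' side `a` in cm.
#'
#' @param N1,N2 nonnegative integer counts.
#' @param a grid side length in cm (> 0).
#' @return Object of class `grid_count`.
#' @export
grid_count <- function(N1, N2, a) {
  stopifnot(N1 >= 0, N2 >= 0, N1 == round(N1), N2 == round(N2),
            is.finite(a), a > 0)
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2), a = a),
            class = "grid_count")
}

#' Grid-paper area: S = (N1 + N2) * a^2
#'
#' @param gc a [grid_count()].
#' @return Area in cm^2.
#' @examples
#' grid_area(grid_count(300, 6, 0.5))  # 76.5
#' @export
grid_area <- function(gc) {
  stopifnot(inherits(gc, "grid_count"))
  (gc$N1 + gc$N2) * gc$a^2
}

#' Simulate the manual grid-paper count on a mask
#'
#' Overlays an axis-aligned grid of side `a` cm with its origin at the mask
#' bounding-box corner (the manual protocol defines no origin), counts cells
#' whose pixel coverage is complete as `N1` and cells with coverage above
#' one half as `N2`. This is the manual-method oracle used to validate the
#' image-based area against the grid-paper protocol on synthetic data.
#'
#' @param mask non-empty [binary_mask].
#' @param cal a [calibrate_scale()] result.
#' @param a grid side in cm; must span at least one pixel.
#' @return A [grid_count()] with attribute `"area_cm2"` (its [grid_area()]).
#' @export
simulate_grid_count <- function(mask, cal, a = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  check_cal(cal)
  if (!any(mask$pixels)) stop("mask is empty")
  cell_px <- a * cal$px_per_cm
  if (cell_px < 1) stop("grid side smaller than one pixel")
  idx <- which(mask$pixels, arr.ind = TRUE)
  xs0 <- idx[, 2] - 1L; ys0 <- idx[, 1] - 1L
  x0 <- min(xs0); y0 <- min(ys0)
  ix <- floor((xs0 - x0) / cell_px)
  iy <- floor((ys0 - y0) / cell_px)
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  covered <- table(factor(ix + nx * iy, levels = 0:(nx * ny - 1L)))
  # pixel capacity of each cell along each axis (cells are half-open
  # [x0 + i*c, x0 + (i+1)*c) over integer pixel coordinates)
  cap_axis <- function(o, n) {
    lo <- o + (0:(n - 1L)) * cell_px
    hi <- o + (1:n) * cell_px
    ceiling(hi - 1e-9) - ceiling(lo - 1e-9)
  }
  cap <- outer(cap_axis(y0, ny), cap_axis(x0, nx))  # ny x nx, row-major in iy
  capv <- as.vector(t(cap))                         # index = ix + nx*iy
  cov <- as.numeric(covered) / capv
  N1 <- sum(cov >= 1 - 1e-12)
  N2 <- sum(cov > 0.5 & cov < 1 - 1e-12)
  gc <- grid_count(N1, N2, a)
  attr(gc, "area_cm2") <- grid_area(gc)
  gc
}

#' Gaussian-fit outlier elimination
#'
#' Fits a normal distribution to the values by moments (sample mean and
#' sample standard deviation), removes values more than `k` standard
#' deviations from the mean, and refits once on the retained set. Intended
#' to eliminate random measurement outliers while retaining real measured
#' values, not to normalize the data. A pass that would remove more than
#' half the points aborts with an error (pathological data).
#'
#' @param values numeric vector, at least 4 values, not all identical.
#' @param k cutoff in standard deviations (default 2.5).
#' @param max_iter number of removal passes (default 1; the refit after the
#'   single pass is reported but triggers no further removal).
#' @return Object of class `gaussian_fit`: list with `mu`, `sigma` (of the
#'   retained set), `n_used`, `retained_indices`, `removed_indices`.
#' @export
gaussian_outlier_filter <- function(values, k = 2.5, max_iter = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) stop("need at least 4 values to fit and filter")
  if (stats::sd(values) == 0) stop("all values identical; sigma is zero")
  retained <- seq_len(n)
  for (it in seq_len(max_iter)) {
    mu <- mean(values[retained]); sigma <- stats::sd(values[retained])
    if (sigma == 0) break
    keep <- abs(values[retained] - mu) <= k * sigma
    if (sum(!keep) > ceiling(n / 2))
      stop("outlier filter would remove more than half the data; aborting")
    if (all(keep)) break
    retained <- retained[keep]
  }
  mu <- mean(values[retained]); sigma <- stats::sd(values[retained])
  structure(list(mu = mu, sigma = sigma, n_used = length(retained),
                 retained_indices = retained,
                 removed_indices = setdiff(seq_len(n), retained)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit mu %.4g, sigma %.4g, retained %d (removed %d)>\n",
              x$mu, x$sigma, x$n_used, length(x$removed_indices)))
  invisible(x)
}

#' Pearson agreement between two measurement series
#'
#' Product-moment correlation with the two-sided p-value from the exact t
#' transform on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, nonzero variance.
#' @return Object of class `agreement_report`: list with `pearson_r`,
#'   `p_value`, `n`.
#' @export
pearson_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement: r = %.4f, p = %.3g, n = %d>\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Grading accuracy against a reference
#'
#' `100 * matches / n`, with per-grade confusion counts.
#'
#' @param predicted,reference equal-length nonempty vectors of grade labels.
#' @return list with `accuracy_pct`, `n_correct`, `n`, `confusion` (a
#'   `table` of reference x predicted).
#' @export
grading_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (length(predicted) == 0L) stop("empty grade lists")
  predicted <- as.character(predicted); reference <- as.character(reference)
  lev <- sort(unique(c(predicted, reference)))
  list(accuracy_pct = 100 * sum(predicted == reference) / length(predicted),
       n_correct = sum(predicted == reference),
       n = length(predicted),
       confusion = table(reference = factor(reference, lev),
                         predicted = factor(predicted, lev)))
}
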