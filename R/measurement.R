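# Minimum-area oriented bounding rectangle of a set of mask pixels.
# Pixels are unit squares: the hull is taken over pixel corners (computed
# from the center hull first to keep the point set small), then rotating
# calipers over hull edges. Returns c(long, short) side lengths in px.
min_area_rect_px <- function(xs0, ys0) {
  if (length(xs0) == 0L) stop("empty point set")
  pts <- cbind(xs0, ys0)
  if (nrow(pts) > 4L) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[h, , drop = FALSE]
  }
  # corners of the (candidate) boundary pixels
  corners <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
  h <- grDevices::chull(corners[, 1], corners[, 2])
  hull <- corners[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) {  # all corners collinear cannot happen for unit squares
    d <- sqrt(sum((hull[1, ] - hull[min(2, n), ])^2))
    return(c(long = d, short = 0))
  }
  best <- c(area = Inf, long = NA_real_, short = NA_real_)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    cth <- e[1] / len; sth <- e[2] / len
    xr <- hull[, 1] * cth + hull[, 2] * sth
    yr <- -hull[, 1] * sth + hull[, 2] * cth
    w <- diff(range(xr)); hgt <- diff(range(yr))
    if (w * hgt < best["area"])
      best <- c(area = w * hgt, long = max(w, hgt), short = min(w, hgt))
  }
  best[c("long", "short")]
}

#' Measure length, width and area of a mask in physical units
#'
#' Length and width are the long and short sides of the minimum-area
#' oriented bounding rectangle of the mask (the deterministic analogue of
#' measuring the longest part and the widest part of the cut with a
#' caliper); `method = "feret"` instead returns the maximum caliper (Feret)
#' diameter as length with the width measured perpendicular to it. Area is
#' the mask pixel count converted to cm^2.
#'
#' @param mask a non-empty [binary_mask], expected to be a single connected
#'   region.
#' @param cal a [calibrate_scale()] result.
#' @param method `"oriented_box"` (default) or `"feret"`.
#' @return Named numeric vector `c(length_cm, width_cm, area_cm2)` with
#'   `length_cm >= width_cm`.
#' @export
measure_dimensions <- function(mask, cal, method = c("oriented_box", "feret")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "binary_mask"))
  check_cal(cal)
  if (!any(mask$pixels)) stop("cannot measure an empty mask")
  idx <- which(mask$pixels, arr.ind = TRUE)
  xs0 <- idx[, 2] - 1L   # 0-based x = column
  ys0 <- idx[, 1] - 1L
  if (method == "oriented_box") {
    lw <- min_area_rect_px(xs0, ys0)
  } else {
    lw <- feret_px(xs0, ys0)
  }
  c(length_cm = px_to_cm(unname(lw[1]), cal),
    width_cm = px_to_cm(unname(lw[2]), cal),
    area_cm2 = px2_to_cm2(nrow(idx), cal))
}

# Max Feret diameter over pixel corners plus perpendicular extent.
feret_px <- function(xs0, ys0) {
  pts <- cbind(xs0, ys0)
  if (nrow(pts) > 4L) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[h, , drop = FALSE]
  }
  corners <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
  h <- grDevices::chull(corners[, 1], corners[, 2])
  hull <- corners[h, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- hull[ij[1], ]; b <- hull[ij[2], ]
  len <- sqrt(sum((b - a)^2))
  u <- (b - a) / len
  perp <- hull[, 1] * (-u[2]) + hull[, 2] * u[1]
  c(long = len, short = diff(range(perp)))
}

#' Marbling percentage from size-filtered fat particles
#'
#' `100 * (sum of particle areas) / ribeye_area_cm2`, capped at 100 (with a
#' warning) should segmentation pathologies push it above.
#'
#' @param fat_particles particle table from [particle_analysis()] (already
#'   size-filtered).
#' @param ribeye_area_cm2 positive rib-eye area, the denominator (marbling
#'   is expressed relative to the total cross-section area).
#' @return Marbling percentage in `[0, 100]`.
#' @export
marbling_percentage <- function(fat_particles, ribeye_area_cm2) {
  if (!is.finite(ribeye_area_cm2) || ribeye_area_cm2 <= 0)
    stop("ribeye area must be positive")
  pct <- 100 * sum(fat_particles$area_cm2) / ribeye_area_cm2
  if (pct > 100) {
    warning("marbling percentage above 100 capped (segmentation pathology?)")
    pct <- 100
  }
  pct
}

#' Mean R, G, B intensities over masked pixels
#'
#' Arithmetic channel means over the mask only; background pixels are
#' excluded. Means are taken over the whole rib-eye region including fat
#' pixels (channel statistics on the separated cut, not the lean only).
#'
#' @param img an [rgb_image].
#' @param mask a non-empty [binary_mask].
#' @return Named numeric vector `c(mean_r, mean_g, mean_b)`.
#' @export
channel_means <- function(img, mask) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "binary_mask"))
  if (!any(mask$pixels)) stop("cannot take channel means over an empty mask")
  c(mean_r = mean(img$pixels[, , 1][mask$pixels]),
    mean_g = mean(img$pixels[, , 2][mask$pixels]),
    mean_b = mean(img$pixels[, , 3][mask$pixels]))
}

#' Red colour ratio R/(R + G + B)
#'
#' Computed from mean channel intensities (mean-of-channels, not the mean
#' of per-pixel ratios). Lower values accompany brighter, fattier,
#' higher-grade cuts.
#'
#' @param mean_r,mean_g,mean_b nonnegative channel means; alternatively pass
#'   the vector returned by [channel_means()] as `mean_r`.
#' @return The ratio in `(0, 1]`.
#' @export
red_ratio <- function(mean_r, mean_g = NULL, mean_b = NULL) {
  if (length(mean_r) == 3L && is.null(mean_g)) {
    mean_g <- mean_r[[2]]; mean_b <- mean_r[[3]]; mean_r <- mean_r[[1]]
  }
  if (min(mean_r, mean_g, mean_b) < 0) stop("channel means must be nonnegative")
  s <- mean_r + mean_g + mean_b
  if (s <= 0) stop("channel means sum to zero; ratio undefined")
  mean_r / s
}

#' Measure one sample: dimensions, marbling and colour
#'
#' Composes [measure_dimensions()], [particle_analysis()] on the marbling
#' mask, [marbling_percentage()], [channel_means()] and [red_ratio()] into a
#' single record. Deterministic given the image and configuration.
#'
#' @param ci a [calibrated_image()].
#' @param ribeye,marbling masks from [segment_ribeye()] and
#'   [segment_marbling()] for the same image.
#' @param config configuration overrides, see [default_config()].
#' @param sample_id identifier stored in the record.
#' @return An object of class `measurement_record`: a list with fields
#'   `sample_id`, `length_cm`, `width_cm`, `area_cm2`, `marbling_pct`,
#'   `mean_r`, `mean_g`, `mean_b`, `red_ratio`.
#' @export
measure_sample <- function(ci, ribeye, marbling, config = list(),
                           sample_id = "sample") {
  cfg <- resolve_config(config)
  dims <- measure_dimensions(ribeye, ci$calibration)
  parts <- particle_analysis(marbling, ci$calibration,
                             min_size_cm2 = cfg$`particles.min_cm2`,
                             max_size_cm2 = cfg$`particles.max_cm2`)
  pct <- marbling_percentage(parts, dims[["area_cm2"]])
  ch <- channel_means(ci$image, ribeye)
  structure(list(sample_id = sample_id,
                 length_cm = dims[["length_cm"]],
                 width_cm = dims[["width_cm"]],
                 area_cm2 = dims[["area_cm2"]],
                 marbling_pct = pct,
                 mean_r = ch[["mean_r"]],
                 mean_g = ch[["mean_g"]],
                 mean_b = ch[["mean_b"]],
                 red_ratio = red_ratio(ch)),
            class = "measurement_record")
}

#' @export
as.data.frame.measurement_record <- function(x, ...) {
  data.frame(sample_id = x$sample_id, length_cm = x$length_cm,
             width_cm = x$width_cm, area_cm2 = x$area_cm2,
             marbling_pct = x$marbling_pct, mean_r = x$mean_r,
             mean_g = x$mean_g, mean_b = x$mean_b, red_ratio = x$red_ratio,
             stringsAsFactors = FALSE)
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf(paste0("<measurement_record %s: L %.2f cm, W %.2f cm, ",
                     "area %.2f cm2, marbling %.1f%%, R/(R+G+B) %.3f>\n"),
              x$sample_id, x$length_cm, x$width_cm, x$area_cm2,
              x$marbling_pct, x$red_ratio))
  invisible(x)
}
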