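#' Calibrate the pixel-to-centimetre scale from an in-image reference
#'
#' Replaces the interactive "Set Scale" step: two pixel points on a physical
#' reference of known length define a single global scale for the frame
#' (fixed perpendicular capture geometry is assumed upstream; no lens
#' distortion model).
#'
#' @param p1,p2 numeric length-2 pixel coordinates `c(x, y)`, 0-based.
#' @param known_distance_cm physical distance between the points, cm (> 0).
#' @return An object of class `scale_calibration` with fields `px_per_cm`,
#'   `known_distance_cm` and `reference_points` (2 x 2 matrix, one point per
#'   row).
#' @examples
#' cal <- calibrate_scale(c(0, 0), c(500, 0), 5)
#' cal$px_per_cm   # 100
#' @export
calibrate_scale <- function(p1, p2, known_distance_cm) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L)
    stop("calibration error: reference points must be length-2 (x, y)")
  if (!is.finite(known_distance_cm) || known_distance_cm <= 0)
    stop("calibration error: known distance must be positive")
  d <- sqrt(sum((p2 - p1)^2))
  if (d == 0)
    stop("calibration error: reference points are coincident")
  structure(list(px_per_cm = d / known_distance_cm,
                 known_distance_cm = known_distance_cm,
                 reference_points = rbind(p1, p2, deparse.level = 0)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration: %.4f px/cm (reference %.3g cm)>\n",
              x$px_per_cm, x$known_distance_cm))
  invisible(x)
}

check_cal <- function(cal) {
  if (!inherits(cal, "scale_calibration") || !is.finite(cal$px_per_cm) ||
      cal$px_per_cm <= 0)
    stop("invalid scale calibration")
  cal
}

#' Convert between pixel and physical units
#'
#' `px_to_cm`/`cm_to_px` convert lengths, `px2_to_cm2`/`cm2_to_px2` convert
#' areas. All four are exact inverses up to floating point.
#'
#' @param n_px,n_cm,n_px2,n_cm2 nonnegative numeric values.
#' @param cal a [calibrate_scale()] result.
#' @return Converted numeric vector.
#' @export
px_to_cm <- function(n_px, cal) n_px / check_cal(cal)$px_per_cm

#' @rdname px_to_cm
#' @export
cm_to_px <- function(n_cm, cal) n_cm * check_cal(cal)$px_per_cm

#' @rdname px_to_cm
#' @export
px2_to_cm2 <- function(n_px2, cal) n_px2 / check_cal(cal)$px_per_cm^2

#' @rdname px_to_cm
#' @export
cm2_to_px2 <- function(n_cm2, cal) n_cm2 * check_cal(cal)$px_per_cm^2

#' Bundle an image with its scale calibration
#'
#' @param image an [rgb_image].
#' @param calibration a [calibrate_scale()] result applying to the whole
#'   frame.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(image, calibration) {
  stopifnot(inherits(image, "rgb_image"))
  check_cal(calibration)
  structure(list(image = image, calibration = calibration),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$image$pixels)
  cat(sprintf("<calibrated_image %d x %d at %.3f px/cm>\n",
              d[1], d[2], x$calibration$px_per_cm))
  invisible(x)
}
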