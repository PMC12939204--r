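#' Construct a binary mask
#'
#' @param pixels `H x W` logical matrix, `TRUE` = object.
#' @param role one of `"ribeye"`, `"marbling"`, `"generic"`.
#' @param flags character vector of warning flags attached to the mask.
#' @return Object of class `binary_mask` with fields `pixels`, `role`,
#'   `flags`.
#' @export
binary_mask <- function(pixels, role = "generic", flags = character()) {
  if (!is.matrix(pixels)) stop("mask pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  structure(list(pixels = pixels, role = role, flags = flags),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask [%s] %d x %d, %d object px%s>\n", x$role,
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' The default `"unweighted"` mode averages the three channels, matching the
#' plain RGB-to-8-bit conversion of ImageJ without weighted conversion;
#' `"luma"` applies Rec. 601 weights 0.299/0.587/0.114.
#'
#' @param img an [rgb_image].
#' @param mode `"unweighted"` or `"luma"`.
#' @return Object of class `gray_image` with integer `pixels` in
#'   `[0, 255]` and the conversion `mode`.
#' @export
to_grayscale <- function(img, mode = c("unweighted", "luma")) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  g <- if (mode == "unweighted") {
    (p[, , 1] + p[, , 2] + p[, , 3]) / 3
  } else {
    0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  }
  g <- matrix(clamp(round(g), 0L, 255L), dim(p)[1], dim(p)[2])
  storage.mode(g) <- "integer"
  structure(list(pixels = g, mode = mode), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d (%s)>\n", nrow(x$pixels), ncol(x$pixels),
              x$mode))
  invisible(x)
}

gray_histogram <- function(gray) {
  px <- if (inherits(gray, "gray_image")) gray$pixels else gray
  tabulate(as.integer(px) + 1L, nbins = 256L)
}

#' Percentile-saturation automatic contrast stretch
#'
#' From the 256-bin histogram, finds the lowest cut `low` such that at most
#' `saturated_fraction/2` of the pixels lie strictly below it, and the
#' highest cut `high` with at most `saturated_fraction/2` strictly above,
#' then linearly rescales `[low, high]` to `[0, 255]` with clamping and
#' rounding. A degenerate histogram (`low == high`) returns the input
#' unchanged. The stretch is monotone: it never reverses the order of two
#' intensities.
#'
#' @param gray a `gray_image`.
#' @param saturated_fraction total fraction of pixels allowed to saturate
#'   (default 0.0035, i.e. 0.35%, the conventional "auto" saturation).
#' @return A `gray_image` of the same size.
#' @export
auto_contrast <- function(gray, saturated_fraction = 0.0035) {
  stopifnot(inherits(gray, "gray_image"),
            saturated_fraction >= 0, saturated_fraction < 0.5)
  counts <- gray_histogram(gray)
  n <- sum(counts)
  allowed <- floor(n * saturated_fraction / 2)
  below <- c(0, cumsum(counts))[1:256]   # below[v+1] = #(x < v)
  above <- n - cumsum(counts)            # above[v+1] = #(x > v)
  low <- max(which(below <= allowed)) - 1L
  high <- min(which(above <= allowed)) - 1L
  if (low >= high) return(gray)
  out <- clamp(round((gray$pixels - low) * 255 / (high - low)), 0L, 255L)
  storage.mode(out) <- "integer"
  structure(list(pixels = out, mode = gray$mode), class = "gray_image")
}

#' Isodata (intermeans) automatic threshold
#'
#' Iterative intermeans on the 256-bin histogram: starting from the midpoint
#' of the populated intensity range, repeat
#' `t <- round((mean(values <= t) + mean(values > t)) / 2)` until a fixed
#' point. For bright-on-dark scenes the object is the class strictly above
#' the returned threshold.
#'
#' @param x a `gray_image`, an integer matrix of intensities, or a numeric
#'   length-256 histogram of counts for intensities 0..255.
#' @return Integer threshold `t` in `[0, 255]`.
#' @export
isodata_threshold <- function(x) {
  counts <- if (is.numeric(x) && length(x) == 256L && is.null(dim(x))) x
            else gray_histogram(x)
  vals <- 0:255
  pop <- vals[counts > 0]
  if (length(pop) < 2L)
    stop("degenerate histogram: fewer than two populated intensity bins")
  lo <- min(pop); hi <- max(pop)
  t <- clamp(round((lo + hi) / 2), lo, hi - 1L)
  seen <- integer()
  for (i in 1:256) {
    w <- counts
    low_idx <- vals <= t
    m1 <- sum(w[low_idx] * vals[low_idx]) / sum(w[low_idx])
    m2 <- sum(w[!low_idx] * vals[!low_idx]) / sum(w[!low_idx])
    t_new <- clamp(round((m1 + m2) / 2), lo, hi - 1L)
    if (t_new == t) break
    if (t_new %in% seen) { t <- t_new; break }  # rounding 2-cycle guard
    seen <- c(seen, t)
    t <- t_new
  }
  as.integer(t)
}

#' 8-connected labeling of a binary mask
#'
#' Connected-component labels with the ImageJ particle-analyzer convention
#' (8-connectivity for the foreground). Built on 4-connected labeling with
#' a union-find merge of diagonally adjacent labels.
#'
#' @param pixels logical matrix.
#' @return Integer matrix of labels, 0 = background, components numbered
#'   from 1.
#' @export
label_components_8 <- function(pixels) {
  stopifnot(is.matrix(pixels))
  lab <- EBImage::bwlabel(pixels * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(pixels), ncol(pixels))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W])))   # down-left
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  compact <- match(root, sort(unique(root)))
  idx <- lab > 0L
  lab[idx] <- compact[lab[idx]]
  lab
}

fill_holes <- function(pixels) {
  matrix(as.logical(EBImage::fillHull(pixels * 1L) > 0),
         nrow(pixels), ncol(pixels))
}

#' ImageJ-style particle analysis with a size-range filter
#'
#' Labels 8-connected components of a mask, discards those outside the
#' calibrated size range, and returns the survivors sorted by area
#' (descending; ties broken by centroid `(y, x)`).
#'
#' @param mask a [binary_mask].
#' @param cal a [calibrate_scale()] result.
#' @param min_size_cm2,max_size_cm2 inclusive size range in cm^2; the
#'   default floor of 0.5 cm^2 filters tiny impurities (the floor is read
#'   in calibrated units, which is logged by the batch driver because the
#'   unit convention matters for marbling flecks).
#' @return data frame with one row per particle: `area_px`, `area_cm2`,
#'   `centroid_x`, `centroid_y` (0-based), `xmin`, `ymin`, `xmax`, `ymax`
#'   (0-based inclusive bounding box).
#' @export
particle_analysis <- function(mask, cal, min_size_cm2 = 0.5,
                              max_size_cm2 = Inf) {
  stopifnot(inherits(mask, "binary_mask"))
  check_cal(cal)
  empty <- data.frame(area_px = integer(), area_cm2 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      xmin = integer(), ymin = integer(),
                      xmax = integer(), ymax = integer())
  if (!any(mask$pixels)) return(empty)
  lab <- label_components_8(mask$pixels)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(lab)        # 0-based y
  cols0 <- (idx - 1L) %/% nrow(lab)       # 0-based x
  area_px <- tabulate(ids)
  cx <- tapply(cols0, ids, mean)
  cy <- tapply(rows0, ids, mean)
  df <- data.frame(area_px = area_px,
                   area_cm2 = px2_to_cm2(area_px, cal),
                   centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
                   xmin = as.integer(tapply(cols0, ids, min)),
                   ymin = as.integer(tapply(rows0, ids, min)),
                   xmax = as.integer(tapply(cols0, ids, max)),
                   ymax = as.integer(tapply(rows0, ids, max)))
  df <- df[df$area_cm2 >= min_size_cm2 & df$area_cm2 <= max_size_cm2, ,
           drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  df <- df[order(-df$area_cm2, df$centroid_y, df$centroid_x), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default pipeline configuration
#'
#' Flat key-value configuration for segmentation, measurement and grading.
#' Unknown keys passed to `resolve_config()` are rejected.
#'
#' @return Named list of defaults:
#' \describe{
#'   \item{grayscale.mode}{"unweighted" or "luma" (default "unweighted").}
#'   \item{autocontrast.saturation}{saturated fraction for [auto_contrast()]
#'     (default 0.0035).}
#'   \item{threshold.method}{"isodata" or "fixed".}
#'   \item{threshold.fixed_value}{threshold used when method = "fixed".}
#'   \item{particles.min_cm2, particles.max_cm2}{particle size range for the
#'     marbling analysis (default 0.5 to Inf, calibrated cm^2).}
#'   \item{cleanup.min_object_cm2}{components smaller than this are removed
#'     before the largest-component rule when isolating the rib eye
#'     (default 1.0 cm^2, removes bench debris).}
#'   \item{marbling.min_separation}{minimum gray-level separation of the
#'     within-muscle class means for a marbling threshold to be accepted;
#'     below it the sample is treated as uniform lean (default 20).}
#'   \item{grading.strategy}{grade combination rule, see [combine_grades()].}
#' }
#' @export
default_config <- function() {
  list(`grayscale.mode` = "unweighted",
       `autocontrast.saturation` = 0.0035,
       `threshold.method` = "isodata",
       `threshold.fixed_value` = NA_real_,
       `particles.min_cm2` = 0.5,
       `particles.max_cm2` = Inf,
       `cleanup.min_object_cm2` = 1.0,
       `marbling.min_separation` = 20,
       `grading.strategy` = "majority_marbling")
}

#' Merge user configuration over the defaults, rejecting unknown keys
#' @param config named list of overrides (possibly empty).
#' @return Fully resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  base <- default_config()
  if (length(config) == 0L) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Segment the rib-eye muscle from the dark background
#'
#' Grayscale conversion, automatic contrast stretch, isodata threshold
#' (object = above threshold), hole filling, removal of components below
#' `cleanup.min_object_cm2`, then the largest connected component is kept so
#' the returned mask is a single connected region.
#'
#' @param ci a [calibrated_image()] containing one bright object on a dark
#'   background.
#' @param config configuration overrides, see [default_config()].
#' @return A [binary_mask] with role `"ribeye"`; the threshold used is
#'   recorded in field `threshold`.
#' @export
segment_ribeye <- function(ci, config = list()) {
  stopifnot(inherits(ci, "calibrated_image"))
  cfg <- resolve_config(config)
  gray <- to_grayscale(ci$image, cfg$`grayscale.mode`)
  ac <- auto_contrast(gray, cfg$`autocontrast.saturation`)
  t <- if (identical(cfg$`threshold.method`, "fixed")) {
    as.integer(cfg$`threshold.fixed_value`)
  } else {
    tryCatch(isodata_threshold(ac),
             error = function(e) stop("segmentation failure: ",
                                      conditionMessage(e), call. = FALSE))
  }
  m <- ac$pixels > t
  m <- fill_holes(m)
  min_px <- cm2_to_px2(cfg$`cleanup.min_object_cm2`, ci$calibration)
  lab <- label_components_8(m)
  if (max(lab) == 0L)
    stop("segmentation failure: empty foreground after thresholding")
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_px)
  if (length(keep) == 0L)
    stop("segmentation failure: no component above the minimum object size")
  largest <- keep[which.max(areas[keep])]
  out <- binary_mask(lab == largest, role = "ribeye")
  out$threshold <- as.integer(t)
  out
}

#' Segment marbling (intramuscular fat) inside the rib-eye mask
#'
#' Applies isodata thresholding to the grayscale histogram restricted to
#' pixels inside the rib-eye mask; fat is the brighter class (white/milky
#' fat against red muscle). If the within-mask histogram is degenerate, or
#' the two class means are closer than `marbling.min_separation` gray
#' levels (a uniform lean sample, where a split would only partition sensor
#' noise), an empty mask is returned with a warning flag.
#'
#' @param ci a [calibrated_image()].
#' @param ribeye the rib-eye [binary_mask] from [segment_ribeye()].
#' @param config configuration overrides, see [default_config()].
#' @return A [binary_mask] with role `"marbling"`, always a subset of
#'   `ribeye`; `flags` may contain `"degenerate_histogram"` or
#'   `"low_contrast"`; the threshold used (or NA) is in field `threshold`.
#' @export
segment_marbling <- function(ci, ribeye, config = list()) {
  stopifnot(inherits(ci, "calibrated_image"), inherits(ribeye, "binary_mask"))
  if (!any(ribeye$pixels)) stop("ribeye mask is empty")
  cfg <- resolve_config(config)
  gray <- to_grayscale(ci$image, cfg$`grayscale.mode`)
  inside <- gray$pixels[ribeye$pixels]
  counts <- tabulate(as.integer(inside) + 1L, nbins = 256L)
  empty <- function(flag) {
    out <- binary_mask(matrix(FALSE, nrow(ribeye$pixels), ncol(ribeye$pixels)),
                       role = "marbling", flags = flag)
    out$threshold <- NA_integer_
    out
  }
  if (sum(counts > 0) < 2L) return(empty("degenerate_histogram"))
  t <- if (identical(cfg$`threshold.method`, "fixed")) {
    as.integer(cfg$`threshold.fixed_value`)
  } else isodata_threshold(counts)
  m1 <- mean(inside[inside <= t])
  m2 <- mean(inside[inside > t])
  if (!is.finite(m2) || (m2 - m1) < cfg$`marbling.min_separation`)
    return(empty("low_contrast"))
  out <- binary_mask(gray$pixels > t & ribeye$pixels, role = "marbling")
  out$threshold <- as.integer(t)
  out
}

#' Crop a calibrated image (and mask) to the mask bounding box
#'
#' The box is expanded by `margin_px` and clamped to the frame; the scale
#' calibration is unchanged, so all downstream measurements are invariant to
#' the crop.
#'
#' @param ci a [calibrated_image()].
#' @param mask a non-empty [binary_mask].
#' @param margin_px nonnegative integer margin.
#' @return list with elements `image` (cropped [calibrated_image()]),
#'   `mask` (shifted mask) and `offset` (0-based `c(x, y)` of the crop
#'   origin in the source frame).
#' @export
crop_to_mask <- function(ci, mask, margin_px = 0L) {
  stopifnot(inherits(ci, "calibrated_image"), inherits(mask, "binary_mask"),
            margin_px >= 0L)
  if (!any(mask$pixels)) stop("cannot crop to an empty mask")
  idx <- which(mask$pixels, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - margin_px); r1 <- min(nrow(mask$pixels), max(idx[, 1]) + margin_px)
  c0 <- max(1L, min(idx[, 2]) - margin_px); c1 <- min(ncol(mask$pixels), max(idx[, 2]) + margin_px)
  img <- rgb_image(ci$image$pixels[r0:r1, c0:c1, , drop = FALSE],
                   source = ci$image$source)
  list(image = calibrated_image(img, ci$calibration),
       mask = binary_mask(mask$pixels[r0:r1, c0:c1, drop = FALSE],
                          role = mask$role, flags = mask$flags),
       offset = c(x = c0 - 1L, y = r0 - 1L))
}
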