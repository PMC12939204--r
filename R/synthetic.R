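#' Specification for one synthetic rib-eye image
#'
#' Describes a smooth perturbed-ellipse muscle silhouette on a near-black
#' background, an internal fat-blob network at a controlled area fraction,
#' grade-typical muscle/fat colours, Gaussian sensor noise, and an embedded
#' scale bar of known physical length. Rendering is deterministic given
#' `seed` (the generator runs on its own isolated random stream).
#'
#' @param seed integer RNG seed.
#' @param px_per_cm rendering resolution (default 25 px/cm, a scaled-down
#'   analogue of a close-range smartphone capture).
#' @param silhouette_axes_cm semi-axes `c(a, b)` of the base ellipse, cm.
#' @param boundary_amp relative amplitude of the smooth boundary
#'   perturbation (0 = exact ellipse).
#' @param target_marbling_fraction fat area fraction within the silhouette
#'   to aim for, in `[0, 1)`; blobs are added until the realized fraction is
#'   within one percentage point of the target.
#' @param blob_area_range_cm2 range of individual fat-blob areas, cm^2.
#' @param muscle_rgb,fat_rgb,background_rgb 8-bit colour triples.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   levels; default 3).
#' @param scale_bar_cm physical length of the rendered scale bar (cm).
#' @param margin_cm background margin around the silhouette.
#' @param intended_grade optional grade label `"A1"`..`"A5"` carried into
#'   the ground truth (set by [generate_grade_panel()]).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           px_per_cm = 25,
                           silhouette_axes_cm = c(5.2, 3.4),
                           boundary_amp = 0.02,
                           target_marbling_fraction = 0.2,
                           blob_area_range_cm2 = c(0.5, 2.0),
                           muscle_rgb = c(200, 90, 78),
                           fat_rgb = c(178, 172, 160),
                           background_rgb = c(25, 25, 25),
                           noise_sd = 3,
                           scale_bar_cm = 5,
                           margin_cm = 1.5,
                           intended_grade = NA_character_) {
  stopifnot(length(silhouette_axes_cm) == 2L, all(silhouette_axes_cm > 0),
            target_marbling_fraction >= 0, target_marbling_fraction < 1,
            px_per_cm > 0, noise_sd >= 0, boundary_amp >= 0,
            length(blob_area_range_cm2) == 2L,
            blob_area_range_cm2[1] <= blob_area_range_cm2[2],
            scale_bar_cm > 0, margin_cm > 0)
  structure(list(seed = as.integer(seed), px_per_cm = px_per_cm,
                 silhouette_axes_cm = silhouette_axes_cm,
                 boundary_amp = boundary_amp,
                 target_marbling_fraction = target_marbling_fraction,
                 blob_area_range_cm2 = blob_area_range_cm2,
                 muscle_rgb = as.integer(muscle_rgb),
                 fat_rgb = as.integer(fat_rgb),
                 background_rgb = as.integer(background_rgb),
                 noise_sd = noise_sd, scale_bar_cm = scale_bar_cm,
                 margin_cm = margin_cm, intended_grade = intended_grade),
            class = "synthetic_spec")
}

#' Draw a scale bar into an RGB pixel array
#'
#' Draws a straight bar of the given thickness between two pixel points and
#' returns the endpoints, which feed [calibrate_scale()] in tests. Drawing
#' over any `forbidden` region (e.g. the muscle silhouette) is a placement
#' error.
#'
#' @param pixels `H x W x 3` numeric array (modified copy is returned).
#' @param p1,p2 0-based endpoint coordinates `c(x, y)`.
#' @param thickness_px bar thickness in px.
#' @param color 8-bit colour triple.
#' @param forbidden optional logical matrix; bar pixels must not fall on it.
#' @return list with `pixels`, `p1`, `p2`.
#' @export
render_scale_bar <- function(pixels, p1, p2, thickness_px = 4,
                             color = c(150, 150, 150), forbidden = NULL) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  half <- thickness_px / 2
  xr <- clamp(c(floor(min(p1[1], p2[1]) - half), ceiling(max(p1[1], p2[1]) + half)), 0, W - 1)
  yr <- clamp(c(floor(min(p1[2], p2[2]) - half), ceiling(max(p1[2], p2[2]) + half)), 0, H - 1)
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- clamp(((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / len2, 0, 1)
  dist <- sqrt((gx - (p1[1] + t * d[1]))^2 + (gy - (p1[2] + t * d[2]))^2)
  on_bar <- dist <= half
  rows <- gy[on_bar] + 1L; cols <- gx[on_bar] + 1L
  if (!is.null(forbidden) && any(forbidden[cbind(rows, cols)]))
    stop("placement error: scale bar overlaps the silhouette")
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[cbind(rows, cols)] <- color[ch]
    pixels[, , ch] <- plane
  }
  list(pixels = pixels, p1 = p1, p2 = p2)
}

# Rasterize the perturbed-ellipse silhouette. Returns a logical H x W mask.
raster_silhouette <- function(H, W, cx, cy, sa_px, sb_px, amp, phases) {
  dx <- matrix((0:(W - 1)) - cx, H, W, byrow = TRUE) / sa_px
  dy <- matrix((0:(H - 1)) - cy, H, W) / sb_px
  th <- atan2(dy, dx)
  f <- 1 + amp * (sin(2 * th + phases[1]) + 0.6 * sin(3 * th + phases[2]) +
                  0.3 * sin(5 * th + phases[3]))
  sqrt(dx^2 + dy^2) <= f
}

#' Render one synthetic rib-eye image with exact ground truth
#'
#' Renders background, the perturbed-ellipse muscle, fat blobs placed by
#' rejection sampling until the within-silhouette fat fraction is within one
#' percentage point of the target, adds clamped Gaussian noise, and embeds a
#' scale bar. The ground truth (masks, area, length, width, marbling
#' fraction, channel means, colour ratio) is computed from the rendering
#' stencils themselves, so it is exact by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements
#'   `image` (a [calibrated_image()]; calibration recovered from the scale
#'   bar endpoints), and `truth`: list with `ribeye_mask`, `marbling_mask`,
#'   `area_cm2`, `length_cm`, `width_cm`, `marbling_pct`, `channel_means`,
#'   `red_ratio`, `intended_grade`, `scale_bar` (endpoints + length).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ppcm <- spec$px_per_cm
    sa <- spec$silhouette_axes_cm[1]; sb <- spec$silhouette_axes_cm[2]
    amp_tot <- 1.9 * spec$boundary_amp
    bar_zone <- 1.0
    W <- ceiling((max(2 * sa * (1 + amp_tot), spec$scale_bar_cm + 0.8) +
                  2 * spec$margin_cm) * ppcm)
    H <- ceiling((2 * sb * (1 + amp_tot) + 2 * spec$margin_cm + bar_zone) * ppcm)
    cy <- (H - bar_zone * ppcm - 1) / 2
    cx <- (W - 1) / 2
    phases <- runif(3, 0, 2 * pi)
    sil <- raster_silhouette(H, W, cx, cy, sa * ppcm, sb * ppcm,
                             spec$boundary_amp, phases)
    n_sil <- sum(sil)
    if (n_sil == 0L) stop("generation error: silhouette rasterized empty")

    fat <- matrix(FALSE, H, W)
    n_fat <- 0L
    target <- spec$target_marbling_fraction
    if (target > 0) {
      sil_idx <- which(sil)
      min_keep_px <- 0.5 * ppcm^2
      attempts <- 0L
      while (n_fat / n_sil < target - 0.0099) {
        attempts <- attempts + 1L
        if (attempts > 6000L)
          stop("generation error: marbling target unattainable for the ",
               "blob-size budget")
        rem_cm2 <- (target - n_fat / n_sil) * n_sil / ppcm^2
        amax <- min(spec$blob_area_range_cm2[2],
                    max(spec$blob_area_range_cm2[1], 2 * rem_cm2))
        A <- runif(1, spec$blob_area_range_cm2[1], amax)
        q <- runif(1, 1, 2.2)
        u <- sqrt(A * q / pi) * ppcm   # semi-axes in px
        v <- (A / pi) * ppcm^2 / u
        om <- runif(1, 0, pi)
        ctr <- sil_idx[sample.int(length(sil_idx), 1L)]
        cyb <- (ctr - 1L) %% H; cxb <- (ctr - 1L) %/% H
        e <- ceiling(max(u, v)) + 1L
        r0 <- max(0L, cyb - e); r1 <- min(H - 1L, cyb + e)
        c0 <- max(0L, cxb - e); c1 <- min(W - 1L, cxb + e)
        gx <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE) - cxb
        gy <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L) - cyb
        xr <- gx * cos(om) + gy * sin(om)
        yr <- -gx * sin(om) + gy * cos(om)
        inside <- (xr / u)^2 + (yr / v)^2 <= 1
        sub_rows <- (r0 + 1L):(r1 + 1L); sub_cols <- (c0 + 1L):(c1 + 1L)
        blob <- inside & sil[sub_rows, sub_cols]
        existing <- fat[sub_rows, sub_cols]
        n_new <- sum(blob & !existing)
        if (n_new == 0L) next
        # a clipped fleck below the particle floor that touches no other
        # fat would be invisible to the analysis; skip it
        if (sum(blob) < min_keep_px && !any(blob & existing)) next
        if ((n_fat + n_new) / n_sil > target + 0.0099) next
        fat[sub_rows, sub_cols] <- existing | blob
        n_fat <- n_fat + n_new
      }
    }

    px <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_rgb[ch], H, W)
      plane[sil] <- spec$muscle_rgb[ch]
      plane[fat] <- spec$fat_rgb[ch]
      px[, , ch] <- plane
    }

    bar_y <- H - round(0.55 * ppcm)
    bar_x0 <- round(0.4 * ppcm)
    bar_len <- round(spec$scale_bar_cm * ppcm)
    bar <- render_scale_bar(px, c(bar_x0, bar_y), c(bar_x0 + bar_len, bar_y),
                            thickness_px = max(2, round(0.16 * ppcm)),
                            color = c(150, 150, 150), forbidden = sil)
    px <- bar$pixels
    if (spec$noise_sd > 0)
      px <- px + rnorm(length(px), 0, spec$noise_sd)
    img <- rgb_image(clamp(round(px), 0, 255), source = "synthetic")

    cal <- calibrate_scale(bar$p1, bar$p2, spec$scale_bar_cm)
    ci <- calibrated_image(img, cal)
    true_cal <- calibrate_scale(c(0, 0), c(ppcm, 0), 1)  # exact px/cm
    frac <- n_fat / n_sil
    tcm <- (frac * spec$fat_rgb + (1 - frac) * spec$muscle_rgb)
    dims <- measure_dimensions(binary_mask(sil), true_cal)
    truth <- list(
      ribeye_mask = binary_mask(sil, role = "ribeye"),
      marbling_mask = binary_mask(fat, role = "marbling"),
      area_cm2 = n_sil / ppcm^2,
      length_cm = dims[["length_cm"]],
      width_cm = dims[["width_cm"]],
      marbling_pct = 100 * frac,
      channel_means = c(mean_r = tcm[1], mean_g = tcm[2], mean_b = tcm[3]),
      red_ratio = tcm[1] / sum(tcm),
      intended_grade = spec$intended_grade,
      scale_bar = list(p1 = bar$p1, p2 = bar$p2,
                       length_cm = spec$scale_bar_cm))
    list(image = ci, truth = truth, spec = spec)
  })
}

# Per-grade draw ranges used by generate_grade_panel: realized parameters
# sit well inside the grading intervals (>= 10% of the interval width away
# from every shared boundary).
panel_ranges <- list(
  A1 = list(area = c(42, 48), marb = c(0.03, 0.08), rho = c(0.505, 0.530)),
  A2 = list(area = c(52, 58), marb = c(0.14, 0.26), rho = c(0.4765, 0.4835)),
  A3 = list(area = c(63, 72), marb = c(0.34, 0.46), rho = c(0.4565, 0.4635)),
  A4 = list(area = c(77, 88), marb = c(0.54, 0.64), rho = c(0.4365, 0.4435)),
  A5 = list(area = c(94, 105), marb = c(0.73, 0.77), rho = c(0.406, 0.424)))

# Solve the muscle red channel so that the fat/muscle area-weighted mixture
# attains the target colour ratio rho given the fat palette and fraction f.
solve_muscle_rgb <- function(rho, f, fat_rgb, muscle_sum) {
  Sf <- sum(fat_rgb); Rf <- fat_rgb[1]
  Rm <- (rho * (f * Sf + (1 - f) * muscle_sum) - f * Rf) / (1 - f)
  Rm <- round(Rm)
  gb <- muscle_sum - Rm
  Gm <- round(gb * 0.55); Bm <- gb - Gm
  c(Rm, Gm, Bm)
}

#' Generate a graded panel of synthetic samples
#'
#' For each grade A1-A5, draws sample specifications whose ground-truth
#' area, marbling fraction and palette-implied colour ratio fall strictly
#' inside that grade's intervals (at least 10% of the interval width away
#' from the shared boundaries), so the three parameter grades of the ground
#' truth are unanimous. Every returned sample is verified: its ground-truth
#' triple must grade to the intended grade, otherwise it is redrawn.
#'
#' @param n_per_grade samples per grade (>= 1); a panel with 6 per grade
#'   mirrors a 30-sample validation set.
#' @param seed integer seed for the panel's isolated random stream.
#' @param table the `grading_table` the panel is generated against.
#' @param px_per_cm rendering resolution passed to each sample.
#' @return list of `5 * n_per_grade` samples as returned by
#'   [generate_sample()], grades in order A1..A5.
#' @export
generate_grade_panel <- function(n_per_grade, seed = 1L,
                                 table = default_grading_table(),
                                 px_per_cm = 25) {
  stopifnot(n_per_grade >= 1L)
  validate_grading_table(table)
  with_seed(seed, {
    out <- vector("list", 5L * n_per_grade)
    k <- 0L
    for (g in 1:5) {
      rg <- panel_ranges[[g]]
      for (i in seq_len(n_per_grade)) {
        sample_ok <- NULL
        for (try in 1:8) {
          fat_rgb <- round(c(178, 172, 160) + runif(3, -4, 4))
          f <- runif(1, rg$marb[1], rg$marb[2])
          muscle_sum <- runif(1, 356, 372)
          # cap rho so the solved muscle red stays within 8 bits
          rho_cap <- (f * fat_rgb[1] + (1 - f) * 250) /
                     (f * sum(fat_rgb) + (1 - f) * muscle_sum) - 0.002
          rho_hi <- min(rg$rho[2], rho_cap)
          if (rho_hi <= rg$rho[1]) next
          rho <- runif(1, rg$rho[1], rho_hi)
          muscle_rgb <- solve_muscle_rgb(rho, f, fat_rgb, muscle_sum)
          if (muscle_rgb[1] > 252 || any(muscle_rgb[2:3] < 12)) next
          area <- runif(1, rg$area[1], rg$area[2])
          ar <- runif(1, max(1.35, area / 75.4), min(1.65, 165 / area))
          sp <- synthetic_spec(
            seed = sample.int(.Machine$integer.max, 1L),
            px_per_cm = px_per_cm,
            silhouette_axes_cm = c(sqrt(area * ar / pi), sqrt(area / (pi * ar))),
            target_marbling_fraction = f,
            muscle_rgb = muscle_rgb, fat_rgb = fat_rgb,
            intended_grade = grade_labels[g])
          smp <- generate_sample(sp)
          tr <- smp$truth
          ok <- identical(grade_parameter(tr$area_cm2, "area_cm2", table), g) &&
                identical(grade_parameter(tr$marbling_pct, "marbling_pct", table), g) &&
                identical(grade_parameter(tr$red_ratio, "red_ratio", table), g)
          if (ok) { sample_ok <- smp; break }
        }
        if (is.null(sample_ok))
          stop("generation error: could not realize grade ", grade_labels[g],
               " within the draw budget")
        k <- k + 1L
        out[[k]] <- sample_ok
      }
    }
    out
  })
}
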