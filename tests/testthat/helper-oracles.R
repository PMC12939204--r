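# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive re-derivations of the operations they check and share
# no code with the package internals.

# --- flood-fill connected components (8-neighbourhood), BFS ---------------
oracle_components_8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    px <- matrix(integer(), 0, 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- rbind(px, p)
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    comps[[length(comps) + 1L]] <- px
  }
  comps
}

# Canonical particle summary (0-based bbox) from the flood-fill oracle.
oracle_particle_table <- function(mask) {
  comps <- oracle_components_8(mask)
  if (length(comps) == 0L)
    return(data.frame(area_px = integer(), xmin = integer(), ymin = integer(),
                      xmax = integer(), ymax = integer()))
  df <- do.call(rbind, lapply(comps, function(px) {
    data.frame(area_px = nrow(px),
               xmin = min(px[, 2]) - 1L, ymin = min(px[, 1]) - 1L,
               xmax = max(px[, 2]) - 1L, ymax = max(px[, 1]) - 1L)
  }))
  df[order(df$area_px, df$ymin, df$xmin), , drop = FALSE]
}

# --- sort-based auto-contrast oracle --------------------------------------
oracle_autocontrast <- function(px, sat) {
  n <- length(px)
  m <- floor(n * sat / 2)
  s <- sort(as.integer(px))
  low <- s[m + 1L]; high <- s[n - m]
  if (low >= high) return(px)
  out <- round((px - low) * 255 / (high - low))
  out[out < 0] <- 0L; out[out > 255] <- 255L
  out
}

# --- exhaustive intermeans fixed-point scan -------------------------------
oracle_isodata_fixed_points <- function(counts) {
  vals <- 0:255
  pop <- vals[counts > 0]
  lo <- min(pop); hi <- max(pop)
  fp <- integer()
  for (t in lo:(hi - 1L)) {
    low <- vals <= t
    m1 <- sum(counts[low] * vals[low]) / sum(counts[low])
    m2 <- sum(counts[!low] * vals[!low]) / sum(counts[!low])
    if (round((m1 + m2) / 2) == t) fp <- c(fp, t)
  }
  fp
}

# --- simple mask builders -------------------------------------------------
disc_mask <- function(H, W, cy, cx, r) {
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  dx^2 + dy^2 <= r^2
}

rect_mask <- function(H, W, r0, r1, c0, c1) {
  m <- matrix(FALSE, H, W)
  m[r0:r1, c0:c1] <- TRUE
  m
}

unit_cal <- function(px_per_cm) calibrate_scale(c(0, 0), c(px_per_cm, 0), 1)

# --- shared fixed-seed grade panel with pipeline results ------------------
# Generated once per test session; mirrors a 30-sample validation set
# (6 samples per grade).
panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- generate_grade_panel(6, seed = 42)
      runs <- lapply(seq_along(panel), function(i)
        grade_image(panel[[i]]$image, sample_id = sprintf("s%02d", i)))
      cache <<- list(panel = panel, runs = runs)
    }
    cache
  }
})
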