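#' Construct an 8-bit RGB image object
#'
#' @param pixels `H x W x 3` numeric array of intensities in `[0, 255]`
#'   (channel order red, green, blue), or an `H x W` matrix which is
#'   replicated across the three channels.
#' @param source character tag recording where the raster came from.
#' @return An object of class `rgb_image` with fields `pixels` (integer
#'   array), `source` and `colorspace` (always `"sRGB"`; no colour
#'   management is applied).
#' @export
rgb_image <- function(pixels, source = "memory") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array or an H x W matrix")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, source = source, colorspace = "sRGB"),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, 8-bit sRGB, source: %s>\n",
              d[1], d[2], x$source))
  invisible(x)
}

#' Load a JPEG or PNG image as an 8-bit RGB raster
#'
#' Grayscale sources are replicated to three channels and alpha channels are
#' dropped. PNG loading is lossless; JPEG is accepted but decodes through a
#' lossy codec.
#'
#' @param path path to a decodable JPEG or PNG file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("input error: no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image extension: ", ext)),
    error = function(e) stop("input error: cannot decode image file ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  px <- round(raw * 255)
  if (is.matrix(px)) {
    px <- array(rep(px, 3L), c(dim(px), 3L))
  } else if (dim(px)[3] == 2L) {           # gray + alpha
    px <- array(rep(px[, , 1L], 3L), c(dim(px)[1:2], 3L))
  } else if (dim(px)[3] >= 3L) {
    px <- px[, , 1:3, drop = FALSE]
  }
  rgb_image(px, source = path)
}

#' Write an RGB image or binary mask to PNG (lossless, 8-bit)
#'
#' Masks are written as 0/255 grayscale for audit.
#'
#' @param x an [rgb_image] or [binary_mask].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(x, path) {
  if (inherits(x, "rgb_image")) {
    png::writePNG(x$pixels / 255, path)
  } else if (inherits(x, "binary_mask")) {
    png::writePNG(x$pixels * 1, path)
  } else stop("x must be an rgb_image or binary_mask")
  invisible(path)
}

#' Write measurement records (and optional grades) to CSV or JSON
#'
#' Schema: `sample_id,length_cm,width_cm,area_cm2,marbling_pct,mean_r,`
#' `mean_g,mean_b,red_ratio,grade`. The file re-reads losslessly with
#' [read_measurements()].
#'
#' @param records a data frame with the schema columns (minus `grade`), a
#'   single `measurement_record`, or a list of them.
#' @param path output path; `.csv` or `.json` selects the format.
#' @param grades optional character vector of grade labels (`"A1"`..`"A5"`),
#'   one per record, or a list of `grade_result` objects.
#' @return The written data frame, invisibly.
#' @export
write_measurements <- function(records, path, grades = NULL) {
  df <- records_to_df(records)
  if (nrow(df) == 0L) stop("records must be non-empty")
  if (!is.null(grades)) {
    if (is.list(grades) && inherits(grades[[1]], "grade_result"))
      grades <- vapply(grades, function(g) g$final_grade, character(1))
    stopifnot(length(grades) == nrow(df))
    df$grade <- as.character(grades)
  } else if (is.null(df$grade)) df$grade <- NA_character_
  df <- df[, c("sample_id", "length_cm", "width_cm", "area_cm2",
               "marbling_pct", "mean_r", "mean_g", "mean_b", "red_ratio",
               "grade")]
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext == "json") {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           na = "null")
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write measurements to ", path)
  invisible(df)
}

#' Read a measurement table written by [write_measurements()]
#' @param path `.csv` or `.json` file.
#' @return data frame with one row per sample.
#' @export
read_measurements <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

records_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (inherits(records, "measurement_record")) records <- list(records)
  if (!is.list(records) || length(records) == 0L)
    stop("records must be non-empty")
  do.call(rbind, lapply(records, as.data.frame))
}
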