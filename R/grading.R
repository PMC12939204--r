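grade_labels <- paste0("A", 1:5)

make_param_table <- function(lower, upper, lower_inc, upper_inc) {
  data.frame(index = 1:5, label = grade_labels,
             lower = lower, upper = upper,
             lower_inc = lower_inc, upper_inc = upper_inc)
}

#' The default five-level grading table
#'
#' Interval thresholds mapping rib-eye area (cm^2), marbling percentage and
#' the R/(R+G+B) colour ratio to grades A1-A5. Printed grading standards
#' share endpoints between adjacent grades; here intervals are made
#' half-open deterministically: lower-inclusive for the increasing
#' parameters (area, marbling) and upper-inclusive for the decreasing colour
#' ratio, so a shared endpoint always resolves toward the lower grade index.
#'
#' * area: A1 `[40, 50)`, A2 `[50, 60)`, A3 `[60, 75)`, A4 `[75, 90)`,
#'   A5 `[90, Inf)`; values below 40 cm^2 are below the grading scale.
#' * marbling %: A1 `[0, 10)`, A2 `[10, 30)`, A3 `[30, 50)`, A4 `[50, 70)`,
#'   A5 `[70, 100]`.
#' * colour ratio: A1 `(0.49, 1]`, A2 `(0.47, 0.49]`, A3 `(0.45, 0.47]`,
#'   A4 `(0.43, 0.45]`, A5 `(0, 0.43]`.
#'
#' @return Object of class `grading_table`: a list with one interval data
#'   frame per parameter (`area_cm2`, `marbling_pct`, `red_ratio`).
#' @export
default_grading_table <- function() {
  structure(list(
    area_cm2 = make_param_table(c(40, 50, 60, 75, 90),
                                c(50, 60, 75, 90, Inf),
                                lower_inc = rep(TRUE, 5),
                                upper_inc = rep(FALSE, 5)),
    marbling_pct = make_param_table(c(0, 10, 30, 50, 70),
                                    c(10, 30, 50, 70, 100),
                                    lower_inc = rep(TRUE, 5),
                                    upper_inc = c(rep(FALSE, 4), TRUE)),
    red_ratio = make_param_table(c(0.49, 0.47, 0.45, 0.43, 0),
                                 c(1, 0.49, 0.47, 0.45, 0.43),
                                 lower_inc = rep(FALSE, 5),
                                 upper_inc = rep(TRUE, 5))),
    class = "grading_table")
}

#' @export
print.grading_table <- function(x, ...) {
  cat("<grading_table A1-A5>\n")
  for (p in names(x)) {
    iv <- vapply(1:5, function(i) {
      r <- x[[p]][i, ]
      sprintf("%s%s, %s%s", if (r$lower_inc) "[" else "(",
              format(r$lower), format(r$upper), if (r$upper_inc) "]" else ")")
    }, character(1))
    cat(sprintf("  %-13s %s\n", p, paste(iv, collapse = "  ")))
  }
  invisible(x)
}

validate_grading_table <- function(table) {
  stopifnot(inherits(table, "grading_table"),
            identical(sort(names(table)),
                      sort(c("area_cm2", "marbling_pct", "red_ratio"))))
  for (p in names(table))
    stopifnot(nrow(table[[p]]) == 5L,
              identical(table[[p]]$label, grade_labels))
  table
}

#' Grade a single parameter value against the table
#'
#' @param value finite numeric value.
#' @param parameter one of `"area_cm2"`, `"marbling_pct"`, `"red_ratio"`.
#' @param table a `grading_table` (default [default_grading_table()]).
#' @return Integer grade index 1-5, or `NA_integer_` when the value falls
#'   outside every interval (e.g. area below 40 cm^2, below the scale).
#'   Flags, not exceptions.
#' @export
grade_parameter <- function(value, parameter = c("area_cm2", "marbling_pct",
                                                 "red_ratio"),
                            table = default_grading_table()) {
  parameter <- match.arg(parameter)
  validate_grading_table(table)
  if (!is.finite(value)) return(NA_integer_)
  tb <- table[[parameter]]
  in_lo <- ifelse(tb$lower_inc, value >= tb$lower, value > tb$lower)
  in_hi <- ifelse(tb$upper_inc, value <= tb$upper, value < tb$upper)
  hit <- which(in_lo & in_hi)
  if (length(hit) != 1L) return(NA_integer_)
  tb$index[hit]
}

#' Combine the three per-parameter grades into a final grade
#'
#' Strategies:
#' * `"majority_marbling"` (default): if at least two parameter grades
#'   agree, that grade wins; otherwise the marbling grade is used (marbling
#'   being the single most important grading indicator).
#' * `"marbling_only"`: the marbling grade.
#' * `"minimum"`: the lowest of the in-range grades (conservative).
#'
#' A spread above one grade between parameters sets a `"disagreement"`
#' flag; out-of-range parameters set flags named `<parameter>_out_of_range`.
#'
#' @param area_g,marbling_g,ratio_g integer grade indices 1-5 or `NA`.
#' @param strategy combination rule.
#' @return list with `final_index`, `final_grade` (label), `strategy`,
#'   `flags`.
#' @export
combine_grades <- function(area_g, marbling_g, ratio_g,
                           strategy = c("majority_marbling", "marbling_only",
                                        "minimum")) {
  strategy <- match.arg(strategy)
  g <- c(area = area_g, marbling = marbling_g, ratio = ratio_g)
  flags <- if (anyNA(g)) paste0(names(g)[is.na(g)], "_out_of_range")
           else character()
  if (all(is.na(g))) stop("ungradable: all parameter grades out of range")
  if (is.na(marbling_g) && strategy != "minimum")
    stop("ungradable: marbling grade out of range")
  ok <- g[!is.na(g)]
  if (diff(range(ok)) > 1L) flags <- c(flags, "disagreement")
  final <- switch(strategy,
    marbling_only = marbling_g,
    minimum = min(ok),
    majority_marbling = {
      tt <- table(ok)
      if (max(tt) >= 2L) as.integer(names(tt)[which.max(tt)]) else marbling_g
    })
  list(final_index = as.integer(final),
       final_grade = grade_labels[final],
       strategy = strategy, flags = flags)
}

#' Grade a measured sample A1-A5
#'
#' Grades area, marbling percentage and colour ratio individually with
#' [grade_parameter()], then combines them with [combine_grades()]. An area
#' below the 40 cm^2 floor of the scale is flagged `"below_scale"` rather
#' than clamped, unless `clamp_below_scale = TRUE` maps it to A1.
#'
#' @param record a `measurement_record`, or any list/one-row data frame with
#'   `area_cm2`, `marbling_pct` and `red_ratio`.
#' @param table a `grading_table`.
#' @param strategy see [combine_grades()].
#' @param clamp_below_scale clamp sub-scale areas to grade A1 instead of
#'   flagging them out of range.
#' @return Object of class `grade_result`: list with `area_grade`,
#'   `marbling_grade`, `ratio_grade`, `final_index`, `final_grade`,
#'   `strategy`, `flags`.
#' @examples
#' grade_sample(list(area_cm2 = 45, marbling_pct = 5, red_ratio = 0.52))
#' @export
grade_sample <- function(record, table = default_grading_table(),
                         strategy = c("majority_marbling", "marbling_only",
                                      "minimum"),
                         clamp_below_scale = FALSE) {
  strategy <- match.arg(strategy)
  a <- record$area_cm2; m <- record$marbling_pct; r <- record$red_ratio
  flags <- character()
  ga <- grade_parameter(a, "area_cm2", table)
  if (is.na(ga) && is.finite(a) && a < min(table$area_cm2$lower)) {
    flags <- c(flags, "below_scale")
    if (clamp_below_scale) ga <- 1L
  }
  gm <- grade_parameter(m, "marbling_pct", table)
  gr <- grade_parameter(r, "red_ratio", table)
  comb <- combine_grades(ga, gm, gr, strategy)
  structure(list(area_grade = ga, marbling_grade = gm, ratio_grade = gr,
                 final_index = comb$final_index,
                 final_grade = comb$final_grade,
                 strategy = comb$strategy,
                 flags = unique(c(flags, comb$flags))),
            class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf("<grade_result %s (area %s, marbling %s, ratio %s; %s%s)>\n",
              x$final_grade,
              ifelse(is.na(x$area_grade), "-", x$area_grade),
              ifelse(is.na(x$marbling_grade), "-", x$marbling_grade),
              ifelse(is.na(x$ratio_grade), "-", x$ratio_grade),
              x$strategy,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Serialize a grading table to JSON (and back)
#'
#' Plain-text representation so alternate national grading standards can be
#' dropped in. `Inf` bounds are stored as the string `"Inf"`.
#'
#' @param table a `grading_table`.
#' @param path JSON file path.
#' @return `write_grading_table` returns `path` invisibly;
#'   `read_grading_table` returns a `grading_table`.
#' @export
write_grading_table <- function(table, path) {
  validate_grading_table(table)
  out <- lapply(table, function(tb) {
    list(label = tb$label,
         lower = ifelse(is.finite(tb$lower), tb$lower, "Inf"),
         upper = ifelse(is.finite(tb$upper), tb$upper, "Inf"),
         lower_inc = tb$lower_inc, upper_inc = tb$upper_inc)
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_grading_table
#' @export
read_grading_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbs <- lapply(raw, function(x) {
    make_param_table(as.numeric(ifelse(x$lower == "Inf", Inf, x$lower)),
                     as.numeric(ifelse(x$upper == "Inf", Inf, x$upper)),
                     as.logical(x$lower_inc), as.logical(x$upper_inc))
  })
  validate_grading_table(structure(tbs, class = "grading_table"))
}
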