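test_that("the default table has five contiguous intervals per parameter", {
  tb <- default_grading_table()
  expect_identical(sort(names(tb)), c("area_cm2", "marbling_pct", "red_ratio"))
  expect_identical(sum(vapply(tb, nrow, integer(1))), 15L)
  # shared endpoints resolve toward the lower grade index
  expect_identical(grade_parameter(50, "area_cm2", tb), 2L)
  expect_identical(grade_parameter(0.49, "red_ratio", tb), 2L)
  expect_identical(grade_parameter(10, "marbling_pct", tb), 2L)
})

test_that("single-parameter grading follows the interval thresholds", {
  expect_identical(grade_parameter(5, "marbling_pct"), 1L)
  expect_identical(grade_parameter(95, "area_cm2"), 5L)
  expect_identical(grade_parameter(0.46, "red_ratio"), 3L)
  expect_identical(grade_parameter(30, "area_cm2"), NA_integer_)  # below scale
  expect_identical(grade_parameter(Inf, "area_cm2"), NA_integer_)
})

test_that("every in-scale value receives exactly one grade (coverage grid)", {
  tb <- default_grading_table()
  hits <- function(value, p) {
    t <- tb[[p]]
    in_lo <- ifelse(t$lower_inc, value >= t$lower, value > t$lower)
    in_hi <- ifelse(t$upper_inc, value <= t$upper, value < t$upper)
    sum(in_lo & in_hi)
  }
  for (a in seq(40, 120, by = 0.01 * 25))  # thinned grid, endpoints included
    expect_identical(hits(a, "area_cm2"), 1L)
  for (m in seq(0, 100, by = 0.01 * 10))
    expect_identical(hits(m, "marbling_pct"), 1L)
  for (r in seq(0.01, 1, by = 0.01))
    expect_identical(hits(r, "red_ratio"), 1L)
  # the exact printed boundaries, at full resolution
  for (a in c(40, 50, 60, 75, 90)) expect_identical(hits(a, "area_cm2"), 1L)
  for (r in c(0.43, 0.45, 0.47, 0.49)) expect_identical(hits(r, "red_ratio"), 1L)
})

test_that("grade combination strategies behave as documented on all 125 triples", {
  # want: independent restatement of the majority-then-marbling rule —
  # any pair involving marbling yields marbling; area==ratio yields that
  # pair; otherwise fall back to marbling
  for (a in 1:5) for (m in 1:5) for (r in 1:5) {
    got <- combine_grades(a, m, r, "majority_marbling")
    want <- if (a == m || m == r) m else if (a == r) a else m
    expect_identical(got$final_index, as.integer(want))
    expect_identical(combine_grades(a, m, r, "marbling_only")$final_index,
                     as.integer(m))
    expect_identical(combine_grades(a, m, r, "minimum")$final_index,
                     as.integer(min(a, m, r)))
    if (diff(range(c(a, m, r))) > 1)
      expect_true("disagreement" %in% got$flags)
    if (a == m && m == r) {   # unanimity under every strategy
      for (s in c("majority_marbling", "marbling_only", "minimum"))
        expect_identical(combine_grades(a, m, r, s)$final_index,
                         as.integer(a))
    }
  }
})

test_that("no-majority triples fall back to the marbling grade", {
  expect_identical(combine_grades(2, 4, 3)$final_grade, "A4")
  expect_identical(combine_grades(4, 4, 4)$final_grade, "A4")
  expect_identical(combine_grades(3, 4, 4)$final_grade, "A4")
})

test_that("final grade is monotone in marbling under the default strategy", {
  for (a in 1:5) for (r in 1:5) {
    fin <- vapply(1:5, function(m)
      combine_grades(a, m, r)$final_index, integer(1))
    expect_true(all(diff(fin) >= 0))
  }
})

test_that("grade_sample composes the parameter grades with flags", {
  g <- grade_sample(list(area_cm2 = 45, marbling_pct = 5, red_ratio = 0.52))
  expect_identical(g$final_grade, "A1")
  g4 <- grade_sample(list(area_cm2 = 80, marbling_pct = 60, red_ratio = 0.44))
  expect_identical(g4$final_grade, "A4")
  expect_length(g4$flags, 0L)

  below <- grade_sample(list(area_cm2 = 35, marbling_pct = 5, red_ratio = 0.52))
  expect_true("below_scale" %in% below$flags)
  expect_identical(below$final_grade, "A1")  # via marbling/ratio majority
  clamped <- grade_sample(list(area_cm2 = 35, marbling_pct = 55,
                               red_ratio = 0.52),
                          clamp_below_scale = TRUE)
  expect_identical(clamped$area_grade, 1L)

  expect_error(grade_sample(list(area_cm2 = 10, marbling_pct = NA,
                                 red_ratio = 2)), "ungradable")
})

test_that("strategies agree on concordant synthetic samples", {
  fx <- panel_fixture()
  for (i in seq_along(fx$panel)) {
    tr <- fx$panel[[i]]$truth
    rec <- list(area_cm2 = tr$area_cm2, marbling_pct = tr$marbling_pct,
                red_ratio = tr$red_ratio)
    gs <- vapply(c("majority_marbling", "marbling_only", "minimum"),
                 function(s) grade_sample(rec, strategy = s)$final_grade,
                 character(1))
    expect_identical(unique(unname(gs)), tr$intended_grade)
  }
})

test_that("grading tables round-trip through JSON", {
  tb <- default_grading_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_grading_table(tb, path)
  back <- read_grading_table(path)
  for (p in names(tb))
    expect_equal(back[[p]], tb[[p]])
  expect_identical(grade_parameter(0.46, "red_ratio", back), 3L)
})
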