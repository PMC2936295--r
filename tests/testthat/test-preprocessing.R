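test_that("not-a-knot spline reproduces polynomials of degree <= 3 exactly", {
  t4 <- c(0, 30, 60, 120)
  expect_equal(spline_interpolate(t4, 2 * t4, 90), 180, tolerance = 1e-12)
  expect_equal(spline_interpolate(t4, t4^3, 90), 729000, tolerance = 1e-9)
  # degree-3 reproduction through more than 4 points
  t7 <- c(0, 10, 25, 47, 60, 88, 120)
  p <- function(x) 2 - 0.5 * x + 0.03 * x^2 - 1e-4 * x^3
  for (q in c(5, 33, 71, 119))
    expect_equal(spline_interpolate(t7, p(t7), q), p(q),
                 tolerance = 1e-9 * max(1, abs(p(q))))
})

test_that("spline agrees with an independent not-a-knot oracle", {
  # frozen values from an independent cubic-spline implementation
  expect_equal(spline_interpolate(c(0, 30, 60, 120), sin(c(0, 30, 60, 120) / 20), 90),
               -0.855668849063985, tolerance = 1e-9)
  t6 <- c(0, 20, 40, 60, 80, 120)
  expect_equal(spline_interpolate(t6, sin(t6 / 20), 90),
               -1.0382286477768439, tolerance = 1e-9)
  expect_equal(spline_interpolate(t6, sin(t6 / 20), 50),
               0.5948496004386005, tolerance = 1e-9)
  t7 <- c(0, 10, 25, 47, 60, 88, 120)
  v7 <- exp(-t7 / 40) + 0.1 * sqrt(t7)
  expect_equal(spline_interpolate(t7, v7, 5), 1.0703683193680615, tolerance = 1e-9)
  expect_equal(spline_interpolate(t7, v7, 33), 1.0067716710295895, tolerance = 1e-9)
  expect_equal(spline_interpolate(t7, v7, 90), 1.0542975974049753, tolerance = 1e-9)
  expect_equal(spline_interpolate(t7, v7, 119), 1.1421923962678497, tolerance = 1e-9)
})

test_that("spline interpolation at a knot returns the stored value exactly", {
  t <- c(0, 30, 60, 90, 120)
  v <- c(1.5, -0.2, 0.7, 3.1, 2.2)
  for (i in seq_along(t))
    expect_identical(spline_interpolate(t, v, t[i]), v[i])
})

test_that("spline edge cases: few points fall back, extrapolation errors", {
  expect_warning(out <- spline_interpolate(c(0, 30, 60), c(0, 3, 6), 45),
                 "linear")
  expect_equal(out, 4.5)
  expect_error(spline_interpolate(c(0, 30, 60, 90), 1:4, 100), "outside")
  expect_error(spline_interpolate(c(0, 0, 30, 60), 1:4, 10), "distinct")
})

make_raw <- function(spec) {
  # spec: named list experiment -> times; values are a deterministic
  # function of (gene, experiment, time) so interpolation is checkable
  genes <- c("gA", "gB", "gC")
  cols <- list(); ann <- list()
  for (ex in names(spec)) {
    for (tt in spec[[ex]]) {
      id <- paste0(ex, "_", tt)
      cols[[id]] <- seq_along(genes) * 100 + tt  # linear in time per gene
      ann[[id]] <- data.frame(array_id = id, experiment_id = ex, time_min = tt)
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- genes
  list(expr = expr, ann = do.call(rbind, ann))
}

test_that("select_equidistant keeps complete grids, rescues a missing final
           point by interpolation, and drops the rest", {
  raw <- make_raw(list(e1 = c(0, 30, 60, 90),
                       e2 = c(0, 30, 60, 120, 180),
                       e3 = c(0, 60)))
  suppressMessages(
    ds <- select_equidistant(raw$expr, raw$ann, c(0, 30, 60, 90),
                             interpolation_source = 120))
  expect_setequal(names(ds$experiments), c("e1", "e2"))
  expect_equal(ds$time_grid, c(0, 30, 60, 90))
  # e1 retained verbatim
  expect_equal(unname(ds$experiments$e1["gB", ]), 200 + c(0, 30, 60, 90))
  # e2: value at 90 interpolated; the generating function is linear in t,
  # which the spline reproduces exactly
  expect_equal(unname(ds$experiments$e2["gC", 4]), 390, tolerance = 1e-9)
})

test_that("select_equidistant is idempotent on its own output", {
  raw <- make_raw(list(e1 = c(0, 30, 60, 90), e2 = c(0, 30, 60, 120, 180)))
  suppressMessages(
    ds <- select_equidistant(raw$expr, raw$ann, c(0, 30, 60, 90), 120))
  f <- tempfile(); g <- tempfile()
  write_expression(ds, f, g)
  suppressMessages(
    ds2 <- select_equidistant(read_expression(f), read_annotation(g),
                              c(0, 30, 60, 90), 120))
  expect_equal(ds2$experiments, ds$experiments)
})

test_that("select_equidistant rejects malformed input", {
  raw <- make_raw(list(e1 = c(0, 30, 60, 90)))
  dup <- rbind(raw$ann, raw$ann[1, ])
  dup$array_id[nrow(dup)] <- "other"
  expr2 <- cbind(raw$expr, other = raw$expr[, 1])
  expect_error(select_equidistant(expr2, dup, c(0, 30, 60, 90)),
               "duplicate")
  raw2 <- make_raw(list(e1 = c(0, 60)))
  expect_error(
    suppressMessages(select_equidistant(raw2$expr, raw2$ann, c(0, 30, 60, 90))),
    "no experiment")
  # a missing middle time point is not rescued
  raw3 <- make_raw(list(e1 = c(0, 60, 90, 120)))
  expect_error(
    suppressMessages(select_equidistant(raw3$expr, raw3$ann,
                                        c(0, 30, 60, 90), 120)),
    "no experiment")
})

test_that("time_course_dataset enforces its invariants", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_s3_class(time_course_dataset(list(e1 = m), c(0, 30, 60, 90)),
                  "TimeCourseDataset")
  expect_error(time_course_dataset(list(e1 = m), c(0, 30, 70, 90)),
               "equidistant")
  expect_error(time_course_dataset(list(e1 = m), c(0, 30, 60)), "columns")
  m2 <- m; m2[1, 1] <- NA
  expect_error(time_course_dataset(list(e1 = m2), c(0, 30, 60, 90)),
               "non-finite")
})
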