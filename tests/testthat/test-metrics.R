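# Comparative emptying metrics: ratio arithmetic, degenerate pairs,
# antisymmetry and report determinism.

test_that("retention and speed statistics are plain escaped-particle means", {
  s <- tibble::tibble(id = 1:3,
                      status = factor(c("ESCAPED_OUTLET", "ESCAPED_OUTLET", "TIMED_OUT"),
                                      levels = c("ESCAPED_OUTLET", "ESCAPED_INLET", "TIMED_OUT")),
                      retention_time = c(1, 2, NA),
                      mean_speed = c(0.02, 0.04, 0.1),
                      n_samples = c(10L, 20L, 5L))
  st <- retention_and_speed_stats(s)
  expect_equal(st$mean_retention, 1.5)
  expect_equal(st$mean_speed, 0.03)
  expect_equal(st$n_escaped, 2L)
  none <- s; none$status[] <- "TIMED_OUT"
  expect_error(retention_and_speed_stats(none), "max_time")
})

test_that("identical model results give the degenerate report", {
  a <- fake_result("CGJ", pyl = 2e-6, anast = 1.6e-5, dp = 4, ret = 30, spd = 0.022)
  b <- fake_result("SPGJ", pyl = 2e-6, anast = 1.6e-5, dp = 4, ret = 30, spd = 0.022)
  rep <- build_report(a, b)
  expect_equal(rep$pyloric_flow_ratio_pct, 100)
  expect_equal(rep$pressure_drop_reduction_pct, 0)
  expect_equal(rep$retention_time_ratio, 1)
  expect_error(build_report(a, a), "different")
})

test_that("a fully blocked pyloric path gives a zero flow ratio", {
  a <- fake_result("CGJ", pyl = 2e-6, anast = 1.6e-5, dp = 4, ret = 30, spd = 0.022)
  b <- fake_result("SPGJ", pyl = 0, anast = 1.8e-5, dp = 3.6, ret = 20, spd = 0.029)
  expect_equal(pyloric_flow_ratio(a, b), 0)
  # undefined when the CGJ reference flux is numerically zero
  z <- fake_result("CGJ", pyl = 0, anast = 1.8e-5, dp = 4, ret = 30, spd = 0.022)
  expect_error(pyloric_flow_ratio(z, b), "undefined")
  expect_error(pyloric_flow_ratio(b, a), "order")
})

test_that("swapping the pair inverts the comparative ratios", {
  a <- fake_result("CGJ", pyl = 3e-6, anast = 1.5e-5, dp = 4.2, ret = 36, spd = 0.021)
  b <- fake_result("SPGJ", pyl = 6e-7, anast = 1.74e-5, dp = 3.8, ret = 24, spd = 0.028)
  fwd <- build_report(a, b)
  a2 <- a; a2$variant <- "SPGJ"
  b2 <- b; b2$variant <- "CGJ"
  rev <- build_report(b2, a2)
  expect_equal(fwd$retention_time_ratio, 1 / rev$retention_time_ratio)
  expect_equal(fwd$pyloric_flow_ratio_pct, 100^2 / rev$pyloric_flow_ratio_pct)
})

test_that("the report is a pure function of its inputs and serializes", {
  a <- fake_result("CGJ", pyl = 3e-6, anast = 1.5e-5, dp = 4.2, ret = 36, spd = 0.021)
  b <- fake_result("SPGJ", pyl = 6e-7, anast = 1.74e-5, dp = 3.8, ret = 24, spd = 0.028)
  expect_identical(build_report(a, b), build_report(a, b))
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_report(build_report(a, b), jf, cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$pressure_drop_reduction_pct,
               build_report(a, b)$pressure_drop_reduction_pct, tolerance = 1e-12)
  expect_true(file.exists(cf))
})

test_that("flux-split closure holds across the anatomic bifurcation", {
  pair <- anatomy_pair()
  for (r in pair) {
    expect_lt(r$flux_closure, 0.005)
  }
})
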