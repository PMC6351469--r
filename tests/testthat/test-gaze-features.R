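# I-VT event detection, confidence ellipse, 18-biomarker extraction.

test_that("I-VT classifies a constructed stationary-shift-stationary trace", {
  # 200 ms still, 40 ms linear 10 deg shift (250 deg/s), 200 ms still @100 Hz
  gx <- c(rep(0, 20), 2.5, 5, 7.5, rep(10, 22))
  g <- gaze_recording("t", 100, gx, rep(0, 45))
  ev <- detect_events_ivt(g, velocity_threshold = 30, min_fixation = 60,
                          max_gap = 75)
  expect_equal(ev$kind, c("fixation", "saccade", "fixation"))
  expect_equal(ev$duration_ms[2], 40)
})

test_that("I-VT degenerate traces: all-still, all-saccade, all-invalid", {
  g <- gaze_recording("a", 100, rep(1, 1000), rep(2, 1000))
  ev <- detect_events_ivt(g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")

  set.seed(1)
  noise <- rnorm(500, 0, 10)   # white-noise positions, huge per-sample speed
  ev2 <- detect_events_ivt(gaze_recording("b", 100, noise, noise))
  expect_false(any(ev2$kind == "fixation"))

  g3 <- gaze_recording("c", 100, rep(0, 100), rep(0, 100),
                       valid = rep(FALSE, 100))
  expect_warning(ev3 <- detect_events_ivt(g3), "valid")
  expect_equal(nrow(ev3), 0)
})

test_that("I-VT events are ordered, positive, and alternate between gaps", {
  p <- severity_profile("a", "patient", 0.8, 25)
  g <- generate_gaze_recording(p, seed = 21)
  ev <- detect_events_ivt(g)
  expect_true(all(diff(ev$start) > 0))
  expect_true(all(ev$duration_ms > 0))
  expect_true(all(ev$end >= ev$start))
  # no overlap
  expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))
  # adjacent same-kind events only where separated by unclassified time
  same <- which(ev$kind[-1] == ev$kind[-nrow(ev)])
  if (length(same) > 0)
    expect_true(all(ev$start[same + 1] - ev$end[same] > 1 / g$rate + 1e-9))
})

test_that("confidence ellipse has chi-square geometry and correct coverage", {
  set.seed(42)
  P <- matrix(rnorm(20000), ncol = 2)
  e <- confidence_ellipse(P, 0.95)
  full_axes <- 2 * e$semi_axes
  expect_equal(full_axes, rep(2 * sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.02)
  expect_equal(e$area, pi * qchisq(0.95, 2), tolerance = 0.04)
  cov_emp <- mean(in_ellipse(P, e))
  expect_gte(cov_emp, 0.94)
  expect_lte(cov_emp, 0.96)

  expect_error(confidence_ellipse(matrix(1, 10, 2)), "degenerate")
  expect_error(confidence_ellipse(cbind(1:10, 2 * (1:10))), "degenerate")
  expect_error(confidence_ellipse(P[1:2, ]), "n >= 3")
})

test_that("single-event and missing-ratio conventions", {
  ev <- structure(data.frame(kind = "fixation", start = 0, end = 0.5,
                             duration_ms = 500, stringsAsFactors = FALSE),
                  class = c("gaze_event_sequence", "data.frame"))
  g <- gaze_recording("a", 100, rep(3, 1200), rep(4, 1200))
  fv <- extract_feature_vector(g, ev)
  expect_equal(unname(fv["MeanFix"]), 500)
  expect_equal(unname(fv["VarianceFix"]), 0)
  expect_equal(unname(fv["RangeX"]), 0)
  expect_true(is.na(fv["Fix2SacNratio"]))   # zero saccades -> flagged NA
  expect_true(is.na(fv["RatioRange"]))      # RangeY = 0 -> flagged NA
  expect_length(unclass(fv), 18)
  expect_named(fv, oculomotor_feature_names())
})

test_that("features are translation invariant and scale linearly", {
  p <- severity_profile("a", "patient", 0.5, 30)
  g <- generate_gaze_recording(p, seed = 9)
  ev <- detect_events_ivt(g)
  fv <- extract_feature_vector(g, ev)

  g_shift <- g
  g_shift$gx <- g$gx + 17.3
  g_shift$gy <- g$gy - 4.2
  expect_equal(extract_feature_vector(g_shift, ev), fv, tolerance = 1e-12)

  g_mag <- g
  g_mag$gx <- 2 * g$gx
  g_mag$gy <- 2 * g$gy
  fv2 <- extract_feature_vector(g_mag, ev)
  linear <- c("RangeX", "RangeY", "VarianceX", "VarianceY",
              "VelocityX", "VelocityY", "Velocity")
  expect_equal(unclass(fv2)[linear], 2 * unclass(fv)[linear],
               tolerance = 1e-10)
  expect_equal(unname(fv2["EllArea"]), 4 * unname(fv["EllArea"]),
               tolerance = 1e-10)
  expect_equal(unname(fv2["RatioRange"]), unname(fv["RatioRange"]),
               tolerance = 1e-10)
  # duration statistics are untouched by spatial transforms
  expect_equal(unname(fv2["MeanFix"]), unname(fv["MeanFix"]))
})

test_that("Euclidean speed dominates component velocities on generated traces", {
  for (s in 1:5) {
    p <- severity_profile("a", "patient", runif(1), 30)
    g <- generate_gaze_recording(p, seed = 400 + s)
    fv <- extract_feature_vector(g, detect_events_ivt(g))
    expect_gte(fv["Velocity"], max(fv["VelocityX"], fv["VelocityY"]))
  }
})

test_that("planted cohort MeanFix is recovered through the full extractor", {
  prm <- gaze_gen_params(mean_fix_ms = c(300, 300))
  mf <- vapply(1:12, function(i) {
    p <- severity_profile("s", "patient", 0.5, 30)
    g <- generate_gaze_recording(p, rate = 100, duration = 60,
                                 seed = 600 + i, params = prm)
    fv <- extract_feature_vector(g, detect_events_ivt(g))
    unname(fv["MeanFix"])
  }, 0)
  expect_lt(abs(mean(mf) - 300) / 300, 0.10)
})
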