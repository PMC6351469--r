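# Synthetic cohort generator: determinism, planted truth, calibration.

test_that("generators validate their arguments", {
  p <- severity_profile("a", "patient", 0.5, 30)
  expect_error(generate_gaze_recording(p, duration = 5), "duration")
  expect_error(generate_gaze_recording(p, rate = 20), "rate")
  expect_error(generate_cop_recording(p, "EO", duration = 10), "duration")
  expect_error(severity_profile("a", "patient", 1.5), "severity")
  expect_error(cohort_config(n_patients = 0), "counts")
})

test_that("gaze generation is deterministic and degenerate case is flat", {
  p <- severity_profile("a", "patient", 0.7, 25)
  g1 <- generate_gaze_recording(p, seed = 11)
  g2 <- generate_gaze_recording(p, seed = 11)
  expect_identical(g1, g2)

  # zero jitter and zero-size box -> constant trajectory, RangeX = 0
  prm <- gaze_gen_params(jitter_sd_deg = 0, range_x_deg = c(0, 0),
                         range_y_deg = c(0, 0))
  g0 <- generate_gaze_recording(p, seed = 3, params = prm)
  expect_equal(diff(range(g0$gx)), 0)
  expect_equal(diff(range(g0$gy)), 0)
})

test_that("generator-expected calibration is monotone across severity", {
  cal <- gaze_calibration(c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(diff(cal$mean_fix_ms) < 0))
  expect_true(all(diff(cal$range_x_deg) > 0))
  expect_true(all(diff(cal$range_y_deg) > 0))
})

test_that("detected MeanFix matches the calibration endpoints within 10%", {
  mean_fix <- function(sev, n = 50) {
    mean(vapply(seq_len(n), function(i) {
      p <- severity_profile("s", "patient", sev, 30)
      g <- generate_gaze_recording(p, seed = 2000 + i)
      ev <- detect_events_ivt(g)
      mean(ev$duration_ms[ev$kind == "fixation"])
    }, 0))
  }
  mf0 <- mean_fix(0)
  mf1 <- mean_fix(1)
  expect_lt(abs(mf0 - 316) / 316, 0.10)
  expect_lt(abs(mf1 - 153) / 153, 0.10)
})

test_that("CoP bursts realise the planted fraction and jitter-free sampling is uniform", {
  prm <- cop_gen_params(a = 0.6, b_eo = 0)
  p0 <- severity_profile("a", "control", 0, 37)
  r0 <- generate_cop_recording(p0, "EO", 60, seed = 1, params = prm)
  expect_equal(attr(r0, "truth")$f, 0)
  expect_equal(nrow(attr(r0, "truth")$burst_blocks), 0)

  p1 <- severity_profile("b", "patient", 1, 20)
  fr <- vapply(1:20, function(s) {
    r <- generate_cop_recording(p1, "EO", 60, seed = s, params = prm)
    attr(r, "truth")$realised_f_scored
  }, 0)
  expect_true(all(abs(fr - 0.6) <= 0.05))

  prm0 <- cop_gen_params(timestamp_jitter = 0)
  r <- generate_cop_recording(p1, "EC", 30, seed = 2, params = prm0)
  expect_equal(diff(r$t), rep(1 / prm0$nominal_rate_hz, length(r$t) - 1),
               tolerance = 1e-12)
  expect_true(all(diff(r$t) > 0))
})

test_that("cohort generation is deterministic and groups are ordered", {
  cfg <- cohort_config(n_patients = 10, n_controls = 9, seed = 5)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1$truth), 19)
  sev_p <- co1$truth$severity[co1$truth$group == "patient"]
  sev_c <- co1$truth$severity[co1$truth$group == "control"]
  expect_gt(median(sev_p), median(sev_c))
  expect_true(all(co1$truth$attention_subscore >= 0 &
                    co1$truth$attention_subscore <= 37))
  # attention decreases with severity in expectation
  expect_lt(cor(co1$truth$severity, co1$truth$attention_subscore), 0)
})

test_that("effect_scale = 0 decouples gaze statistics from severity", {
  # null cohorts: MeanFix ~ severity correlation should rarely be significant
  sig <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n_patients = 20, n_controls = 20,
                                        gaze_duration = 20, seed = 900 + s,
                                        effect_scale = 0))
    mf <- vapply(co$gaze, function(g) {
      ev <- detect_events_ivt(g)
      mean(ev$duration_ms[ev$kind == "fixation"])
    }, 0)
    cor.test(mf, co$truth$severity)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(!sig), 0.90)
})

test_that("write_cohort emits the three CSV contracts", {
  co <- generate_cohort(cohort_config(n_patients = 2, n_controls = 1,
                                      gaze_duration = 10, cop_duration = 25,
                                      seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  gz <- read.csv(paths[1])
  expect_named(gz, c("subject_id", "t_s", "gaze_x_deg", "gaze_y_deg",
                     "valid"))
  cp <- read.csv(paths[2])
  expect_named(cp, c("subject_id", "condition", "t_s", "cop_x_cm",
                     "cop_y_cm"))
  tr <- read.csv(paths[3])
  expect_named(tr, c("subject_id", "group", "severity", "f_EO", "f_EC",
                     "attention_subscore"))
  expect_equal(sort(unique(cp$condition)), c("EC", "EO"))
})
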