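# SWARII resampling, window descriptors, quiet/unquiet mixture, score.

test_that("swarii_resample preserves constants and is a convex combination", {
  set.seed(1)
  t <- sort(runif(80, 0, 10))
  raw <- cop_recording("a", "EO", t, rep(5, 80), rep(-2, 80))
  rs <- swarii_resample(raw, 25)
  expect_true(all(rs$x == 5))
  expect_true(all(rs$y == -2))

  raw2 <- cop_recording("a", "EO", t, rnorm(80), rnorm(80))
  rs2 <- swarii_resample(raw2, 25)
  expect_true(all(rs2$x >= min(raw2$x) & rs2$x <= max(raw2$x)))
  expect_true(all(rs2$y >= min(raw2$y) & rs2$y <= max(raw2$y)))
})

test_that("swarii_resample centred mean and interpolation fallback are exact", {
  # x(t) = t sampled symmetrically around the grid point 0.5
  raw <- cop_recording("a", "EO", c(0.4, 0.45, 0.55, 0.6),
                       c(0.4, 0.45, 0.55, 0.6), rep(0, 4))
  rs <- swarii_resample(raw, rate = 10, window = 0.4)
  expect_equal(rs$t[2], 0.5)
  expect_equal(rs$x[2], 0.5)

  # empty window at t = 0.5 -> linear interpolation between (0,0) and (1,10)
  raw2 <- cop_recording("a", "EO", c(0, 1), c(0, 10), c(0, 0))
  rs2 <- swarii_resample(raw2, rate = 2, window = 0.04)
  expect_equal(rs2$t, c(0, 0.5, 1))
  expect_equal(rs2$x[2], 5.0)

  expect_error(swarii_resample(list(t = 1, x = 1, y = 1)), "2 raw samples")
})

test_that("window_descriptors counts windows and flags stationary signals", {
  sig <- structure(list(rate = 25, t0 = 0, t = seq(0, 25, by = 0.04),
                        x = rep(1, 626), y = rep(2, 626),
                        subject_id = "a", condition = "EO"),
                   class = "uniform_cop_signal")
  wd <- window_descriptors(sig, 1, 25)
  expect_equal(nrow(wd$desc), 25)
  expect_true(all(wd$desc == 0))

  short <- structure(list(rate = 25, t0 = 0, t = seq(0, 10, by = 0.04),
                          x = rnorm(251), y = rnorm(251)),
                     class = "uniform_cop_signal")
  expect_error(window_descriptors(short, 1, 25), "shorter than keep_last")
})

test_that("descriptors separate planted quiet and burst windows bimodally", {
  p <- severity_profile("a", "patient", 1, 20)
  r <- generate_cop_recording(p, "EO", 60, seed = 4,
                              params = cop_gen_params(a = 0.5, b_eo = 0))
  wd <- window_descriptors(swarii_resample(r, 25), 1, 25)
  truth <- attr(r, "truth")
  # label each window by the regime covering its midpoint
  mid <- wd$start_times + wd$window_len / 2
  burst_win <- vapply(mid, function(s)
    any(s >= truth$burst_blocks$start & s < truth$burst_blocks$end), TRUE)
  expect_gt(sum(burst_win), 3)
  expect_gt(sum(!burst_win), 3)
  # bimodal with the planted split: the two regimes do not even overlap
  norm_b <- sqrt(rowSums(wd$desc[burst_win, , drop = FALSE]^2))
  norm_q <- sqrt(rowSums(wd$desc[!burst_win, , drop = FALSE]^2))
  expect_gt(min(norm_b), max(norm_q))
  expect_gt(median(norm_b), 2 * median(norm_q))
})

test_that("mixture fit recovers planted weights and is deterministic", {
  fx <- make_separated_descriptors(7)
  m1 <- fit_quiet_unquiet_model(fx$desc, seed = 1)
  m2 <- fit_quiet_unquiet_model(fx$desc, seed = 1)
  expect_identical(m1, m2)
  expect_true(m1$converged)
  w_unquiet <- m1$weights[m1$unquiet]
  expect_lt(abs(w_unquiet - 0.3), 0.05)
  expect_equal(classify_windows(m1, fx$desc), fx$labels)
})

test_that("degenerate descriptor pools are flagged and classified quiet", {
  X <- matrix(1, 30, 3, dimnames = list(NULL, c("path_len", "pos_sd",
                                                "mean_speed")))
  expect_warning(m <- fit_quiet_unquiet_model(X, seed = 1), "degenerate")
  expect_true(m$degenerate)
  expect_false(any(classify_windows(m, X)))
  expect_error(fit_quiet_unquiet_model(X[1:10, ], seed = 1), "20")
})

test_that("postural score follows the unquiet-fraction formula exactly", {
  fx <- make_separated_descriptors(8)
  model <- fit_quiet_unquiet_model(fx$desc, seed = 2)
  quiet <- fx$desc[!fx$labels, ][1:25, ]
  unquiet <- fx$desc[fx$labels, ][1:25, ]
  mk <- function(n_unquiet, cond)
    as_descriptor_set(rbind(quiet[seq_len(25 - n_unquiet), , drop = FALSE],
                            unquiet[seq_len(n_unquiet), , drop = FALSE]),
                      "S", cond)

  ps <- compute_postural_score(model, mk(10, "EO"), mk(15, "EC"))
  expect_equal(ps$f_EO, 0.4)
  expect_equal(ps$f_EC, 0.6)
  expect_equal(ps$score, 50)
  expect_equal(compute_postural_score(model, mk(0, "EO"), mk(0, "EC"))$score,
               100)
  expect_equal(compute_postural_score(model, mk(25, "EO"),
                                      mk(25, "EC"))$score, 0)
  expect_error(compute_postural_score(model, NULL, mk(0, "EC")), "required")

  # strictly decreasing in each planted unquiet fraction, other held fixed
  s_eo <- vapply(0:25, function(k)
    compute_postural_score(model, mk(k, "EO"), mk(5, "EC"))$score, 0)
  expect_true(all(diff(s_eo) < 0))
})

test_that("score_cohort drops subjects missing a condition with a warning", {
  co <- generate_cohort(cohort_config(n_patients = 4, n_controls = 4,
                                      seed = 12))
  cop <- co$cop
  cop[["S01.EC"]] <- NULL
  expect_warning(res <- score_cohort(cop, seed = 1), "S01")
  expect_false("S01" %in% res$scores$subject_id)
  expect_equal(nrow(res$scores), 7)
})
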