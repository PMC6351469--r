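## Synthetic cohort generator.
##
## A latent per-subject severity in [0,1] jointly drives (i) oculomotor
## statistics -- shorter fixations, larger horizontal/vertical gaze excursions
## as severity grows -- and (ii) the fraction of "unquiet" high-sway bursts in
## the centre-of-pressure trajectory. This plants a gaze<->posture coupling
## that the downstream modules must recover, without any patient data.

# Calibration endpoints for the gaze generator: group-mean oculomotor values
# at severity 0 (intact) and severity 1 (maximally impaired). Expected
# detected mean fixation duration runs 316 -> 153 ms and the per-second
# horizontal/vertical gaze ranges run 6.0 -> 14.6 and 3.4 -> 9.5 deg.
GAZE_CAL <- list(
  mean_fix_ms  = c(intact = 316, impaired = 153),
  range_x_deg  = c(intact = 6.0, impaired = 14.6),
  range_y_deg  = c(intact = 3.4, impaired = 9.5)
)

#' Default parameters of the synthetic gaze generator
#'
#' @param mean_fix_ms Length-2 vector: expected detected mean fixation
#'   duration (ms) at severity 0 and severity 1.
#' @param range_x_deg,range_y_deg Length-2 vectors: target per-second
#'   horizontal/vertical gaze range (degrees) at severity 0 and 1.
#' @param fix_sdlog Log-scale SD of the lognormal fixation-duration law.
#' @param main_seq_slope_ms_per_deg,main_seq_intercept_ms Saccade main
#'   sequence: duration (ms) = slope * amplitude (deg) + intercept.
#' @param jitter_sd_deg SD of the isotropic fixational jitter (degrees).
#' @param blink_rate_hz Expected number of blink gaps per second.
#' @param blink_ms Length-2 range of blink-gap durations (ms).
#' @param boundary_comp_samples Number of sampling periods added to the drawn
#'   fixation durations to offset the samples a velocity-threshold detector
#'   reassigns to the flanking saccades.
#' @param detector_min_fixation_ms Assumed minimum-fixation cutoff of the
#'   downstream detector; the lognormal location is solved so that the mean
#'   of the fixations surviving that cutoff matches the calibration target.
#' @return A named list of generator parameters.
#' @export
gaze_gen_params <- function(mean_fix_ms = GAZE_CAL$mean_fix_ms,
                            range_x_deg = GAZE_CAL$range_x_deg,
                            range_y_deg = GAZE_CAL$range_y_deg,
                            fix_sdlog = 0.45,
                            main_seq_slope_ms_per_deg = 2.2,
                            main_seq_intercept_ms = 21,
                            jitter_sd_deg = 0.1,
                            blink_rate_hz = 0.25,
                            blink_ms = c(100, 300),
                            boundary_comp_samples = 3,
                            detector_min_fixation_ms = 60) {
  list(mean_fix_ms = mean_fix_ms, range_x_deg = range_x_deg,
       range_y_deg = range_y_deg, fix_sdlog = fix_sdlog,
       main_seq_slope_ms_per_deg = main_seq_slope_ms_per_deg,
       main_seq_intercept_ms = main_seq_intercept_ms,
       jitter_sd_deg = jitter_sd_deg, blink_rate_hz = blink_rate_hz,
       blink_ms = blink_ms, boundary_comp_samples = boundary_comp_samples,
       detector_min_fixation_ms = detector_min_fixation_ms)
}

#' Generator-expected gaze statistics at a given severity
#'
#' Linear interpolation between the severity-0 and severity-1 calibration
#' endpoints. Used by calibration tests as the generator's stated truth.
#'
#' @param severity Severity in `[0, 1]` (vectorised).
#' @param params See [gaze_gen_params()].
#' @return Data frame with columns `severity`, `mean_fix_ms`, `range_x_deg`,
#'   `range_y_deg`.
#' @export
gaze_calibration <- function(severity, params = gaze_gen_params()) {
  lerp <- function(v) v[[1]] + (v[[2]] - v[[1]]) * severity
  data.frame(severity = severity,
             mean_fix_ms = lerp(params$mean_fix_ms),
             range_x_deg = lerp(params$range_x_deg),
             range_y_deg = lerp(params$range_y_deg))
}

#' Severity profile of one synthetic subject
#'
#' @param subject_id Identifier string.
#' @param group `"patient"` or `"control"`.
#' @param severity Latent severity in `[0, 1]`; 0 = intact.
#' @param attention_subscore Integer attention subscore in `[0, 37]`.
#' @return A `severity_profile` list.
#' @export
severity_profile <- function(subject_id, group = c("patient", "control"),
                             severity, attention_subscore = NA_integer_) {
  group <- match.arg(group)
  if (!is_scalar_num(severity) || severity < 0 || severity > 1)
    stopf("severity must be a scalar in [0, 1]")
  if (!is.na(attention_subscore) &&
      (attention_subscore < 0 || attention_subscore > 37))
    stopf("attention_subscore must lie in [0, 37]")
  structure(list(subject_id = as.character(subject_id), group = group,
                 severity = severity,
                 attention_subscore = as.integer(attention_subscore)),
            class = "severity_profile")
}

# Raised-cosine position profile for a saccade: smooth, zero end velocity.
saccade_profile <- function(frac) (1 - cos(pi * frac)) / 2

# Width/height of the uniform box fixation centres are drawn from, such that
# the expected per-1-s-window range matches the calibration target. For k
# iid uniform points on [0, W] the expected range is W (k - 1) / (k + 1);
# k is approximated from the expected fixation + saccade cadence.
gaze_box_size <- function(severity, params) {
  cal <- gaze_calibration(severity, params)
  fix_s <- cal$mean_fix_ms / 1000
  sac_s <- 0.045                      # nominal saccade duration for cadence
  k <- 1 + 1 / (fix_s + sac_s)        # fixation centres per 1-s window
  fac <- (k - 1) / (k + 1)
  list(w = cal$range_x_deg / fac, h = cal$range_y_deg / fac)
}

#' Generate one synthetic gaze recording
#'
#' Alternating fixation/saccade process. Fixation centres are iid uniform in
#' a severity-dependent box (larger box = larger per-second gaze range);
#' fixation durations are lognormal with a severity-dependent mean (longer
#' when intact); saccades follow a main-sequence duration-amplitude rule with
#' a raised-cosine trajectory. Fixations carry small isotropic jitter, and a
#' stated fraction of samples is flagged invalid in contiguous blink gaps.
#'
#' @param profile A [severity_profile()].
#' @param rate Sampling rate in Hz (>= 50).
#' @param duration Recording duration in seconds (>= 10).
#' @param seed Integer seed.
#' @param params See [gaze_gen_params()].
#' @return A `gaze_recording`: list with `subject_id`, `rate`, `t`, `gx`,
#'   `gy` (degrees), `valid`, plus a `truth` attribute holding the planted
#'   event sequence and calibration targets.
#' @export
generate_gaze_recording <- function(profile, rate = 100, duration = 60,
                                    seed = 1, params = gaze_gen_params()) {
  if (!is_scalar_num(duration) || duration < 10)
    stopf("duration must be >= 10 s (got %s)", format(duration))
  if (!is_scalar_num(rate) || rate < 50)
    stopf("rate must be >= 50 Hz (got %s)", format(rate))
  set.seed(seed)
  s <- profile$severity
  cal <- gaze_calibration(s, params)
  box <- gaze_box_size(s, params)

  # Solve the lognormal location so that the detector-side mean matches the
  # calibration target: a drawn fixation X is detected with duration about
  # X - b (b = boundary samples reassigned to saccades) and kept only when
  # the detected duration clears the detector's minimum-fixation cutoff, so
  # the target constrains the truncated mean E[X | X > c] - b.
  b <- params$boundary_comp_samples / rate
  cutoff <- params$detector_min_fixation_ms / 1000 + b
  sdlog <- params$fix_sdlog
  target <- cal$mean_fix_ms / 1000 + b
  trunc_mean <- function(meanlog) {
    m <- exp(meanlog + sdlog^2 / 2)
    num <- pnorm((meanlog + sdlog^2 - log(cutoff)) / sdlog)
    den <- pnorm((meanlog - log(cutoff)) / sdlog)
    m * num / den
  }
  meanlog <- uniroot(function(m) trunc_mean(m) - target,
                     lower = log(cutoff) - 3, upper = log(10),
                     tol = 1e-10)$root

  # build the event schedule until it covers `duration`
  cx <- runif(1, 0, box$w); cy <- runif(1, 0, box$h)
  ev_kind <- character(); ev_start <- ev_end <- numeric()
  ev_x0 <- ev_y0 <- ev_x1 <- ev_y1 <- numeric()
  now <- 0
  while (now < duration) {
    d_fix <- rlnorm(1, meanlog, sdlog)
    ev_kind <- c(ev_kind, "fixation")
    ev_start <- c(ev_start, now); ev_end <- c(ev_end, now + d_fix)
    ev_x0 <- c(ev_x0, cx); ev_y0 <- c(ev_y0, cy)
    ev_x1 <- c(ev_x1, cx); ev_y1 <- c(ev_y1, cy)
    now <- now + d_fix
    nx <- runif(1, 0, box$w); ny <- runif(1, 0, box$h)
    amp <- sqrt((nx - cx)^2 + (ny - cy)^2)
    d_sac <- (params$main_seq_slope_ms_per_deg * amp +
                params$main_seq_intercept_ms) / 1000
    ev_kind <- c(ev_kind, "saccade")
    ev_start <- c(ev_start, now); ev_end <- c(ev_end, now + d_sac)
    ev_x0 <- c(ev_x0, cx); ev_y0 <- c(ev_y0, cy)
    ev_x1 <- c(ev_x1, nx); ev_y1 <- c(ev_y1, ny)
    now <- now + d_sac
    cx <- nx; cy <- ny
  }

  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  idx <- findInterval(t, ev_start)
  frac <- (t - ev_start[idx]) / pmax(ev_end[idx] - ev_start[idx], 1e-12)
  sac <- ev_kind[idx] == "saccade"
  prof <- ifelse(sac, saccade_profile(pmin(frac, 1)), 0)
  gx <- ev_x0[idx] + (ev_x1[idx] - ev_x0[idx]) * prof
  gy <- ev_y0[idx] + (ev_y1[idx] - ev_y0[idx]) * prof
  if (params$jitter_sd_deg > 0) {
    gx <- gx + ifelse(sac, 0, rnorm(n, 0, params$jitter_sd_deg))
    gy <- gy + ifelse(sac, 0, rnorm(n, 0, params$jitter_sd_deg))
  }

  # blink gaps: Poisson starts, uniform duration, marked invalid
  valid <- rep(TRUE, n)
  n_blinks <- rbinom(1, n, params$blink_rate_hz / rate)
  if (n_blinks > 0) {
    starts <- sort(runif(n_blinks, 0, duration))
    lens <- runif(n_blinks, params$blink_ms[1], params$blink_ms[2]) / 1000
    for (b in seq_len(n_blinks))
      valid[t >= starts[b] & t < starts[b] + lens[b]] <- FALSE
  }

  structure(
    list(subject_id = profile$subject_id, rate = rate, t = t,
         gx = gx, gy = gy, valid = valid),
    class = "gaze_recording",
    truth = list(severity = s, calibration = cal,
                 events = data.frame(kind = ev_kind, start = ev_start,
                                     end = ev_end),
                 box = box))
}

#' Default parameters of the synthetic centre-of-pressure generator
#'
#' Sway is a mean-reverting (Ornstein-Uhlenbeck) process; "unquiet" bursts
#' inflate its stationary variance by `burst_var_mult`. The planted burst-time
#' fraction is `f = clip(a * severity + b_condition, 0, 1)` with a larger
#' offset for eyes closed.
#'
#' @param nominal_rate_hz Nominal sampling rate before timestamp jitter.
#' @param timestamp_jitter Jitter of each timestamp, as a fraction of the
#'   nominal period (0 = exactly uniform sampling).
#' @param ou_tau_s Relaxation time of the mean-reverting sway.
#' @param quiet_sd_cm Stationary sway SD in the quiet regime.
#' @param burst_var_mult Variance inflation factor of the burst regime.
#' @param block_s Length of the quiet/burst allocation blocks.
#' @param a,b_eo,b_ec Burst-fraction law `f = clip(a*severity + b, 0, 1)`.
#' @return A named list of generator parameters.
#' @export
cop_gen_params <- function(nominal_rate_hz = 40, timestamp_jitter = 0.3,
                           ou_tau_s = 1.0, quiet_sd_cm = 0.3,
                           burst_var_mult = 16, block_s = 1,
                           a = 0.5, b_eo = 0.05, b_ec = 0.15) {
  list(nominal_rate_hz = nominal_rate_hz, timestamp_jitter = timestamp_jitter,
       ou_tau_s = ou_tau_s, quiet_sd_cm = quiet_sd_cm,
       burst_var_mult = burst_var_mult, block_s = block_s,
       a = a, b_eo = b_eo, b_ec = b_ec)
}

#' Generate one synthetic centre-of-pressure recording
#'
#' Two-regime surrogate for quiet vs unquiet sway: an Ornstein-Uhlenbeck
#' process whose innovation variance is inflated inside burst blocks. Burst
#' blocks are allocated so that both the whole record and its final 25 s
#' (the scored epoch) carry the planted burst fraction as closely as the
#' block grid allows. Timestamps are jittered around the nominal period to
#' emulate a force platform with non-constant sampling frequency.
#'
#' @param profile A [severity_profile()].
#' @param condition `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @param duration Duration in seconds (>= 25, the scored epoch length).
#' @param seed Integer seed.
#' @param params See [cop_gen_params()].
#' @return A `cop_recording`: list with `subject_id`, `condition`, `t`
#'   (strictly increasing, seconds), `x`, `y` (cm), plus a `truth` attribute
#'   with the planted fraction `f`, the realised fraction over the final
#'   25 s, and the burst-block log.
#' @export
generate_cop_recording <- function(profile, condition = c("EO", "EC"),
                                   duration = 60, seed = 1,
                                   params = cop_gen_params()) {
  condition <- match.arg(condition)
  if (!is_scalar_num(duration) || duration < 25)
    stopf("duration must be >= 25 s (got %s)", format(duration))
  set.seed(seed)
  b <- if (condition == "EO") params$b_eo else params$b_ec
  f <- clip01(params$a * profile$severity + b)

  block <- params$block_s
  n_blocks <- floor(duration / block)
  tail_blocks <- min(n_blocks, floor(25 / block))
  head_blocks <- n_blocks - tail_blocks
  # stratified allocation: the scored tail carries round(f * tail) bursts
  pick <- function(n_avail, n_burst, offset) {
    if (n_burst <= 0) return(integer())
    offset + sample.int(n_avail, n_burst)
  }
  burst_blocks <- sort(c(
    pick(head_blocks, round(f * head_blocks), 0),
    pick(tail_blocks, round(f * tail_blocks), head_blocks)))
  is_burst_block <- rep(FALSE, n_blocks)
  is_burst_block[burst_blocks] <- TRUE

  rate <- params$nominal_rate_hz
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  if (params$timestamp_jitter > 0) {
    t <- t + runif(n, -params$timestamp_jitter, params$timestamp_jitter) / rate
    t <- t - t[1]                      # start at 0, order preserved
  }
  blk <- pmin(floor(t / block) + 1, n_blocks)
  burst <- is_burst_block[blk]
  sd_stat <- ifelse(burst, params$quiet_sd_cm * sqrt(params$burst_var_mult),
                    params$quiet_sd_cm)

  ou_sim <- function() {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd_stat[1])
    if (n > 1) {
      dt <- diff(t)
      phi <- exp(-dt / params$ou_tau_s)
      innov_sd <- sd_stat[-1] * sqrt(1 - phi^2)
      eps <- rnorm(n - 1)
      for (i in 2:n) x[i] <- phi[i - 1] * x[i - 1] + innov_sd[i - 1] * eps[i - 1]
    }
    x
  }
  x <- ou_sim()
  y <- ou_sim()

  t_tail <- t[n] - 25
  realised <- mean(burst[t >= t_tail])
  structure(
    list(subject_id = profile$subject_id, condition = condition,
         t = t, x = x, y = y),
    class = "cop_recording",
    truth = list(f = f, realised_f_scored = realised,
                 burst_blocks = data.frame(
                   start = (burst_blocks - 1) * block,
                   end = burst_blocks * block),
                 severity = profile$severity))
}

#' Cohort-generation configuration
#'
#' @param n_patients,n_controls Group sizes (>= 1); defaults mirror a
#'   10-patient / 9-control study design.
#' @param gaze_rate Gaze sampling rate (Hz).
#' @param gaze_duration Gaze recording length (s).
#' @param cop_duration Centre-of-pressure recording length per condition (s);
#'   the default leaves a >= 35 s acclimatisation period before the scored
#'   final 25 s.
#' @param seed Integer master seed.
#' @param effect_scale Scaling of the severity effect on gaze statistics;
#'   0 decouples gaze from posture (null cohort).
#' @param gaze_params,cop_params Generator parameter lists.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10, n_controls = 9, gaze_rate = 100,
                          gaze_duration = 60, cop_duration = 60, seed = 1,
                          effect_scale = 1,
                          gaze_params = gaze_gen_params(),
                          cop_params = cop_gen_params()) {
  if (!is_count(n_patients) || !is_count(n_controls))
    stopf("group sizes must be counts >= 1")
  if (gaze_rate <= 0 || gaze_duration <= 0 || cop_duration <= 0)
    stopf("rates and durations must be positive")
  if (!is_scalar_num(effect_scale) || effect_scale < 0)
    stopf("effect_scale must be >= 0")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 gaze_rate = gaze_rate, gaze_duration = gaze_duration,
                 cop_duration = cop_duration, seed = seed,
                 effect_scale = effect_scale, gaze_params = gaze_params,
                 cop_params = cop_params),
            class = "cohort_config")
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject severities (patients stochastically more severe than
#' controls), attention subscores decreasing in expectation with severity,
#' and per-subject gaze and centre-of-pressure recordings. The gaze generator
#' sees `effect_scale * severity`, so `effect_scale = 0` yields a null cohort
#' in which gaze statistics are independent of the planted postural truth.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `profiles`, `gaze` (named list of
#'   `gaze_recording`s), `cop` (named list, two recordings per subject), and
#'   `truth` (data frame: subject_id, group, severity, f_EO, f_EC,
#'   attention_subscore).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients + config$n_controls
  group <- c(rep("patient", config$n_patients),
             rep("control", config$n_controls))
  ids <- sprintf("S%02d", seq_len(n))
  severity <- ifelse(group == "patient", runif(n, 0.2, 1.0), runif(n, 0, 0.2))
  att <- round(37 - 14 * severity) + sample(-2:2, n, replace = TRUE)
  att <- pmin(37L, pmax(0L, as.integer(att)))
  sub_seeds <- floor(derive_seed(config$seed, seq_len(n)))

  profiles <- vector("list", n)
  gaze <- vector("list", n)
  cop <- list()
  truth <- data.frame(subject_id = ids, group = group, severity = severity,
                      f_EO = NA_real_, f_EC = NA_real_,
                      attention_subscore = att,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- severity_profile(ids[i], group[i], severity[i], att[i])
    profiles[[i]] <- p
    p_gaze <- p
    p_gaze$severity <- clip01(config$effect_scale * severity[i])
    gaze[[i]] <- generate_gaze_recording(p_gaze, config$gaze_rate,
                                         config$gaze_duration,
                                         seed = sub_seeds[i],
                                         params = config$gaze_params)
    eo <- generate_cop_recording(p, "EO", config$cop_duration,
                                 seed = sub_seeds[i] + 1,
                                 params = config$cop_params)
    ec <- generate_cop_recording(p, "EC", config$cop_duration,
                                 seed = sub_seeds[i] + 2,
                                 params = config$cop_params)
    cop[[paste0(ids[i], ".EO")]] <- eo
    cop[[paste0(ids[i], ".EC")]] <- ec
    truth$f_EO[i] <- attr(eo, "truth")$f
    truth$f_EC[i] <- attr(ec, "truth")$f
  }
  names(gaze) <- ids
  names(profiles) <- ids
  structure(list(profiles = profiles, gaze = gaze, cop = cop, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `gaze.csv` (subject_id, t_s, gaze_x_deg, gaze_y_deg, valid),
#' `cop.csv` (subject_id, condition, t_s, cop_x_cm, cop_y_cm) and
#' `truth.csv` (the planted truth table) into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the three files.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gaze_df <- do.call(rbind, lapply(cohort$gaze, function(g)
    data.frame(subject_id = g$subject_id, t_s = g$t, gaze_x_deg = g$gx,
               gaze_y_deg = g$gy, valid = as.integer(g$valid))))
  cop_df <- do.call(rbind, lapply(cohort$cop, function(r)
    data.frame(subject_id = r$subject_id, condition = r$condition,
               t_s = r$t, cop_x_cm = r$x, cop_y_cm = r$y)))
  paths <- file.path(dir, c("gaze.csv", "cop.csv", "truth.csv"))
  write.csv(gaze_df, paths[1], row.names = FALSE)
  write.csv(cop_df, paths[2], row.names = FALSE)
  write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
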