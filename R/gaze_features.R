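## Gaze event detection and oculomotor feature engineering.
##
## Events come from a velocity-threshold (I-VT) classifier: angular speed
## from central differences, samples above the threshold are saccadic,
## below-threshold runs are fixation candidates, and fixations shorter than
## a minimum duration are discarded (left unclassified) rather than merged.
## Short invalid gaps are bridged by linear interpolation; longer gaps split
## the recording into independently classified segments.

#' Construct a gaze recording
#'
#' @param subject_id Identifier.
#' @param rate Sampling rate in Hz.
#' @param gx,gy Gaze angles in degrees (uniform sampling assumed).
#' @param valid Logical validity flag per sample (default all valid).
#' @return A `gaze_recording` object.
#' @export
gaze_recording <- function(subject_id, rate, gx, gy,
                           valid = rep(TRUE, length(gx))) {
  if (length(gx) != length(gy) || length(gx) != length(valid))
    stopf("gx, gy, valid must have equal length")
  if (rate <= 0) stopf("rate must be positive")
  structure(list(subject_id = as.character(subject_id), rate = rate,
                 t = (seq_along(gx) - 1) / rate,
                 gx = as.numeric(gx), gy = as.numeric(gy),
                 valid = as.logical(valid)),
            class = "gaze_recording")
}

#' Velocity-threshold (I-VT) fixation/saccade detection
#'
#' Angular speed is computed by central differences (one-sided at segment
#' ends). Runs of samples at or below `velocity_threshold` are fixation
#' candidates; runs above it are saccades. Fixation candidates shorter than
#' `min_fixation` are discarded (their samples stay unclassified), which is
#' why two saccades may appear consecutively, separated by unclassified
#' time. Invalid runs no longer than `max_gap` are bridged by linear
#' interpolation; longer invalid runs split the recording into segments that
#' are classified independently.
#'
#' Event durations use the span convention `t(last) - t(first)` over the
#' samples in the run, with a floor of one sampling period.
#'
#' @param gaze A `gaze_recording`.
#' @param velocity_threshold Saccade speed threshold in deg/s (default 30).
#' @param min_fixation Minimum fixation duration in ms (default 60).
#' @param max_gap Maximum bridgeable invalid gap in ms (default 75).
#' @return A `gaze_event_sequence` data frame with columns `kind`
#'   (`"fixation"`/`"saccade"`), `start`, `end` (s), `duration_ms`, and
#'   attributes `n_discarded_fixations` and `rate`.
#' @export
detect_events_ivt <- function(gaze, velocity_threshold = 30,
                              min_fixation = 60, max_gap = 75) {
  rate <- gaze$rate
  dt <- 1 / rate
  n <- length(gaze$gx)
  valid <- gaze$valid
  if (sum(valid) < 3) {
    warning("fewer than 3 valid samples; returning empty event sequence")
    return(empty_event_sequence(rate))
  }

  # bridge short invalid gaps by linear interpolation
  gx <- gaze$gx; gy <- gaze$gy
  usable <- valid
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  vi <- which(valid)
  for (j in which(!r$values)) {
    gap_ms <- r$lengths[j] * dt * 1000
    i0 <- starts[j]; i1 <- ends[j]
    if (gap_ms <= max_gap && i0 > 1 && i1 < n && valid[i0 - 1] && valid[i1 + 1]) {
      idx <- i0:i1
      frac <- (idx - (i0 - 1)) / (i1 + 1 - (i0 - 1))
      gx[idx] <- gx[i0 - 1] + frac * (gx[i1 + 1] - gx[i0 - 1])
      gy[idx] <- gy[i0 - 1] + frac * (gy[i1 + 1] - gy[i0 - 1])
      usable[idx] <- TRUE
    }
  }

  # segments of contiguous usable samples
  rs <- rle(usable)
  seg_end <- cumsum(rs$lengths)
  seg_start <- seg_end - rs$lengths + 1
  events <- list()
  n_discarded <- 0L
  for (j in which(rs$values)) {
    i0 <- seg_start[j]; i1 <- seg_end[j]
    m <- i1 - i0 + 1
    if (m < 3) next
    sx <- gx[i0:i1]; sy <- gy[i0:i1]
    vx <- c(sx[2] - sx[1],
            (sx[3:m] - sx[1:(m - 2)]) / 2,
            sx[m] - sx[m - 1]) * rate
    vy <- c(sy[2] - sy[1],
            (sy[3:m] - sy[1:(m - 2)]) / 2,
            sy[m] - sy[m - 1]) * rate
    speed <- sqrt(vx^2 + vy^2)
    sac <- speed > velocity_threshold
    rr <- rle(sac)
    re <- cumsum(rr$lengths)
    rb <- re - rr$lengths + 1
    for (k in seq_along(rr$values)) {
      a <- i0 + rb[k] - 1; b <- i0 + re[k] - 1
      dur_ms <- max(gaze$t[b] - gaze$t[a], dt) * 1000
      kind <- if (rr$values[k]) "saccade" else "fixation"
      if (kind == "fixation" && dur_ms < min_fixation) {
        n_discarded <- n_discarded + 1L
        next
      }
      events[[length(events) + 1]] <-
        data.frame(kind = kind, start = gaze$t[a], end = gaze$t[b],
                   duration_ms = dur_ms, stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0) {
    out <- empty_event_sequence(rate)
  } else {
    out <- do.call(rbind, events)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out <- structure(out, class = c("gaze_event_sequence", "data.frame"))
  }
  attr(out, "n_discarded_fixations") <- n_discarded
  attr(out, "rate") <- rate
  out
}

empty_event_sequence <- function(rate) {
  structure(data.frame(kind = character(), start = numeric(),
                       end = numeric(), duration_ms = numeric(),
                       stringsAsFactors = FALSE),
            class = c("gaze_event_sequence", "data.frame"),
            n_discarded_fixations = 0L, rate = rate)
}

#' Bivariate confidence ellipse of a point cloud
#'
#' Ellipse from the sample mean and covariance, scaled by the chi-square
#' quantile with 2 degrees of freedom at the requested coverage:
#' the semi-axes are `sqrt(q * lambda)` for eigenvalues `lambda` of the
#' covariance. The axis whose eigenvector is closer to the horizontal
#' direction is reported first.
#'
#' @param points Numeric matrix (n x 2) of angles in degrees, n >= 3.
#' @param coverage Target coverage in (0, 1), default 0.95.
#' @return An `ellipse_params` list: `center`, `semi_axes`
#'   (horizontal-ish, vertical-ish), `orientation` (radians), `area`
#'   (`pi * prod(semi_axes)`), `coverage`.
#' @export
confidence_ellipse <- function(points, coverage = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2)
    stopf("need an n x 2 matrix with n >= 3")
  if (coverage <= 0 || coverage >= 1) stopf("coverage must be in (0, 1)")
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10 || max(e$values) <= 0)
    stopf("degenerate geometry: points are (nearly) collinear")
  q <- qchisq(coverage, df = 2)
  semi <- sqrt(q * e$values)
  # order axes so the more horizontal eigenvector comes first
  if (abs(e$vectors[1, 1]) < abs(e$vectors[1, 2])) {
    semi <- rev(semi)
    vec1 <- e$vectors[, 2]
  } else {
    vec1 <- e$vectors[, 1]
  }
  structure(list(center = colMeans(points),
                 semi_axes = semi,
                 orientation = atan2(vec1[2], vec1[1]),
                 area = pi * prod(semi),
                 coverage = coverage),
            class = "ellipse_params")
}

#' Test which points fall inside a confidence ellipse
#'
#' @param points n x 2 matrix.
#' @param ellipse An `ellipse_params`.
#' @return Logical vector.
#' @export
in_ellipse <- function(points, ellipse) {
  points <- as.matrix(points)
  d <- sweep(points, 2, ellipse$center)
  ca <- cos(ellipse$orientation); sa <- sin(ellipse$orientation)
  u <- d[, 1] * ca + d[, 2] * sa
  v <- -d[, 1] * sa + d[, 2] * ca
  (u / ellipse$semi_axes[1])^2 + (v / ellipse$semi_axes[2])^2 <= 1
}

#' Names of the 18 oculomotor biomarkers
#' @return Character vector of length 18.
#' @export
oculomotor_feature_names <- function() {
  c("RangeX", "RangeY", "RatioRange", "VarianceX", "VarianceY",
    "VelocityX", "VelocityY", "Velocity", "EllArea",
    "MeanFix", "VarianceFix", "SkewFix", "KurtFix",
    "MeanSac", "VarianceSac", "SkewSac", "KurtSac", "Fix2SacNratio")
}

#' Extract the 18 oculomotor biomarkers for one recording
#'
#' Dynamic features are computed over consecutive non-overlapping windows of
#' `window_len` seconds (trailing partial window dropped) and averaged:
#' per-window range (max - min) of each gaze component, per-window standard
#' deviation (reported under the conventional "Variance" names), and the
#' area of the per-window 95% confidence ellipse (`EllArea`; mean full
#' horizontal/vertical axes are attached as attributes `EllH`/`EllV`).
#' Velocities are mean absolute component velocities and the mean Euclidean
#' speed over consecutive valid samples of the whole task. Duration
#' statistics (mean, SD, skewness, kurtosis with the non-excess convention,
#' normal = 3) summarise fixation and saccade durations from `events`.
#' `RatioRange = RangeX / RangeY` and `Fix2SacNratio` = number of fixations
#' over number of saccades in the whole task; undefined ratios (zero
#' denominator) are returned as `NA`, never as infinities.
#'
#' @param gaze A `gaze_recording` of at least 10 s.
#' @param events A `gaze_event_sequence` from [detect_events_ivt()].
#' @param window_len Window length in seconds (default 1).
#' @param coverage Ellipse coverage (default 0.95).
#' @return Named numeric vector of length 18 (class
#'   `oculomotor_features`) with attributes `n_fixations`, `n_saccades`,
#'   `EllH`, `EllV`.
#' @export
extract_feature_vector <- function(gaze, events, window_len = 1,
                                   coverage = 0.95) {
  if (nrow(events) == 0) stopf("event sequence is empty")
  n <- length(gaze$gx)
  dur <- n / gaze$rate
  if (dur < 10) stopf("recording must be at least 10 s")

  t <- gaze$t
  ok <- gaze$valid
  n_win <- floor(dur / window_len)
  w <- floor(t / window_len) + 1

  rx <- ry <- sx <- sy <- area <- ah <- av <- rep(NA_real_, n_win)
  for (k in seq_len(n_win)) {
    i <- which(ok & w == k)
    if (length(i) < 2) next
    rx[k] <- max(gaze$gx[i]) - min(gaze$gx[i])
    ry[k] <- max(gaze$gy[i]) - min(gaze$gy[i])
    sx[k] <- sd(gaze$gx[i])
    sy[k] <- sd(gaze$gy[i])
    if (length(i) >= 3) {
      ell <- tryCatch(confidence_ellipse(cbind(gaze$gx[i], gaze$gy[i]),
                                         coverage),
                      error = function(e) NULL)
      if (is.null(ell)) {
        area[k] <- 0; ah[k] <- 0; av[k] <- 0
      } else {
        area[k] <- ell$area
        ah[k] <- 2 * ell$semi_axes[1]
        av[k] <- 2 * ell$semi_axes[2]
      }
    }
  }

  # velocities over consecutive valid sample pairs
  pair <- ok[-n] & ok[-1]
  vx <- (gaze$gx[-1] - gaze$gx[-n])[pair] * gaze$rate
  vy <- (gaze$gy[-1] - gaze$gy[-n])[pair] * gaze$rate

  fix <- events$duration_ms[events$kind == "fixation"]
  sac <- events$duration_ms[events$kind == "saccade"]
  dur_stats <- function(d) {
    if (length(d) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(d), if (length(d) > 1) sd(d) else 0,
      moment_skewness(d), moment_kurtosis(d))
  }
  fs <- dur_stats(fix)
  ss <- dur_stats(sac)

  range_x <- mean(rx, na.rm = TRUE)
  range_y <- mean(ry, na.rm = TRUE)
  out <- c(
    RangeX = range_x,
    RangeY = range_y,
    RatioRange = if (isTRUE(range_y > 0)) range_x / range_y else NA_real_,
    VarianceX = mean(sx, na.rm = TRUE),
    VarianceY = mean(sy, na.rm = TRUE),
    VelocityX = mean(abs(vx)),
    VelocityY = mean(abs(vy)),
    Velocity = mean(sqrt(vx^2 + vy^2)),
    EllArea = mean(area, na.rm = TRUE),
    MeanFix = fs[1], VarianceFix = fs[2], SkewFix = fs[3], KurtFix = fs[4],
    MeanSac = ss[1], VarianceSac = ss[2], SkewSac = ss[3], KurtSac = ss[4],
    Fix2SacNratio = if (length(sac) > 0) length(fix) / length(sac)
                    else NA_real_
  )
  structure(out, class = "oculomotor_features",
            n_fixations = length(fix), n_saccades = length(sac),
            EllH = mean(ah, na.rm = TRUE), EllV = mean(av, na.rm = TRUE))
}

#' Extract the oculomotor feature table for a cohort
#'
#' @param gaze_list Named list of `gaze_recording`s.
#' @param velocity_threshold,min_fixation,max_gap I-VT parameters, see
#'   [detect_events_ivt()].
#' @param window_len Window length for the dynamic features.
#' @return Data frame: one row per subject, `subject_id`, the 18 biomarkers,
#'   and `n_fixations`/`n_saccades` counts.
#' @export
extract_gaze_features <- function(gaze_list, velocity_threshold = 30,
                                  min_fixation = 60, max_gap = 75,
                                  window_len = 1) {
  rows <- lapply(gaze_list, function(g) {
    ev <- detect_events_ivt(g, velocity_threshold, min_fixation, max_gap)
    fv <- extract_feature_vector(g, ev, window_len)
    cbind(data.frame(subject_id = g$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv))),
          data.frame(n_fixations = attr(fv, "n_fixations"),
                     n_saccades = attr(fv, "n_saccades")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
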