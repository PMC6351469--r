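## Centre-of-pressure processing: resampling of irregularly sampled
## force-platform recordings to a uniform grid, local window descriptors,
## a two-component Gaussian-mixture quiet/unquiet classifier, and the
## 0-100 postural score.

#' Construct a raw centre-of-pressure recording
#'
#' @param subject_id Identifier.
#' @param condition `"EO"` or `"EC"`.
#' @param t Strictly increasing timestamps (s), length >= 2.
#' @param x,y CoP coordinates (cm), same length as `t`.
#' @return A `cop_recording` object.
#' @export
cop_recording <- function(subject_id, condition, t, x, y) {
  if (length(t) < 2 || length(x) != length(t) || length(y) != length(t))
    stopf("t, x, y must have equal length >= 2")
  if (any(diff(t) <= 0))
    stopf("timestamps must be strictly increasing")
  structure(list(subject_id = as.character(subject_id),
                 condition = match.arg(condition, c("EO", "EC")),
                 t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
            class = "cop_recording")
}

#' Sliding-window average resampling with interpolation fallback (SWARII)
#'
#' Resamples an irregularly sampled recording onto a uniform grid spanning
#' `[min(t), max(t)]`. Each grid value is the mean of the raw samples within
#' a centred window of width `window`; where the window is empty the value
#' is linearly interpolated between the nearest raw samples before and after
#' the grid point. Both operations are convex combinations of raw values, so
#' the output is bounded by the raw data.
#'
#' @param raw A `cop_recording` (or any list with `t`, `x`, `y`).
#' @param rate Target rate in Hz (default 25).
#' @param window Averaging-window width in seconds (default one target
#'   period, `1/rate`).
#' @return A `uniform_cop_signal`: list with `rate`, `t0`, `t`, `x`, `y`.
#' @export
swarii_resample <- function(raw, rate = 25, window = 1 / rate) {
  if (length(raw$t) < 2) stopf("need at least 2 raw samples")
  if (rate <= 0 || window <= 0) stopf("rate and window must be positive")
  if (any(diff(raw$t) <= 0)) stopf("timestamps must be strictly increasing")
  t <- raw$t
  t0 <- t[1]
  grid <- t0 + seq(0, floor((t[length(t)] - t0) * rate)) / rate

  resample1 <- function(v) {
    lo <- findInterval(grid - window / 2, t, left.open = TRUE) + 1
    hi <- findInterval(grid + window / 2, t)
    out <- numeric(length(grid))
    empty <- lo > hi
    if (any(!empty)) {
      cs <- c(0, cumsum(v))
      out[!empty] <- (cs[hi[!empty] + 1] - cs[lo[!empty]]) /
        (hi[!empty] - lo[!empty] + 1)
    }
    if (any(empty))
      out[empty] <- approx(t, v, xout = grid[empty], rule = 2)$y
    out
  }
  structure(list(rate = rate, t0 = t0, t = grid,
                 x = resample1(raw$x), y = resample1(raw$y),
                 subject_id = raw$subject_id, condition = raw$condition),
            class = "uniform_cop_signal")
}

#' Local window descriptors of a uniform CoP signal
#'
#' Only the final `keep_last` seconds are analysed (the preceding portion is
#' treated as acclimatisation), in consecutive non-overlapping windows of
#' `window_len` seconds. Each window is summarised by its path length (cm),
#' its positional standard deviation (cm, pooled over x and y) and its mean
#' speed (cm/s).
#'
#' @param signal A `uniform_cop_signal`.
#' @param window_len Window length in seconds (default 1).
#' @param keep_last Scored epoch length in seconds (default 25).
#' @return A `window_descriptor_set`: list with `window_len`, `start_times`,
#'   and a numeric matrix `desc` with columns `path_len`, `pos_sd`,
#'   `mean_speed`.
#' @export
window_descriptors <- function(signal, window_len = 1, keep_last = 25) {
  if (keep_last < window_len) stopf("keep_last must be >= window_len")
  t <- signal$t
  dur <- t[length(t)] - t[1]
  if (dur < keep_last)
    stopf("signal duration %.2f s is shorter than keep_last = %g s",
          dur, keep_last)
  t_start <- t[length(t)] - keep_last
  keep <- t >= t_start - 1e-9
  t <- t[keep]; x <- signal$x[keep]; y <- signal$y[keep]
  n_win <- floor(keep_last / window_len)
  w <- floor((t - t_start) / window_len) + 1
  ok <- w >= 1 & w <= n_win

  desc <- matrix(NA_real_, n_win, 3,
                 dimnames = list(NULL, c("path_len", "pos_sd", "mean_speed")))
  for (k in seq_len(n_win)) {
    i <- which(ok & w == k)
    if (length(i) < 2) { desc[k, ] <- 0; next }
    path <- sum(sqrt(diff(x[i])^2 + diff(y[i])^2))
    psd <- sqrt(var(x[i]) + var(y[i]))
    desc[k, ] <- c(path, psd, path / window_len)
  }
  structure(list(window_len = window_len,
                 start_times = t_start + (seq_len(n_win) - 1) * window_len,
                 desc = desc, subject_id = signal$subject_id,
                 condition = signal$condition),
            class = "window_descriptor_set")
}

#' Fit the two-component quiet/unquiet Gaussian mixture
#'
#' Expectation-maximisation on window descriptors pooled across the whole
#' cohort (both groups and both conditions), with k-means initialisation and
#' diagonal covariances. Descriptors are standardised internally; the
#' "unquiet" component is the one whose mean has the larger Euclidean norm
#' in the original descriptor units (high-sway windows score larger on every
#' descriptor). A zero-variance descriptor pool yields a degenerate model
#' under which every window is quiet.
#'
#' @param desc Numeric matrix of pooled descriptors (rows = windows), or a
#'   `window_descriptor_set`, or a list of them.
#' @param seed Integer seed (k-means initialisation).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A `quiet_unquiet_model`: mixing weights, component means and
#'   variances (standardised space), the standardisation, the unquiet
#'   component index, and convergence diagnostics.
#' @export
fit_quiet_unquiet_model <- function(desc, seed = 1, max_iter = 200,
                                    tol = 1e-8) {
  X <- pool_descriptors(desc)
  if (nrow(X) < 20) stopf("need at least 20 pooled windows, got %d", nrow(X))

  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  degenerate <- all(scale_ <= 1e-12)
  scale_[scale_ <= 1e-12] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")

  if (degenerate) {
    warning("descriptor pool has zero variance; degenerate model, all quiet")
    return(structure(list(weights = c(1, 0), means = rbind(0, 0)[, rep(1, ncol(X)), drop = FALSE] * 0,
                          vars = matrix(1, 2, ncol(X)), center = center,
                          scale = scale_, unquiet = 2L, degenerate = TRUE,
                          converged = TRUE, n_iter = 0L,
                          loglik = NA_real_),
                     class = "quiet_unquiet_model"))
  }

  set.seed(seed)
  km <- suppressWarnings(kmeans(Z, centers = 2, nstart = 5, iter.max = 50))
  mu <- km$centers
  va <- matrix(NA_real_, 2, ncol(Z))
  for (k in 1:2) {
    zk <- Z[km$cluster == k, , drop = FALSE]
    va[k, ] <- if (nrow(zk) > 1) apply(zk, 2, var) else rep(1, ncol(Z))
  }
  va <- pmax(va, 1e-6)
  w <- tabulate(km$cluster, 2) / nrow(Z)
  w <- pmax(w, 1e-6); w <- w / sum(w)

  loglik_prev <- -Inf; converged <- FALSE; it <- 0
  log_dens <- function(mu, va, w) {
    sapply(1:2, function(k) {
      log(w[k]) + rowSums(dnorm(Z, rep(mu[k, ], each = nrow(Z)),
                                rep(sqrt(va[k, ]), each = nrow(Z)),
                                log = TRUE))
    })
  }
  for (it in seq_len(max_iter)) {
    ld <- log_dens(mu, va, w)
    m <- pmax(ld[, 1], ld[, 2])
    ll <- sum(m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
    resp <- exp(ld - m)
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    w <- nk / nrow(Z)
    for (k in 1:2) {
      mu[k, ] <- colSums(resp[, k] * Z) / nk[k]
      va[k, ] <- pmax(colSums(resp[, k] * sweep(Z, 2, mu[k, ])^2) / nk[k],
                      1e-6)
    }
    if (is.finite(loglik_prev) && abs(ll - loglik_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    loglik_prev <- ll
  }
  if (!converged)
    warning(sprintf(
      "EM did not converge in %d iterations (last loglik %.6g)", max_iter, ll))

  mu_orig <- sweep(sweep(mu, 2, scale_, "*"), 2, center, "+")
  unquiet <- which.max(sqrt(rowSums(mu_orig^2)))
  structure(list(weights = w, means = mu, vars = va, center = center,
                 scale = scale_, unquiet = as.integer(unquiet),
                 degenerate = FALSE, converged = converged,
                 n_iter = it, loglik = ll),
            class = "quiet_unquiet_model")
}

# Accept a matrix, a window_descriptor_set, or a list of them.
pool_descriptors <- function(desc) {
  if (is.matrix(desc)) return(desc)
  if (inherits(desc, "window_descriptor_set")) return(desc$desc)
  if (is.list(desc)) return(do.call(rbind, lapply(desc, pool_descriptors)))
  stopf("cannot interpret descriptors of class %s", class(desc)[1])
}

#' Label windows as quiet or unquiet
#'
#' @param model A `quiet_unquiet_model`.
#' @param desc Descriptor matrix or `window_descriptor_set`.
#' @return Logical vector: `TRUE` where the window's maximum posterior
#'   responsibility belongs to the unquiet component.
#' @export
classify_windows <- function(model, desc) {
  X <- pool_descriptors(desc)
  if (model$degenerate) return(rep(FALSE, nrow(X)))
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  ld <- sapply(1:2, function(k) {
    log(model$weights[k]) +
      rowSums(dnorm(Z, rep(model$means[k, ], each = nrow(Z)),
                    rep(sqrt(model$vars[k, ]), each = nrow(Z)), log = TRUE))
  })
  if (nrow(X) == 1) ld <- matrix(ld, nrow = 1)
  max.col(ld, ties.method = "first") == model$unquiet
}

#' Compute the 0-100 postural score for one subject
#'
#' Windows of each condition are labelled by the cohort-level mixture model;
#' with unquiet fractions `f_EO` and `f_EC` the score is
#' `100 * ((1 - f_EO) + (1 - f_EC)) / 2` (0 = bad, 100 = excellent).
#'
#' @param model A `quiet_unquiet_model`.
#' @param eo,ec `window_descriptor_set`s for the eyes-open and eyes-closed
#'   conditions.
#' @param subject_id Identifier (defaults to the one carried by `eo`).
#' @return A `postural_score`: one-row data frame with `subject_id`,
#'   `score`, `f_EO`, `f_EC`.
#' @export
compute_postural_score <- function(model, eo, ec,
                                   subject_id = eo$subject_id) {
  if (is.null(eo) || is.null(ec))
    stopf("both EO and EC descriptor sets are required")
  f_eo <- mean(classify_windows(model, eo))
  f_ec <- mean(classify_windows(model, ec))
  structure(data.frame(subject_id = subject_id %||% NA_character_,
                       score = 100 * ((1 - f_eo) + (1 - f_ec)) / 2,
                       f_EO = f_eo, f_EC = f_ec,
                       stringsAsFactors = FALSE),
            class = c("postural_score", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a cohort of centre-of-pressure recordings
#'
#' Convenience wrapper for the full postural pipeline: resample every
#' recording, compute window descriptors, fit one quiet/unquiet mixture on
#' the windows pooled across the whole cohort, then score every subject that
#' has both conditions.
#'
#' @param cop Named list of `cop_recording`s (both conditions per subject).
#' @param seed Seed for the mixture fit.
#' @param rate,swarii_window Resampling parameters.
#' @param window_len,keep_last Windowing parameters.
#' @return List with `scores` (data frame: subject_id, score, f_EO, f_EC)
#'   and `model` (the fitted mixture). Subjects missing a condition are
#'   dropped with a warning.
#' @export
score_cohort <- function(cop, seed = 1, rate = 25, swarii_window = 1 / rate,
                         window_len = 1, keep_last = 25) {
  desc <- lapply(cop, function(r)
    window_descriptors(swarii_resample(r, rate, swarii_window),
                       window_len, keep_last))
  subjects <- unique(vapply(desc, function(d) d$subject_id, ""))
  model <- fit_quiet_unquiet_model(desc, seed = seed)
  rows <- list()
  for (s in subjects) {
    mine <- Filter(function(d) identical(d$subject_id, s), desc)
    conds <- vapply(mine, function(d) d$condition, "")
    if (!all(c("EO", "EC") %in% conds)) {
      warning(sprintf("subject %s lacks a condition; dropped from scoring", s))
      next
    }
    rows[[s]] <- compute_postural_score(model,
                                        mine[[match("EO", conds)]],
                                        mine[[match("EC", conds)]],
                                        subject_id = s)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(scores = scores, model = model)
}
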