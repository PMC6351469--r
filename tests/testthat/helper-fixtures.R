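# Shared fixtures, all built in code at test time.

# Planted importance-recovery dataset: 4 equally informative features whose
# columns are orthogonalised (designed experiment, each carrying exactly its
# planted share of signal) plus 14 pure-noise features.
make_planted_importance_data <- function(seed, n = 40, p = 18,
                                         n_signal = 4, beta = 8,
                                         noise_sd = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("F", seq_len(p))))
  B <- scale(X[, seq_len(n_signal)])
  Q <- qr.Q(qr(cbind(1, B)))[, 1 + seq_len(n_signal)] * sqrt(n - 1)
  X[, seq_len(n_signal)] <- Q
  signs <- rep_len(c(1, -1), n_signal)
  y <- drop(Q %*% (beta * signs)) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = paste0("F", seq_len(n_signal)))
}

# Two well-separated descriptor clouds (>6 pooled SDs apart) for the
# quiet/unquiet mixture, mixing 0.7 / 0.3.
make_separated_descriptors <- function(seed, n = 600, w_unquiet = 0.3) {
  set.seed(seed)
  n2 <- round(n * w_unquiet)
  n1 <- n - n2
  quiet <- cbind(rnorm(n1, 1, 0.3), rnorm(n1, 0.1, 0.03), rnorm(n1, 1, 0.3))
  unquiet <- cbind(rnorm(n2, 8, 0.3), rnorm(n2, 0.8, 0.03), rnorm(n2, 8, 0.3))
  X <- rbind(quiet, unquiet)
  colnames(X) <- c("path_len", "pos_sd", "mean_speed")
  list(desc = X, labels = rep(c(FALSE, TRUE), c(n1, n2)),
       weights = c(1 - w_unquiet, w_unquiet))
}

# Descriptor set stub with a given subject/condition, built from a matrix.
as_descriptor_set <- function(desc, subject_id = "S", condition = "EO") {
  structure(list(window_len = 1,
                 start_times = seq_len(nrow(desc)) - 1,
                 desc = desc, subject_id = subject_id,
                 condition = condition),
            class = "window_descriptor_set")
}

# Small coupled cohort scored end-to-end; returns the patient modelling table.
make_patient_table <- function(seed, n_patients = 10) {
  co <- generate_cohort(cohort_config(n_patients = n_patients,
                                      n_controls = 1, seed = seed))
  sc <- score_cohort(co$cop, seed = seed)
  fe <- extract_gaze_features(co$gaze)
  m <- merge(merge(fe, sc$scores, by = "subject_id"),
             co$truth[, c("subject_id", "group")], by = "subject_id")
  pat <- m[m$group == "patient", ]
  X <- as.matrix(pat[, oculomotor_feature_names()])
  rownames(X) <- pat$subject_id
  list(X = X, y = pat$score, subject_id = pat$subject_id, truth = co$truth)
}

# Exact two-sided rank-sum p-value by full enumeration of all pooled-rank
# assignments (independent oracle; assumes no ties).
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(i) sum(r[i]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}
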