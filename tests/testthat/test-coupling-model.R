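# Random-forest importance (Imp = mean(d)/sd(d)), selection, LOO prediction.

test_that("importance_from_d matches hand arithmetic and conventions", {
  expect_equal(importance_from_d(c(0.2, 0.4, 0.3)), 3.0)
  expect_equal(importance_from_d(c(0.3, 0.3, 0.3)), 0)   # sd = 0
  expect_equal(importance_from_d(0.5), 0)                # single tree
  expect_equal(importance_from_d(numeric()), 0)
})

test_that("quartile-threshold selection uses the interpolated lower quartile", {
  imp <- structure(list(imp_runs = rbind(
    A = c(0.3, 0.3, 0.3, 0.3, 0.3),
    B = c(0.0, 0.05, 0.3, 0.3, 0.3),
    C = c(-0.2, 0, -0.1, 0, -0.3)),
    quartile25 = NULL, threshold = 0.1),
    class = "importance_result")
  expect_equal(unname(quantile(c(0.0, 0.05, 0.3, 0.3, 0.3), 0.25, type = 7)),
               0.05)
  expect_equal(select_features(imp, 0.1), "A")
  expect_equal(select_features(imp, 0.01), c("A", "B"))
})

test_that("forest fit and importance are deterministic and validate input", {
  d <- make_planted_importance_data(1)
  cfg <- forest_config(n_trees = 100, seed = 9)
  i1 <- oob_permutation_importance(d$X, d$y, cfg)
  i2 <- oob_permutation_importance(d$X, d$y, cfg)
  expect_identical(i1, i2)
  expect_equal(dim(i1$imp_runs), c(18, 5))
  expect_equal(i1$seeds, 9:13)

  expect_error(oob_permutation_importance(d$X, rep(1, 40), cfg),
               "degenerate target")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(oob_permutation_importance(Xna, d$y, cfg), "imputed")
  expect_error(oob_permutation_importance(d$X[1:4, ], d$y[1:4], cfg),
               "at least 5")
})

test_that("a constant feature gets zero importance by the 0/0 convention", {
  d <- make_planted_importance_data(2)
  X <- d$X
  X[, "F18"] <- 7.7
  imp <- oob_permutation_importance(X, d$y,
                                    forest_config(n_trees = 200, seed = 1))
  expect_equal(unname(imp$imp_runs["F18", ]), rep(0, 5))
})

test_that("planted informative features rank above noise features", {
  d <- make_planted_importance_data(3)
  imp <- oob_permutation_importance(d$X, d$y,
                                    forest_config(n_trees = 300, seed = 5))
  sel <- select_features(imp)
  expect_true(all(d$informative %in% sel))
  expect_gt(median(imp$imp_runs[d$informative, ]),
            median(imp$imp_runs[setdiff(rownames(imp$imp_runs),
                                        d$informative), ]))
})

test_that("prediction metrics follow the normalised-RMSE worked example", {
  m <- prediction_metrics(c(20, 40), c(30, 30), c("a", "b"))
  expect_equal(m$rmse_norm, 0.10)
  expect_equal(m$rmse_norm_excl, 0.10)   # tie -> first excluded
  expect_equal(m$excluded_subject, "a")
  expect_lte(m$rmse_norm_excl, m$rmse_norm)
})

test_that("LOO prediction: constant target, leakage, determinism, subsets", {
  d <- make_planted_importance_data(4, n = 12)
  cfg <- forest_config(n_trees = 60, seed = 2)

  pc <- loo_predict(d$X, rep(50, 12), cfg)
  expect_equal(pc$table$predicted, rep(50, 12))
  expect_equal(pc$rmse_norm, 0)

  p1 <- loo_predict(d$X, d$y, cfg)
  p2 <- loo_predict(d$X, d$y, cfg)
  expect_identical(p1, p2)
  expect_lte(p1$rmse_norm_excl, p1$rmse_norm)

  # altering only the held-out subject's y leaves its prediction unchanged
  y_alt <- d$y
  y_alt[3] <- y_alt[3] + 1000
  p3 <- loo_predict(d$X, y_alt, cfg)
  expect_equal(p3$table$predicted[3], p1$table$predicted[3])

  expect_error(loo_predict(d$X, d$y, cfg, features = "NotAFeature"),
               "unknown feature")
  psub <- loo_predict(d$X, d$y, cfg, features = d$informative)
  expect_equal(nrow(psub$table), 12)
  expect_error(loo_predict(d$X[1:2, ], d$y[1:2], cfg), "at least 3")
})

test_that("selected-subset refit does not worsen coupled-cohort prediction", {
  res <- t(vapply(1:5, function(s) {
    tab <- make_patient_table(3000 + s)
    cfg <- forest_config(n_trees = 300, seed = 3000 + s)
    imp <- oob_permutation_importance(tab$X, tab$y, cfg)
    sel <- select_features(imp)
    p_all <- loo_predict(tab$X, tab$y, cfg)
    p_sel <- if (length(sel) >= 1)
      loo_predict(tab$X, tab$y, cfg, features = sel) else p_all
    c(all = p_all$rmse_norm, sel = p_sel$rmse_norm)
  }, c(all = 0, sel = 0)))
  expect_lte(median(res[, "sel"]), median(res[, "all"]))
})
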