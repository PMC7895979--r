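test_that("initializations reproduce the condition-statistic recipe", {
  d <- tiny_design()
  tr <- sim_trials("nonlinear", ref_params("nonlinear"), d, seed = 2)
  expect_equal(as.numeric(init_params("null", tr, d)), c(0, 1))

  # hand-constructed toy table: noise {-1, 1}, min SNR {0, 2}, max SNR {2, 4}
  toy <- data.frame(
    snr_db = c(NA, NA, -13, -13, -5, -5),
    activity = c(-1, 1, 0, 2, 2, 4))
  i3 <- init_params("bifurcation", toy, d)
  expect_equal(i3[["mu_noise"]], 0)
  expect_equal(i3[["sigma"]], sqrt(2))           # sample SD, n-1
  expect_equal(i3[["L_high"]], 3 - 1)            # mean(max) - mean(min)
  expect_equal(i3[["step"]], 1 - 0)              # mean(min) - mean(noise)
  expect_equal(i3[["threshsnr"]], -9)            # midpoint of -13 and -5
  expect_equal(i3[["k"]], (3 - 1) / 8)

  i2 <- init_params("nonlinear", toy, d)
  expect_equal(i2[["threshsnr"]], -9)
  expect_equal(i2[["mu_maxsnr"]], 3)
  expect_equal(i2[["L"]], 6)                     # twice mu_maxsnr

  expect_error(init_params("bifurcation",
                           toy[!is.na(toy$snr_db), ], d),
               "noise-only")
})

test_that("null-model ML fit matches the closed-form Gaussian MLE", {
  d <- tiny_design()
  set.seed(7)
  x <- rnorm(300, -0.7, 1.9)
  tr <- data.frame(snr_db = rep(design_conditions(d), length.out = 300),
                   activity = x)
  f <- fit_trial_model(tr, "null", d)
  expect_lt(abs(coef(f)[["mu"]] - mean(x)), 1e-4)
  expect_lt(abs(coef(f)[["sigma"]] - sqrt(mean((x - mean(x))^2))), 1e-4)
  expect_true(f$converged)
  expect_equal(as.numeric(logLik(f)),
               sum(dnorm(x, coef(f)[["mu"]], coef(f)[["sigma"]],
                         log = TRUE)), tolerance = 1e-9)
})

test_that("the optimizer never returns less than the initialization likelihood", {
  d <- tiny_design(trials_per_level = 15L)
  set.seed(11)
  for (i in 1:5) {
    for (model in c("null", "nonlinear", "bifurcation")) {
      gen <- sample(c("nonlinear", "bifurcation"), 1)
      p <- draw_population_params(default_hyper(gen), d, 1)[[1]]
      tr <- sim_trials(gen, p, d, seed = 100 + i)
      f <- fit_trial_model(tr, model, d)
      expect_gte(f$logLik, f$init_loglik)
    }
  }
})

test_that("bifurcation threshold is recovered at experimental scale", {
  d <- tiny_design(trials_per_level = 160L, n_blocks = 20L)
  p <- ref_params("bifurcation")
  tr <- sim_trials("bifurcation", p, d, seed = 42)
  f <- fit_trial_model(tr, "bifurcation", d)
  expect_lt(abs(coef(f)[["threshsnr"]] - p[["threshsnr"]]), 1)
  expect_lt(abs(coef(f)[["mu_noise"]] - p[["mu_noise"]]), 0.15)
})

test_that("cross-validation respects blocks and matches a held-out dnorm oracle", {
  d <- tiny_design(trials_per_level = 30L, n_blocks = 6L)
  tr <- sim_trials("null", ref_params("null"), d, seed = 9)
  cv <- crossval_loglik(tr, "null", d, folds = 5L, seed = 123)
  # every block in exactly one fold
  fa <- cv$fold_assignment
  expect_setequal(names(fa), as.character(sort(unique(tr$block))))
  expect_true(all(table(fa) >= 1))
  # held-out sums recomputed independently from the per-fold fits
  for (i in seq_along(cv$fold_logliks)) {
    test_blocks <- names(fa)[fa == sort(unique(fa))[i]]
    idx <- tr$block %in% as.integer(test_blocks)
    p <- coef(cv$fits[[i]])
    oracle <- sum(dnorm(tr$activity[idx], p[["mu"]], p[["sigma"]],
                        log = TRUE))
    expect_equal(cv$fold_logliks[i], oracle, tolerance = 1e-9)
  }
  # determinism
  cv2 <- crossval_loglik(tr, "null", d, folds = 5L, seed = 123)
  expect_identical(cv$fold_logliks, cv2$fold_logliks)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(crossval_loglik(tr, "null", d, folds = 10L, seed = 1),
               "at least 10 blocks")
})

test_that("window sweep produces one cell per participant-window-model and isolates failures", {
  d <- tiny_design(trials_per_level = 20L)
  sc <- switch_scenario(design = d, windows = c(0, 30), switch_ms = 30)
  tab <- generate_dataset(sc, seed = 4)
  sw <- fit_window_sweep(tab, d, seed = 1)
  expect_equal(nrow(sw$table), 2 * 2 * 3)
  expect_false(any(sw$table$flagged))
  expect_s3_class(sw$fits[["p01"]][["30"]][["bifurcation"]], "model_params")

  # corrupt one participant's second window: those cells flagged, rest intact
  tab2 <- tab
  tab2$activity_w30[tab2$participant == "p01"] <- NaN
  sw2 <- fit_window_sweep(tab2, d, seed = 1)
  bad <- sw2$table$participant == "p01" & sw2$table$window_start_ms == 30
  expect_true(all(sw2$table$flagged[bad]))
  expect_false(any(sw2$table$flagged[!bad]))
  expect_true(all(is.finite(sw2$table$mean_cv_loglik[!bad])))
})

test_that("cross-validation does not systematically favor the mixture on unimodal data", {
  d <- tiny_design(trials_per_level = 60L, n_blocks = 10L)
  hyper <- population_hyper("nonlinear",
    means = c(k = 1.2, threshsnr = -9, mu_maxsnr = 2, L = 3,
              slope_sigma = 0, intercept_sigma = 1),
    sds = c(k = 0.2, threshsnr = 1, mu_maxsnr = 0.3, L = 0.5,
            slope_sigma = 0, intercept_sigma = 0.1))
  pars <- draw_population_params(hyper, d, 30, seed = 21)
  ctl <- list(reltol = 1e-8, restarts = 0L)
  wins3 <- 0L
  for (i in seq_along(pars)) {
    tr <- sim_trials("nonlinear", pars[[i]], d, seed = 300 + i)
    c2 <- crossval_loglik(tr, "nonlinear", d, seed = i, control = ctl)
    c3 <- crossval_loglik(tr, "bifurcation", d, seed = i, control = ctl)
    wins3 <- wins3 + (c3$mean_cv_loglik > c2$mean_cv_loglik)
  }
  # one-sided sign test: no evidence that the 7-parameter mixture beats the
  # 6-parameter unimodal model on its own data once cross-validated
  p <- pbinom(wins3 - 1, length(pars), 0.5, lower.tail = FALSE)
  expect_gt(p, 0.05)
})
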