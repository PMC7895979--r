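test_that("model means match their closed forms, including floors and asymptotes", {
  d <- tiny_design()
  p1 <- linear_params(1, 2, 0, 0, 1)
  expect_equal(mean_activity("linear", p1, -7, d), 0)     # 1*(-7+5)+2
  expect_equal(mean_activity("linear", p1, -13, d), 0)    # raw -6, floored
  expect_equal(mean_activity("linear", p1, NA, d), 0)     # noise -> mu_noise

  p2 <- nonlinear_params(1, -9, 2, 4, 0, 1)
  expect_equal(mean_activity("nonlinear", p2, -9, d),
               4 / 2 - 4 / (1 + exp(-4)) + 2, tolerance = 1e-12)
  expect_equal(mean_activity("nonlinear", p2, -5, d), 2)  # anchored
  expect_equal(mean_activity("nonlinear", p2, NA, d),
               -4 / (1 + exp(-4)) + 2, tolerance = 1e-12) # snr -> -Inf

  p3 <- ref_params("bifurcation")
  expect_equal(mean_activity("bifurcation", p3, -9, d), 3 / 2 + 0.5)
  expect_equal(mean_activity("bifurcation", p3, NA, d), 0)

  expect_error(mean_activity("nonlinear", p2, -8, d), "outside the design")
  expect_error(mean_activity("banana", p2, -9, d), "unknown model")
})

test_that("condition SDs follow the mean-to-SD rule and reject non-positive values", {
  d <- tiny_design()
  expect_equal(sigma_at("linear", linear_params(1, 2, 0, 0, 1), -9, d), 1)
  # nonlinear condition where mu = 2 (the anchor at maxsnr)
  p2 <- nonlinear_params(1, -9, 2, 4, 0.5, 1)
  expect_equal(sigma_at("nonlinear", p2, -5, d), 0.5 * 2 + 1)
  expect_equal(sigma_at("bifurcation", ref_params("bifurcation"),
                        c(-13, NA), d), c(1, 1))
  # steep negative SD slope makes sigma(-13) < 0
  bad <- linear_params(0.5, 2, 0, 3, -0.5)
  expect_error(sigma_at("linear", bad, -13, d), "invalid parameters")
  expect_false(isTRUE(valid_params("linear", bad, d)))
})

test_that("high-state probability is the logistic of SNR, zero for noise, monotone", {
  p3 <- bifurcation_params(1, 1, -9, 0, 0.5, 3, 1)
  expect_equal(high_state_prob(p3, -9), 0.5)
  expect_equal(high_state_prob(p3, -9 + log(3)), 0.75, tolerance = 1e-12)
  expect_equal(high_state_prob(p3, NA), 0)
  grid <- seq(-20, 5, by = 0.5)
  for (k in c(0.3, 1, 4)) {
    pk <- bifurcation_params(1, k, -9, 0, 0.5, 3, 1)
    b <- high_state_prob(pk, grid)
    expect_true(all(diff(b) >= 0))                 # monotone
    expect_true(all(diff(b[grid >= -12 & grid <= -6]) > 0))  # strict near midpoint
  }
})

test_that("trial log-likelihoods are exact and numerically stable", {
  d <- tiny_design()
  expect_equal(trial_loglik("null", null_params(0, 1), -9, 0, d),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # mixture with equal components at the midpoint, against a dnorm oracle
  p3 <- bifurcation_params(1, 20, -9, 0, 2, 1e-12, 1)
  expect_equal(trial_loglik("bifurcation", p3, -9, 1, d),
               log(0.5 * dnorm(1, 0, 1) + 0.5 * dnorm(1, 2, 1)),
               tolerance = 1e-9)
  # extreme observations stay finite (log-sum-exp)
  ll <- trial_loglik("bifurcation", ref_params("bifurcation"),
                     c(-9, -9), c(-1e4, 1e4), d)
  expect_true(all(is.finite(ll)))
  # invalid parameters yield -Inf, not an error
  bad <- bifurcation_params(-1, 1, -9, 0, 0.5, 3, 1)
  expect_identical(trial_loglik("bifurcation", bad, -9, 0, d), -Inf)
})

test_that("degenerate parameter limits collapse onto simpler models", {
  d <- tiny_design()
  set.seed(3)
  snr <- rep(design_conditions(d), 10)
  x <- rnorm(length(snr), 0.3, 1.2)
  # nonlinear with L -> 0: flat mean mu_maxsnr, constant SD
  p2 <- nonlinear_params(1, -9, 0.3, 0, 0.1, 1.2 - 0.1 * 0.3)
  p0 <- null_params(0.3, 1.2)
  expect_equal(trial_loglik("nonlinear", p2, snr, x, d),
               trial_loglik("null", p0, snr, x, d), tolerance = 1e-9)
  # bifurcation with k_high -> 0 and step chosen so mu(snr) = mu_noise:
  # mixture collapses to a single Gaussian for any beta
  mu0 <- 0.3
  p3 <- bifurcation_params(1.2, 1, -9, mu0, mu0 - 2 / 2, 2, 1e-9)
  expect_equal(trial_loglik("bifurcation", p3, snr, x, d),
               trial_loglik("null", null_params(mu0, 1.2), snr, x, d),
               tolerance = 1e-9)
})

test_that("every density integrates to one over the real line", {
  d <- tiny_design()
  for (model in c("null", "linear", "nonlinear", "bifurcation")) {
    pars <- draw_population_params(default_hyper(model), d, 6, seed = 17)
    for (p in pars)
      expect_equal(density_integral(model, p, -9, d), 1, tolerance = 1e-6)
  }
})

test_that("samplers reproduce the model moments", {
  d <- tiny_design()
  expect_identical(sample_trials("null", ref_params("null"), -9, 0, d),
                   numeric(0))
  n <- 1e5
  set.seed(5)
  for (model in c("null", "linear", "nonlinear")) {
    p <- ref_params(model)
    x <- sample_trials(model, p, -7, n, d)
    sig <- sigma_at(model, p, -7, d)
    expect_lt(abs(mean(x) - mean_activity(model, p, -7, d)),
              4 * sig / sqrt(n))
  }
  # bifurcation: closed-form mixture variance, and latent states attached
  p3 <- ref_params("bifurcation")
  x <- sample_trials("bifurcation", p3, -9, n, d)
  expect_true(all(attr(x, "state") %in% c("high", "low")))
  beta <- high_state_prob(p3, -9)
  dmu <- mean_activity("bifurcation", p3, -9, d) - p3[["mu_noise"]]
  v_theory <- p3[["sigma"]]^2 + beta * (1 - beta) * dmu^2
  se_var <- sqrt((mean((x - mean(x))^4) - var(x)^2) / n)
  expect_lt(abs(var(x) - v_theory), 3 * se_var)
  # sample mean matches the state mixture
  expect_lt(abs(mean(x) - (beta * (dmu + p3[["mu_noise"]]) +
                             (1 - beta) * p3[["mu_noise"]])),
            4 * sd(x) / sqrt(n))
})

test_that("linear-model mean is non-decreasing in SNR", {
  d <- tiny_design()
  for (s in 1:5) {
    p <- draw_population_params(default_hyper("linear"), d, 1,
                                seed = s)[[1]]
    if (p[["slope"]] < 0) next
    m <- mean_activity("linear", p, d$snr_levels_db, d)
    expect_true(all(diff(m) >= 0))
  }
})

test_that("parameter vectors round-trip through the text config", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  params <- list(a = ref_params("bifurcation"),
                 nested = list(b = ref_params("nonlinear")))
  write_params(params, path)
  back <- read_params(path)
  expect_equal(back$a, params$a)
  expect_equal(back$nested$b, params$nested$b)
  expect_identical(attr(back$a, "model"), "bifurcation")
  expect_error(bifurcation_params(1, 1, -9, 0, 0.5, 3),
               "argument .* missing|missing")
})
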