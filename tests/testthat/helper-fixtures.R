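# Shared fixtures: a scaled-down design and reference parameter sets used
# across the suite. Everything is generated in code at test time.

tiny_design <- function(trials_per_level = 40L, n_blocks = 5L,
                        n_participants = 2L) {
  design_grid(c(-13, -11, -9, -7, -5), include_noise = TRUE,
              trials_per_level = trials_per_level,
              n_participants = n_participants, n_blocks = n_blocks)
}

ref_params <- function(model) {
  switch(model,
    null = null_params(0.2, 1),
    linear = linear_params(0.25, 2, 0, 0.15, 1),
    nonlinear = nonlinear_params(1.2, -9, 2, 3, 0.15, 1),
    bifurcation = bifurcation_params(1, 1.2, -9, 0, 0.5, 3, 1.2))
}

# one participant's worth of trials from a single generative model
sim_trials <- function(model, params, design,
                       n_per = design$trials_per_level, seed = 1) {
  set.seed(seed)
  snr <- rep(design_conditions(design), each = n_per)
  x <- sample_trials(model, params, snr, design = design)
  out <- data.frame(block = rep(seq_len(design$n_blocks),
                                length.out = length(snr)),
                    snr_db = snr, activity = as.numeric(x))
  attr(out, "state") <- attr(x, "state")
  out
}

# independent quadrature of exp(trial_loglik) over the real line
density_integral <- function(model, params, snr, design) {
  mus <- mean_activity(model, params, c(snr, NA), design)
  sig <- max(sigma_at(model, params, c(snr, NA), design))
  lo <- min(mus) - 15 * sig; hi <- max(mus) + 15 * sig
  stats::integrate(function(x)
    exp(trial_loglik(model, params, rep(snr, length(x)), x, design)),
    lo, hi, abs.tol = 1e-10, subdivisions = 500L)$value
}

# exceedance probabilities of a Dirichlet by 1-D quadrature (independent
# of the package's Monte-Carlo route)
exceedance_quadrature <- function(alpha) {
  vapply(seq_along(alpha), function(k) {
    f <- function(x) {
      others <- vapply(alpha[-k], function(a) stats::pgamma(x, a),
                       numeric(length(x)))
      stats::dgamma(x, alpha[k]) * apply(cbind(others), 1L, prod)
    }
    stats::integrate(f, 0, Inf, abs.tol = 1e-9)$value
  }, 0)
}

# exhaustive pair-counting AUC oracle (ties count one half)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
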