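#' Generative models of single-trial activity
#'
#' Four generative models describe the distribution of a scalar neural
#' activity `x` (arbitrary units) on a single trial as a function of the
#' stimulus SNR (dB; `NA` = noise-only):
#'
#' * **null** — activity is Gaussian with mean `mu` and SD `sigma`,
#'   irrespective of the stimulus.
#' * **linear** (unimodal linear) — Gaussian with mean
#'   `mu(snr) = slope * (snr - maxsnr) + mu_maxsnr`, floored at `mu_noise`
#'   (the evoked mean cannot fall below the no-stimulus mean), and SD
#'   `sigma(snr) = slope_sigma * mu(snr) + intercept_sigma`.
#' * **nonlinear** (unimodal non-linear) — Gaussian with a logistic mean
#'   `mu(snr) = L / (1 + exp(-k (snr - threshsnr))) -
#'    L / (1 + exp(-k (maxsnr - threshsnr))) + mu_maxsnr`
#'   (anchored so that `mu(maxsnr) = mu_maxsnr`) and the same linear
#'   mean-to-SD rule.
#' * **bifurcation** — a two-component Gaussian mixture with shared SD
#'   `sigma`: with probability `beta(snr) = 1 / (1 + exp(-k (snr - threshsnr)))`
#'   the trial is in a *high* state centered on
#'   `mu(snr) = L_high / (1 + exp(-k_high (snr - threshsnr))) + step`,
#'   otherwise in a *low* state centered on `mu_noise`.
#'
#' Noise-only trials use `mu = mu_noise` and `beta = 0` for the linear and
#' bifurcation models, and the `snr -> -Inf` asymptote of the logistic mean
#' for the nonlinear model (which has no separate noise parameter). The null
#' model treats all trials identically.
#'
#' Parameter vectors are plain named numeric vectors; the constructors below
#' build and validate them.
#'
#' @param mu,sigma null-model mean and SD (a.u.).
#' @param slope linear mean slope (a.u./dB).
#' @param mu_maxsnr mean activity at the largest design SNR (a.u.).
#' @param mu_noise mean activity for noise-only trials (a.u.).
#' @param slope_sigma,intercept_sigma coefficients of the linear
#'   mean-to-SD rule (dimensionless; a.u.).
#' @param k logistic steepness (1/dB) of the mean (nonlinear model) or of
#'   the high-state probability (bifurcation model).
#' @param threshsnr logistic midpoint, i.e. the threshold SNR (dB).
#' @param L nonlinear-model logistic amplitude (a.u.).
#' @param step,L_high,k_high baseline, amplitude (a.u.) and steepness (1/dB)
#'   of the bifurcation high-state mean.
#' @return A named numeric vector with attribute `model` and class
#'   `"model_params"`.
#' @name model_params
#' @examples
#' p <- bifurcation_params(sigma = 1, k = 1.2, threshsnr = -9,
#'                         mu_noise = 0, step = 0.5, L_high = 3, k_high = 1.2)
#' d <- default_design()
#' mean_activity("bifurcation", p, -9, d)   # high-state mean at threshold
#' high_state_prob(p, c(-13, -9, -5, NA))
NULL

MODEL_IDS <- c("null", "linear", "nonlinear", "bifurcation")

MODEL_PARAM_NAMES <- list(
  null        = c("mu", "sigma"),
  linear      = c("slope", "mu_maxsnr", "mu_noise", "slope_sigma",
                  "intercept_sigma"),
  nonlinear   = c("k", "threshsnr", "mu_maxsnr", "L", "slope_sigma",
                  "intercept_sigma"),
  bifurcation = c("sigma", "k", "threshsnr", "mu_noise", "step", "L_high",
                  "k_high")
)

#' Normalize a model identifier
#'
#' Accepts the canonical names `"null"`, `"linear"`, `"nonlinear"`,
#' `"bifurcation"` or the integers 0--3.
#' @param model model identifier.
#' @return Canonical model name (character scalar).
#' @export
model_id <- function(model) {
  if (is.numeric(model)) {
    if (!model %in% 0:3) stop("unknown model id: ", model)
    return(MODEL_IDS[model + 1L])
  }
  model <- as.character(model)
  if (!model %in% MODEL_IDS)
    stop("unknown model id: '", model, "' (expected one of ",
         paste(MODEL_IDS, collapse = ", "), " or 0-3)")
  model
}

new_params <- function(model, x) {
  model <- model_id(model)
  want <- MODEL_PARAM_NAMES[[model]]
  if (is.null(names(x))) names(x) <- want
  if (!setequal(names(x), want) || length(x) != length(want))
    stop("parameters for model '", model, "' must be named ",
         paste(want, collapse = ", "))
  structure(as.numeric(x[want]), names = want, model = model,
            class = "model_params")
}

#' @rdname model_params
#' @export
null_params <- function(mu, sigma)
  new_params("null", c(mu = mu, sigma = sigma))

#' @rdname model_params
#' @export
linear_params <- function(slope, mu_maxsnr, mu_noise, slope_sigma,
                          intercept_sigma)
  new_params("linear", c(slope = slope, mu_maxsnr = mu_maxsnr,
                         mu_noise = mu_noise, slope_sigma = slope_sigma,
                         intercept_sigma = intercept_sigma))

#' @rdname model_params
#' @export
nonlinear_params <- function(k, threshsnr, mu_maxsnr, L, slope_sigma,
                             intercept_sigma)
  new_params("nonlinear", c(k = k, threshsnr = threshsnr,
                            mu_maxsnr = mu_maxsnr, L = L,
                            slope_sigma = slope_sigma,
                            intercept_sigma = intercept_sigma))

#' @rdname model_params
#' @export
bifurcation_params <- function(sigma, k, threshsnr, mu_noise, step, L_high,
                               k_high)
  new_params("bifurcation", c(sigma = sigma, k = k, threshsnr = threshsnr,
                              mu_noise = mu_noise, step = step,
                              L_high = L_high, k_high = k_high))

#' @exportS3Method base::print
print.model_params <- function(x, ...) {
  cat("<", attr(x, "model"), " model parameters>\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

as_params <- function(model, params) {
  if (inherits(params, "model_params")) {
    if (model_id(model) != attr(params, "model"))
      stop("parameter vector is for model '", attr(params, "model"),
           "', not '", model_id(model), "'")
    return(params)
  }
  new_params(model, params)
}

#' Validate a parameter vector against a design
#'
#' Checks the structural constraints of each model: `sigma > 0`,
#' `k > 0` / `k_high > 0`, and (for the unimodal models with the
#' mean-dependent SD) that `sigma(snr) > 0` at every condition of the
#' design, including noise-only when present.
#'
#' @inheritParams mean_activity
#' @return `TRUE` if valid, otherwise `FALSE` (invisibly carries a
#'   `"reason"` attribute).
#' @export
valid_params <- function(model, params, design) {
  model <- model_id(model)
  p <- as_params(model, params)
  bad <- function(reason)
    structure(FALSE, reason = reason)
  if (model %in% c("null", "bifurcation") && p[["sigma"]] <= 0)
    return(bad("sigma <= 0"))
  if (model %in% c("nonlinear", "bifurcation") && p[["k"]] <= 0)
    return(bad("k <= 0"))
  if (model == "bifurcation" && p[["k_high"]] <= 0)
    return(bad("k_high <= 0"))
  if (model %in% c("linear", "nonlinear")) {
    snr <- design_conditions(design)
    sig <- model_sigma(model, p, snr, design)
    if (any(sig <= 0)) return(bad("sigma(snr) <= 0 at a design condition"))
  }
  TRUE
}

## Mean of the (high-state, for the bifurcation model) Gaussian component,
## vectorized over snr (NA = noise-only).
model_mu <- function(model, p, snr, design) {
  model <- model_id(model)
  maxsnr <- design$maxsnr_db
  switch(model,
    null = rep(p[["mu"]], length(snr)),
    linear = {
      raw <- p[["slope"]] * (snr - maxsnr) + p[["mu_maxsnr"]]
      out <- pmax(raw, p[["mu_noise"]])
      out[is.na(snr)] <- p[["mu_noise"]]
      out
    },
    nonlinear = {
      anchor <- p[["L"]] * stats::plogis(p[["k"]] * (maxsnr - p[["threshsnr"]]))
      out <- p[["L"]] * stats::plogis(p[["k"]] * (snr - p[["threshsnr"]])) -
        anchor + p[["mu_maxsnr"]]
      out[is.na(snr)] <- -anchor + p[["mu_maxsnr"]]  # snr -> -Inf asymptote
      out
    },
    bifurcation = {
      out <- p[["L_high"]] * stats::plogis(p[["k_high"]] * (snr - p[["threshsnr"]])) +
        p[["step"]]
      out[is.na(snr)] <- p[["step"]]  # snr -> -Inf asymptote of the high mean
      out
    }
  )
}

model_sigma <- function(model, p, snr, design) {
  model <- model_id(model)
  switch(model,
    null = rep(p[["sigma"]], length(snr)),
    bifurcation = rep(p[["sigma"]], length(snr)),
    # unimodal models: SD is a linear function of the condition mean
    p[["slope_sigma"]] * model_mu(model, p, snr, design) +
      p[["intercept_sigma"]]
  )
}

#' Mean activity predicted by a model at a condition
#'
#' For the unimodal models this is the Gaussian mean; for the bifurcation
#' model it is the *high-state* mean (the low-state mean is `mu_noise`).
#' Noise-only conditions (`snr = NA`) return `mu_noise` (linear,
#' bifurcation), the low-SNR asymptote (nonlinear), or `mu` (null).
#'
#' @param model model identifier (see [model_id()]).
#' @param params parameter vector (see [model_params]).
#' @param snr_db numeric vector of conditions in dB; `NA` = noise-only.
#' @param design a [design_grid()] (supplies `maxsnr`).
#' @return Numeric vector of means (a.u.).
#' @export
mean_activity <- function(model, params, snr_db, design) {
  model <- model_id(model)
  p <- as_params(model, params)
  check_condition_in_design(snr_db, design)
  if (model == "bifurcation" && any(is.na(snr_db)))
    { out <- model_mu(model, p, snr_db, design)
      out[is.na(snr_db)] <- p[["mu_noise"]]
      return(out) }
  model_mu(model, p, snr_db, design)
}

#' Condition-specific standard deviation of a model
#'
#' The unimodal models tie the SD linearly to the condition mean
#' (`sigma(snr) = slope_sigma * mu(snr) + intercept_sigma`); the null and
#' bifurcation models use a single shared `sigma`.
#'
#' @inheritParams mean_activity
#' @return Numeric vector of SDs. Raises an error if any computed SD is
#'   non-positive (invalid parameters for the design).
#' @export
sigma_at <- function(model, params, snr_db, design) {
  model <- model_id(model)
  p <- as_params(model, params)
  check_condition_in_design(snr_db, design)
  sig <- model_sigma(model, p, snr_db, design)
  if (any(sig <= 0))
    stop("invalid parameters: sigma(snr) <= 0 at condition ",
         paste(condition_token(snr_db[sig <= 0]), collapse = ", "))
  sig
}

#' High-state probability of the bifurcation model
#'
#' `beta(snr) = 1 / (1 + exp(-k (snr - threshsnr)))`; noise-only trials
#' have `beta = 0` (the `snr -> -Inf` limit).
#'
#' @param params bifurcation parameter vector.
#' @param snr_db numeric vector of conditions (dB; `NA` = noise-only).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
high_state_prob <- function(params, snr_db) {
  p <- as_params("bifurcation", params)
  out <- stats::plogis(p[["k"]] * (snr_db - p[["threshsnr"]]))
  out[is.na(snr_db)] <- 0
  out
}

#' Per-trial log-likelihood under a model
#'
#' Exact log density of the observed activity under the model, vectorized
#' over trials. The bifurcation mixture is evaluated with log-sum-exp for
#' numerical stability. If the parameter vector is invalid for the design
#' (any `sigma <= 0`, `k <= 0`, `k_high <= 0`), every trial receives
#' `-Inf` — the contract used by the optimizer to stay in the valid region.
#'
#' @inheritParams mean_activity
#' @param x numeric vector of observed activities (a.u.), same length as
#'   `snr_db` (or one of them of length 1).
#' @return Numeric vector of log-likelihoods (nats).
#' @export
trial_loglik <- function(model, params, snr_db, x, design) {
  model <- model_id(model)
  p <- as_params(model, params)
  n <- max(length(snr_db), length(x))
  snr_db <- rep_len(snr_db, n); x <- rep_len(x, n)
  if (!isTRUE(valid_params(model, p, design)))
    return(rep(-Inf, n))
  if (model == "bifurcation") {
    beta <- high_state_prob(p, snr_db)
    mu_hi <- model_mu(model, p, snr_db, design)
    sig <- p[["sigma"]]
    la <- log(beta)  + stats::dnorm(x, mu_hi, sig, log = TRUE)
    lb <- log1p(-beta) + stats::dnorm(x, p[["mu_noise"]], sig, log = TRUE)
    m <- pmax(la, lb)
    out <- m + log(exp(la - m) + exp(lb - m))
    out[!is.finite(m)] <- -Inf
    out
  } else {
    mu <- model_mu(model, p, snr_db, design)
    sig <- model_sigma(model, p, snr_db, design)
    stats::dnorm(x, mu, sig, log = TRUE)
  }
}

#' Sample trials from a model
#'
#' I.i.d. draws from the model's trial distribution at the given
#' condition(s). For the bifurcation model the latent state of each draw is
#' attached as attribute `"state"` (`"high"`/`"low"`); the analysis stages
#' never read it — it exists for synthetic ground truth.
#'
#' @inheritParams mean_activity
#' @param n number of draws per element of `snr_db` when `snr_db` has
#'   length 1; otherwise one draw per element and `n` must match.
#' @return Numeric vector of activities (a.u.).
#' @export
sample_trials <- function(model, params, snr_db, n = length(snr_db),
                          design) {
  model <- model_id(model)
  p <- as_params(model, params)
  if (!isTRUE(valid_params(model, p, design)))
    stop("invalid parameters: ", attr(valid_params(model, p, design), "reason"))
  if (n == 0L) return(numeric(0))
  if (length(snr_db) == 1L) snr_db <- rep(snr_db, n)
  stopifnot(length(snr_db) == n)
  if (model == "bifurcation") {
    beta <- high_state_prob(p, snr_db)
    hi <- stats::runif(n) < beta
    mu <- ifelse(hi, model_mu(model, p, snr_db, design), p[["mu_noise"]])
    x <- stats::rnorm(n, mu, p[["sigma"]])
    attr(x, "state") <- ifelse(hi, "high", "low")
    x
  } else {
    mu <- model_mu(model, p, snr_db, design)
    sig <- model_sigma(model, p, snr_db, design)
    stats::rnorm(n, mu, sig)
  }
}

#' Serialize / restore parameter vectors
#'
#' Parameter vectors (or named lists of them, e.g. a ground-truth log of a
#' synthetic experiment) round-trip through a JSON text config keeping
#' field names exactly as in the model definitions.
#'
#' @param params a `model_params` vector or a (nested) list of them.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  enc <- function(p) {
    if (inherits(p, "model_params"))
      list(model = attr(p, "model"),
           params = as.list(stats::setNames(as.numeric(p), names(p))))
    else if (is.list(p)) lapply(p, enc)
    else p
  }
  jsonlite::write_json(enc(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  dec <- function(p) {
    if (is.list(p) && !is.null(p$model) && !is.null(p$params))
      new_params(p$model, unlist(p$params))
    else if (is.list(p)) lapply(p, dec)
    else p
  }
  dec(jsonlite::read_json(path, simplifyVector = FALSE))
}
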