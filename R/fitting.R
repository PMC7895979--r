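## Seed hygiene: run code under a temporary RNG state, restoring the
## caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Window starts (ms) encoded in activity_w<start> column names.
activity_windows <- function(table) {
  nm <- grep("^activity_w(-?[0-9]+)$", names(table), value = TRUE)
  sort(as.numeric(sub("^activity_w", "", nm)))
}

activity_column <- function(start) sprintf("activity_w%d", as.integer(start))

condition_stats <- function(trials) {
  f <- condition_token(trials$snr_db)
  data.frame(
    token = sort(unique(f)),
    mean = as.numeric(tapply(trials$activity, f, mean)[sort(unique(f))]),
    sd = as.numeric(tapply(trials$activity, f, stats::sd)[sort(unique(f))]),
    row.names = NULL
  )
}

#' Initialization of the maximum-likelihood search
#'
#' Starting values derived from condition summary statistics:
#' * null: `mu = 0`, `sigma = 1`;
#' * linear / nonlinear: slope (or `k`) from the line between mean activity
#'   at the lowest and highest SNR; the SD line (`slope_sigma`,
#'   `intercept_sigma`) from the SDs at those two conditions expressed as a
#'   function of their means; `threshsnr` at the midpoint of the SNR range;
#'   `mu_maxsnr` the mean at the highest SNR; `L` twice `mu_maxsnr`;
#' * bifurcation: `sigma` and `mu_noise` are the SD and mean of the
#'   noise-only trials, `L_high` the mean difference between the highest and
#'   lowest SNR, `step` the mean difference between the lowest SNR and
#'   noise-only, `k = k_high` the mean-activity slope, `threshsnr` the SNR
#'   midpoint.
#'
#' Sample SDs use the n-1 denominator. Slopes that must be positive
#' (`k`, `k_high`) are floored at 0.01; SD initializations at 0.05.
#'
#' @param model model identifier.
#' @param trials data frame with columns `snr_db` (`NA` = noise-only) and
#'   `activity`.
#' @param design a [design_grid()].
#' @return A [model_params] vector.
#' @export
init_params <- function(model, trials, design) {
  model <- model_id(model)
  if (model == "null") return(null_params(0, 1))
  snr <- trials$snr_db; x <- trials$activity
  lo <- design$minsnr_db; hi <- design$maxsnr_db
  need <- c(any(!is.na(snr) & snr == lo), any(!is.na(snr) & snr == hi),
            any(is.na(snr)))
  if (!all(need))
    stop("initialization needs trials at the minimum SNR, maximum SNR ",
         "and noise-only conditions")
  m_lo <- mean(x[!is.na(snr) & snr == lo])
  m_hi <- mean(x[!is.na(snr) & snr == hi])
  s_lo <- stats::sd(x[!is.na(snr) & snr == lo])
  s_hi <- stats::sd(x[!is.na(snr) & snr == hi])
  m_ns <- mean(x[is.na(snr)])
  s_ns <- stats::sd(x[is.na(snr)])
  slope <- (m_hi - m_lo) / (hi - lo)
  # SD line in the (mean, SD) plane, matching the sigma(mu) rule
  dsig <- if (abs(m_hi - m_lo) > 1e-12) (s_hi - s_lo) / (m_hi - m_lo) else 0
  isig <- max(s_lo - dsig * m_lo, 0.05)
  mid <- (lo + hi) / 2
  switch(model,
    linear = linear_params(slope, m_hi, m_ns, dsig, isig),
    nonlinear = nonlinear_params(max(slope, 0.01), mid, m_hi, 2 * m_hi,
                                 dsig, isig),
    bifurcation = bifurcation_params(max(s_ns, 0.05), max(slope, 0.01), mid,
                                     m_ns, m_lo - m_ns, m_hi - m_lo,
                                     max(slope, 0.01))
  )
}

#' Fit a generative model to single-trial activity
#'
#' Maximum-likelihood estimation by Nelder--Mead search (one restart from
#' the incumbent), maximizing the summed [trial_loglik()] over trials.
#' Parameter vectors leaving the valid region (non-positive SDs or
#' steepnesses) score `-Inf`, which keeps the unconstrained simplex inside
#' the feasible set.
#'
#' @param trials data frame with columns `snr_db` and `activity`.
#' @param model model identifier (see [model_id()]).
#' @param design a [design_grid()].
#' @param init optional starting [model_params]; default [init_params()].
#' @param control list: `reltol` (default 1e-10), `maxit`
#'   (default `200 * n_params`), `restarts` (default 1).
#' @return Object of class `"trial_model_fit"` with methods `print`,
#'   `summary`, `coef`, `logLik`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @examples
#' d <- design_grid(c(-13, -11, -9, -7, -5), trials_per_level = 40,
#'                  n_participants = 1, n_blocks = 5)
#' p <- bifurcation_params(1, 1.2, -9, 0, 0.5, 3, 1.2)
#' set.seed(1)
#' snr <- rep(design_conditions(d), each = 40)
#' tr <- data.frame(snr_db = snr,
#'                  activity = sample_trials("bifurcation", p, snr, design = d))
#' fit <- fit_trial_model(tr, "bifurcation", d)
#' coef(fit)["threshsnr"]
#' @export
fit_trial_model <- function(trials, model, design, init = NULL,
                            control = list()) {
  model <- model_id(model)
  stopifnot(nrow(trials) > 0)
  check_condition_in_design(trials$snr_db, design)
  if (is.null(init)) init <- init_params(model, trials, design)
  init <- as_params(model, init)
  pnames <- names(init)
  snr <- trials$snr_db; x <- trials$activity
  # objective on the unique-condition grid: same likelihood as
  # trial_loglik(), evaluated with per-condition means/SDs indexed out to
  # trials (the optimizer calls this thousands of times)
  uc <- unique(snr)
  idx <- match(condition_token(snr), condition_token(uc))
  maxsnr <- design$maxsnr_db
  obj <- switch(model,
    null = function(par) {
      if (par[2] <= 0) return(Inf)
      -sum(stats::dnorm(x, par[1], par[2], log = TRUE))
    },
    linear = function(par) {
      mu <- pmax(par[1] * (uc - maxsnr) + par[2], par[3])
      mu[is.na(uc)] <- par[3]
      sig <- par[4] * mu + par[5]
      if (any(sig <= 0)) return(Inf)
      -sum(stats::dnorm(x, mu[idx], sig[idx], log = TRUE))
    },
    nonlinear = function(par) {
      if (par[1] <= 0) return(Inf)
      anchor <- par[4] * stats::plogis(par[1] * (maxsnr - par[2]))
      mu <- par[4] * stats::plogis(par[1] * (uc - par[2])) - anchor + par[3]
      mu[is.na(uc)] <- par[3] - anchor
      sig <- par[5] * mu + par[6]
      if (any(sig <= 0)) return(Inf)
      -sum(stats::dnorm(x, mu[idx], sig[idx], log = TRUE))
    },
    bifurcation = function(par) {
      # par: sigma, k, threshsnr, mu_noise, step, L_high, k_high
      if (par[1] <= 0 || par[2] <= 0 || par[7] <= 0) return(Inf)
      beta <- stats::plogis(par[2] * (uc - par[3]))
      beta[is.na(uc)] <- 0
      mu_hi <- par[6] * stats::plogis(par[7] * (uc - par[3])) + par[5]
      mu_hi[is.na(uc)] <- par[5]
      la <- log(beta)[idx] + stats::dnorm(x, mu_hi[idx], par[1], log = TRUE)
      lb <- log1p(-beta)[idx] + stats::dnorm(x, par[4], par[1], log = TRUE)
      m <- pmax(la, lb)
      ll <- sum(m + log(exp(la - m) + exp(lb - m)))
      if (is.nan(ll)) ll <- -Inf
      -ll
    })
  ll0 <- -obj(as.numeric(init))
  if (!is.finite(ll0))
    stop("initialization is invalid for this design (log-likelihood -Inf)")
  ctl <- list(reltol = control$reltol %||% 1e-10,
              maxit = control$maxit %||% 200L * length(init))
  restarts <- control$restarts %||% 1L
  if (length(init) == 1L) stop("all models have >= 2 parameters")
  opt <- stats::optim(as.numeric(init), obj, method = "Nelder-Mead",
                      control = ctl)
  iters <- opt$counts[["function"]]
  for (r in seq_len(restarts)) {
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
    iters <- iters + opt2$counts[["function"]]
    if (opt2$value <= opt$value) opt <- opt2
  }
  params <- new_params(model, stats::setNames(opt$par, pnames))
  structure(list(
    model = model, params = params, logLik = -opt$value,
    init = init, init_loglik = ll0,
    converged = opt$convergence == 0L, n_iterations = iters,
    n = nrow(trials), design = design,
    snr_db = snr, activity = x
  ), class = "trial_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Observed-trial expectation (mixture mean for the bifurcation model).
model_trial_mean <- function(model, p, snr, design) {
  model <- model_id(model)
  if (model == "bifurcation") {
    beta <- high_state_prob(p, snr)
    beta * model_mu(model, p, snr, design) + (1 - beta) * p[["mu_noise"]]
  } else model_mu(model, p, snr, design)
}

#' @exportS3Method base::print
print.trial_model_fit <- function(x, ...) {
  cat("Single-trial activity model fit (", x$model, ")\n", sep = "")
  cat("  n =", x$n, "trials;  log-likelihood =",
      format(x$logLik, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(stats::setNames(as.numeric(x$params), names(x$params)))
  invisible(x)
}

#' @export
coef.trial_model_fit <- function(object, ...)
  stats::setNames(as.numeric(object$params), names(object$params))

#' @export
logLik.trial_model_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$params), nobs = object$n,
            class = "logLik")
}

#' @export
fitted.trial_model_fit <- function(object, ...)
  model_trial_mean(object$model, object$params, object$snr_db, object$design)

#' @export
residuals.trial_model_fit <- function(object, ...)
  object$activity - fitted(object)

#' Model predictions per condition
#'
#' @param object a `trial_model_fit`.
#' @param newdata optional numeric vector of conditions (dB, `NA` =
#'   noise-only); defaults to all design conditions.
#' @param ... unused.
#' @return Data frame with the condition, the predicted trial mean
#'   (mixture mean for the bifurcation model), the high-state mean and SD,
#'   and the high-state probability.
#' @export
predict.trial_model_fit <- function(object, newdata = NULL, ...) {
  snr <- if (is.null(newdata)) design_conditions(object$design)
         else as.numeric(newdata)
  p <- object$params
  out <- data.frame(
    condition = condition_token(snr),
    snr_db = snr,
    mean = model_trial_mean(object$model, p, snr, object$design),
    sd = model_sigma(object$model, p, snr, object$design)
  )
  if (object$model == "bifurcation") {
    out$mean_high <- mean_activity(object$model, p, snr, object$design)
    out$mean_high[is.na(snr)] <- p[["step"]]
    out$beta <- high_state_prob(p, snr)
    # full trial SD of the mixture
    out$sd <- sqrt(p[["sigma"]]^2 +
                   out$beta * (1 - out$beta) *
                   (out$mean_high - p[["mu_noise"]])^2)
  }
  out
}

#' @export
simulate.trial_model_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    as.data.frame(stats::setNames(lapply(seq_len(nsim), function(i) {
      as.numeric(sample_trials(object$model, object$params, object$snr_db,
                               design = object$design))
    }), paste0("sim_", seq_len(nsim))))
  })
}

#' @export
summary.trial_model_fit <- function(object, ...) {
  obs <- condition_stats(data.frame(snr_db = object$snr_db,
                                    activity = object$activity))
  pred <- predict(object)
  out <- list(fit = object, observed = obs, predicted = pred)
  class(out) <- "summary.trial_model_fit"
  out
}

#' @exportS3Method base::print
print.summary.trial_model_fit <- function(x, ...) {
  print(x$fit)
  cat("\nObserved condition statistics:\n")
  print(x$observed, digits = 4)
  cat("\nModel predictions:\n")
  print(x$predicted, digits = 4)
  invisible(x)
}

#' @export
plot.trial_model_fit <- function(x, ...) {
  obs <- condition_stats(data.frame(snr_db = x$snr_db, activity = x$activity))
  pred <- predict(x)
  ord <- order(pred$snr_db, na.last = FALSE)
  xx <- seq_along(ord)
  oldpar <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(oldpar))
  idx <- match(pred$condition[ord], obs$token)
  graphics::plot(xx, obs$mean[idx], pch = 19, xaxt = "n",
                 xlab = "condition", ylab = "mean activity (a.u.)",
                 main = paste("mean profile -", x$model))
  graphics::axis(1, at = xx, labels = pred$condition[ord])
  graphics::lines(xx, pred$mean[ord], col = "red3")
  graphics::plot(xx, obs$sd[idx], pch = 19, xaxt = "n",
                 xlab = "condition", ylab = "SD across trials (a.u.)",
                 main = "variability profile")
  graphics::axis(1, at = xx, labels = pred$condition[ord])
  graphics::lines(xx, pred$sd[ord], col = "red3")
  invisible(x)
}

#' Block-respecting cross-validated log-likelihood
#'
#' Blocks (not trials) are partitioned into `folds` near-equal groups, so
#' train and test trials never share a block. Per fold, the model is fit on
#' the training blocks and the summed per-trial log-likelihood is evaluated
#' on the held-out blocks; the reported value is the mean over folds of the
#' held-out sums.
#'
#' @inheritParams fit_trial_model
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the one-off block shuffle.
#' @param fold_assignment optional named integer vector (block -> fold)
#'   overriding the shuffle, e.g. to share folds across windows.
#' @return Object of class `"cv_fit"`: `fold_logliks` (held-out sums, one
#'   per fold), `mean_cv_loglik`, `fold_assignment`, and the per-fold fits.
#' @export
crossval_loglik <- function(trials, model, design, folds = 5L, seed = NULL,
                            fold_assignment = NULL, control = list()) {
  model <- model_id(model)
  blocks <- sort(unique(trials$block))
  if (is.null(fold_assignment)) {
    if (length(blocks) < folds)
      stop("need at least ", folds, " blocks for ", folds, "-fold CV; got ",
           length(blocks))
    fold_assignment <- with_seed(seed, {
      shuffled <- sample(blocks)
      stats::setNames(rep(seq_len(folds),
                          each = ceiling(length(blocks) / folds))[
                            order(match(blocks, shuffled))], blocks)
    })
  }
  folds_used <- sort(unique(fold_assignment))
  fold_ll <- numeric(length(folds_used))
  fits <- vector("list", length(folds_used))
  for (i in seq_along(folds_used)) {
    f <- folds_used[i]
    test_blocks <- names(fold_assignment)[fold_assignment == f]
    test <- trials$block %in% test_blocks
    fit <- fit_trial_model(trials[!test, , drop = FALSE], model, design,
                           control = control)
    fold_ll[i] <- sum(trial_loglik(model, fit$params,
                                   trials$snr_db[test],
                                   trials$activity[test], design))
    fits[[i]] <- fit
  }
  structure(list(model = model, fold_logliks = fold_ll,
                 mean_cv_loglik = mean(fold_ll),
                 fold_assignment = fold_assignment, fits = fits),
            class = "cv_fit")
}

#' @exportS3Method base::print
print.cv_fit <- function(x, ...) {
  cat("Cross-validated fit (", x$model, "), ", length(x$fold_logliks),
      " folds\n", sep = "")
  cat("  held-out log-likelihood per fold:",
      paste(format(x$fold_logliks, digits = 5), collapse = ", "), "\n")
  cat("  mean:", format(x$mean_cv_loglik, digits = 6), "\n")
  invisible(x)
}

#' Fit competing models across participants and time windows
#'
#' Runs initialization, maximum-likelihood fitting and block-respecting
#' cross-validation for every (participant, 30-ms window, model) cell of a
#' trial table carrying per-window activities (`activity_w<start>`
#' columns). Per-cell failures are flagged, never fatal to the sweep.
#' Fold assignments are drawn once per participant (from `seed`) and shared
#' across windows and models.
#'
#' @param table trial table (see [read_trial_table()]) with
#'   `activity_w<start>` columns.
#' @param design a [design_grid()].
#' @param models character vector of models to fit; the default is the
#'   comparison set (the linear model is a special case of the nonlinear
#'   one and is excluded).
#' @param folds,seed,control passed to [crossval_loglik()]; the sweep
#'   default (`reltol = 1e-8`, no restart) trades a little optimizer polish
#'   for throughput across the thousands of cells.
#' @param windows optional subset of window starts (ms).
#' @param cv run the cross-validation step (default TRUE); `FALSE` keeps
#'   only the full-data fits, e.g. when the sweep feeds the Bayes-factor
#'   prediction stage rather than model comparison.
#' @return Object of class `"window_sweep"`: `$table` — one row per cell
#'   with `participant`, `window_start_ms`, `model`, `train_loglik`,
#'   `mean_cv_loglik`, `converged`, `flagged`; `$fits` — nested list of
#'   full-data parameter vectors `fits[[participant]][[window]][[model]]`;
#'   `$windows`, `$models`, `$design`.
#' @export
fit_window_sweep <- function(table, design,
                             models = c("null", "nonlinear", "bifurcation"),
                             folds = 5L, seed = 1L, windows = NULL, cv = TRUE,
                             control = list(reltol = 1e-8, restarts = 0L)) {
  models <- vapply(models, model_id, character(1), USE.NAMES = FALSE)
  all_w <- activity_windows(table)
  if (length(all_w) == 0L) stop("no activity_w<start> columns in table")
  if (is.null(windows)) windows <- all_w
  stopifnot(all(windows %in% all_w))
  participants <- sort(unique(table$participant))
  rows <- list(); fits <- list()
  for (ip in seq_along(participants)) {
    pid <- participants[ip]
    ptab <- table[table$participant == pid, , drop = FALSE]
    blocks <- sort(unique(ptab$block))
    fa <- with_seed(seed + ip, {
      shuffled <- sample(blocks)
      stats::setNames(rep(seq_len(folds),
                          each = ceiling(length(blocks) / folds))[
                            order(match(blocks, shuffled))], blocks)
    })
    fits[[as.character(pid)]] <- list()
    for (w in windows) {
      wkey <- as.character(w)
      fits[[as.character(pid)]][[wkey]] <- list()
      trials <- data.frame(block = ptab$block, snr_db = ptab$snr_db,
                           activity = ptab[[activity_column(w)]])
      for (m in models) {
        cell <- tryCatch({
          if (anyNA(trials$activity) || any(!is.finite(trials$activity)))
            stop("non-finite activity values")
          fit <- fit_trial_model(trials, m, design, control = control)
          cvll <- if (cv)
            crossval_loglik(trials, m, design, folds = folds,
                            fold_assignment = fa,
                            control = control)$mean_cv_loglik
          else NA_real_
          fits[[as.character(pid)]][[wkey]][[m]] <- fit$params
          data.frame(participant = pid, window_start_ms = w, model = m,
                     train_loglik = fit$logLik,
                     mean_cv_loglik = cvll,
                     converged = fit$converged, flagged = FALSE)
        }, error = function(e) {
          data.frame(participant = pid, window_start_ms = w, model = m,
                     train_loglik = NA_real_, mean_cv_loglik = NA_real_,
                     converged = FALSE, flagged = TRUE)
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 windows = windows, models = models, design = design),
            class = "window_sweep")
}

#' @exportS3Method base::print
print.window_sweep <- function(x, ...) {
  cat("Window sweep:", length(unique(x$table$participant)), "participants x",
      length(x$windows), "windows x", length(x$models), "models\n")
  cat("  flagged cells:", sum(x$table$flagged), "\n")
  invisible(x)
}
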