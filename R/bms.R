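logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Random-effects Bayesian model selection
#'
#' Group-level comparison of K models from per-participant log model
#' evidences (here: mean cross-validated log-likelihoods, which already
#' penalize model complexity). Model frequencies in the population are
#' given a Dirichlet prior (`alpha0` per model) and the posterior is
#' obtained by the standard variational scheme: iterate
#' `u_nk = exp(L_nk + digamma(alpha_k) - digamma(sum(alpha)))`, normalize
#' to responsibilities `g_nk`, and set `alpha = alpha0 + colSums(g)` until
#' `max |delta alpha| < 1e-6` (at most 500 iterations).
#'
#' Exceedance probabilities (the probability that each model is the most
#' frequent) are computed by Monte-Carlo over the Dirichlet posterior. The
#' Bayes omnibus risk (BOR) — the posterior probability that all models are
#' equally frequent — is computed from the variational free energy of the
#' random-effects model against the exact evidence of the equal-frequency
#' null, and the protected exceedance probability is
#' `pxp = (1 - bor) * ep + bor / K`.
#'
#' @param log_evidence numeric matrix, participants x models (finite).
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param n_mc Monte-Carlo samples for the exceedance step (default 1e5).
#' @param seed integer seed for the Monte-Carlo step.
#' @return Object of class `"bms_result"`: `alpha`, `expected_freq`,
#'   `exceedance_prob`, `bor`, `pxp`, `n_participants`, `converged`.
#' @references Stephan et al. (2009) NeuroImage 46:1004-1017;
#'   Rigoux et al. (2014) NeuroImage 84:971-985.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, n_mc = 1e5, seed = NULL) {
  L <- as.matrix(log_evidence)
  if (ncol(L) < 2L) stop("need at least 2 models")
  if (any(!is.finite(L))) stop("log evidences must be finite")
  N <- nrow(L); K <- ncol(L)
  model_names <- colnames(L)
  a0 <- rep(alpha0, K)
  alpha <- a0 + N / K
  converged <- FALSE
  for (it in seq_len(500L)) {
    lg <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(lg - apply(lg, 1L, logsumexp))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-6) {
      alpha <- alpha_new; converged <- TRUE; break
    }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  ep <- exceedance_mc(alpha, n_samples = n_mc, seed = seed)
  # Free energy of the random-effects model (variational bound)
  E_lnr <- digamma(alpha) - digamma(sum(alpha))
  glg <- g * log(g); glg[g == 0] <- 0
  F1 <- sum(g * L) + sum(sweep(g, 2L, E_lnr, "*")) +
    (lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * E_lnr)) -
    sum(glg) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * E_lnr))
  # Exact evidence of the equal-frequency null
  F0 <- sum(apply(L, 1L, logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * ep + bor / K
  if (!is.null(model_names))
    names(alpha) <- names(ef) <- names(ep) <- names(pxp) <- model_names
  structure(list(alpha = alpha, expected_freq = ef, exceedance_prob = ep,
                 bor = bor, pxp = pxp, n_participants = N,
                 converged = converged),
            class = "bms_result")
}

#' @exportS3Method base::print
print.bms_result <- function(x, digits = 4, ...) {
  cat("Random-effects Bayesian model selection (",
      x$n_participants, " participants, ", length(x$alpha), " models)\n",
      sep = "")
  tab <- rbind(expected_freq = x$expected_freq,
               exceedance = x$exceedance_prob,
               pxp = x$pxp)
  colnames(tab) <- names(x$alpha) %||% paste0("model", seq_along(x$alpha))
  print(round(tab, digits))
  cat("Bayes omnibus risk:", format(x$bor, digits = digits), "\n")
  invisible(x)
}

#' Monte-Carlo exceedance probabilities of a Dirichlet posterior
#'
#' Frequency with which each component of a Dirichlet(`alpha`) draw is the
#' largest, over `n_samples` draws. Serves as the exceedance step of
#' [rfx_bms()] and as an independent oracle for it.
#'
#' @param alpha positive Dirichlet concentration vector.
#' @param n_samples number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return Numeric vector of exceedance probabilities (sums to 1).
#' @export
exceedance_mc <- function(alpha, n_samples = 1e5, seed = NULL) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  with_seed(seed, {
    gam <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha,
                                                           each = n_samples)),
                  nrow = n_samples)
    wins <- max.col(gam, ties.method = "first")
    tabulate(wins, nbins = K) / n_samples
  })
}

#' Simes global test
#'
#' Combines m p-values into a single global p-value:
#' `min_i ( m * p_(i) / i )` over the sorted p-values. Used to control for
#' multiplicity across time windows.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Global p-value (scalar).
#' @export
simes_global <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0L) stop("empty p-value vector")
  stopifnot(all(pvals > 0 & pvals <= 1))
  m <- length(pvals)
  min(m * sort(pvals) / seq_len(m))
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure at level `q`, returning both the rejection
#' mask and the monotone adjusted p-values (via [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return List with `reject` (logical) and `p_adjusted` (numeric).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  stopifnot(all(pvals > 0 & pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}

#' Per-window group model comparison
#'
#' Applies [rfx_bms()] at each time window of a [fit_window_sweep()]
#' result, using the per-participant mean cross-validated log-likelihoods
#' as log model evidence. Windows with flagged cells drop the affected
#' participants (all models of that participant, to keep rows comparable).
#'
#' @param sweep a `"window_sweep"` object.
#' @param alpha0,n_mc,seed passed to [rfx_bms()].
#' @return Data frame with one row per (window, model):
#'   `window_start_ms`, `model`, `expected_freq`, `exceedance_prob`,
#'   `bor`, `pxp`.
#' @export
bms_by_window <- function(sweep, alpha0 = 1, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(sweep, "window_sweep"))
  tab <- sweep$table
  out <- list()
  for (w in sweep$windows) {
    wt <- tab[tab$window_start_ms == w, , drop = FALSE]
    bad <- unique(wt$participant[wt$flagged | !is.finite(wt$mean_cv_loglik)])
    wt <- wt[!wt$participant %in% bad, , drop = FALSE]
    participants <- sort(unique(wt$participant))
    L <- matrix(NA_real_, length(participants), length(sweep$models),
                dimnames = list(NULL, sweep$models))
    for (m in sweep$models) {
      sub <- wt[wt$model == m, , drop = FALSE]
      L[, m] <- sub$mean_cv_loglik[match(participants, sub$participant)]
    }
    res <- rfx_bms(L, alpha0 = alpha0, n_mc = n_mc, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      window_start_ms = w, model = sweep$models,
      expected_freq = res$expected_freq,
      exceedance_prob = res$exceedance_prob,
      bor = res$bor, pxp = res$pxp)
  }
  do.call(rbind, out)
}
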