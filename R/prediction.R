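#' Trial-wise high- versus low-state log Bayes factor
#'
#' Under a fitted bifurcation model, the log-likelihood ratio that a
#' trial's activity belongs to the high state (Gaussian at the high-state
#' mean) versus the low state (Gaussian at `mu_noise`), with the shared
#' `sigma`. This is a pure likelihood ratio — the prior odds
#' `beta / (1 - beta)` are not included (`posterior = TRUE` adds them). No
#' behavioral information enters at any stage.
#'
#' For noise-only trials the high-state mean is the low-SNR asymptote of
#' the high-state logistic (`step`).
#'
#' @param params bifurcation [model_params].
#' @param snr_db conditions (dB; `NA` = noise-only).
#' @param x observed activities (a.u.).
#' @param design a [design_grid()].
#' @param posterior include the log prior odds `log(beta / (1 - beta))`.
#' @return Numeric vector of log Bayes factors (nats).
#' @export
state_log_bf <- function(params, snr_db, x, design, posterior = FALSE) {
  p <- as_params("bifurcation", params)
  if (!isTRUE(valid_params("bifurcation", p, design)))
    stop("invalid bifurcation parameters")
  check_condition_in_design(snr_db, design)
  mu_hi <- model_mu("bifurcation", p, snr_db, design)
  out <- stats::dnorm(x, mu_hi, p[["sigma"]], log = TRUE) -
    stats::dnorm(x, p[["mu_noise"]], p[["sigma"]], log = TRUE)
  if (posterior) {
    beta <- high_state_prob(p, snr_db)
    out <- out + log(beta) - log1p(-beta)
  }
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the proportion of (positive, negative) pairs in which the
#' positive trial scores higher, ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; `TRUE` = positive.
#' @return AUC in \[0, 1\].
#' @export
report_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict conscious reports across time windows
#'
#' From the full-data bifurcation fits of a [fit_window_sweep()], computes
#' per-trial log Bayes factors at each window and scores how well they
#' discriminate the behavioral labels — `heard` (audibility >= 30%,
#' active session; by default restricted to the intermediate SNRs
#' -11, -9, -7 dB) or `probe_sound` (mind-wandering probe reported as
#' "the sound", passive session; all conditions pooled). Group inference
#' is a two-sided t-test of the per-participant AUCs against 0.5 per
#' window, BH-FDR corrected across windows. The fits never saw the labels.
#'
#' @param sweep a `"window_sweep"` containing bifurcation fits.
#' @param table the trial table the sweep was fit on.
#' @param which `"heard"` or `"probe_sound"`.
#' @param snr_subset conditions to pool (numeric, `NA` = noise-only);
#'   default `c(-11, -9, -7)` for `"heard"`, all conditions for
#'   `"probe_sound"`.
#' @param q FDR level.
#' @param posterior passed to [state_log_bf()].
#' @return List: `auc` (participants x windows matrix), `group` (data
#'   frame: window_start_ms, n, mean_auc, t, p, p_adjusted, significant),
#'   `skipped` (cells without both label classes).
#' @export
predict_timecourse <- function(sweep, table,
                               which = c("heard", "probe_sound"),
                               snr_subset = NULL, q = 0.05,
                               posterior = FALSE) {
  stopifnot(inherits(sweep, "window_sweep"))
  which <- match.arg(which)
  if (is.null(snr_subset) && which == "heard") snr_subset <- c(-11, -9, -7)
  labels_all <- switch(which,
    heard = as.logical(table$heard),
    probe_sound = table$probe_label == "sound")
  keep <- !is.na(labels_all)
  if (!is.null(snr_subset))
    keep <- keep & (table$snr_db %in% snr_subset |
                      (anyNA(snr_subset) & is.na(table$snr_db)))
  participants <- sort(unique(table$participant))
  windows <- sweep$windows
  auc <- matrix(NA_real_, length(participants), length(windows),
                dimnames = list(participants, windows))
  skipped <- auc * 0 > 0  # all-FALSE logical matrix
  for (i in seq_along(participants)) {
    rows <- keep & table$participant == participants[i]
    lab <- labels_all[rows]
    for (j in seq_along(windows)) {
      p3 <- sweep$fits[[as.character(participants[i])]][[
        as.character(windows[j])]][["bifurcation"]]
      if (is.null(p3)) { skipped[i, j] <- TRUE; next }
      if (length(unique(lab)) < 2L) { skipped[i, j] <- TRUE; next }
      bf <- state_log_bf(p3, table$snr_db[rows],
                         table[[activity_column(windows[j])]][rows],
                         sweep$design, posterior = posterior)
      auc[i, j] <- report_auc(bf, lab)
    }
  }
  group <- do.call(rbind, lapply(seq_along(windows), function(j) {
    a <- auc[, j][!is.na(auc[, j])]
    if (length(a) < 2L || stats::sd(a) == 0)
      return(data.frame(window_start_ms = windows[j], n = length(a),
                        mean_auc = mean(a), t = NA_real_, p = NA_real_))
    tt <- stats::t.test(a, mu = 0.5)
    data.frame(window_start_ms = windows[j], n = length(a),
               mean_auc = mean(a), t = unname(tt$statistic), p = tt$p.value)
  }))
  ok <- !is.na(group$p)
  group$p_adjusted <- NA_real_
  group$p_adjusted[ok] <- bh_fdr(group$p[ok], q)$p_adjusted
  group$significant <- !is.na(group$p_adjusted) & group$p_adjusted <= q
  list(auc = auc, group = group, skipped = skipped)
}
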