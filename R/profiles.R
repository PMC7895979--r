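#' Mean and variability response profiles
#'
#' Per-condition across-trial mean and SD (n-1 denominator) of the
#' activity, with the noise-only values subtracted from every condition's
#' mean and SD respectively — the baseline correction that makes profiles
#' comparable across participants. After subtraction the noise-only entry
#' is exactly (0, 0). The across-trial SD as a function of SNR is the
#' variability response profile; an interior peak near threshold is the
#' bifurcation signature.
#'
#' @param trials data frame with `snr_db` and either `activity` or the
#'   `activity_w<start>` column selected by `window`.
#' @param window optional window start (ms) selecting an
#'   `activity_w<start>` column.
#' @param baseline_subtract subtract the noise-only mean/SD (default TRUE;
#'   requires noise-only trials).
#' @return Object of class `"profile_set"`: data frame with `condition`,
#'   `snr_db`, `mean`, `sd`, `n`, `flagged` (conditions with < 2 trials
#'   have undefined SD), ordered noise-only first then SNR ascending.
#' @export
response_profiles <- function(trials, window = NULL,
                              baseline_subtract = TRUE) {
  act <- if (is.null(window)) trials$activity
         else trials[[activity_column(window)]]
  stopifnot(!is.null(act))
  snr <- trials$snr_db
  conds <- sort(unique(snr), na.last = FALSE)
  n <- as.integer(table(factor(condition_token(snr),
                               levels = condition_token(conds))))
  m <- vapply(conds, function(cc) mean(act[same_cond(snr, cc)]), 0)
  s <- vapply(conds, function(cc) {
    idx <- same_cond(snr, cc)
    if (sum(idx) < 2L) NA_real_ else stats::sd(act[idx])
  }, 0)
  flagged <- n < 2L
  if (any(flagged))
    warning("condition(s) with < 2 trials: SD undefined for ",
            paste(condition_token(conds[flagged]), collapse = ", "))
  if (baseline_subtract) {
    if (!any(is.na(conds)))
      stop("baseline subtraction requires noise-only trials")
    i0 <- which(is.na(conds))
    m <- m - m[i0]; s <- s - s[i0]
  }
  structure(data.frame(condition = condition_token(conds), snr_db = conds,
                       mean = m, sd = s, n = n, flagged = flagged),
            baseline_subtracted = baseline_subtract,
            class = c("profile_set", "data.frame"))
}

same_cond <- function(snr, cc) {
  if (is.na(cc)) is.na(snr) else !is.na(snr) & snr == cc
}

#' Heard / not-heard labels from audibility ratings
#'
#' A rating at 30% or above counts as "heard"; the criterion sits at the
#' trough of the bimodal audibility distribution observed at threshold.
#'
#' @param audibility numeric vector of ratings in \[0, 100\].
#' @return Logical vector.
#' @export
heard_labels <- function(audibility) {
  if (any(audibility < 0 | audibility > 100, na.rm = TRUE))
    stop("audibility ratings must lie in [0, 100]")
  audibility >= 30
}

#' Neuro-behavioral profile correlations over time windows
#'
#' For each participant, the Pearson correlation between the neural profile
#' (mean or SD across trials, per condition) at each time window and that
#' participant's behavioral profile over the same conditions; at the group
#' level, a one-sided t-test (positive coupling) of the correlation
#' coefficients against zero per window, BH-FDR corrected across windows.
#' Participants with a zero-variance profile at a window are excluded from
#' that window's test.
#'
#' @param neural list (one element per participant) of numeric matrices,
#'   windows x conditions.
#' @param behavior numeric matrix, participants x conditions.
#' @param q FDR level (default 0.05).
#' @return List: `r` (participants x windows matrix of correlations),
#'   `group` (data frame: window index, n, t, p, p_adjusted, significant),
#'   `excluded` (participants x windows logical).
#' @export
profile_correlation <- function(neural, behavior, q = 0.05) {
  stopifnot(is.list(neural), nrow(behavior) == length(neural))
  nw <- nrow(neural[[1]])
  np <- length(neural)
  r <- matrix(NA_real_, np, nw)
  for (i in seq_len(np)) {
    stopifnot(ncol(neural[[i]]) == ncol(behavior))
    b <- behavior[i, ]
    for (w in seq_len(nw)) {
      x <- neural[[i]][w, ]
      if (stats::sd(x) == 0 || stats::sd(b) == 0) next
      r[i, w] <- stats::cor(x, b)
    }
  }
  excluded <- is.na(r)
  group <- do.call(rbind, lapply(seq_len(nw), function(w) {
    rv <- r[, w][!is.na(r[, w])]
    if (length(rv) < 2L || stats::sd(rv) == 0)
      return(data.frame(window = w, n = length(rv), t = NA_real_,
                        p = NA_real_))
    tt <- stats::t.test(rv, alternative = "greater")
    data.frame(window = w, n = length(rv),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  ok <- !is.na(group$p)
  group$p_adjusted <- NA_real_
  group$p_adjusted[ok] <- bh_fdr(group$p[ok], q)$p_adjusted
  group$significant <- !is.na(group$p_adjusted) & group$p_adjusted <= q
  list(r = r, group = group, excluded = excluded)
}

shift_profile <- function(b, s) {
  # shift toward lower SNR by s grid levels; vacated low entries take the
  # first (noise-only) value
  idx <- pmax(seq_along(b) - s, 1L)
  b[idx]
}

#' Best active-to-passive threshold shift
#'
#' The perceptual threshold moves between active and passive listening;
#' the behavioral profile (collected in the active session) is shifted
#' down the SNR axis by 1 or 2 grid levels and the shift whose window-wise
#' correlations with the passive neural profiles exceed 3 SDs of the
#' pre-stimulus baseline correlations by the largest summed amount is
#' retained. Conditions must be ordered noise-only first, then SNR
#' ascending. Ties go to the smaller shift; if no window exceeds the
#' baseline band for any shift, shift 1 is returned with a warning.
#'
#' @param neural numeric matrix, windows x conditions, for one participant.
#' @param behavior numeric vector over the same conditions.
#' @param baseline_windows integer indices of the pre-stimulus windows used
#'   for the baseline correlation distribution.
#' @param shifts candidate shifts in grid levels (default `c(1, 2)`).
#' @return List: `shift` (chosen), `scores` (summed supra-threshold r per
#'   candidate), `r` (windows x candidates matrix).
#' @export
best_shift <- function(neural, behavior, baseline_windows,
                       shifts = c(1L, 2L)) {
  nw <- nrow(neural)
  stopifnot(length(behavior) == ncol(neural),
            all(baseline_windows %in% seq_len(nw)))
  post <- setdiff(seq_len(nw), baseline_windows)
  rmat <- sapply(shifts, function(s) {
    b <- shift_profile(behavior, s)
    apply(neural, 1L, function(x)
      if (stats::sd(x) == 0 || stats::sd(b) == 0) 0 else stats::cor(x, b))
  })
  scores <- vapply(seq_along(shifts), function(j) {
    base <- rmat[baseline_windows, j]
    thr <- mean(base) + 3 * stats::sd(base)
    rv <- rmat[post, j]
    sum(rv[rv > thr])
  }, 0)
  if (all(scores == 0)) {
    warning("no window exceeds the baseline band for any shift; ",
            "defaulting to shift ", min(shifts))
    return(list(shift = min(shifts), scores = scores, r = rmat))
  }
  best <- shifts[which.max(scores)]  # which.max takes the first (smaller)
  list(shift = best, scores = scores, r = rmat)
}

#' Trial-activity distributions by condition (kernel density)
#'
#' Activities are z-scored per participant with all conditions pooled, then
#' the distribution within each condition is estimated with a Gaussian
#' kernel at the normal-reference bandwidth `sd * (4 / (3 n))^(1/5)` on a
#' fixed grid of 91 points between -9 and +9 (step 0.2, z-units). Group
#' curves are obtained by averaging participant curves on the shared grid;
#' around threshold the bifurcation regime shows up as bimodality.
#'
#' @param trials data frame with `snr_db` and `activity` for one
#'   participant.
#' @param min_n minimum trials per condition (default 10).
#' @return List of class `"density_set"`: `grid` (91 points) and
#'   `density`, a conditions x 91 matrix (rows named by condition token).
#' @export
activity_density <- function(trials, min_n = 10L) {
  x <- trials$activity
  if (stats::sd(x) == 0) stop("degenerate (zero-variance) activity")
  z <- (x - mean(x)) / stats::sd(x)
  grid <- seq(-9, 9, by = 0.2)
  conds <- sort(unique(trials$snr_db), na.last = FALSE)
  dens <- t(vapply(conds, function(cc) {
    zi <- z[same_cond(trials$snr_db, cc)]
    if (length(zi) < min_n)
      stop("condition ", condition_token(cc), " has fewer than ", min_n,
           " trials")
    bw <- stats::sd(zi) * (4 / (3 * length(zi)))^(1 / 5)
    colMeans(stats::dnorm(outer(zi, grid, "-") / bw)) / bw
  }, numeric(length(grid))))
  rownames(dens) <- condition_token(conds)
  structure(list(grid = grid, density = dens), class = "density_set")
}

#' Interior local maxima of a curve
#'
#' Utility for detecting bimodality in estimated densities: indices `i`
#' with `y[i] > y[i-1]` and `y[i] > y[i+1]`.
#'
#' @param y numeric vector.
#' @return Integer indices of strict interior local maxima.
#' @export
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}
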