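#' Epoch array container
#'
#' Multichannel epoched data for one participant: a 3-D numeric array
#' (trials x channels x samples) with uniform sample times (ms), channel
#' names, and trial ids linking rows to a trial table's `trial_index`.
#'
#' @param data numeric array, trials x channels x samples.
#' @param times numeric vector of sample times (ms), uniformly spaced.
#' @param channels character vector of channel names.
#' @param trial_ids unique ids, one per trial.
#' @return Object of class `"epoch_array"`.
#' @export
epoch_array <- function(data, times, channels, trial_ids) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times),
            dim(data)[1] == length(trial_ids))
  if (anyDuplicated(trial_ids)) stop("trial_ids must be unique")
  dt <- diff(times)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9)
    stop("times must be uniformly spaced")
  structure(list(data = data, times = times, channels = channels,
                 trial_ids = trial_ids), class = "epoch_array")
}

#' @exportS3Method base::print
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch array:", d[1], "trials x", d[2], "channels x", d[3],
      "samples (", min(x$times), "to", max(x$times), "ms,",
      round(1000 / diff(x$times[1:2])), "Hz )\n")
  invisible(x)
}

#' Train a stimulus presence/absence classifier
#'
#' L2-penalized logistic regression at fixed regularization `C` (the
#' penalized objective `sum(loss) + ||w||^2 / (2C)`), fit with glmnet
#' (`alpha = 0`, `lambda = 1/(n C)`). Features are standardized with
#' training-set statistics, which travel with the decision rule.
#'
#' @param X numeric matrix, trials x features (channels).
#' @param y logical (or 0/1) labels; `TRUE` = stimulus present.
#' @param C inverse regularization strength (default 1).
#' @return Object of class `"linear_decision"`: `weights`, `bias` (in
#'   standardized feature space), `center`, `scale`.
#' @export
train_presence_classifier <- function(X, y, C = 1) {
  X <- as.matrix(X); y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fit <- glmnet::glmnet(Xs, factor(y, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / (nrow(Xs) * C), standardize = FALSE,
                        thresh = 1e-10)
  structure(list(weights = as.numeric(fit$beta), bias = as.numeric(fit$a0),
                 center = center, scale = scale),
            class = "linear_decision")
}

#' Projected activity: signed distance to the decision plane
#'
#' Positive toward "stimulus present", zero on the boundary. This scalar
#' per trial is the multivariate summary consumed by all the dynamics
#' analyses.
#'
#' @param decision a [train_presence_classifier()] fit.
#' @param X numeric matrix, trials x features (raw, unstandardized).
#' @return Numeric vector, one signed distance per trial.
#' @export
projected_activity <- function(decision, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(decision$weights))
    stop("feature dimension mismatch: ", ncol(X), " vs ",
         length(decision$weights))
  Xs <- sweep(sweep(X, 2L, decision$center), 2L, decision$scale, "/")
  as.numeric(Xs %*% decision$weights + decision$bias) /
    sqrt(sum(decision$weights^2))
}

#' Decoding AUC for present versus absent projections
#'
#' @param proj_present,proj_absent projected activities of
#'   stimulus-present and stimulus-absent trials.
#' @return Rank-based AUC (see [report_auc()]).
#' @export
decode_auc <- function(proj_present, proj_absent) {
  report_auc(c(proj_present, proj_absent),
             c(rep(TRUE, length(proj_present)),
               rep(FALSE, length(proj_absent))))
}

block_folds <- function(blocks, folds, seed) {
  ub <- sort(unique(blocks))
  if (length(ub) < folds)
    stop("need at least ", folds, " blocks for ", folds, "-fold CV")
  with_seed(seed, {
    shuffled <- sample(ub)
    stats::setNames(rep(seq_len(folds),
                        each = ceiling(length(ub) / folds))[
                          order(match(ub, shuffled))], ub)
  })
}

#' Per-window projected activity via cross-validated decoding
#'
#' For each 30-ms analysis window, epoch samples are averaged into one
#' feature vector per trial, a presence classifier (max-SNR versus
#' noise-only) is trained per cross-validation fold on the training
#' blocks, and every trial of the held-out blocks — all conditions —
#' receives its out-of-fold signed distance. Each trial is tested exactly
#' once (in its own block's fold) and never by a classifier that saw its
#' block. The result is a trial table whose `activity_w<start>` columns
#' hold projected activity, format-identical to scalar (ROI-averaged)
#' input for the downstream model fitting.
#'
#' @param epochs an [epoch_array()] for one participant.
#' @param table the matching trial-table rows (`trial_index` matching
#'   `epochs$trial_ids`).
#' @param design a [design_grid()].
#' @param windows window starts (ms); default all windows covered by the
#'   epochs in 30-ms steps from the table's activity columns, else from 0.
#' @param folds number of block folds (default 10).
#' @param seed integer seed for the block shuffle.
#' @param C classifier regularization.
#' @return The table with its `activity_w<start>` columns replaced by
#'   projected activity.
#' @export
project_windows <- function(epochs, table, design, windows = NULL,
                            folds = 10L, seed = 1L, C = 1) {
  stopifnot(inherits(epochs, "epoch_array"))
  ord <- match(table$trial_index, epochs$trial_ids)
  if (anyNA(ord)) stop("trial ids in table and epochs do not match")
  if (is.null(windows)) windows <- activity_windows(table)
  if (length(windows) == 0L) stop("no windows given or derivable")
  fa <- block_folds(table$block, folds, seed)
  is_max <- !is.na(table$snr_db) & table$snr_db == design$maxsnr_db
  is_noise <- is.na(table$snr_db)
  out <- table
  for (w in windows) {
    sel <- epochs$times >= w & epochs$times < w + 30
    if (!any(sel)) stop("window ", w, " ms not covered by epoch times")
    feat <- rowMeans(epochs$data[ord, , sel, drop = FALSE], dims = 2L)
    proj <- rep(NA_real_, nrow(table))
    for (f in sort(unique(fa))) {
      test <- fa[as.character(table$block)] == f
      train <- !test & (is_max | is_noise)
      dec <- train_presence_classifier(feat[train, , drop = FALSE],
                                       is_max[train], C = C)
      proj[test] <- projected_activity(dec, feat[test, , drop = FALSE])
    }
    out[[activity_column(w)]] <- proj
  }
  out
}

decim_factor <- function(times, decim) {
  rate <- 1000 / diff(times[1:2])
  max(1L, as.integer(round(decim * rate / 500)))
}

#' Temporal generalization of presence decoding
#'
#' Classifiers trained at each time sample on the reference contrast
#' (max-SNR present versus absent) are tested at every time sample and
#' every SNR, under block-respecting cross-validation: per (train time,
#' test time, SNR), the AUC of held-out projections for present-at-SNR
#' versus absent trials, averaged over folds. Decimation is expressed
#' relative to the 500 Hz acquisition rate (`decim = 5` targets 100 Hz;
#' epochs already at 100 Hz are used as is).
#'
#' Passing `epochs_test`/`table_test` from another session trains on all
#' eligible trials of the first session and tests on the second
#' (cross-session generalization); `folds` is then ignored.
#'
#' @param epochs,table an [epoch_array()] and matching trial table
#'   (one participant).
#' @param design a [design_grid()].
#' @param folds block folds (default 10).
#' @param decim decimation factor relative to 500 Hz (default 5).
#' @param seed integer seed.
#' @param C classifier regularization.
#' @param epochs_test,table_test optional held-out session.
#' @return List of class `"temporal_generalization"`: `auc` — array
#'   train_time x test_time x snr; `times` — the decimated sample times;
#'   `snr_levels`.
#' @export
temporal_generalization <- function(epochs, table, design, folds = 10L,
                                    decim = 5L, seed = 1L, C = 1,
                                    epochs_test = NULL, table_test = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  ord <- match(table$trial_index, epochs$trial_ids)
  if (anyNA(ord)) stop("trial ids in table and epochs do not match")
  step <- decim_factor(epochs$times, decim)
  tidx <- seq(1L, length(epochs$times), by = step)
  times <- epochs$times[tidx]
  snr_levels <- design$snr_levels_db
  is_max <- !is.na(table$snr_db) & table$snr_db == design$maxsnr_db
  is_noise <- is.na(table$snr_db)
  cross <- !is.null(epochs_test)
  if (cross) {
    ord2 <- match(table_test$trial_index, epochs_test$trial_ids)
    if (anyNA(ord2)) stop("test trial ids do not match test epochs")
    fold_sets <- list(list(train = seq_len(nrow(table)),
                           test = seq_len(nrow(table_test))))
  } else {
    fa <- block_folds(table$block, folds, seed)
    fold_sets <- lapply(sort(unique(fa)), function(f) {
      test <- which(fa[as.character(table$block)] == f)
      list(train = setdiff(seq_len(nrow(table)), test), test = test)
    })
  }
  nt <- length(tidx)
  auc_sum <- array(0, dim = c(nt, nt, length(snr_levels)))
  auc_n <- array(0L, dim = dim(auc_sum))
  for (fs in fold_sets) {
    tr <- fs$train[is_max[fs$train] | is_noise[fs$train]]
    te <- fs$test
    te_snr <- if (cross) table_test$snr_db[te] else table$snr_db[te]
    te_dat <- if (cross) epochs_test$data[ord2[te], , , drop = FALSE]
              else epochs$data[ord[te], , , drop = FALSE]
    for (i in seq_len(nt)) {
      Xtr <- epochs$data[ord[tr], , tidx[i], drop = TRUE]
      dec <- train_presence_classifier(Xtr, is_max[tr], C = C)
      wv <- dec$weights / dec$scale
      b0 <- dec$bias - sum(dec$center * dec$weights / dec$scale)
      nrm <- sqrt(sum(dec$weights^2))
      for (j in seq_len(nt)) {
        proj <- (te_dat[, , tidx[j]] %*% wv + b0) / nrm
        abs_proj <- proj[is.na(te_snr)]
        if (length(abs_proj) == 0L) next
        for (s in seq_along(snr_levels)) {
          pres <- proj[!is.na(te_snr) & te_snr == snr_levels[s]]
          if (length(pres) == 0L) next
          auc_sum[i, j, s] <- auc_sum[i, j, s] + decode_auc(pres, abs_proj)
          auc_n[i, j, s] <- auc_n[i, j, s] + 1L
        }
      }
    }
  }
  auc <- auc_sum / pmax(auc_n, 1L)
  auc[auc_n == 0L] <- NA_real_
  structure(list(auc = auc, times = times, snr_levels = snr_levels),
            class = "temporal_generalization")
}

#' Group significance mask for AUC maps
#'
#' Two-sided sign test of participant AUCs against chance (0.5) per cell
#' (ties dropped; `p = min(1, 2 P(Binom(n, 1/2) <= min(k, n - k)))`), with
#' BH-FDR correction across all cells of the map. At least 6 participants
#' are required — below that a two-sided sign test cannot reach p < 0.05.
#'
#' @param auc_maps list of equal-dimension numeric arrays (one per
#'   participant), or an array whose first dimension is participants.
#' @param q FDR level (default 0.05).
#' @return List: `p` (array of sign-test p-values), `p_adjusted`,
#'   `mask` (logical array, `p_adjusted <= q`), `n_above`, `n_used`.
#' @export
group_sig_mask <- function(auc_maps, q = 0.05) {
  if (is.list(auc_maps)) {
    dims <- dim(auc_maps[[1]]) %||% length(auc_maps[[1]])
    arr <- array(unlist(auc_maps), dim = c(dims, length(auc_maps)))
    np <- length(auc_maps)
    perm <- c(length(dim(arr)), seq_len(length(dim(arr)) - 1L))
    arr <- aperm(arr, perm)
  } else { arr <- auc_maps; np <- dim(arr)[1] }
  if (np < 6L) stop("need at least 6 participants for the sign test")
  cell_dims <- dim(arr)[-1]
  flat <- matrix(arr, nrow = np)
  pv <- apply(flat, 2L, function(a) {
    a <- a[!is.na(a) & a != 0.5]
    n <- length(a)
    if (n == 0L) return(NA_real_)
    k <- sum(a > 0.5)
    min(1, 2 * stats::pbinom(min(k, n - k), n, 0.5))
  })
  n_above <- apply(flat, 2L, function(a) sum(a > 0.5, na.rm = TRUE))
  n_used <- apply(flat, 2L, function(a) sum(!is.na(a) & a != 0.5))
  adj <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  adj[ok] <- bh_fdr(pv[ok], q)$p_adjusted
  shape <- function(v) array(v, dim = cell_dims)
  list(p = shape(pv), p_adjusted = shape(adj),
       mask = shape(!is.na(adj) & adj <= q),
       n_above = shape(n_above), n_used = shape(n_used))
}
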