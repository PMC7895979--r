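make_clouds <- function(n = 60, sep = 6, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  y <- rep(c(TRUE, FALSE), each = n)
  X[y, 1] <- X[y, 1] + sep
  list(X = X, y = y)
}

test_that("the presence classifier separates clouds and respects the ridge geometry", {
  cl <- make_clouds()
  dec <- train_presence_classifier(cl$X, cl$y)
  proj <- projected_activity(dec, cl$X)
  expect_equal(decode_auc(proj[cl$y], proj[!cl$y]), 1)
  # duplicating a feature leaves predictions unchanged (penalty splits weight)
  Xd <- cbind(cl$X, cl$X[, 1])
  decd <- train_presence_classifier(Xd, cl$y)
  pd <- projected_activity(decd, Xd)
  expect_gt(cor(proj, pd), 0.999)
  expect_error(train_presence_classifier(cl$X, rep(TRUE, nrow(cl$X))),
               "both classes")
  # shuffled labels decode at chance on held-out data
  set.seed(2)
  ys <- sample(cl$y)
  half <- seq_len(nrow(cl$X)) <= nrow(cl$X) / 2
  decs <- train_presence_classifier(cl$X[half, ], ys[half])
  ps <- projected_activity(decs, cl$X[!half, ])
  expect_lt(abs(report_auc(ps, ys[!half]) - 0.5), 0.2)
})

test_that("projected activity is the signed Euclidean distance to the boundary", {
  cl <- make_clouds(p = 5)
  dec <- train_presence_classifier(cl$X, cl$y)
  # algebraic oracle in the standardized space
  Xs <- sweep(sweep(cl$X, 2, dec$center), 2, dec$scale, "/")
  oracle <- as.numeric(Xs %*% dec$weights + dec$bias) /
    sqrt(sum(dec$weights^2))
  expect_equal(projected_activity(dec, cl$X), oracle, tolerance = 1e-12)
  # a boundary point projects to zero
  xs_b <- -dec$bias * dec$weights / sum(dec$weights^2)
  xb <- xs_b * dec$scale + dec$center
  expect_equal(projected_activity(dec, matrix(xb, 1)), 0,
               tolerance = 1e-10)
  # reflection through the boundary flips the sign
  xs_p <- xs_b + dec$weights            # off-boundary point
  xs_m <- xs_b - dec$weights            # its mirror image
  pp <- projected_activity(dec, matrix(xs_p * dec$scale + dec$center, 1))
  pm <- projected_activity(dec, matrix(xs_m * dec$scale + dec$center, 1))
  expect_equal(pp, -pm, tolerance = 1e-10)
  expect_error(projected_activity(dec, cl$X[, 1:3]), "dimension mismatch")
})

test_that("per-window projection tests every trial exactly once, out of fold", {
  d <- tiny_design(trials_per_level = 20L, n_participants = 1L,
                   n_blocks = 10L)
  sc <- bifurcation_scenario(design = d, windows = c(0, 30))
  tab <- generate_dataset(sc, seed = 3)
  ep <- generate_epochs(tab, topo_config(n_channels = 16,
                                         topography = c(rep(1, 4),
                                                        rep(0, 12)),
                                         noise_sd = 0.5), seed = 4)
  ptab <- project_windows(ep, tab, d, folds = 10, seed = 5)
  expect_false(anyNA(ptab$activity_w0))
  expect_false(anyNA(ptab$activity_w30))
  # projections track the generating scalar activity
  expect_gt(cor(ptab$activity_w30, tab$activity_w30), 0.8)
  # metadata untouched
  expect_identical(ptab$snr_db, tab$snr_db)
})

test_that("temporal generalization exposes sustained versus sequential codes", {
  # one condition (-5 dB) versus noise-only, two analysis windows
  d <- design_grid(-5, trials_per_level = 60L, n_participants = 1L,
                   n_blocks = 10L)
  n <- 2 * 60
  set.seed(6)
  snr <- sample(rep(c(NA, -5), each = 60))
  tab <- data.frame(participant = "p01", session = "active",
                    block = rep(1:10, each = 12), trial_index = 1:n,
                    snr_db = snr)
  times <- seq(0, 190, by = 10)   # 100 Hz, 20 samples
  nch <- 8
  topoA <- c(1, 1, 0, 0, 0, 0, 0, 0)
  topoB <- c(0, 0, 1, 1, 0, 0, 0, 0)
  winA <- times < 100; winB <- times >= 100
  mk_ep <- function(sustained) {
    arr <- array(rnorm(n * nch * length(times), 0, 0.4),
                 c(n, nch, length(times)))
    amp <- ifelse(is.na(snr), 0, 2)
    for (tr in seq_len(n)) {
      arr[tr, , winA] <- arr[tr, , winA] + topoA * amp[tr]
      arr[tr, , winB] <- arr[tr, , winB] +
        (if (sustained) topoA else topoB) * amp[tr]
    }
    epoch_array(arr, times, sprintf("ch%d", 1:nch), tab$trial_index)
  }
  tg_seq <- temporal_generalization(mk_ep(FALSE), tab, d, folds = 10,
                                    decim = 5, seed = 7)
  expect_identical(tg_seq$times, times)   # decim 5 at 100 Hz: identity
  aucs <- tg_seq$auc[, , 1]
  iA <- which(winA); iB <- which(winB)
  expect_gt(mean(aucs[iA, iA]), 0.95)     # within-code generalization
  expect_gt(mean(aucs[iB, iB]), 0.95)
  expect_lt(mean(aucs[iA, iB]), 0.65)     # orthogonal code: chance
  expect_lt(mean(aucs[iB, iA]), 0.65)
  tg_sus <- temporal_generalization(mk_ep(TRUE), tab, d, folds = 10,
                                    decim = 5, seed = 7)
  expect_gt(mean(tg_sus$auc[, , 1]), 0.95)  # near-square block
})

test_that("decoders generalize across sessions when the code is shared", {
  d <- design_grid(-5, trials_per_level = 40L, n_participants = 1L,
                   n_blocks = 8L)
  n <- 80
  set.seed(9)
  mk <- function(seed, session) {
    set.seed(seed)
    snr <- sample(rep(c(NA, -5), each = 40))
    tab <- data.frame(participant = "p01", session = session,
                      block = rep(1:8, each = 10), trial_index = 1:n,
                      snr_db = snr)
    times <- seq(0, 90, by = 10)
    topo <- c(1, 1, 0, 0)
    arr <- array(rnorm(n * 4 * 10, 0, 0.4), c(n, 4, 10))
    amp <- ifelse(is.na(snr), 0, 2)
    for (tr in 1:n) arr[tr, , ] <- arr[tr, , ] + topo %o% rep(amp[tr], 10)
    list(tab = tab, ep = epoch_array(arr, times, paste0("ch", 1:4), 1:n))
  }
  act <- mk(1, "active"); pas <- mk(2, "passive")
  tg <- temporal_generalization(act$ep, act$tab, d, decim = 5, seed = 3,
                                epochs_test = pas$ep, table_test = pas$tab)
  expect_gt(mean(tg$auc[, , 1]), 0.9)
})

test_that("group significance masks use the exact two-sided sign test with FDR", {
  maps <- lapply(1:20, function(i) array(0.7, c(2, 2)))
  res <- group_sig_mask(maps)
  expect_equal(res$p[1, 1], 2 * 0.5^20)
  expect_true(all(res$mask))
  # exactly half above chance: p = 1
  maps2 <- lapply(1:20, function(i) array(if (i <= 10) 0.7 else 0.3, 1))
  res2 <- group_sig_mask(maps2)
  expect_equal(res2$p[1], 1)
  expect_false(res2$mask[1])
  # ties at exactly 0.5 are dropped
  maps3 <- lapply(1:20, function(i) array(if (i <= 12) 0.7 else 0.5, 1))
  expect_equal(group_sig_mask(maps3)$n_used[1], 12)
  expect_error(group_sig_mask(maps[1:5]), "at least 6")
})

test_that("null AUC maps stay below the FDR level", {
  set.seed(8)
  maps <- lapply(1:20, function(i)
    array(0.5 + rnorm(25, 0, 0.05), c(5, 5)))
  res <- group_sig_mask(maps)
  expect_lte(mean(res$mask), 0.05)
})
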