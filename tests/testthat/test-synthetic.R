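test_that("the default design matches the experimental protocol", {
  d <- default_design()
  expect_equal(d$maxsnr_db, -5)
  expect_equal(d$snr_levels_db, c(-13, -11, -9, -7, -5))
  expect_equal(d$trials_per_level, 160L)
  expect_equal(d$n_participants, 20L)
  expect_true(d$include_noise)
  dp <- default_design("passive")
  expect_equal(dp$snr_levels_db, c(-13, -11, -9, -7, -5, -3))
  expect_error(design_grid(c(-5, -13)), "strictly increasing")
})

test_that("population draws respect dispersions and always validate", {
  d <- tiny_design()
  h0 <- population_hyper("bifurcation",
    means = c(sigma = 1, k = 1.2, threshsnr = -9, mu_noise = 0,
              step = 0.5, L_high = 3, k_high = 1.2),
    sds = c(sigma = 0, k = 0, threshsnr = 0, mu_noise = 0, step = 0,
            L_high = 0, k_high = 0))
  pars <- draw_population_params(h0, d, 5, seed = 1)
  for (p in pars) expect_equal(as.numeric(p), as.numeric(pars[[1]]))

  h <- default_hyper("bifurcation")
  pars <- draw_population_params(h, d, 200, seed = 2)
  th <- vapply(pars, function(p) p[["threshsnr"]], 0)
  se <- h$sds[["threshsnr"]] / sqrt(200)
  expect_lt(abs(mean(th) - h$means[["threshsnr"]]), 4 * se)
  for (p in pars[1:20])
    expect_true(isTRUE(valid_params("bifurcation", p, d)))
})

test_that("generated experiments have exact counts, contiguous blocks and ground truth", {
  d <- tiny_design(trials_per_level = 24L, n_blocks = 6L,
                   n_participants = 3L)
  sc <- switch_scenario(design = d, windows = c(-30, 0, 30), switch_ms = 30)
  tab <- generate_dataset(sc, seed = 5)
  expect_equal(nrow(tab), 3 * 6 * 24)
  for (p in unique(tab$participant)) {
    cnt <- table(condition_token(tab$snr_db[tab$participant == p]))
    expect_true(all(cnt == 24L))
    blk <- tab$block[tab$participant == p]
    expect_true(all(diff(match(blk, unique(blk))) >= 0))  # contiguous
  }
  gt <- attr(tab, "ground_truth")
  expect_length(gt, 3)
  expect_s3_class(gt$p01$bifurcation, "model_params")
  expect_true(all(tab$latent_state %in% c("high", "low")))
  # same seed, bit-identical table
  tab2 <- generate_dataset(sc, seed = 5)
  expect_identical(tab, tab2)
  # ground truth round-trips through the serializer
  path <- tempfile(fileext = ".json"); on.exit(unlink(path))
  write_params(gt, path)
  expect_equal(read_params(path)$p01$bifurcation, gt$p01$bifurcation)
})

test_that("report linking ties heard labels to the lapsed latent state", {
  d <- design_grid(-9, trials_per_level = 160L, n_participants = 1L,
                   n_blocks = 5L)
  h <- population_hyper("bifurcation",
    means = c(sigma = 1, k = 1.2, threshsnr = -9, mu_noise = 0,
              step = 0.5, L_high = 3, k_high = 1.2),
    sds = c(sigma = 0, k = 0, threshsnr = 0, mu_noise = 0, step = 0,
            L_high = 0, k_high = 0))
  # lapse 0: heard flag equals the latent high-state flag exactly
  sc0 <- bifurcation_scenario(design = d, windows = c(300, 330),
                              hyper = list(bifurcation = h),
                              linking = list(lapse_rate = 0))
  tab0 <- generate_dataset(sc0, seed = 6)
  expect_identical(tab0$heard, tab0$latent_state == "high")
  # degenerate unheard component pins low-state ratings
  sc00 <- bifurcation_scenario(design = d, windows = c(300, 330),
                               hyper = list(bifurcation = h),
                               linking = list(lapse_rate = 0,
                                              audibility_unheard =
                                                c(mean = 0, sd = 0)))
  tab00 <- generate_dataset(sc00, seed = 7)
  expect_true(all(tab00$audibility[tab00$latent_state == "low"] == 0))
  # default lapse: heard fraction at threshold near one half
  sc <- bifurcation_scenario(design = d, windows = c(300, 330),
                             hyper = list(bifurcation = h))
  tab <- generate_dataset(sc, seed = 8)
  at_thresh <- tab$heard[!is.na(tab$snr_db)]
  expect_lt(abs(mean(at_thresh) - 0.5),
            2.58 * sqrt(0.25 / length(at_thresh)) + 0.02)
})

test_that("audibility ratings at threshold are bimodal around the 30% criterion", {
  d <- design_grid(-9, trials_per_level = 160L, n_participants = 10L,
                   n_blocks = 5L)
  sc <- bifurcation_scenario(design = d, windows = c(300, 330))
  tab <- generate_dataset(sc, seed = 9)
  dens <- density(tab$audibility, from = 0, to = 100, n = 201)
  modes <- local_maxima(dens$y)
  expect_gte(length(modes), 2)
  expect_true(any(dens$x[modes] < 30) && any(dens$x[modes] > 30))
  expect_true(all(tab$audibility >= 0 & tab$audibility <= 100))
})

test_that("passive sessions carry well-formed mind-wandering probe labels", {
  d <- tiny_design(trials_per_level = 20L)
  sc <- bifurcation_scenario(design = d, windows = c(300, 330),
                             session = "passive")
  tab <- generate_dataset(sc, seed = 10)
  expect_true(all(tab$probe_label %in%
                    c("sound", "task", "thoughts", "nothing")))
  expect_null(tab$audibility)
  # high-state trials mostly report the sound (lapse 0.1)
  frac <- mean(tab$probe_label[tab$latent_state == "high"] == "sound")
  expect_gt(frac, 0.8)
})

test_that("synthetic epochs follow the forward model", {
  d <- tiny_design(trials_per_level = 4L, n_participants = 1L)
  sc <- bifurcation_scenario(design = d, windows = c(0, 30))
  tab <- generate_dataset(sc, seed = 11)
  cfg <- topo_config(n_channels = 64, topography = c(1, rep(0, 63)),
                     noise_sd = 0)
  ep <- generate_epochs(tab, cfg, seed = 1)
  expect_equal(dim(ep$data), c(nrow(tab), 64, 250))
  expect_equal(ep$times, seq(-500, 1990, by = 10))
  # zero noise, one active channel: epoch equals activity on that channel
  i30 <- which(ep$times >= 30 & ep$times < 60)
  expect_equal(ep$data[3, 1, i30],
               rep(tab$activity_w30[3], length(i30)))
  expect_true(all(ep$data[, 2, ] == 0))
  # samples outside every window carry no signal
  expect_true(all(ep$data[, 1, ep$times < 0] == 0))
  # signal scales linearly with the topography
  cfg2 <- topo_config(n_channels = 64, topography = c(2, rep(0, 63)),
                      noise_sd = 0)
  ep2 <- generate_epochs(tab, cfg2, seed = 1)
  expect_equal(ep2$data[, 1, ], 2 * ep$data[, 1, ])
})
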