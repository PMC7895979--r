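#' Default experimental design
#'
#' The near-threshold auditory detection design: five SNR levels
#' (-13, -11, -9, -7, -5 dB) plus a noise-only condition, 160 trials per
#' condition, 20 participants, 20 blocks. The passive variant adds a
#' -3 dB level.
#'
#' @param session `"active"` or `"passive"`.
#' @return A [design_grid()].
#' @export
default_design <- function(session = c("active", "passive")) {
  session <- match.arg(session)
  levels <- c(-13, -11, -9, -7, -5)
  if (session == "passive") levels <- c(levels, -3)
  design_grid(levels, include_noise = TRUE, trials_per_level = 160L,
              n_participants = 20L, n_blocks = 20L)
}

#' Population hyperparameters for a model family
#'
#' Per-parameter population means and dispersions from which
#' participant-level parameter vectors are drawn (independent normals,
#' redrawn until the vector is valid for the design).
#'
#' @param model model identifier.
#' @param means,sds named numeric vectors over the model's parameters.
#' @return Object of class `"population_hyper"`.
#' @export
population_hyper <- function(model, means, sds) {
  model <- model_id(model)
  want <- MODEL_PARAM_NAMES[[model]]
  stopifnot(setequal(names(means), want), setequal(names(sds), want),
            all(sds[want] >= 0))
  structure(list(model = model, means = means[want], sds = sds[want]),
            class = "population_hyper")
}

#' Default population hyperparameters
#'
#' Values chosen to emulate a realistic near-threshold experiment in
#' arbitrary activity units with baseline SD about 1: threshold near the
#' central design level (-9 dB), high-state separation of about 2 SD at
#' threshold, and mild inter-participant dispersion.
#'
#' @param model model identifier.
#' @return A [population_hyper()].
#' @export
default_hyper <- function(model) {
  model <- model_id(model)
  switch(model,
    null = population_hyper("null",
      means = c(mu = 0, sigma = 1),
      sds = c(mu = 0.1, sigma = 0.1)),
    linear = population_hyper("linear",
      means = c(slope = 0.25, mu_maxsnr = 2, mu_noise = 0,
                slope_sigma = 0.15, intercept_sigma = 1),
      sds = c(slope = 0.05, mu_maxsnr = 0.3, mu_noise = 0.2,
              slope_sigma = 0.05, intercept_sigma = 0.1)),
    nonlinear = population_hyper("nonlinear",
      means = c(k = 1.2, threshsnr = -9, mu_maxsnr = 2, L = 3,
                slope_sigma = 0.15, intercept_sigma = 1),
      sds = c(k = 0.2, threshsnr = 1, mu_maxsnr = 0.3, L = 0.5,
              slope_sigma = 0.05, intercept_sigma = 0.1)),
    bifurcation = population_hyper("bifurcation",
      means = c(sigma = 1, k = 1.2, threshsnr = -9, mu_noise = 0,
                step = 0.5, L_high = 3, k_high = 1.2),
      sds = c(sigma = 0.1, k = 0.2, threshsnr = 1, mu_noise = 0.2,
              step = 0.15, L_high = 0.5, k_high = 0.3))
  )
}

#' Draw participant-level parameters from a population
#'
#' Independent normal draws per parameter; a vector failing the model's
#' validity check on the design (e.g. negative SDs) is redrawn, up to 100
#' attempts per participant.
#'
#' @param hyper a [population_hyper()].
#' @param design a [design_grid()].
#' @param n number of participants.
#' @param seed integer seed (optional; draws from the current RNG stream
#'   when `NULL`).
#' @return List of `n` [model_params] vectors.
#' @export
draw_population_params <- function(hyper, design, n, seed = NULL) {
  stopifnot(inherits(hyper, "population_hyper"))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(100L)) {
        v <- stats::rnorm(length(hyper$means), hyper$means, hyper$sds)
        names(v) <- names(hyper$means)
        p <- new_params(hyper$model, v)
        if (isTRUE(valid_params(hyper$model, p, design))) return(p)
      }
      stop("could not draw valid parameters for model '", hyper$model,
           "' after 100 attempts")
    })
  })
}

#' Synthetic experiment scenarios
#'
#' A scenario specifies, per 30-ms analysis window, which generative model
#' produces the activity, plus the population hyperparameters and the
#' report linking model. The stock scenarios are:
#'
#' * `unimodal_scenario()` — every post-stimulus window generated by a
#'   unimodal model (`"nonlinear"` by default, or `"linear"`),
#'   pre-stimulus windows by the null model;
#' * `bifurcation_scenario()` — post-stimulus windows generated by the
#'   bifurcation model (one latent high/low state per trial, shared by all
#'   bifurcation windows);
#' * `switch_scenario()` — unimodal non-linear dynamics up to `switch_ms`,
#'   bifurcation dynamics from `switch_ms` on: the regime change the
#'   analysis pipeline is designed to detect.
#'
#' The report linking model (invented for the generator; real reports are
#' observed, not modelled) applies a lapse to the trial's latent state and
#' draws an audibility rating from a truncated normal: heard-side draws
#' from `audibility_heard` truncated to \[30, 100\], unheard-side from
#' `audibility_unheard` truncated to \[0, 30). The `heard` flag (rating
#' >= 30) therefore equals the lapsed latent state exactly, and the rating
#' distribution at threshold is bimodal with modes on either side of 30.
#'
#' @param design a [design_grid()].
#' @param windows numeric vector of 30-ms window starts (ms); default
#'   `seq(-90, 570, by = 30)` (a 90-ms pre-stimulus baseline and 660 ms of
#'   post-stimulus response).
#' @param model unimodal family for `unimodal_scenario`.
#' @param switch_ms latency (ms) of the unimodal-to-bifurcation switch.
#' @param hyper named list of [population_hyper()] overrides per model.
#' @param linking list with `lapse_rate`, `audibility_heard` (mean, sd in
#'   %), `audibility_unheard`.
#' @param report_window window start (ms) whose latent state defines the
#'   behavioral report (default 300).
#' @param session `"active"` (audibility ratings) or `"passive"`
#'   (mind-wandering probe labels).
#' @return Object of class `"scenario"`.
#' @name scenarios
NULL

default_linking <- function() {
  list(lapse_rate = 0.1,
       audibility_heard = c(mean = 60, sd = 15),
       audibility_unheard = c(mean = 5, sd = 7))
}

new_scenario <- function(design, windows, generating, hyper, linking,
                         report_window, session) {
  stopifnot(length(generating) == length(windows))
  families <- unique(generating)
  h <- lapply(families, function(m) hyper[[m]] %||% default_hyper(m))
  names(h) <- families
  lk <- utils::modifyList(default_linking(), linking %||% list())
  stopifnot(lk$lapse_rate >= 0, lk$lapse_rate <= 1)
  if (!report_window %in% windows) report_window <- windows[
    which.min(abs(windows - report_window))]
  structure(list(design = design, windows = windows,
                 generating = generating, hyper = h, linking = lk,
                 report_window = report_window, session = session),
            class = "scenario")
}

#' @rdname scenarios
#' @export
unimodal_scenario <- function(design = default_design(),
                              windows = seq(-90, 570, by = 30),
                              model = "nonlinear", hyper = list(),
                              linking = list(), report_window = 300,
                              session = "active") {
  model <- model_id(model)
  gen <- ifelse(windows < 0, "null", model)
  new_scenario(design, windows, gen, hyper, linking, report_window, session)
}

#' @rdname scenarios
#' @export
bifurcation_scenario <- function(design = default_design(),
                                 windows = seq(-90, 570, by = 30),
                                 hyper = list(), linking = list(),
                                 report_window = 300, session = "active") {
  gen <- ifelse(windows < 0, "null", "bifurcation")
  new_scenario(design, windows, gen, hyper, linking, report_window, session)
}

#' @rdname scenarios
#' @export
switch_scenario <- function(design = default_design(),
                            windows = seq(-90, 570, by = 30),
                            switch_ms = 300, hyper = list(),
                            linking = list(), report_window = 300,
                            session = "active") {
  gen <- ifelse(windows < 0, "null",
                ifelse(windows < switch_ms, "nonlinear", "bifurcation"))
  new_scenario(design, windows, gen, hyper, linking, report_window, session)
}

#' @exportS3Method base::print
print.scenario <- function(x, ...) {
  cat("Synthetic scenario (", x$session, " session)\n", sep = "")
  cat("  windows:", length(x$windows), "x 30 ms, from",
      min(x$windows), "to", max(x$windows) + 30, "ms\n")
  rl <- rle(x$generating)
  cat("  generating:", paste(sprintf("%s x%d", rl$values, rl$lengths),
                             collapse = ", "), "\n")
  cat("  report window:", x$report_window, "ms; lapse rate:",
      x$linking$lapse_rate, "\n")
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a complete synthetic experiment
#'
#' Draws participant-level parameters from the scenario's population
#' hyperparameters, assigns trials (every condition exactly
#' `trials_per_level` times per participant, order randomized, blocks as
#' contiguous chunks), samples per-window activity from the window's
#' generating model, and attaches behavioral reports. For bifurcation
#' windows a single latent high/low state is drawn per trial (from the
#' participant's `beta(snr)`) and shared by all bifurcation windows of that
#' trial — the all-or-none character of the late response.
#'
#' @param scenario a [scenarios] object.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return Data frame (trial table) with columns `participant`, `session`,
#'   `block`, `trial_index`, `snr_db`, one `activity_w<start>` column per
#'   window, `latent_state`, and the report fields from
#'   [attach_reports()]. The per-participant ground-truth parameters are
#'   attached as attribute `"ground_truth"` (a list
#'   `[[participant]][[model]]`).
#' @export
generate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "scenario"))
  d <- scenario$design
  conds <- design_conditions(d)
  n_trials <- length(conds) * d$trials_per_level
  with_seed(seed, {
    truth <- list()
    tabs <- list()
    for (pid in seq_len(d$n_participants)) {
      params <- lapply(scenario$hyper, function(h)
        draw_population_params(h, d, 1L)[[1L]])
      truth[[sprintf("p%02d", pid)]] <- params
      snr <- sample(rep(conds, each = d$trials_per_level))
      block <- rep(seq_len(d$n_blocks),
                   each = ceiling(n_trials / d$n_blocks))[seq_len(n_trials)]
      tab <- data.frame(participant = sprintf("p%02d", pid),
                        session = scenario$session,
                        block = block, trial_index = seq_len(n_trials),
                        snr_db = snr)
      has_bif <- "bifurcation" %in% scenario$generating
      if (has_bif) {
        bp <- params[["bifurcation"]]
        state_hi <- stats::runif(n_trials) < high_state_prob(bp, snr)
      } else state_hi <- rep(NA, n_trials)
      for (i in seq_along(scenario$windows)) {
        gm <- scenario$generating[i]
        col <- activity_column(scenario$windows[i])
        if (gm == "bifurcation") {
          bp <- params[["bifurcation"]]
          mu <- ifelse(state_hi, model_mu("bifurcation", bp, snr, d),
                       bp[["mu_noise"]])
          tab[[col]] <- stats::rnorm(n_trials, mu, bp[["sigma"]])
        } else {
          p <- params[[gm]]
          tab[[col]] <- stats::rnorm(n_trials, model_mu(gm, p, snr, d),
                                     model_sigma(gm, p, snr, d))
        }
      }
      tab$latent_state <- if (has_bif) ifelse(state_hi, "high", "low")
                          else "n/a"
      tabs[[pid]] <- tab
    }
    out <- do.call(rbind, tabs)
    out <- attach_reports(out, scenario)
    attr(out, "ground_truth") <- truth
    attr(out, "scenario") <- scenario
    out
  })
}

#' Attach behavioral reports to a trial table
#'
#' Applies the scenario's linking model to the latent state recorded at the
#' report window. Active sessions receive an `audibility` rating in
#' \[0, 100\] (truncated-normal draw from the heard or unheard component
#' after a lapse flip of the state) and the derived `heard` flag
#' (rating >= 30). Passive sessions receive a mind-wandering `probe_label`:
#' `"sound"` for (lapsed) high-state trials, otherwise one of `"task"`,
#' `"thoughts"`, `"nothing"` uniformly.
#'
#' Trials without a latent state (purely unimodal scenarios) get no
#' reports.
#'
#' @param table a trial table with a `latent_state` column.
#' @param scenario a [scenarios] object.
#' @param seed integer seed (optional; default uses the current stream).
#' @return The table with report columns added.
#' @export
attach_reports <- function(table, scenario, seed = NULL) {
  with_seed(seed, {
    n <- nrow(table)
    if (all(table$latent_state == "n/a")) {
      if (scenario$session == "active") {
        table$audibility <- NA_real_; table$heard <- NA
      } else table$probe_label <- "none"
      return(table)
    }
    hi <- table$latent_state == "high"
    lapse <- stats::runif(n) < scenario$linking$lapse_rate
    reported_hi <- xor(hi, lapse)
    if (scenario$session == "active") {
      ah <- scenario$linking$audibility_heard
      au <- scenario$linking$audibility_unheard
      aud <- numeric(n)
      aud[reported_hi] <- rtrunc_norm(sum(reported_hi), ah[["mean"]],
                                      ah[["sd"]], 30, 100)
      aud[!reported_hi] <- rtrunc_norm(sum(!reported_hi), au[["mean"]],
                                       au[["sd"]], 0, 30 - 1e-9)
      table$audibility <- aud
      table$heard <- heard_labels(aud)
    } else {
      lbl <- rep(NA_character_, n)
      lbl[reported_hi] <- "sound"
      k <- sum(!reported_hi)
      lbl[!reported_hi] <- sample(c("task", "thoughts", "nothing"), k,
                                  replace = TRUE)
      table$probe_label <- lbl
    }
    table
  })
}

#' Topography configuration for synthetic epochs
#'
#' Defines the forward model used by [generate_epochs()]: a fixed spatial
#' topography over channels, a temporal envelope over samples, and
#' spatially correlated sensor noise built from a small number of latent
#' noise sources with a fixed random mixing matrix.
#'
#' @param n_channels number of channels (default 64).
#' @param topography numeric vector over channels; default a smooth bump
#'   centered mid-array.
#' @param envelope numeric vector over samples or `NULL` (constant 1).
#' @param noise_sd sensor-noise SD (a.u.).
#' @param n_noise_sources latent noise sources (default 8).
#' @param mixing_seed seed fixing the noise mixing matrix.
#' @return Object of class `"topo_config"`.
#' @export
topo_config <- function(n_channels = 64L, topography = NULL,
                        envelope = NULL, noise_sd = 1,
                        n_noise_sources = 8L, mixing_seed = 99L) {
  if (is.null(topography))
    topography <- exp(-((seq_len(n_channels) - n_channels / 2)^2) /
                        (2 * (n_channels / 8)^2))
  stopifnot(length(topography) == n_channels)
  structure(list(n_channels = as.integer(n_channels),
                 topography = topography, envelope = envelope,
                 noise_sd = noise_sd,
                 n_noise_sources = as.integer(n_noise_sources),
                 mixing_seed = as.integer(mixing_seed)),
            class = "topo_config")
}

#' Synthetic multichannel epochs from a trial table
#'
#' Forward model for the decoding stage:
#' `epoch(channel, t) = activity(window(t)) * topography(channel) *
#' envelope(t) + correlated noise`, sampled at 100 Hz from -500 to
#' +1990 ms (250 samples). Samples outside every analysis window carry no
#' signal.
#'
#' @param table trial table rows for a single participant, with
#'   `activity_w<start>` columns.
#' @param config a [topo_config()].
#' @param seed integer seed for the noise draws.
#' @return An `epoch_array` (see [epoch_array()]).
#' @export
generate_epochs <- function(table, config = topo_config(), seed = 1L) {
  stopifnot(length(unique(table$participant)) == 1L)
  windows <- activity_windows(table)
  times <- seq(-500, 1990, by = 10)
  ns <- length(times); nch <- config$n_channels; ntr <- nrow(table)
  env <- config$envelope %||% rep(1, ns)
  stopifnot(length(env) == ns)
  # map each sample to its window (NA if outside all windows)
  widx <- rep(NA_integer_, ns)
  for (i in seq_along(windows))
    widx[times >= windows[i] & times < windows[i] + 30] <- i
  act <- as.matrix(table[, activity_column(windows), drop = FALSE])
  sig <- matrix(0, ntr, ns)
  ok <- !is.na(widx)
  sig[, ok] <- act[, widx[ok], drop = FALSE]
  sig <- sweep(sig, 2L, env, "*")
  mix <- with_seed(config$mixing_seed,
    matrix(stats::rnorm(config$n_noise_sources * nch), config$n_noise_sources,
           nch) / sqrt(config$n_noise_sources))
  arr <- array(0, dim = c(ntr, nch, ns))
  with_seed(seed, {
    for (tr in seq_len(ntr)) {
      noise <- if (config$noise_sd > 0)
        config$noise_sd *
          t(mix) %*% matrix(stats::rnorm(config$n_noise_sources * ns),
                            config$n_noise_sources, ns)
      else matrix(0, nch, ns)
      arr[tr, , ] <- outer(config$topography, sig[tr, ]) + noise
    }
  })
  epoch_array(arr, times = times,
              channels = sprintf("ch%02d", seq_len(nch)),
              trial_ids = table$trial_index)
}
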