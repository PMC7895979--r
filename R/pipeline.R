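#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic scenario (or
#' a path to an existing trial table), the analysis windows, model set,
#' fold count, seeds, output directory and stage toggles.
#'
#' @param scenario a [scenarios] object (used by the `simulate` stage), or
#'   `NULL` when `trials_path` is given.
#' @param trials_path optional path to an existing trial-table TSV.
#' @param out_dir output directory.
#' @param models models for the sweep.
#' @param folds cross-validation folds.
#' @param windows window starts (ms); default the scenario's.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param stages stages to run, in order, among `"simulate"`, `"fit"`,
#'   `"compare"`, `"profiles"`, `"predict"`.
#' @param which prediction target (`"heard"` or `"probe_sound"`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = switch_scenario(),
                            trials_path = NULL, out_dir = "bifdyn_run",
                            models = c("null", "nonlinear", "bifurcation"),
                            folds = 5L, windows = NULL, seed = 1L,
                            stages = c("simulate", "fit", "compare",
                                       "profiles", "predict"),
                            which = "heard") {
  stopifnot(!is.null(scenario) || !is.null(trials_path))
  structure(list(scenario = scenario, trials_path = trials_path,
                 out_dir = out_dir, models = models, folds = folds,
                 windows = windows %||% scenario$windows,
                 seed = as.integer(seed), stages = stages, which = which),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cc in names(df)[num]) df[[cc]] <- fmt_num(df[[cc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic experiment),
#' fit (per-participant, per-window model sweep with cross-validation),
#' compare (per-window group Bayesian model selection), profiles
#' (per-participant response profiles at the report window), predict
#' (Bayes-factor report prediction) — writing each stage's table to
#' `out_dir` plus a run manifest (package version, seeds, config hash).
#' Identical configuration and seed give byte-identical outputs. A stage
#' failure aborts with the stage name; tables already written remain.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  seeds <- list(simulate = config$seed, fit = config$seed + 1000L,
                bms = config$seed + 2000L)
  run_stage <- function(name, expr) {
    if (!name %in% config$stages) {
      say("stage '", name, "' disabled; skipped")
      return(NULL)
    }
    say("stage '", name, "' ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$trials <- run_stage("simulate", {
    tab <- generate_dataset(config$scenario, seed = seeds$simulate)
    write_trial_table(tab, file.path(config$out_dir, "trials.tsv"))
    write_params(attr(tab, "ground_truth"),
                 file.path(config$out_dir, "ground_truth.json"))
    tab
  })
  if (is.null(res$trials)) {
    if (is.null(config$trials_path))
      stop("stage 'simulate' disabled and no trials_path given")
    res$trials <- read_trial_table(config$trials_path)
  }
  design <- if (!is.null(config$scenario)) config$scenario$design
            else default_design()

  res$sweep <- run_stage("fit", {
    sw <- fit_window_sweep(res$trials, design, models = config$models,
                           folds = config$folds, seed = seeds$fit,
                           windows = config$windows)
    write_tsv(sw$table, file.path(config$out_dir, "fit.tsv"))
    sw
  })

  res$bms <- run_stage("compare", {
    if (is.null(res$sweep)) stop("requires the fit stage")
    bm <- bms_by_window(res$sweep, seed = seeds$bms)
    write_tsv(bm, file.path(config$out_dir, "bms.tsv"))
    bm
  })

  res$profiles <- run_stage("profiles", {
    w <- if (!is.null(config$scenario)) config$scenario$report_window
         else config$windows[which.min(abs(config$windows - 300))]
    pr <- do.call(rbind, lapply(split(res$trials, res$trials$participant),
      function(pt) {
        ps <- response_profiles(pt, window = w)
        cbind(participant = pt$participant[1], window_start_ms = w,
              as.data.frame(ps))
      }))
    rownames(pr) <- NULL
    write_tsv(pr, file.path(config$out_dir, "profiles.tsv"))
    pr
  })

  res$prediction <- run_stage("predict", {
    if (is.null(res$sweep)) stop("requires the fit stage")
    pred <- predict_timecourse(res$sweep, res$trials, which = config$which)
    write_tsv(pred$group, file.path(config$out_dir, "prediction.tsv"))
    pred
  })

  cfg_json <- jsonlite::toJSON(list(
    models = config$models, folds = config$folds,
    windows = config$windows, stages = config$stages,
    which = config$which, seed = config$seed), auto_unbox = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_path)
  manifest <- list(package = "bifdyn",
                   version = as.character(utils::packageVersion("bifdyn")),
                   seed = config$seed, stage_seeds = seeds,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   stages_run = intersect(config$stages,
                                          c("simulate", "fit", "compare",
                                            "profiles", "predict")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done; outputs in ", config$out_dir)
  invisible(c(res, list(out_dir = config$out_dir)))
}
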