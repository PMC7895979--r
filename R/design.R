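#' Experimental design grid
#'
#' Describes the stimulus design of a near-threshold detection experiment:
#' the ordered signal-to-noise ratio (SNR) levels in dB relative to the
#' masking noise, whether noise-only (stimulus absent) trials are included,
#' and the sampling structure (trials per level, participants, blocks).
#'
#' Throughout the package a stimulus condition is encoded as a numeric SNR
#' in dB, with `NA` standing for the noise-only condition.
#'
#' @param snr_levels_db strictly increasing numeric vector of SNR levels (dB).
#' @param include_noise logical; include a noise-only condition.
#' @param trials_per_level number of trials per condition (>= 1).
#' @param n_participants number of participants.
#' @param n_blocks number of blocks partitioning each participant's trials.
#' @return An object of class `"design_grid"`.
#' @seealso [default_design()]
#' @export
design_grid <- function(snr_levels_db, include_noise = TRUE,
                        trials_per_level = 160L, n_participants = 20L,
                        n_blocks = 20L) {
  snr_levels_db <- as.numeric(snr_levels_db)
  if (length(snr_levels_db) < 1L || anyNA(snr_levels_db))
    stop("'snr_levels_db' must be non-empty and free of NA")
  if (is.unsorted(snr_levels_db, strictly = TRUE))
    stop("'snr_levels_db' must be strictly increasing")
  if (trials_per_level < 1L) stop("'trials_per_level' must be >= 1")
  structure(list(
    snr_levels_db = snr_levels_db,
    include_noise = isTRUE(include_noise),
    maxsnr_db = max(snr_levels_db),
    minsnr_db = min(snr_levels_db),
    trials_per_level = as.integer(trials_per_level),
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks)
  ), class = "design_grid")
}

#' @exportS3Method base::print
print.design_grid <- function(x, ...) {
  cat("Design grid:", length(x$snr_levels_db), "SNR levels (dB):",
      paste(format(x$snr_levels_db), collapse = ", "), "\n")
  cat("  noise-only condition:", if (x$include_noise) "yes" else "no", "\n")
  cat("  trials/level:", x$trials_per_level,
      " participants:", x$n_participants,
      " blocks:", x$n_blocks, "\n")
  invisible(x)
}

#' All conditions of a design
#'
#' @param design a [design_grid()].
#' @return Numeric vector of conditions (dB), `NA` first for noise-only when
#'   present, then SNR levels in increasing order.
#' @export
design_conditions <- function(design) {
  stopifnot(inherits(design, "design_grid"))
  if (design$include_noise) c(NA_real_, design$snr_levels_db)
  else design$snr_levels_db
}

#' Format / parse condition tokens
#'
#' Conditions are serialized as `"noise"` or the SNR in dB with one decimal
#' (e.g. `"-9.0"`).
#'
#' @param snr_db numeric vector of conditions (`NA` = noise-only).
#' @return `condition_token()`: character vector; `parse_condition()`:
#'   numeric vector with `NA` for noise-only.
#' @export
condition_token <- function(snr_db) {
  ifelse(is.na(snr_db), "noise", sprintf("%.1f", snr_db))
}

#' @param token character vector of condition tokens.
#' @rdname condition_token
#' @export
parse_condition <- function(token) {
  token <- trimws(as.character(token))
  out <- rep(NA_real_, length(token))
  is_noise <- token == "noise"
  num <- suppressWarnings(as.numeric(token[!is_noise]))
  if (anyNA(num)) {
    bad <- token[!is_noise][is.na(num)]
    stop("unparseable condition token(s): ",
         paste(unique(bad), collapse = ", "),
         " (expected 'noise' or a dB value)")
  }
  out[!is_noise] <- num
  out
}

check_condition_in_design <- function(snr_db, design) {
  ok <- is.na(snr_db) & design$include_noise |
    (!is.na(snr_db) & snr_db %in% design$snr_levels_db)
  if (!all(ok))
    stop("condition(s) outside the design grid: ",
         paste(unique(condition_token(snr_db[!ok])), collapse = ", "))
  invisible(TRUE)
}
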