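TRIAL_META_COLS <- c("participant", "session", "block", "trial_index",
                     "condition")
TRIAL_OPT_COLS <- c("audibility", "heard", "probe_label", "latent_state")

fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Read and write trial tables
#'
#' Trial tables are tab-separated text with a fixed header: the required
#' columns `participant`, `session`, `block`, `trial_index`, `condition`
#' (token `"noise"` or a dB value), at least one activity column
#' (`activity` or `activity_w<start>`), and optionally `audibility`,
#' `heard`, `probe_label`, `latent_state`. Unknown columns are rejected;
#' schema violations report the offending column or line. Activities are
#' written with 9 significant digits (stable, diff-able output); a
#' read-write cycle is idempotent.
#'
#' In memory the condition is the numeric `snr_db` column (`NA` =
#' noise-only).
#'
#' @param table trial table (data frame with `snr_db`).
#' @param path file path.
#' @return `read_trial_table()`: the trial table; `write_trial_table()`:
#'   `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(all(c("participant", "session", "block", "trial_index")
                %in% names(table)))
  act_cols <- grep("^activity($|_w-?[0-9]+$)", names(table), value = TRUE)
  if (length(act_cols) == 0L) stop("no activity column(s) to write")
  out <- data.frame(participant = table$participant,
                    session = table$session, block = table$block,
                    trial_index = table$trial_index,
                    condition = condition_token(table$snr_db))
  for (cc in act_cols) out[[cc]] <- fmt_num(table[[cc]])
  for (cc in TRIAL_OPT_COLS) if (cc %in% names(table)) {
    out[[cc]] <- if (cc == "audibility") fmt_num(table[[cc]])
                 else as.character(table[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_req <- setdiff(TRIAL_META_COLS, hdr)
  if (length(missing_req))
    stop("trial table schema violation: missing required column(s) ",
         paste(missing_req, collapse = ", "))
  act_cols <- grep("^activity($|_w-?[0-9]+$)", hdr, value = TRUE)
  if (length(act_cols) == 0L)
    stop("trial table schema violation: no activity column ",
         "(activity or activity_w<start>)")
  unknown <- setdiff(hdr, c(TRIAL_META_COLS, act_cols, TRIAL_OPT_COLS))
  if (length(unknown))
    stop("trial table schema violation: unknown column(s) ",
         paste(unknown, collapse = ", "))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  bad <- !(tab$condition == "noise" |
             grepl("^-?[0-9]*\\.?[0-9]+$", tab$condition))
  if (any(bad))
    stop("unparseable condition token(s) at line(s) ",
         paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
         ": ", paste(utils::head(unique(tab$condition[bad]), 5L),
                     collapse = ", "))
  out <- data.frame(participant = tab$participant, session = tab$session,
                    block = tab$block,
                    trial_index = as.integer(tab$trial_index),
                    snr_db = parse_condition(tab$condition))
  for (cc in act_cols) out[[cc]] <- as.numeric(tab[[cc]])
  for (cc in intersect(TRIAL_OPT_COLS, names(tab))) {
    out[[cc]] <- switch(cc,
      audibility = as.numeric(tab[[cc]]),
      heard = as.logical(tab[[cc]]),
      tab[[cc]])
  }
  out
}

#' Read and write epoch arrays
#'
#' Plain-text epoch container: a first line holding a JSON header
#' (`n_trials`, `n_channels`, `n_samples`, `times`, `channels`,
#' `trial_ids`), followed by one tab-separated line of samples per
#' (trial, channel), trial-major. Values carry full double precision, so
#' the round trip is lossless.
#'
#' @param epochs an [epoch_array()].
#' @param path file path.
#' @param table optional trial table to validate alignment against
#'   (`trial_index` must match `trial_ids`).
#' @return `read_epochs()`: an `epoch_array`; `write_epochs()`: `path`,
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  hdr <- jsonlite::toJSON(list(n_trials = d[1], n_channels = d[2],
                               n_samples = d[3], times = epochs$times,
                               channels = epochs$channels,
                               trial_ids = epochs$trial_ids),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      writeLines(paste(sprintf("%.17g", epochs$data[tr, ch, ]),
                       collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) stop("corrupt epoch file header: ",
                                           conditionMessage(e)))
  need <- hdr$n_trials * hdr$n_channels
  if (length(lines) - 1L != need)
    stop("truncated epoch file: expected ", need, " data lines, found ",
         length(lines) - 1L)
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  if (any(lengths(vals) != hdr$n_samples))
    stop("truncated epoch file: ragged sample rows")
  arr <- array(0, dim = c(hdr$n_trials, hdr$n_channels, hdr$n_samples))
  i <- 1L
  for (tr in seq_len(hdr$n_trials))
    for (ch in seq_len(hdr$n_channels)) {
      arr[tr, ch, ] <- vals[[i]]; i <- i + 1L
    }
  ep <- epoch_array(arr, times = as.numeric(hdr$times),
                    channels = as.character(hdr$channels),
                    trial_ids = hdr$trial_ids)
  if (!is.null(table) && !setequal(table$trial_index, ep$trial_ids))
    stop("epoch/table alignment mismatch: trial ids differ")
  ep
}
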