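# Trial-table CSV I/O. On disk, RTs are integer milliseconds (lossless and
# human-readable); in memory they are seconds.

TRIAL_COLS <- c("participant_id", "group", "condition", "stimulus_class",
                "response", "rt_ms", "censored")

#' Read a trial table from CSV
#'
#' Expects the schema `participant_id, group, condition, stimulus_class,
#' response, rt_ms, censored` with `response` and `stimulus_class` drawn from
#' `old`/`new`, positive integer `rt_ms`, and `censored` coded 0/1. RTs are
#' converted to seconds. Validation failures report the offending line
#' numbers.
#'
#' @param path CSV file path.
#' @return A trial tibble (`participant`, `group`, `condition`,
#'   `stimulus_class`, `response`, `rt` in seconds, `censored`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    condition = readr::col_character(),
    stimulus_class = readr::col_character(),
    response = readr::col_character(),
    rt_ms = readr::col_double(),
    censored = readr::col_integer()))
  miss <- setdiff(TRIAL_COLS, names(raw))
  if (length(miss))
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(miss, collapse = ", ")))
  bad_row <- function(cond, what) {
    if (any(cond)) {
      lines <- which(cond) + 1L  # header is line 1
      abort(paste0(what, " at line(s): ",
                   paste(utils::head(lines, 5), collapse = ", "),
                   if (sum(cond) > 5) " ..." else ""))
    }
  }
  bad_row(!is.finite(raw$rt_ms) | raw$rt_ms <= 0 |
            raw$rt_ms != round(raw$rt_ms),
          "`rt_ms` must be a positive integer")
  bad_row(!raw$response %in% c("old", "new"), "Unknown `response` label")
  bad_row(!raw$stimulus_class %in% c("old", "new"),
          "Unknown `stimulus_class` label")
  bad_row(!raw$censored %in% c(0L, 1L), "`censored` must be 0 or 1")
  tibble(participant = raw$participant_id, group = raw$group,
         condition = raw$condition, stimulus_class = raw$stimulus_class,
         response = raw$response, rt = raw$rt_ms / 1000,
         censored = raw$censored == 1L)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: seconds become integer milliseconds (rounded),
#' logical `censored` becomes 0/1, and columns are written in the fixed
#' schema order.
#'
#' @param trials A trial tibble as produced by [generate_experiment()] or
#'   [read_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trial_cols(trials, c("participant", "group", "condition",
                             "stimulus_class", "response", "rt", "censored"))
  out <- tibble(participant_id = trials$participant, group = trials$group,
                condition = trials$condition,
                stimulus_class = trials$stimulus_class,
                response = trials$response,
                rt_ms = as.integer(round(trials$rt * 1000)),
                censored = as.integer(trials$censored))
  readr::write_csv(out, path)
  invisible(path)
}
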