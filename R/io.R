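# CSV readers/writers for behavior logs, surveys and day records, plus
# run configuration and provenance.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

.check_binary_col <- function(x, name, path) {
  bad <- which(!is.na(x) & !(x %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("%s: non-binary value in column '%s' (row %d)",
                 path, name, bad[1L]), call. = FALSE)
  invisible(x)
}

#' Read a behavior log from CSV
#'
#' Expects columns \code{participant_id}, \code{day}, \code{beh}, and
#' optionally \code{cue} (defaults to 1 when absent, matching the
#' stable-context assumption), \code{rem}, \code{lab}. Empty fields
#' are missing; an empty \code{beh} marks an unobserved day. Calendar
#' dates in a \code{date} column are converted to 1-based day indices
#' per participant.
#'
#' @param path CSV file path.
#' @return Validated behavior-log data frame.
#' @export
read_behavior_log <- function(path) {
  df <- .read_csv(path)
  if (!is.null(df$date) && is.null(df$day)) {
    d <- as.Date(df$date)
    if (anyNA(d)) stop(path, ": unparseable dates", call. = FALSE)
    df$day <- as.integer(as.integer(d) -
                           ave(as.integer(d), df$participant_id,
                               FUN = min) + 1L)
    df$date <- NULL
  }
  need <- c("participant_id", "day", "beh")
  if (!all(need %in% names(df)))
    stop(path, ": requires columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$cue)) df$cue <- 1L
  if (is.null(df$rem)) df$rem <- 0L
  if (is.null(df$lab)) df$lab <- 0L
  for (col in c("beh", "cue", "rem", "lab"))
    .check_binary_col(df[[col]], col, path)
  if (anyNA(df$day) || any(df$day < 1))
    stop(path, ": day indices must be positive integers", call. = FALSE)
  df[c("participant_id", "day", "beh", "cue", "rem", "lab")]
}

#' Read weekly surveys from CSV
#'
#' Expects columns \code{participant_id}, \code{day}, \code{srbai},
#' \code{att_instrumental}, \code{att_affective},
#' \code{self_report_rate}. The three scale scores must lie in
#' \eqn{[1, 7]} and the self-reported rate in \eqn{[0, 1]}.
#'
#' @param path CSV file path.
#' @return Validated survey data frame.
#' @export
read_surveys <- function(path) {
  df <- .read_csv(path)
  need <- c("participant_id", "day", "srbai", "att_instrumental",
            "att_affective", "self_report_rate")
  if (!all(need %in% names(df)))
    stop(path, ": requires columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("srbai", "att_instrumental", "att_affective")) {
    x <- df[[col]]
    bad <- which(!is.na(x) & (x < 1 | x > 7))
    if (length(bad))
      stop(sprintf("%s: '%s' outside the 1-7 scale (row %d)", path, col,
                   bad[1L]), call. = FALSE)
  }
  x <- df$self_report_rate
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad))
    stop(sprintf("%s: 'self_report_rate' outside [0, 1] (row %d)", path,
                 bad[1L]), call. = FALSE)
  df[need]
}

#' Write a behavior log / survey table to CSV
#'
#' Inverse of the readers: comma-separated, UTF-8, header row, empty
#' string for missing values.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read episode timestamps from CSV
#'
#' Expects columns \code{participant_id} and \code{start} (ISO 8601
#' date-times).
#'
#' @param path CSV file path.
#' @return Data frame of episodes.
#' @export
read_episodes <- function(path) {
  df <- .read_csv(path)
  if (!all(c("participant_id", "start") %in% names(df)))
    stop(path, ": requires columns participant_id, start", call. = FALSE)
  df
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates top-level keys against the known schema and rejects
#' unknown ones to catch typos early.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("logs", "surveys", "episodes", "output_dir", "mode", "models",
             "k", "seed", "random_steps", "grid_steps", "study", "ridge")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

# Machine-readable provenance: enough to re-execute a run exactly.
.write_provenance <- function(dir, seed, extra = list()) {
  info <- c(list(
    package = "habitcast",
    version = as.character(utils::packageVersion("habitcast")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(info, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(info)
}
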