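# Trial-table CSV I/O with validation.
#
# Columns: trial, task, condition, stimulus, response, outcome, confidence,
# scale. Recall rows leave stimulus/response empty; recognition rows must
# satisfy outcome == (response == stimulus). The scale string must be
# uniform within each (task, condition) block.

.TRIAL_COLS <- c("trial", "task", "condition", "stimulus", "response",
                 "outcome", "confidence", "scale")

#' Validate a trial table
#'
#' Checks column presence, value domains, outcome consistency for
#' recognition rows, scale uniformity per (task, condition) block, and
#' confidence ranges. Errors name the offending row and column.
#'
#' @param trials Data frame to validate.
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(c("task", "outcome", "confidence", "scale"),
                          names(trials))
  if (length(missing_cols))
    .stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  for (col in setdiff(.TRIAL_COLS, names(trials)))
    trials[[col]] <- if (col == "trial") seq_len(nrow(trials)) else NA
  bad <- which(!trials$task %in% c("recall", "recognition"))
  if (length(bad)) .stopf("row %d, column task: invalid value '%s'",
                          bad[1], trials$task[bad[1]])
  bad <- which(!trials$outcome %in% c(0, 1))
  if (length(bad)) .stopf("row %d, column outcome: must be 0 or 1", bad[1])

  recog <- trials$task == "recognition"
  if (any(recog)) {
    bad <- which(recog & (!trials$stimulus %in% c("S1", "S2") |
                            !trials$response %in% c("S1", "S2")))
    if (length(bad))
      .stopf("row %d, column stimulus/response: recognition rows need S1/S2",
             bad[1])
    expected <- as.integer(trials$stimulus[recog] == trials$response[recog])
    bad <- which(recog)[trials$outcome[recog] != expected]
    if (length(bad))
      .stopf("row %d, column outcome: inconsistent with stimulus/response",
             bad[1])
  }

  cond <- ifelse(is.na(trials$condition), "", as.character(trials$condition))
  blocks <- interaction(trials$task, cond, drop = TRUE)
  for (b in levels(blocks)) {
    sel <- blocks == b
    if (length(unique(trials$scale[sel])) > 1L)
      .stopf("mixed scales within block '%s'", b)
    sc <- .parse_scale(trials$scale[which(sel)[1]])
    conf <- trials$confidence[sel]
    if (sc$type == "continuous") {
      bad <- which(sel)[conf < 0 | conf > 1]
      if (length(bad))
        .stopf("row %d, column confidence: outside [0, 1]", bad[1])
    } else {
      bad <- which(sel)[conf != round(conf) | conf < 1 | conf > sc$n]
      if (length(bad))
        .stopf("row %d, column confidence: not an integer in 1..%d",
               bad[1], sc$n)
    }
  }
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' @param path CSV file path (header required).
#' @param percent Divide confidence by 100 first (0-100 percentage scales).
#' @return Validated trial-table data frame.
#' @export
read_trials <- function(path, percent = FALSE) {
  tt <- read.csv(path, stringsAsFactors = FALSE)
  if (percent) tt$confidence <- tt$confidence / 100
  for (col in setdiff(.TRIAL_COLS, names(tt)))
    tt[[col]] <- if (col == "trial") seq_len(nrow(tt)) else NA
  tt <- tt[, .TRIAL_COLS]
  tt$stimulus <- as.character(tt$stimulus)
  tt$response <- as.character(tt$response)
  tt$condition <- as.character(tt$condition)
  validate_trials(tt)
  tt
}

#' Write a trial table to CSV
#'
#' @param trials Trial table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials[, .TRIAL_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

# Structured key-value run configuration (JSON).
.read_config <- function(path, known_keys) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), known_keys)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}
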