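.TRIAL_COLUMNS <- c("individual_id", "eggmass_id", "treatment", "context",
                    "trial", "distance", "svl")

#' Validate a long-format trial table
#'
#' Checks the schema and domain constraints of the behavioural trial format:
#' all required columns present; treatment and context labels among the
#' known levels; trial indices integers in 0--5; distances non-negative and
#' strictly positive in the familiar context (the familiar assay has no
#' hurdle, a zero there has no likelihood); SVL strictly positive.
#'
#' @param trials a data frame.
#' @param n_trials maximum number of trials per context (trial indices must
#'   lie in `0:(n_trials - 1)`).
#' @return `trials` invisibly, with treatment/context coerced to character.
#' @export
validate_trials <- function(trials, n_trials = 6L) {
  if (!is.data.frame(trials)) stop("trials must be a data frame")
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trials is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  trials$treatment <- as.character(trials$treatment)
  trials$context <- as.character(trials$context)
  bad_t <- setdiff(unique(trials$treatment), TREATMENTS)
  if (length(bad_t))
    stop("unknown treatment label(s): ", paste(bad_t, collapse = ", "))
  bad_c <- setdiff(unique(trials$context), CONTEXTS)
  if (length(bad_c))
    stop("unknown context label(s): ", paste(bad_c, collapse = ", "))
  if (!is.numeric(trials$trial) || any(trials$trial != round(trials$trial)) ||
      any(trials$trial < 0) || any(trials$trial > n_trials - 1L))
    stop("trial must be an integer in 0..", n_trials - 1L)
  if (!is.numeric(trials$distance) || any(!is.finite(trials$distance)) ||
      any(trials$distance < 0))
    stop("distance must be finite and non-negative")
  if (any(trials$distance == 0 & trials$context == "familiar"))
    stop("distance must be positive in the familiar context (no hurdle there)")
  if (!is.numeric(trials$svl) || any(!is.finite(trials$svl)) ||
      any(trials$svl <= 0))
    stop("svl must be finite and positive")
  # an individual belongs to exactly one treatment and one egg mass
  tt <- unique(trials[, c("individual_id", "treatment")])
  if (anyDuplicated(tt$individual_id))
    stop("an individual_id appears under more than one treatment")
  te <- unique(trials[, c("individual_id", "eggmass_id")])
  if (anyDuplicated(te$individual_id))
    stop("an individual_id appears under more than one eggmass_id")
  invisible(trials)
}

#' Read and write trial tables as CSV
#'
#' Lossless round-trip of the long-format schema (`individual_id`,
#' `eggmass_id`, `treatment`, `context`, `trial`, `distance`, `svl`), UTF-8
#' with header row and `.` decimal separator.  Exact zeros in `distance`
#' (trials where the individual never left the acclimation zone) are
#' preserved exactly.  [read_trials()] validates on load and fails with a
#' named error on malformed rows.
#'
#' @param trials a validated trial data frame (or the `$trials` component of
#'   an [simulate_trials()] result).
#' @param path file path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "hlmm_sim")) trials <- trials$trials
  validate_trials(trials)
  utils::write.csv(trials[, .TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_trials(df)
  df$trial <- as.integer(df$trial)
  df
}
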