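IPD_COLUMNS <- c("study_id", "drug", "participant_id",
                 "placebo_decline", "drug_decline",
                 "placebo_decline_repeat")
STUDY_COLUMNS <- c("study_id", "drug", "n", "mean_placebo_decline",
                   "mean_drug_decline", "mean_diff", "se_diff")

#' Read and validate an IPD CSV
#'
#' Expects a UTF-8, decimal-point CSV with header columns `study_id`,
#' `drug`, `participant_id`, `placebo_decline`, `drug_decline` and
#' optionally `placebo_decline_repeat` (empty where no repeat placebo test
#' was done). Declines are on the 0-100 pp scale, positive when FEV1 fell
#' (`sign = "fall-positive"`); files that store falls as negative numbers
#' are converted with `sign = "fall-negative"`.
#'
#' @param path Path to the CSV file.
#' @param sign `"fall-positive"` (default) or `"fall-negative"`.
#' @return A validated IPD data.frame (see [simulate_ipd()] for the
#'   contract). Rows with missing required declines or duplicated
#'   `(study_id, participant_id)` pairs raise an error naming the offending
#'   file lines.
#' @export
read_ipd <- function(path, sign = c("fall-positive", "fall-negative")) {
  sign <- match.arg(sign)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(IPD_COLUMNS, "placebo_decline_repeat")
  miss <- setdiff(required, names(df))
  unknown <- setdiff(names(df), IPD_COLUMNS)
  if (length(miss) || length(unknown))
    stop("IPD schema mismatch in '", path, "'",
         if (length(miss)) paste0("; missing columns: ",
                                  paste(miss, collapse = ", ")),
         if (length(unknown)) paste0("; unknown columns: ",
                                     paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!"placebo_decline_repeat" %in% names(df))
    df$placebo_decline_repeat <- NA_real_
  df <- df[IPD_COLUMNS]
  for (col in c("placebo_decline", "drug_decline",
                "placebo_decline_repeat"))
    df[[col]] <- as.numeric(df[[col]])

  bad <- which(!is.finite(df$placebo_decline) | !is.finite(df$drug_decline))
  if (length(bad))
    stop("missing or non-numeric declines in '", path, "' at line",
         if (length(bad) > 1) "s", " ",
         paste(bad + 1L, collapse = ", "),   # +1 for the header line
         call. = FALSE)
  key <- paste(df$study_id, df$participant_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (study_id, participant_id) in '", path, "' at line",
         if (length(dup) > 1) "s", " ", paste(dup + 1L, collapse = ", "),
         call. = FALSE)
  if (sign == "fall-negative") {
    df$placebo_decline <- -df$placebo_decline
    df$drug_decline <- -df$drug_decline
    df$placebo_decline_repeat <- -df$placebo_decline_repeat
  }
  df
}

#' Write an IPD table to CSV
#'
#' @param ipd IPD data.frame.
#' @param path Output path. Missing repeat declines are written as empty
#'   cells.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  check_ipd(ipd)
  if (!"placebo_decline_repeat" %in% names(ipd))
    ipd$placebo_decline_repeat <- NA_real_
  write.csv(ipd[IPD_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a study-level summary CSV
#'
#' Columns: `study_id`, `drug`, `n`, `mean_placebo_decline`,
#' `mean_drug_decline`, `mean_diff` (drug minus placebo, pp), `se_diff`.
#'
#' @param path Path to the CSV file.
#' @return A validated study-summary data.frame.
#' @export
read_study_summaries <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(STUDY_COLUMNS, names(df))
  if (length(miss))
    stop("study summary schema mismatch in '", path, "'; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[STUDY_COLUMNS]
  if (any(df$n < 2))
    stop("studies with n < 2 are not analyzable (SE undefined)",
         call. = FALSE)
  if (any(!is.finite(df$se_diff)) || any(df$se_diff < 0))
    stop("se_diff must be finite and >= 0", call. = FALSE)
  bad <- which(abs(df$mean_diff -
                     (df$mean_drug_decline - df$mean_placebo_decline)) > 1e-6)
  if (length(bad))
    stop("mean_diff inconsistent with the mean declines at line",
         if (length(bad) > 1) "s", " ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a study-level summary table to CSV
#'
#' @param studies Study-summary data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_summaries <- function(studies, path) {
  write.csv(studies[STUDY_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}
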