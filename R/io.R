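#' Trial-table schema columns
#'
#' The single tabular interchange format of the package: UTF-8 CSV with a
#' header row, one row per subject-trial, 1-based trial numbering. Required
#' columns and bounds: `subject_id` (string), `group` (string), `age_years`
#' (real), `trial` (consecutive integers from 1 per subject), `reward_belief`
#' (1--7), `effort_exerted_fraction` (>= 0), `effort_threshold`
#' (0.42--0.92), `reward_magnitude` (integer 1--7), `success` (0/1,
#' consistent with exerted effort vs threshold under the tie-counts-as-
#' success rule). `effort_belief` (0--1) is optional.
#'
#' @name trial_table
#' @keywords internal
NULL

trial_required_cols <- c("subject_id", "group", "age_years", "trial",
                         "reward_belief", "effort_exerted_fraction",
                         "effort_threshold", "reward_magnitude", "success")

# Returns a character vector of row-level violations (empty if clean) and
# the indices of offending rows, as a list.
validate_trial_rows <- function(df) {
  bad <- rep(FALSE, nrow(df))
  msgs <- character(0)
  flag <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      bad[cond & !is.na(cond)] <<- TRUE
      msgs <<- c(msgs, sprintf("%s (%d row(s))", msg, sum(cond, na.rm = TRUE)))
    }
  }
  flag(df$reward_belief < 1 | df$reward_belief > 7,
       "reward_belief outside [1, 7]")
  flag(!df$reward_magnitude %in% 1:7,
       "reward_magnitude outside 1..7")
  flag(df$effort_threshold < 0.42 | df$effort_threshold > 0.92,
       "effort_threshold outside [0.42, 0.92]")
  flag(df$effort_exerted_fraction < 0, "negative effort_exerted_fraction")
  flag(!df$success %in% c(0, 1), "success not 0/1")
  flag(df$success != as.integer(
    df$effort_exerted_fraction >= df$effort_threshold),
    "success inconsistent with exerted effort vs threshold")
  if ("effort_belief" %in% names(df))
    flag(!is.na(df$effort_belief) &
           (df$effort_belief < 0 | df$effort_belief > 1),
         "effort_belief outside [0, 1]")
  for (col in c("age_years", "trial", "reward_belief",
                "effort_exerted_fraction", "effort_threshold",
                "reward_magnitude", "success"))
    flag(is.na(df[[col]]), paste0("missing ", col))
  list(bad = bad, msgs = msgs)
}

#' Read and validate a trial-level CSV
#'
#' In strict mode (the default) any schema violation -- a missing column,
#' an out-of-bounds value, a success flag inconsistent with the effort rule,
#' or a gap in the per-subject trial numbering -- is an error. In lenient
#' mode offending rows are dropped with a message reporting the counts
#' (numbering gaps remain warnings).
#'
#' @param path CSV file path.
#' @param strict Fail on any violation (`TRUE`) or drop offending rows
#'   (`FALSE`).
#' @return A validated trial-table data frame.
#' @export
read_trials <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_required_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("age_years", "trial", "reward_belief",
                "effort_exerted_fraction", "effort_threshold",
                "reward_magnitude", "success"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column ", col, call. = FALSE)

  v <- validate_trial_rows(df)
  if (length(v$msgs)) {
    if (strict)
      stop("trial table violates the schema: ",
           paste(v$msgs, collapse = "; "), call. = FALSE)
    message("dropping ", sum(v$bad), " invalid row(s): ",
            paste(v$msgs, collapse = "; "))
    df <- df[!v$bad, , drop = FALSE]
  }
  gaps <- vapply(split(df$trial, df$subject_id), function(tr)
    !identical(as.integer(sort(tr)), seq_along(tr)), logical(1))
  if (any(gaps)) {
    msg <- paste0("non-consecutive trial numbering for subject(s): ",
                  paste(names(gaps)[gaps], collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  df
}

#' Write a trial table to CSV
#'
#' @param trials A trial-table data frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_required_cols, names(trials))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(seed = 1L,
       n_trials = 40L,
       step_sd_reward = 0.5,
       step_sd_effort = 0.03,
       max_abs_corr = 0.2,
       variants = paste0("V", 1:6),
       n_restarts = 20L,
       welch_policy = "auto",
       include_previous_effort = FALSE,
       n_boot = 10000L,
       success_prob = 0.725)
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (seed 1, 40 trials, walk step SDs 0.5 / 0.03, decorrelation bound 0.2,
#' variants V1--V6, 20 restarts, Welch policy `"auto"`, 10,000 bootstrap
#' samples, success probability 0.725).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  if (out$n_restarts < 0 || out$n_boot < 100 || out$n_trials < 2 ||
      out$max_abs_corr <= 0 || out$max_abs_corr > 1 ||
      out$success_prob < 0 || out$success_prob > 1)
    stop("config values outside documented ranges", call. = FALSE)
  out
}

#' Write an analysis report as JSON
#'
#' Serialises a list of results (numbers, vectors, data frames) to pretty
#' JSON with unboxed scalars.
#'
#' @param report A list.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
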