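#' Generate a drifting reward/effort task schedule
#'
#' Builds the per-trial reward magnitudes (1--7 coins) and effort thresholds
#' (fractions of the subject's maximum presses, 0.42--0.92) for the effortful
#' reward-attainment task. Both quantities follow latent real-valued Gaussian
#' random walks with reflecting boundaries; the reward walk is rounded to the
#' nearest integer coin. Because reward and effort must carry independent
#' information, candidate schedules are rejection-sampled until the Pearson
#' correlation between the two final sequences is below `max_abs_corr`.
#'
#' @param n_trials Number of trials (>= 2). The study design uses 40.
#' @param step_sd_reward Step SD of the latent reward walk, in coins.
#'   The default traverses roughly half the 1--7 range over 40 trials.
#' @param step_sd_effort Step SD of the effort-threshold walk (fraction of
#'   maximum presses).
#' @param max_abs_corr Decorrelation bound on |Pearson r| between the reward
#'   and threshold sequences.
#' @param seed Integer seed; the schedule is bit-reproducible given the seed.
#' @param max_retries Rejection-sampling budget before giving up.
#'
#' @return An object of class `task_schedule`: a list with `n_trials`,
#'   `reward_magnitude` (integer vector), `effort_threshold` (numeric
#'   vector), and `seed`.
#' @export
generate_schedule <- function(n_trials, step_sd_reward = 0.5,
                              step_sd_effort = 0.03, max_abs_corr = 0.2,
                              seed = NULL, max_retries = 1000L) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2)
    stop("`n_trials` must be a single integer >= 2", call. = FALSE)
  if (step_sd_reward < 0 || step_sd_effort < 0)
    stop("step SDs must be non-negative", call. = FALSE)
  if (max_abs_corr <= 0 || max_abs_corr > 1)
    stop("`max_abs_corr` must be in (0, 1]", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)

  for (try in seq_len(max_retries)) {
    reward_latent <- reflected_walk(n_trials, lo = 1, hi = 7,
                                    step_sd = step_sd_reward)
    reward <- as.integer(round(reward_latent))
    threshold <- reflected_walk(n_trials, lo = 0.42, hi = 0.92,
                                step_sd = step_sd_effort)
    r <- safe_cor(reward, threshold)
    if (abs(r) < max_abs_corr) {
      out <- structure(
        list(n_trials = n_trials,
             reward_magnitude = reward,
             effort_threshold = threshold,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
        class = "task_schedule")
      return(out)
    }
  }
  stop(sprintf(
    "could not generate a schedule with |corr| < %.3g within %d retries (last |r| = %.3f)",
    max_abs_corr, max_retries, abs(r)), call. = FALSE)
}

# Random walk reflected into [lo, hi]; the start point is uniform in range.
reflected_walk <- function(n, lo, hi, step_sd) {
  x0 <- stats::runif(1, lo, hi)
  steps <- if (step_sd > 0) stats::rnorm(n - 1, 0, step_sd) else numeric(n - 1)
  reflect_into(cumsum(c(x0, steps)), lo, hi)
}

# Fold values into [lo, hi] by repeated reflection at the boundaries.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

# Pearson r that treats a constant sequence as uncorrelated.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("Task schedule: %d trials (seed %s)\n", x$n_trials,
              ifelse(is.na(x$seed), "unset", x$seed)))
  cat(sprintf("  reward: %d..%d coins, mean %.2f\n",
              min(x$reward_magnitude), max(x$reward_magnitude),
              mean(x$reward_magnitude)))
  cat(sprintf("  effort threshold: %.2f..%.2f, mean %.2f\n",
              min(x$effort_threshold), max(x$effort_threshold),
              mean(x$effort_threshold)))
  cat(sprintf("  |corr(reward, threshold)| = %.3f\n",
              abs(safe_cor(x$reward_magnitude, x$effort_threshold))))
  invisible(x)
}

#' Staircase update of a subject's maximum effort
#'
#' The task calibrates effort to each subject: whenever a trial's press count
#' exceeds the current maximum, the maximum is raised to it. The maximum is
#' therefore non-decreasing over the session.
#'
#' @param current_max_presses Current calibrated maximum (positive count).
#' @param presses Presses exerted this trial (non-negative count).
#' @return The updated maximum, `max(current_max_presses, presses)`.
#' @export
staircase_update <- function(current_max_presses, presses) {
  if (!is.numeric(current_max_presses) || current_max_presses <= 0)
    stop("`current_max_presses` must be positive", call. = FALSE)
  if (!is.numeric(presses) || length(presses) != 1L || presses < 0)
    stop("`presses` must be a single non-negative count", call. = FALSE)
  max(current_max_presses, presses)
}

#' Evaluate the outcome of a single trial
#'
#' Success means the exerted effort reached the threshold (a tie counts as
#' success). The reward magnitude is displayed on every trial -- on failures
#' a cross marks that no coins are won, but the magnitude remains visible, so
#' subjects can learn the reward even when they fail the effort requirement.
#'
#' @param exerted_fraction Effort exerted as a fraction of the subject's
#'   maximum presses (>= 0).
#' @param threshold Effort threshold in `[0.42, 0.92]`.
#' @param reward_magnitude Coins on offer, integer 1--7.
#' @return A list with `success` (logical), `coins_won` (0 on failure) and
#'   `displayed_reward` (always `reward_magnitude`).
#' @export
evaluate_trial <- function(exerted_fraction, threshold, reward_magnitude) {
  if (exerted_fraction < 0)
    stop("`exerted_fraction` must be >= 0", call. = FALSE)
  if (threshold < 0.42 || threshold > 0.92)
    stop("`threshold` must lie in [0.42, 0.92]", call. = FALSE)
  if (!reward_magnitude %in% 1:7)
    stop("`reward_magnitude` must be an integer in 1..7", call. = FALSE)
  success <- exerted_fraction >= threshold
  list(success = success,
       coins_won = if (success) as.integer(reward_magnitude) else 0L,
       displayed_reward = as.integer(reward_magnitude))
}

#' Write / read a task schedule as CSV
#'
#' Columns: `trial`, `reward_magnitude`, `effort_threshold`.
#'
#' @param schedule A `task_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `task_schedule` (with `seed` `NA`;
#'   regeneration from seed requires the original parameters).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  utils::write.csv(
    data.frame(trial = seq_len(schedule$n_trials),
               reward_magnitude = schedule$reward_magnitude,
               effort_threshold = schedule$effort_threshold),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "reward_magnitude", "effort_threshold")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schedule file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(n_trials = nrow(df),
                 reward_magnitude = as.integer(df$reward_magnitude),
                 effort_threshold = df$effort_threshold,
                 seed = NA_integer_),
            class = "task_schedule")
}
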