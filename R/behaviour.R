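#' Per-subject behavioural summary and optimism bias
#'
#' The optimism-bias statistic is the subject's mean reported reward belief
#' minus the mean displayed reward across the task: positive values mean the
#' subject systematically expected more coins than the task offered.
#' Calibration summaries (success rate, total points won, mean and SD of
#' exerted effort) are returned alongside.
#'
#' @param records One subject's trial records (>= 1 row).
#' @return A one-row data frame: `subject_id`, `group`, `age_years` (when
#'   present in `records`, else `NA`), `optimism_bias`, `mean_belief`,
#'   `belief_sd`, `mean_reward`, `success_rate`, `total_points`,
#'   `effort_mean`, `effort_sd`.
#' @export
summarize_subject <- function(records) {
  if (is.null(nrow(records)) || nrow(records) == 0)
    stop("`records` must be non-empty", call. = FALSE)
  grab <- function(col, default) {
    if (col %in% names(records)) records[[col]][1] else default
  }
  mean_belief <- mean(records$reward_belief)
  mean_reward <- mean(records$reward_magnitude)
  data.frame(
    subject_id = grab("subject_id", NA_character_),
    group = grab("group", NA_character_),
    age_years = grab("age_years", NA_real_),
    optimism_bias = mean_belief - mean_reward,
    mean_belief = mean_belief,
    belief_sd = stats::sd(records$reward_belief),
    mean_reward = mean_reward,
    success_rate = mean(records$success),
    total_points = sum(records$reward_magnitude[records$success == 1]),
    effort_mean = mean(records$effort_exerted_fraction),
    effort_sd = stats::sd(records$effort_exerted_fraction))
}

#' Summarise every subject of a trial table
#'
#' @param trials A trial table with a `subject_id` column.
#' @return A data frame with one [summarize_subject()] row per subject.
#' @export
summarize_cohort <- function(trials) {
  do.call(rbind, lapply(split(trials, trials$subject_id), summarize_subject))
}

#' Trial-lagged regression of reward belief for one subject
#'
#' Ordinary least squares of the reported reward belief at trial `t` on the
#' previous trial's displayed reward, an effort-failure indicator for the
#' previous trial (failure coded +1, success -1), the subject's own previous
#' reported belief, and optionally the previously exerted effort. Trial 1 is
#' dropped (it has no lagged predictors). If the subject never failed (or
#' never succeeded) the failure column is constant and is dropped with a
#' warning; its coefficient is returned as `NA`.
#'
#' @param records One subject's trial records in trial order.
#' @param include_previous_effort Add the previous exerted-effort fraction as
#'   a predictor.
#' @return Named numeric vector of coefficients: `intercept`,
#'   `previous_reward`, `previous_failure`, `previous_belief` (and
#'   `previous_effort` if requested).
#' @export
belief_regression <- function(records, include_previous_effort = FALSE) {
  n <- nrow(records)
  y <- records$reward_belief[-1]
  X <- cbind(intercept = 1,
             previous_reward = records$reward_magnitude[-n],
             previous_failure = ifelse(records$success[-n] == 1, -1, 1),
             previous_belief = records$reward_belief[-n])
  if (include_previous_effort)
    X <- cbind(X, previous_effort = records$effort_exerted_fraction[-n])
  full_names <- colnames(X)
  if (length(y) < ncol(X) + 2)
    stop("too few usable trials for the regression", call. = FALSE)

  dropped <- character(0)
  const <- apply(X[, -1, drop = FALSE], 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    dropped <- names(const)[const]
    warning("constant predictor(s) dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, !colnames(X) %in% dropped, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  beta <- drop(solve(crossprod(X), crossprod(X, y)))
  out <- stats::setNames(rep(NA_real_, length(full_names)), full_names)
  out[names(beta)] <- beta
  out
}

#' Per-subject belief regressions across a cohort, with group-level tests
#'
#' Runs [belief_regression()] for every subject and tests each coefficient
#' for consistency across subjects with a one-sample t-test against zero
#' (the summary-statistics approach: first-level OLS per subject,
#' second-level t-test over subjects).
#'
#' @param trials A trial table.
#' @param include_previous_effort Passed to [belief_regression()].
#' @return A list with `betas` (subjects x coefficients data frame) and
#'   `group_test` (the [group_level_coefficient_test()] table).
#' @export
cohort_regression <- function(trials, include_previous_effort = FALSE) {
  per <- lapply(split(trials, trials$subject_id), function(rec)
    suppressWarnings(belief_regression(rec, include_previous_effort)))
  betas <- as.data.frame(do.call(rbind, per))
  betas <- cbind(subject_id = names(per), betas, row.names = NULL)
  list(betas = betas,
       group_test = group_level_coefficient_test(betas[, -1, drop = FALSE]))
}

#' Group-level one-sample t-tests on per-subject coefficients
#'
#' @param betas Data frame or matrix, one row per subject, one column per
#'   coefficient; `NA`s (e.g. dropped constant predictors) are excluded
#'   per coefficient.
#' @return Data frame with `coefficient`, `mean`, `sd`, `t`, `df`, `p`.
#' @export
group_level_coefficient_test <- function(betas) {
  betas <- as.data.frame(betas)
  if (nrow(betas) < 3) stop("need at least 3 subjects", call. = FALSE)
  do.call(rbind, lapply(names(betas), function(nm) {
    b <- betas[[nm]][!is.na(betas[[nm]])]
    if (stats::sd(b) == 0)
      stop("zero variance across subjects for coefficient ", nm,
           call. = FALSE)
    tt <- stats::t.test(b, mu = 0)
    data.frame(coefficient = nm, mean = mean(b), sd = stats::sd(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
}

#' One-way between-subjects ANOVA with partial eta squared
#'
#' @param values Numeric outcome, one per subject.
#' @param groups Group labels (factor or character), >= 2 groups with >= 2
#'   subjects each.
#' @param pairwise Also run all pairwise t-tests ([pairwise_t()]).
#' @param welch_policy Passed to [pairwise_t()].
#' @return A list of class `group_comparison`: `F`, `df_between`,
#'   `df_within`, `p`, `partial_eta_sq`, `group_means`, and (optionally)
#'   `pairwise`, a data frame of pairwise tests.
#' @export
one_way_anova <- function(values, groups, pairwise = FALSE,
                          welch_policy = "auto") {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ss_b <- tab["groups", "Sum Sq"]
  ss_w <- tab["Residuals", "Sum Sq"]
  out <- list(F = tab["groups", "F value"],
              df_between = tab["groups", "Df"],
              df_within = tab["Residuals", "Df"],
              p = tab["groups", "Pr(>F)"],
              partial_eta_sq = ss_b / (ss_b + ss_w),
              group_means = tapply(values, groups, mean))
  if (pairwise) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    out$pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      pt <- pairwise_t(values[groups == pr[1]], values[groups == pr[2]],
                       welch_policy = welch_policy)
      data.frame(group_a = pr[1], group_b = pr[2], t = pt$t, df = pt$df,
                 p = pt$p, cohens_d = pt$cohens_d)
    }))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$partial_eta_sq))
  if (!is.null(x$pairwise)) {
    cat("Pairwise t-tests:\n")
    print(x$pairwise, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Independent-samples t-test with Cohen's d
#'
#' `welch_policy = "auto"` uses the Welch correction when the larger sample
#' variance exceeds the smaller by a factor of at least 1.5, and the pooled
#' (Student) test otherwise; `"welch"` and `"student"` force one choice.
#' Cohen's d always uses the pooled SD.
#'
#' @param values_a,values_b Numeric samples (>= 2 each).
#' @param welch_policy `"auto"`, `"welch"`, or `"student"`.
#' @return List with `t`, `df` (fractional under Welch), `p`, `cohens_d`,
#'   and `welch` (whether the correction was applied).
#' @export
pairwise_t <- function(values_a, values_b, welch_policy = "auto") {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each sample needs >= 2 values", call. = FALSE)
  v <- c(stats::var(values_a), stats::var(values_b))
  if (all(v == 0)) stop("zero variance in both samples", call. = FALSE)
  use_welch <- switch(welch_policy,
                      welch = TRUE,
                      student = FALSE,
                      auto = max(v) / max(min(v), .Machine$double.eps) >= 1.5,
                      stop("unknown welch_policy: ", welch_policy,
                           call. = FALSE))
  tt <- stats::t.test(values_a, values_b, var.equal = !use_welch)
  n_a <- length(values_a); n_b <- length(values_b)
  sd_pooled <- sqrt(((n_a - 1) * v[1] + (n_b - 1) * v[2]) / (n_a + n_b - 2))
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohens_d = abs(mean(values_a) - mean(values_b)) / sd_pooled,
       welch = use_welch)
}

#' Correlation between learning-rate asymmetry and optimism bias
#'
#' Computes the Pearson correlation between the fitted learning-rate
#' asymmetry `alpha_pos - alpha_neg` and the behavioural optimism bias, and
#' the partial correlation controlling for age (obtained by residualising
#' both variables on age and correlating the residuals).
#'
#' @param fits Data frame with `subject_id`, `alpha_pos`, `alpha_neg` (e.g.
#'   one variant's rows of [fit_cohort()] output).
#' @param summaries Data frame with `subject_id`, `optimism_bias`,
#'   `age_years` (from [summarize_cohort()]).
#' @return List with `pearson_r`, `p`, `partial_r_controlling_age`,
#'   `p_partial`, and `n`.
#' @export
asymmetry_bias_correlation <- function(fits, summaries) {
  d <- merge(fits[, c("subject_id", "alpha_pos", "alpha_neg")],
             summaries[, c("subject_id", "optimism_bias", "age_years")],
             by = "subject_id")
  if (nrow(d) < 4) stop("need >= 4 subjects with fit and summary",
                        call. = FALSE)
  asym <- d$alpha_pos - d$alpha_neg
  if (stats::sd(asym) == 0 || stats::sd(d$optimism_bias) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  ct <- stats::cor.test(asym, d$optimism_bias)
  res_a <- stats::residuals(stats::lm(asym ~ d$age_years))
  res_b <- stats::residuals(stats::lm(d$optimism_bias ~ d$age_years))
  pct <- stats::cor.test(res_a, res_b)
  # partial correlation p uses n - 3 df
  r_p <- unname(pct$estimate)
  t_p <- r_p * sqrt((nrow(d) - 3) / (1 - r_p^2))
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       partial_r_controlling_age = r_p,
       p_partial = 2 * stats::pt(-abs(t_p), df = nrow(d) - 3),
       n = nrow(d))
}
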