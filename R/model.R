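#' Belief-learning model parameters
#'
#' Parameters of the valence-asymmetric Rescorla--Wagner belief model:
#' a prior reward belief `mu0` (static optimism component, on the 1--7 coin
#' scale), separate learning rates for positive (`alpha_pos`) and negative
#' (`alpha_neg`) prediction errors, and a report-noise scale `xi`. Two
#' optional extension parameters support the wider model family: `kappa`, an
#' additive belief decrement applied after an effort failure, and `lambda`,
#' a per-trial decay of the belief toward the scale midpoint (4).
#'
#' `alpha_pos > alpha_neg` is optimistic learning: better-than-expected
#' outcomes move the belief more than worse-than-expected ones, so the
#' long-run belief sits above the true average reward.
#'
#' @param mu0 Prior belief, in `[1, 7]`.
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @param xi Report-noise scale (> 0), in belief units.
#' @param kappa Post-failure belief decrement, `[0, 1]` (0 = absent).
#' @param lambda Decay rate toward the midpoint, `[0, 1]` (0 = absent).
#' @return An object of class `rw_params` (a named list).
#' @export
rw_params <- function(mu0 = 4, alpha_pos = 0.3, alpha_neg = 0.3, xi = 0.5,
                      kappa = 0, lambda = 0) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stop(sprintf("`%s` must be a single value in [%g, %g]", nm, lo, hi),
           call. = FALSE)
  }
  chk(mu0, 1, 7, "mu0")
  chk(alpha_pos, 0, 1, "alpha_pos")
  chk(alpha_neg, 0, 1, "alpha_neg")
  if (!is.numeric(xi) || length(xi) != 1L || is.na(xi) || xi <= 0)
    stop("`xi` must be a single positive value", call. = FALSE)
  chk(kappa, 0, 1, "kappa")
  chk(lambda, 0, 1, "lambda")
  structure(list(mu0 = mu0, alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                 xi = xi, kappa = kappa, lambda = lambda),
            class = "rw_params")
}

#' Single Rescorla--Wagner belief update with valence-split learning rates
#'
#' Computes the prediction error `delta = outcome - belief` and applies
#' `alpha_pos` when `delta > 0`, `alpha_neg` when `delta < 0`. With outcomes
#' and beliefs on the same bounded scale and rates in `[0, 1]`, the updated
#' belief is a convex combination and stays in `[1, 7]`.
#'
#' @param belief Current belief in `[1, 7]`.
#' @param outcome Displayed reward, integer 1--7.
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @return The updated belief.
#' @export
rw_update <- function(belief, outcome, alpha_pos, alpha_neg) {
  if (belief < 1 || belief > 7)
    stop("`belief` must lie in [1, 7]", call. = FALSE)
  if (!outcome %in% 1:7)
    stop("`outcome` must be an integer in 1..7", call. = FALSE)
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1)
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  delta <- outcome - belief
  if (delta > 0) belief + alpha_pos * delta
  else if (delta < 0) belief + alpha_neg * delta
  else belief
}

#' Deterministic latent belief trajectory for an outcome sequence
#'
#' Runs the belief recursion from the model's prior through a sequence of
#' displayed rewards. The returned trajectory has `length(outcomes) + 1`
#' entries: element `t` is the belief held *before* the outcome of trial `t`
#' (so element 1 is the prior) and the final element is the belief after the
#' last outcome.
#'
#' @param params An [rw_params] object (the variant's constraints, e.g. a
#'   fixed prior or tied rates, are expected to be already baked in).
#' @param outcomes Integer vector of displayed rewards (1--7), non-empty.
#' @param failures Optional 0/1 vector of effort failures, required only by
#'   variants with a post-failure decrement (`kappa > 0`); defaults to all
#'   successes.
#' @return Numeric vector of latent beliefs.
#' @export
predict_beliefs <- function(params, outcomes, failures = NULL) {
  stopifnot(inherits(params, "rw_params"))
  if (length(outcomes) == 0)
    stop("`outcomes` must be non-empty", call. = FALSE)
  if (!all(outcomes %in% 1:7))
    stop("all outcomes must be integers in 1..7", call. = FALSE)
  if (is.null(failures)) failures <- integer(length(outcomes))
  if (length(failures) != length(outcomes))
    stop("`failures` must match `outcomes` in length", call. = FALSE)
  latent_beliefs_cpp(params$mu0, params$alpha_pos, params$alpha_neg,
                     params$kappa, params$lambda,
                     as.integer(outcomes), as.integer(failures))
}

#' Asymptotic belief for symmetric two-point outcomes (analytic oracle)
#'
#' For i.i.d. outcomes taking values `r_lo` and `r_hi` with equal
#' probability, the expected belief update vanishes at
#' `(alpha_pos * r_hi + alpha_neg * r_lo) / (alpha_pos + alpha_neg)`; because
#' the per-branch dynamics are affine, this is also the stationary mean of
#' the belief chain. Equal rates give the unbiased outcome mean; a larger
#' positive rate biases the belief upward (optimism).
#'
#' @param alpha_pos,alpha_neg Learning rates, not both zero.
#' @param r_lo,r_hi The two outcome values, `r_lo < r_hi`.
#' @return The fixed-point belief.
#' @export
asymptotic_bias_oracle <- function(alpha_pos, alpha_neg, r_lo, r_hi) {
  if (alpha_pos <= 0 && alpha_neg <= 0)
    stop("at least one learning rate must be positive", call. = FALSE)
  if (r_lo >= r_hi) stop("`r_lo` must be < `r_hi`", call. = FALSE)
  (alpha_pos * r_hi + alpha_neg * r_lo) / (alpha_pos + alpha_neg)
}

#' Simulate an agent playing a task schedule
#'
#' Generates one subject's trial records: latent beliefs evolve by the
#' valence-split update against the displayed reward on every trial (the
#' reward magnitude is visible even on failed trials); the reported belief is
#' drawn from a Gaussian centred on the latent belief with scale `xi`,
#' truncated to the 1--7 rating scale -- i.e. from exactly the observation
#' model the likelihood assumes, so simulation-based recovery is
#' well-specified. Effort success is generated by the chosen policy --
#' the default is an i.i.d. Bernoulli with probability `success_prob`,
#' mirroring a staircase-calibrated task in which success rates do not differ
#' systematically across subjects. The exerted effort fraction is drawn to be
#' consistent with the success flag under the tie-counts-as-success rule.
#'
#' @param params An [rw_params] object.
#' @param schedule A `task_schedule` from [generate_schedule()].
#' @param effort_policy Only `"bernoulli"` is implemented.
#' @param success_prob Per-trial success probability under the Bernoulli
#'   policy.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of trial records with columns `trial`,
#'   `reward_belief`, `effort_belief`, `effort_exerted_fraction`,
#'   `effort_threshold`, `reward_magnitude`, `success`, plus the latent
#'   belief in `latent_belief` (dropped on CSV export by [write_trials()]
#'   consumers that follow the trial-table schema).
#' @export
simulate_agent <- function(params, schedule, effort_policy = "bernoulli",
                           success_prob = 0.725, seed = NULL) {
  stopifnot(inherits(params, "rw_params"), inherits(schedule, "task_schedule"))
  if (!identical(effort_policy, "bernoulli"))
    stop("unknown effort policy: ", effort_policy, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- schedule$n_trials
  success <- stats::rbinom(n, 1L, success_prob)
  thr <- schedule$effort_threshold
  exerted <- ifelse(success == 1L,
                    pmin(thr + stats::runif(n, 0, 0.08), 1),
                    pmax(thr - 0.01 - stats::runif(n, 0, 0.15), 0))
  latent <- predict_beliefs(params, schedule$reward_magnitude,
                            failures = 1L - success)[seq_len(n)]
  # inverse-CDF draw from the [1, 7]-truncated Gaussian report model
  p_lo <- stats::pnorm((1 - latent) / params$xi)
  p_hi <- stats::pnorm((7 - latent) / params$xi)
  reported <- latent + params$xi *
    stats::qnorm(stats::runif(n, p_lo, p_hi))
  reported <- pmin(pmax(reported, 1), 7)
  effort_belief <- pmin(pmax(thr + stats::rnorm(n, 0, 0.08), 0), 1)
  data.frame(trial = seq_len(n),
             reward_belief = reported,
             effort_belief = effort_belief,
             effort_exerted_fraction = exerted,
             effort_threshold = thr,
             reward_magnitude = schedule$reward_magnitude,
             success = as.integer(success),
             latent_belief = latent)
}
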