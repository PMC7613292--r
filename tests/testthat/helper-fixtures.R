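# Small fixtures built in code; no data files.

sim_subject <- function(mu0 = 5, alpha_pos = 0.4, alpha_neg = 0.1, xi = 0.5,
                        n_trials = 40, seed = 1) {
  sched <- generate_schedule(n_trials, seed = seed)
  simulate_agent(rw_params(mu0, alpha_pos, alpha_neg, xi), sched,
                 seed = seed + 1L)
}

# Minimal hand-built trial records (defaults keep the success flag
# consistent with the effort rule).
make_records <- function(beliefs, rewards, success = NULL) {
  n <- length(beliefs)
  if (is.null(success)) success <- rep(1L, n)
  data.frame(trial = seq_len(n),
             reward_belief = beliefs,
             effort_belief = rep(0.6, n),
             effort_exerted_fraction = ifelse(success == 1, 0.8, 0.5),
             effort_threshold = rep(0.7, n),
             reward_magnitude = as.integer(rewards),
             success = as.integer(success))
}

# A six-subject, 20-trial cohort for integration-style tests.
tiny_cohort_spec <- function(seed = 7L) {
  spec <- default_cohort_spec(seed = seed)
  spec$groups$n_subjects <- c(2L, 2L, 2L)
  spec$n_trials <- 20L
  spec
}

# Negative-control cohort: no age effect on the negative rate, equal priors.
null_cohort_spec <- function(seed = 1L) {
  spec <- default_cohort_spec(seed = seed)
  spec$slope_per_year <- 0
  spec$base_alpha_neg <- 0.2
  spec$groups$mu0_mean <- rep(5.0, 3)
  spec
}

# Independent R-side reimplementation of the truncated-Gaussian NLL used as
# an oracle against the compiled likelihood.
nll_oracle <- function(params, records) {
  b <- params$mu0
  nll <- 0
  for (t in seq_len(nrow(records))) {
    num <- stats::dnorm(records$reward_belief[t], b, params$xi)
    den <- stats::pnorm((7 - b) / params$xi) -
      stats::pnorm((1 - b) / params$xi)
    nll <- nll - log(num / den)
    d <- records$reward_magnitude[t] - b
    b <- b + if (d > 0) params$alpha_pos * d else params$alpha_neg * d
    if (params$kappa != 0 && records$success[t] == 0) b <- b - params$kappa
    if (params$lambda != 0) b <- b + params$lambda * (4 - b)
    b <- min(max(b, 1), 7)
  }
  nll
}
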