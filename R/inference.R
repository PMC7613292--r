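#' Negative log-likelihood of reported beliefs under a belief-learning model
#'
#' The observation model is a Gaussian centred on the latent belief predicted
#' for each trial, with scale `xi`, truncated to the 1--7 rating scale
#' (reports come from a bounded visual-analogue scale, so truncation keeps
#' the density proper). The first trial's prediction is the prior `mu0`;
#' subsequent predictions follow the valence-split update against the
#' displayed reward (plus, for variants that use them, the post-failure
#' decrement and midpoint decay).
#'
#' @param params An [rw_params] object.
#' @param records A trial-record data frame with columns `reward_belief`,
#'   `reward_magnitude`, and `success`.
#' @return The negative log-likelihood (finite on valid input).
#' @export
negative_log_likelihood <- function(params, records) {
  stopifnot(inherits(params, "rw_params"))
  if (is.null(nrow(records)) || nrow(records) == 0)
    stop("`records` must be non-empty", call. = FALSE)
  if (params$xi <= 0) stop("`xi` must be positive", call. = FALSE)
  if (any(records$reward_belief < 1 | records$reward_belief > 7))
    stop("reported beliefs must lie in [1, 7]", call. = FALSE)
  nll_truncnorm_cpp(params$mu0, params$alpha_pos, params$alpha_neg,
                    params$kappa, params$lambda, params$xi,
                    as.integer(records$reward_magnitude),
                    as.integer(1L - records$success),
                    as.numeric(records$reward_belief))
}

#' Fit one subject by maximum likelihood with multi-start optimisation
#'
#' Minimises the truncated-Gaussian negative log-likelihood over the
#' variant's free parameters with box constraints (`mu0` in `[1,7]`, rates in
#' `[0,1]`, `xi` in `[0.01,5]`) using L-BFGS-B from `n_restarts` uniform
#' random starting points plus one box-midpoint start. Belief-learning
#' likelihoods are multimodal in the learning rates when trials are few, so
#' multiple starts are essential.
#'
#' @param records Trial records for one subject (see
#'   [negative_log_likelihood()]).
#' @param spec A [model_spec()].
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Optional seed for the random starts.
#' @param min_trials Minimum number of trials required (default 10).
#' @return An object of class `rw_fit`: fitted `params`, `nll`, `n_free`,
#'   `aic`, `bic`, `n_obs`, `converged`, `n_restarts_used`, and
#'   `flat_likelihood` (`TRUE` when the likelihood is insensitive to the
#'   learning rates, e.g. constant reports matching constant outcomes).
#' @export
fit_subject <- function(records, spec, n_restarts = 20L, seed = NULL,
                        min_trials = 10L) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(nrow(records)) || nrow(records) < min_trials)
    stop(sprintf("need at least %d trials to fit (got %d)", min_trials,
                 if (is.null(nrow(records))) 0L else nrow(records)),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  outcomes <- as.integer(records$reward_magnitude)
  failures <- as.integer(1L - records$success)
  reports <- as.numeric(records$reward_belief)
  free <- spec$free
  bounds <- vapply(free, param_bounds, numeric(2))
  lower <- bounds[1, ]
  upper <- bounds[2, ]
  fixed_mu0 <- if (!is.null(spec$fixed)) unname(spec$fixed["mu0"]) else NA_real_
  codes <- c(mu0 = 0L, alpha = 1L, alpha_pos = 2L, alpha_neg = 3L, xi = 4L,
             kappa = 5L, lambda = 6L)[free]

  obj <- function(theta) {
    v <- stats::setNames(as.list(theta), free)
    ap <- if (spec$tie_alpha) v$alpha else v$alpha_pos
    an <- if (spec$tie_alpha) v$alpha else v$alpha_neg
    nll_truncnorm_cpp(if (is.null(v$mu0)) fixed_mu0 else v$mu0,
                      ap, an,
                      if (is.null(v$kappa)) 0 else v$kappa,
                      if (is.null(v$lambda)) 0 else v$lambda,
                      v$xi, outcomes, failures, reports)
  }

  starts <- rbind((lower + upper) / 2,
                  if (n_restarts > 0)
                    matrix(stats::runif(n_restarts * length(free), lower,
                                        upper),
                           ncol = length(free), byrow = TRUE))
  best <- fit_rw_cpp(starts, lower, upper, unname(codes),
                     fixed_mu0, outcomes, failures, reports,
                     factr = 1e4, maxit = 300L)
  if (best$n_ok == 0L || !is.finite(best$value))
    stop("all optimisation restarts failed", call. = FALSE)
  n_ok <- best$n_ok
  # guard against epsilon-sized excursions past the box in the final iterate
  best$par <- pmin(pmax(best$par, lower), upper)
  names(best$par) <- free

  params <- spec_to_params(best$par, spec)
  # Flat-likelihood diagnostic: nudge the learning-rate parameters; if the
  # NLL is numerically unchanged the rates are unidentifiable on this data.
  alpha_idx <- which(free %in% c("alpha", "alpha_pos", "alpha_neg"))
  flat <- length(alpha_idx) > 0 && all(vapply(alpha_idx, function(j) {
    th <- best$par
    th[j] <- min(upper[j], max(lower[j], th[j] + 0.1))
    up <- abs(obj(th) - best$value)
    th <- best$par
    th[j] <- min(upper[j], max(lower[j], th[j] - 0.1))
    dn <- abs(obj(th) - best$value)
    max(up, dn) < 1e-8
  }, logical(1)))
  if (flat)
    warning("likelihood is flat in the learning rates; they are not ",
            "identifiable on this data", call. = FALSE)

  n_free <- length(free)
  n_obs <- nrow(records)
  structure(list(spec = spec, params = params, nll = best$value,
                 n_free = n_free,
                 aic = 2 * best$value + 2 * n_free,
                 bic = 2 * best$value + n_free * log(n_obs),
                 n_obs = n_obs,
                 converged = best$convergence == 0L,
                 n_restarts_used = n_ok,
                 flat_likelihood = flat),
            class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s fit: nll = %.3f, BIC = %.2f (%d obs, %d free params)\n",
              x$spec$variant_id, x$nll, x$bic, x$n_obs, x$n_free))
  cat(sprintf("  mu0 = %.3f, alpha+ = %.3f, alpha- = %.3f, xi = %.3f\n",
              p$mu0, p$alpha_pos, p$alpha_neg, p$xi))
  invisible(x)
}

#' Fit every subject of a trial table under one or more model variants
#'
#' @param trials A trial table (see [read_trials()]) with a `subject_id`
#'   column.
#' @param specs A list of [model_spec()] objects (default: all six variants).
#' @param n_restarts,seed Passed to [fit_subject()]; per-subject seeds are
#'   derived from `seed` so fits are independent and reproducible.
#' @return A data frame with one row per subject x variant: identifiers,
#'   `nll`, `n_free`, `aic`, `bic`, `converged`, `flat_likelihood`, and the
#'   fitted parameter values.
#' @export
fit_cohort <- function(trials, specs = model_variants(), n_restarts = 20L,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(trials$subject_id)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  rows <- vector("list", length(ids) * length(specs))
  k <- 0L
  for (i in seq_along(ids)) {
    rec <- trials[trials$subject_id == ids[i], , drop = FALSE]
    for (j in seq_along(specs)) {
      fit <- fit_subject(rec, specs[[j]], n_restarts = n_restarts,
                         seed = sub_seeds[i] %% 2147480000L + j)
      p <- fit$params
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = ids[i], variant_id = fit$spec$variant_id,
        nll = fit$nll, n_free = fit$n_free, n_obs = fit$n_obs,
        aic = fit$aic, bic = fit$bic, converged = fit$converged,
        flat_likelihood = fit$flat_likelihood,
        mu0 = p$mu0, alpha_pos = p$alpha_pos, alpha_neg = p$alpha_neg,
        xi = p$xi, kappa = p$kappa, lambda = p$lambda)
    }
  }
  do.call(rbind, rows)
}

#' BIC model comparison across subjects
#'
#' Sums BIC per variant over subjects; the best variant minimises the summed
#' BIC. Per-subject win counts (how many subjects each variant fits best)
#' are reported as a secondary view.
#'
#' @param fit_table A data frame from [fit_cohort()] in which every subject
#'   has a row for every variant.
#' @return An object of class `model_comparison` with `summed_ic` (named,
#'   sorted ascending), `best_variant`, `best_count`, and the per-subject IC
#'   table in wide form (`per_subject_ic`).
#' @export
compare_models <- function(fit_table) {
  need <- c("subject_id", "variant_id", "bic")
  if (!all(need %in% names(fit_table)))
    stop("`fit_table` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- table(fit_table$subject_id, fit_table$variant_id)
  if (any(tab != 1))
    stop("every subject must be fitted under every variant exactly once",
         call. = FALSE)
  wide <- stats::reshape(
    fit_table[, need], idvar = "subject_id", timevar = "variant_id",
    direction = "wide")
  names(wide) <- sub("^bic\\.", "", names(wide))
  variants <- setdiff(names(wide), "subject_id")
  ic <- as.matrix(wide[, variants, drop = FALSE])
  summed <- sort(colSums(ic))
  wins <- variants[apply(ic, 1, which.min)]
  best_count <- stats::setNames(integer(length(variants)), variants)
  win_tab <- table(wins)
  best_count[names(win_tab)] <- as.integer(win_tab)
  structure(list(summed_ic = summed,
                 best_variant = names(summed)[1],
                 best_count = best_count,
                 per_subject_ic = wide),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("BIC model comparison (", nrow(x$per_subject_ic), " subjects)\n",
      sep = "")
  for (v in names(x$summed_ic))
    cat(sprintf("  %s: summed BIC = %.1f, best for %d subject(s)%s\n", v,
                x$summed_ic[[v]], x$best_count[[v]],
                if (v == x$best_variant) "  <- winner" else ""))
  invisible(x)
}

#' Parameter recovery for a model variant
#'
#' Simulates agents with known parameters on freshly generated schedules,
#' refits them, and tabulates how well each parameter is re-identified:
#' Pearson correlation, mean bias (recovered minus true) and RMSE.
#'
#' @param spec A [model_spec()].
#' @param n_agents Number of simulated agents (>= 2).
#' @param n_trials Trials per agent.
#' @param param_sampler Optional named list of `function(n)` samplers for the
#'   free parameters; defaults span the parameter boxes. A constant sampler
#'   yields an undefined correlation for that parameter (reported `NA` with
#'   a warning).
#' @param n_restarts,seed Fitting settings; `seed` drives the whole
#'   simulation-and-fit experiment.
#' @return An object of class `recovery_report` with `truth` and `recovered`
#'   data frames and a `summary` table (`parameter`, `pearson_r`, `bias`,
#'   `rmse`).
#' @export
parameter_recovery <- function(spec, n_agents, n_trials = 40L,
                               param_sampler = NULL, n_restarts = 20L,
                               seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (n_agents < 2) stop("`n_agents` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sampler <- default_param_sampler(spec)
  if (!is.null(param_sampler)) sampler[names(param_sampler)] <- param_sampler

  truth <- as.data.frame(lapply(sampler, function(f) f(n_agents)))
  sub_seeds <- sample.int(.Machine$integer.max - 3L, n_agents)
  recovered <- truth[0, , drop = FALSE]
  for (i in seq_len(n_agents)) {
    sched <- generate_schedule(n_trials, seed = sub_seeds[i])
    pars <- spec_to_params(as.numeric(truth[i, spec$free]), spec)
    rec <- simulate_agent(pars, sched, seed = sub_seeds[i] + 1L)
    fit <- fit_subject(rec, spec, n_restarts = n_restarts,
                       seed = sub_seeds[i] + 2L)
    fp <- fit$params
    recovered[i, ] <- vapply(spec$free, function(nm) {
      if (nm == "alpha") fp$alpha_pos else fp[[nm]]
    }, numeric(1))
  }
  summary <- do.call(rbind, lapply(spec$free, function(nm) {
    tr <- truth[[nm]]; rc <- recovered[[nm]]
    r <- if (stats::sd(tr) == 0) {
      warning("constant true values for ", nm,
              "; recovery correlation undefined", call. = FALSE)
      NA_real_
    } else stats::cor(tr, rc)
    data.frame(parameter = nm, pearson_r = r, bias = mean(rc - tr),
               rmse = sqrt(mean((rc - tr)^2)))
  }))
  structure(list(truth = truth, recovered = recovered, summary = summary,
                 spec = spec, n_trials = n_trials),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery, %s, %d agents x %d trials\n",
              x$spec$variant_id, nrow(x$truth), x$n_trials))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Model recovery: confusion matrix of generating vs best-fitting variant
#'
#' For each generating variant, simulates agents with sampled parameters,
#' fits every candidate variant to each agent, and assigns the agent to the
#' variant with the lowest BIC. Rows of the confusion matrix (generating
#' variant) sum to one.
#'
#' @param specs List of at least two candidate [model_spec()] objects fitted
#'   to every agent.
#' @param n_agents_per_spec Agents simulated per generating variant.
#' @param n_trials Trials per agent.
#' @param param_sampler Optional sampler overrides (see
#'   [parameter_recovery()]), applied to every generating variant.
#' @param generating_specs Variants agents are generated from (default: all
#'   of `specs`).
#' @param n_restarts,seed As in [parameter_recovery()].
#' @return A list of class `confusion_report`: `confusion` (row-normalised,
#'   generating x recovered), `summed_bic` (generating x candidate, summed
#'   over that row's agents) and `assignments` (per-agent generating and
#'   winning variant).
#' @export
model_recovery <- function(specs, n_agents_per_spec, n_trials = 40L,
                           param_sampler = NULL, generating_specs = specs,
                           n_restarts = 20L, seed = NULL) {
  if (length(specs) < 2) stop("need at least two variants", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(specs, function(s) s$variant_id, character(1))
  names(specs) <- ids
  gen_ids <- vapply(generating_specs, function(s) s$variant_id, character(1))
  confusion <- matrix(0, length(gen_ids), length(ids),
                      dimnames = list(generating = gen_ids, recovered = ids))
  summed_bic <- confusion
  assignments <- list()
  for (g in gen_ids) {
    gspec <- specs[[g]]
    sampler <- default_param_sampler(gspec)
    if (!is.null(param_sampler))
      sampler[intersect(names(param_sampler), names(sampler))] <-
        param_sampler[intersect(names(param_sampler), names(sampler))]
    truth <- as.data.frame(lapply(sampler, function(f) f(n_agents_per_spec)))
    sub_seeds <- sample.int(.Machine$integer.max - 3L, n_agents_per_spec)
    for (i in seq_len(n_agents_per_spec)) {
      sched <- generate_schedule(n_trials, seed = sub_seeds[i])
      pars <- spec_to_params(as.numeric(truth[i, gspec$free]), gspec)
      rec <- simulate_agent(pars, sched, seed = sub_seeds[i] + 1L)
      bics <- vapply(specs, function(s)
        fit_subject(rec, s, n_restarts = n_restarts,
                    seed = sub_seeds[i] + 2L)$bic, numeric(1))
      win <- ids[which.min(bics)]
      confusion[g, win] <- confusion[g, win] + 1
      summed_bic[g, ] <- summed_bic[g, ] + bics
      assignments[[length(assignments) + 1L]] <-
        data.frame(generating = g, recovered = win)
    }
  }
  confusion <- confusion / rowSums(confusion)
  structure(list(confusion = confusion, summed_bic = summed_bic,
                 assignments = do.call(rbind, assignments)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Model-recovery confusion matrix (rows: generating variant)\n")
  print(round(x$confusion, 3))
  invisible(x)
}
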