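#' Point estimates of the three-variable mediation path model
#'
#' Standard path notation: X is the independent variable (here age in
#' years), M the mediator (negative learning rate), Y the outcome (optimism
#' bias). Path `a` is the OLS slope of M on X; `b` and `c_prime` are the
#' slopes of M and X in the joint OLS of Y on X and M; `c` is the total
#' effect (OLS of Y on X); the indirect effect is `ab = a * b`. On a common
#' sample the OLS decomposition `c = c_prime + a * b` holds exactly.
#'
#' @param X,M,Y Numeric vectors of equal length >= 4; X and M non-constant
#'   and not collinear.
#' @return Named list: `a`, `b`, `c`, `c_prime`, `ab`.
#' @export
fit_paths <- function(X, M, Y) {
  n <- length(X)
  if (length(M) != n || length(Y) != n || n < 4)
    stop("X, M, Y must have equal length >= 4", call. = FALSE)
  if (stats::sd(X) == 0 || stats::sd(M) == 0)
    stop("X and M must be non-constant", call. = FALSE)
  if (abs(stats::cor(X, M)) > 0.999)
    stop("X and M are (nearly) collinear", call. = FALSE)
  .fit_paths_fast(X, M, Y)
}

# Closed-form path estimates via covariances; no input checks (hot path for
# the bootstrap).
.fit_paths_fast <- function(X, M, Y) {
  sxx <- stats::var(X)
  smm <- stats::var(M)
  sxm <- stats::cov(X, M)
  sxy <- stats::cov(X, Y)
  smy <- stats::cov(M, Y)
  det <- sxx * smm - sxm^2
  a <- sxm / sxx
  b <- (smy * sxx - sxy * sxm) / det
  c_prime <- (sxy * smm - smy * sxm) / det
  c_tot <- sxy / sxx
  list(a = a, b = b, c = c_tot, c_prime = c_prime, ab = a * b)
}

# BCa interval from a bootstrap sample. z0 from the fraction of draws below
# the point estimate; acceleration from jackknife estimates. With z0 = 0 and
# accel = 0 this is the plain percentile interval.
bca_interval <- function(boots, estimate, jack = NULL, conf = 0.95,
                         z0 = NULL, accel = NULL) {
  B <- length(boots)
  if (is.null(z0)) {
    prop <- sum(boots < estimate) / B
    prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
    z0 <- stats::qnorm(prop)
  }
  if (is.null(accel)) {
    if (is.null(jack)) stop("need jackknife values for acceleration")
    d <- mean(jack) - jack
    denom <- sum(d^2)^1.5
    accel <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  }
  alpha <- (1 - conf) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  stats::quantile(boots, probs = adj, names = FALSE, type = 7)
}

#' BCa bootstrap mediation analysis
#'
#' Case-resampling bootstrap of [fit_paths()]: subjects are resampled with
#' replacement keeping their (X, M, Y) rows together, and each of the `a`,
#' `b`, `c`, `c_prime` and `ab` path coefficients receives a bias-corrected
#' accelerated (BCa) confidence interval. The bias-correction term derives
#' from the fraction of bootstrap draws below the point estimate and the
#' acceleration from a leave-one-out jackknife. Two p-values are reported
#' per path: the primary bootstrap-distribution p,
#' `2 * min(Pr(draws <= 0), Pr(draws >= 0))` floored at `1 / n_boot`, and a
#' normal-approximation p from `z = estimate / bootstrap SE`.
#'
#' @param X,M,Y As in [fit_paths()].
#' @param n_boot Number of bootstrap samples (>= 100; the reference
#'   procedure uses 10,000).
#' @param conf Confidence level of the intervals.
#' @param seed Optional seed.
#' @return An object of class `mediation_result`: a `paths` data frame
#'   (`path`, `estimate`, `boot_se`, `z`, `p_boot`, `p_norm`, `ci_lo`,
#'   `ci_hi`) plus `n`, `n_boot`, `conf`, and `boots` (the bootstrap draws).
#' @export
bca_bootstrap_mediation <- function(X, M, Y, n_boot = 10000L, conf = 0.95,
                                    seed = NULL) {
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  est <- fit_paths(X, M, Y)  # validates inputs
  if (!is.null(seed)) set.seed(seed)
  n <- length(X)
  paths <- c("a", "b", "c", "c_prime", "ab")

  boots <- matrix(NA_real_, n_boot, length(paths),
                  dimnames = list(NULL, paths))
  for (i in seq_len(n_boot)) {
    for (retry in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(X[idx]) > 0 && stats::sd(M[idx]) > 0 &&
          abs(stats::cor(X[idx], M[idx])) <= 0.999) break
      if (retry == 100)
        stop("bootstrap resampling kept producing degenerate draws",
             call. = FALSE)
    }
    boots[i, ] <- unlist(.fit_paths_fast(X[idx], M[idx], Y[idx]),
                         use.names = FALSE)
  }
  jack <- matrix(NA_real_, n, length(paths), dimnames = list(NULL, paths))
  for (j in seq_len(n))
    jack[j, ] <- unlist(.fit_paths_fast(X[-j], M[-j], Y[-j]),
                        use.names = FALSE)

  tab <- do.call(rbind, lapply(paths, function(p) {
    bs <- boots[, p]
    se <- stats::sd(bs)
    ci <- bca_interval(bs, est[[p]], jack = jack[, p], conf = conf)
    p_boot <- max(2 * min(mean(bs <= 0), mean(bs >= 0)), 1 / n_boot)
    p_boot <- min(p_boot, 1)
    z <- est[[p]] / se
    data.frame(path = p, estimate = est[[p]], boot_se = se, z = z,
               p_boot = p_boot, p_norm = 2 * stats::pnorm(-abs(z)),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  structure(list(paths = tab, n = n, n_boot = as.integer(n_boot),
                 conf = conf, boots = boots),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("BCa bootstrap mediation (n = %d, %d bootstrap samples, %.0f%% CI)\n",
              x$n, x$n_boot, 100 * x$conf))
  print(x$paths, row.names = FALSE, digits = 3)
  ab <- x$paths[x$paths$path == "ab", ]
  cat(sprintf("Indirect effect ab %s 0 (CI [%.4f, %.4f])\n",
              if (ab$ci_lo > 0 || ab$ci_hi < 0) "excludes" else "includes",
              ab$ci_lo, ab$ci_hi))
  invisible(x)
}

#' Run the mediation analysis from a per-subject table
#'
#' Convenience wrapper mapping the study's variables onto the path model:
#' X = `age_years`, M = `alpha_neg` (fitted negative learning rate),
#' Y = `optimism_bias`.
#'
#' @param subjects Data frame with columns `age_years`, `alpha_neg`,
#'   `optimism_bias`.
#' @param ... Passed to [bca_bootstrap_mediation()].
#' @return A `mediation_result`.
#' @export
mediate_age_bias <- function(subjects, ...) {
  need <- c("age_years", "alpha_neg", "optimism_bias")
  if (!all(need %in% names(subjects)))
    stop("`subjects` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bca_bootstrap_mediation(subjects$age_years, subjects$alpha_neg,
                          subjects$optimism_bias, ...)
}
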