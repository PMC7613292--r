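#' Model variants of the belief-learning family
#'
#' Six nested variants of the Rescorla--Wagner belief model. Every variant
#' frees the report-noise scale `xi`; they differ in whether the learning
#' rate is split by prediction-error valence, whether the prior is free or
#' fixed at the scale midpoint (4), and whether an extra mechanism is added:
#'
#' * `V1`: single learning rate, prior fixed at 4.
#' * `V2`: single learning rate, free prior `mu0`.
#' * `V3`: split rates `alpha_pos`/`alpha_neg`, prior fixed at 4.
#' * `V4`: split rates, free prior (the full valence-asymmetric model).
#' * `V5`: `V4` plus an additive belief decrement `kappa` after effort
#'   failure.
#' * `V6`: single rate, free prior, plus decay `lambda` of the belief toward
#'   the scale midpoint.
#'
#' @param variant_id One of `"V1"`..`"V6"`.
#' @return `model_spec()` returns an object of class `model_spec` with
#'   fields `variant_id`, `free` (names of free parameters), `tie_alpha`
#'   (single learning rate?), and `fixed` (named fixed values).
#'   `model_variants()` returns a named list of all six specs.
#' @export
model_spec <- function(variant_id) {
  specs <- list(
    V1 = list(free = c("alpha", "xi"), tie_alpha = TRUE,  fixed = c(mu0 = 4)),
    V2 = list(free = c("mu0", "alpha", "xi"), tie_alpha = TRUE, fixed = NULL),
    V3 = list(free = c("alpha_pos", "alpha_neg", "xi"), tie_alpha = FALSE,
              fixed = c(mu0 = 4)),
    V4 = list(free = c("mu0", "alpha_pos", "alpha_neg", "xi"),
              tie_alpha = FALSE, fixed = NULL),
    V5 = list(free = c("mu0", "alpha_pos", "alpha_neg", "xi", "kappa"),
              tie_alpha = FALSE, fixed = NULL),
    V6 = list(free = c("mu0", "alpha", "xi", "lambda"), tie_alpha = TRUE,
              fixed = NULL))
  if (!variant_id %in% names(specs))
    stop("unknown variant: ", variant_id, call. = FALSE)
  s <- specs[[variant_id]]
  structure(list(variant_id = variant_id, free = s$free,
                 tie_alpha = s$tie_alpha, fixed = s$fixed),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_variants <- function() {
  ids <- paste0("V", 1:6)
  stats::setNames(lapply(ids, model_spec), ids)
}

# Box bounds for free parameters, by name.
param_bounds <- function(name) {
  switch(name,
         mu0 = c(1, 7),
         alpha = , alpha_pos = , alpha_neg = c(0, 1),
         xi = c(0.01, 5),
         kappa = c(0, 1),
         lambda = c(0, 1),
         stop("no bounds for parameter ", name, call. = FALSE))
}

# Map a free-parameter vector (in spec$free order) to a full rw_params.
spec_to_params <- function(theta, spec) {
  v <- as.list(stats::setNames(theta, spec$free))
  if (spec$tie_alpha) {
    v$alpha_pos <- v$alpha
    v$alpha_neg <- v$alpha
    v$alpha <- NULL
  }
  fixed <- spec$fixed
  mu0 <- if (!is.null(v$mu0)) v$mu0 else unname(fixed["mu0"])
  rw_params(mu0 = mu0,
            alpha_pos = v$alpha_pos,
            alpha_neg = v$alpha_neg,
            xi = v$xi,
            kappa = if (!is.null(v$kappa)) v$kappa else 0,
            lambda = if (!is.null(v$lambda)) v$lambda else 0)
}

# Draw true parameters for a variant from a sampler spec: a named list of
# function(n) generators, with sensible defaults spanning the boxes.
default_param_sampler <- function(spec) {
  samplers <- list(
    mu0 = function(n) stats::runif(n, 2, 6.5),
    alpha = function(n) stats::runif(n, 0.05, 0.7),
    alpha_pos = function(n) stats::runif(n, 0.05, 0.7),
    alpha_neg = function(n) stats::runif(n, 0.02, 0.6),
    xi = function(n) stats::runif(n, 0.3, 1),
    kappa = function(n) stats::runif(n, 0, 0.4),
    lambda = function(n) stats::runif(n, 0, 0.3))
  samplers[spec$free]
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model variant %s: free = {%s}%s%s\n", x$variant_id,
              paste(x$free, collapse = ", "),
              if (x$tie_alpha) ", single learning rate" else "",
              if (!is.null(x$fixed))
                paste0(", fixed ", paste(names(x$fixed), "=", x$fixed,
                                         collapse = ", ")) else ""))
  invisible(x)
}
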