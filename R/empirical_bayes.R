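#' A patient's accumulated dosing history
#'
#' Bundles a patient's covariate values with the (dose, response) pairs
#' accumulated over the steps of the dosing algorithm.  May be empty (the
#' state at the first algorithm step, before any blood sample).
#'
#' @param covariates Numeric covariate vector \eqn{X} (may be empty).
#' @param doses,responses Strictly positive numeric vectors of equal
#'   length (may be empty).
#' @return An object of class `patient_history`.
#' @export
patient_history <- function(covariates = numeric(0), doses = numeric(0),
                            responses = numeric(0)) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (any(doses <= 0) || any(responses <= 0) ||
      any(!is.finite(doses)) || any(!is.finite(responses)))
    stop("all doses and responses must be finite and > 0")
  structure(list(covariates = as.numeric(covariates), doses = doses,
                 responses = responses),
            class = "patient_history")
}

#' Record a new (dose, response) observation
#' @param history A [patient_history].
#' @param dose,response The newly administered dosage and the measured
#'   steady-state trough response.
#' @return The extended [patient_history].
#' @export
add_observation <- function(history, dose, response) {
  patient_history(history$covariates, c(history$doses, dose),
                  c(history$responses, response))
}

#' Empirical Bayes (BLUP) posterior of a patient's intercept
#'
#' Combines the estimated population model (the empirical prior) with the
#' patient's observed history.  Writing \eqn{\bar r} for the mean of the
#' [log_residuals()] \eqn{r_j = \log Y_j - \beta^T X - d \log D_j} over the
#' \eqn{n} observations, the normal-normal posterior of \eqn{\alpha} is
#' \deqn{\hat\alpha = \frac{\sigma^2_\varepsilon \mu_\alpha +
#'   n \sigma^2_\alpha \bar r}{\sigma^2_\varepsilon + n \sigma^2_\alpha},
#'   \qquad
#'   v = \frac{\sigma^2_\alpha \sigma^2_\varepsilon}
#'            {\sigma^2_\varepsilon + n \sigma^2_\alpha},}
#' the usual shrinkage (BLUP) predictor.  With no observations the prior
#' \eqn{(\mu_\alpha, \sigma^2_\alpha)} is returned, so the first algorithm
#' step predicts \eqn{\hat\alpha_1 = \mu_\alpha}.  The posterior depends on
#' the history only through \eqn{(n, \bar r)}: it is invariant to the order
#' of observations and shrinks \eqn{\bar r} toward \eqn{\mu_\alpha}.
#'
#' @param model A [population_model] (treated as known at its estimates).
#' @param history A [patient_history].
#' @return An object of class `posterior_intercept`: list with `alpha_hat`
#'   (posterior mean), `v` (posterior variance), `n_obs`.
#' @export
posterior_intercept <- function(model, history) {
  stopifnot(inherits(model, "population_model"),
            inherits(history, "patient_history"))
  n <- length(history$doses)
  if (n == 0L) {
    post <- list(alpha_hat = model$mu_alpha, v = model$sigma_alpha2,
                 n_obs = 0L)
  } else {
    rbar <- mean(log_residuals(model, history$covariates,
                               history$doses, history$responses))
    denom <- model$sigma_eps2 + n * model$sigma_alpha2
    post <- list(
      alpha_hat = (model$sigma_eps2 * model$mu_alpha +
                     n * model$sigma_alpha2 * rbar) / denom,
      v = model$sigma_alpha2 * model$sigma_eps2 / denom,
      n_obs = n)
  }
  structure(post, class = "posterior_intercept")
}

#' @export
print.posterior_intercept <- function(x, ...) {
  cat(sprintf(
    "Empirical Bayes intercept posterior: alpha_hat = %.6g, v = %.6g (n = %d)\n",
    x$alpha_hat, x$v, x$n_obs))
  invisible(x)
}

#' Standardized pharmacokinetic index gamma
#'
#' The covariate-adjusted proxy for apparent clearance,
#' \eqn{\gamma = (\alpha - \mu_\alpha)/\sigma_\alpha}.  A patient with
#' \eqn{\gamma = 0} responds like the average individual; \eqn{\gamma > 0}
#' flags slower-than-average drug elimination (higher trough levels at a
#' given dosage), \eqn{\gamma < 0} faster elimination.
#'
#' @param alpha Intercept value (true or predicted).
#' @param model A [population_model] with `sigma_alpha2 > 0`.
#' @return The standardized index (scalar, or vectorized over `alpha`).
#' @export
gamma_index <- function(alpha, model) {
  stopifnot(inherits(model, "population_model"))
  if (model$sigma_alpha2 == 0)
    stop("gamma undefined: sigma_alpha2 is 0 (no inter-patient variability)")
  (alpha - model$mu_alpha) / sqrt(model$sigma_alpha2)
}
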