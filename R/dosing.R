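#' Therapeutic window
#'
#' The response interval \eqn{(l_1, l_2)}, \eqn{0 < l_1 < l_2}, within
#' which the drug is considered both effective and safe.  The ratio
#' \eqn{l_2/l_1} is the therapeutic index; the geometric midpoint
#' \eqn{g = \sqrt{l_1 l_2}} is the window center on the log scale and the
#' target all dose formulas aim at.
#'
#' @param l1,l2 Lower and upper bounds (response units), `0 < l1 < l2`.
#' @return An object of class `therapeutic_window` with fields `l1`, `l2`,
#'   `therapeutic_index`, `g`.
#' @export
therapeutic_window <- function(l1, l2) {
  stopifnot(is.numeric(l1), is.numeric(l2), length(l1) == 1, length(l2) == 1)
  if (!(l1 > 0 && l2 > l1))
    stop("need 0 < l1 < l2")
  structure(list(l1 = l1, l2 = l2, therapeutic_index = l2 / l1,
                 g = sqrt(l1 * l2)),
            class = "therapeutic_window")
}

#' @export
print.therapeutic_window <- function(x, ...) {
  cat(sprintf(
    "Therapeutic window (%g, %g): index %.4g, geometric midpoint %.4g\n",
    x$l1, x$l2, x$therapeutic_index, x$g))
  invisible(x)
}

## Shared dose formula: D = [g * exp(-(alpha_hat) - beta'X)]^(1/d).
eb_dose_formula <- function(model, alpha_hat, X, window) {
  eta <- if (length(model$beta)) sum(model$beta * X) else 0
  exp((log(window$g) - alpha_hat - eta) / model$d)
}

#' Probability that a dose lands the response in the therapeutic window
#'
#' Under the model, \eqn{\log Y} at dosage \eqn{D} is normal with mean
#' \eqn{m = \alpha + \beta^T X + d \log D} and variance
#' \eqn{\sigma^2_\varepsilon}; integrating over residual uncertainty about
#' \eqn{\alpha} (normal with mean `alpha_mean`, variance `alpha_var`) gives
#' \deqn{P(l_1 < Y < l_2) = \Phi\!\Big(\frac{\log l_2 - m}{s}\Big) -
#'   \Phi\!\Big(\frac{\log l_1 - m}{s}\Big), \quad
#'   s = \sqrt{\mathrm{alpha\_var} + \sigma^2_\varepsilon},}
#' with \eqn{m} evaluated at `alpha_mean`.  `alpha_var = 0` gives the
#' known-\eqn{\alpha} attainment probability; `alpha_var = v` from
#' [posterior_intercept()] gives the posterior-predictive probability whose
#' complement is the Bayes risk minimized by the dosing algorithm.
#'
#' @param model A [population_model].
#' @param alpha_mean,alpha_var Mean and variance of the intercept belief.
#' @param X Covariate vector.
#' @param dose Positive dosage (vectorized).
#' @param window A [therapeutic_window].
#' @return Probability in \[0, 1\] (vector if `dose` is a vector).
#' @export
window_probability <- function(model, alpha_mean, alpha_var, X, dose,
                               window) {
  stopifnot(inherits(model, "population_model"),
            inherits(window, "therapeutic_window"))
  if (any(dose <= 0)) stop("dose must be > 0")
  if (alpha_var < 0) stop("alpha_var must be >= 0")
  X <- check_covariates(model, X)
  eta <- if (length(model$beta)) sum(model$beta * X) else 0
  m <- alpha_mean + eta + model$d * log(dose)
  s <- sqrt(alpha_var + model$sigma_eps2)
  stats::pnorm((log(window$l2) - m) / s) -
    stats::pnorm((log(window$l1) - m) / s)
}

#' Maximum attainable window probability for a single patient
#'
#' Even with the patient's \eqn{\alpha} known exactly, intra-patient noise
#' caps the attainment probability at
#' \deqn{P_{max} = 2\,\Phi\!\Big(\frac{\log(l_2/l_1)}{2\sigma_\varepsilon}\Big) - 1,}
#' reached by centering \eqn{\log Y} on the log-scale window midpoint.  It
#' depends only on the therapeutic index \eqn{l_2/l_1} and
#' \eqn{\sigma^2_\varepsilon} - not on the patient - and is strictly below 1
#' whenever \eqn{\sigma_\varepsilon > 0}.
#'
#' @param model A [population_model].
#' @param window A [therapeutic_window].
#' @return Probability in (0, 1\].
#' @export
max_attainable_probability <- function(model, window) {
  stopifnot(inherits(model, "population_model"),
            inherits(window, "therapeutic_window"))
  2 * stats::pnorm(log(window$l2 / window$l1) /
                     (2 * sqrt(model$sigma_eps2))) - 1
}

#' Initial dose for a previously unobserved patient
#'
#' With no patient data, \eqn{\alpha} is predicted by its population mean
#' (\eqn{\hat\alpha_1 = \mu_\alpha}) and the first-step dosage is
#' \deqn{D_1 = \left[\sqrt{l_1 l_2}\,
#'   e^{-\mu_\alpha - \beta^T X}\right]^{1/d},}
#' the dose that is optimal for the average patient with covariates
#' \eqn{X}: it centers the predictive distribution of \eqn{\log Y} on the
#' log-window midpoint, which maximizes the window probability for any
#' predictive variance.
#'
#' @param model A [population_model].
#' @param X Covariate vector.
#' @param window A [therapeutic_window].
#' @return An object of class `dose_recommendation`: `dose`, `step` (= 1),
#'   `predicted_window_probability` (posterior-predictive, here prior
#'   predictive), and the `posterior` used.
#' @export
initial_dose <- function(model, X, window) {
  update_dose(model, patient_history(covariates = X), window)
}

#' Empirical Bayes dose update from accumulated history
#'
#' At step \eqn{i} the intercept predictor \eqn{\hat\alpha_i} from
#' [posterior_intercept()] replaces \eqn{\mu_\alpha} in the dose formula:
#' \deqn{D_i = \left[\sqrt{l_1 l_2}\,
#'   e^{-\hat\alpha_i - \beta^T X}\right]^{1/d}.}
#' This dose minimizes the Bayes risk \eqn{1 - P(l_1 < Y < l_2)} under the
#' current posterior: on the log scale the predictive distribution is
#' normal, so centering it on the window midpoint is optimal whatever the
#' predictive variance.  With an empty history it reduces to
#' [initial_dose()].
#'
#' @param model A [population_model].
#' @param history A [patient_history] (covariates + accumulated
#'   dose/response pairs).
#' @param window A [therapeutic_window].
#' @return A `dose_recommendation` (see [initial_dose()]); `step` is
#'   `n_obs + 1`.
#' @export
update_dose <- function(model, history, window) {
  stopifnot(inherits(history, "patient_history"))
  post <- posterior_intercept(model, history)
  dose <- eb_dose_formula(model, post$alpha_hat, history$covariates, window)
  structure(
    list(dose = dose, step = post$n_obs + 1L,
         predicted_window_probability = window_probability(
           model, post$alpha_hat, post$v, history$covariates, dose, window),
         posterior = post),
    class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Step %d dose recommendation: %.6g\n", x$step, x$dose))
  cat(sprintf("  predicted window probability: %.4f\n",
              x$predicted_window_probability))
  print(x$posterior)
  invisible(x)
}

#' Is a dose omega-optimum for a given patient?
#'
#' A dosage is \eqn{\omega}-optimum for a patient if it achieves at least
#' the fraction \eqn{\omega} (a number close to 1) of that patient's
#' maximum attainable window probability, evaluated at the patient's true
#' intercept.
#'
#' @param dose Positive dosage (vectorized).
#' @param true_alpha The patient's intercept.
#' @param model A [population_model].
#' @param X Covariate vector.
#' @param window A [therapeutic_window].
#' @param omega Fraction in (0, 1).
#' @return Logical.
#' @export
is_omega_optimum <- function(dose, true_alpha, model, X, window, omega) {
  if (!(omega > 0 && omega < 1)) stop("omega must be in (0, 1)")
  window_probability(model, true_alpha, 0, X, dose, window) >=
    omega * max_attainable_probability(model, window)
}

#' Traditional TDM proportional dose adjustment
#'
#' The textbook therapeutic-drug-monitoring rule: scale the previous dosage
#' by the ratio of the target trough concentration \eqn{C_0} to the
#' measured level,
#' \deqn{D_{new} = D_{prev} \cdot \left(C_0 / Y_{meas}\right)^{1/d}.}
#' The classical rule is the \eqn{d = 1} case (proportionality between
#' dose and steady-state level); for \eqn{d \ne 1} the exponent generalizes
#' the correction consistently with the model.
#'
#' @param previous_dose,measured_level,target_C0 Positive scalars.
#' @param d Dose exponent (default 1, the traditional rule).
#' @return The adjusted dose.
#' @export
tdm_update <- function(previous_dose, measured_level, target_C0, d = 1) {
  if (any(previous_dose <= 0) || any(measured_level <= 0) ||
      any(target_C0 <= 0) || d <= 0)
    stop("all inputs must be > 0")
  previous_dose * (target_C0 / measured_level)^(1 / d)
}

#' Minimum number of blood samples for population-wide omega-optimality
#'
#' Monte Carlo estimate of the smallest number \eqn{n} of blood samples
#' such that, across the patient population, the empirical-Bayes dose
#' computed after \eqn{n} samples (i.e. the step-\eqn{(n+1)} dose) is
#' \eqn{\omega}-optimum for at least a fraction `population_fraction` of
#' patients.  Patients are simulated from the population model and run
#' through the dosing algorithm; because the algorithm removes all fixed
#' effects exactly, attainment depends only on the prediction error
#' \eqn{\hat\alpha - \alpha}, so the result does not depend on the
#' covariate distribution (covariates are still simulated for fidelity).
#'
#' @param model A [population_model].
#' @param window A [therapeutic_window].
#' @param omega,population_fraction Fractions in (0, 1).
#' @param X_generator Covariate specification (list of [cov_binary()] /
#'   [cov_normal()]), or empty.
#' @param max_n Largest number of samples tried.
#' @param n_sim Number of simulated patients (>= 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @return Integer: the minimum number of samples, or `max_n + 1L`
#'   (sentinel, with attribute `attained = FALSE`) if `max_n` samples do
#'   not suffice.  Attribute `fractions` holds the attainment fraction for
#'   n = 0..max_n.
#' @export
minimum_samples <- function(model, window, omega = 0.9,
                            population_fraction = 0.9,
                            X_generator = list(), max_n = 10L,
                            n_sim = 10000L, seed = 1L) {
  stopifnot(inherits(model, "population_model"),
            inherits(window, "therapeutic_window"))
  if (!(omega > 0 && omega < 1) ||
      !(population_fraction > 0 && population_fraction < 1))
    stop("omega and population_fraction must be in (0, 1)")
  if (n_sim < 1000) stop("n_sim must be >= 1000")
  pmax_target <- omega * max_attainable_probability(model, window)
  w2 <- log(window$l2 / window$l1) / 2
  se <- sqrt(model$sigma_eps2)
  ## known-alpha window probability of the EB dose depends only on the
  ## prediction error delta = alpha_hat - alpha:
  ## P(delta) = pnorm((w2 - delta)/se) - pnorm((-w2 - delta)/se)
  pwin <- function(delta)
    stats::pnorm((w2 - delta) / se) - stats::pnorm((-w2 - delta) / se)
  fracs <- local_seed(seed, {
    alpha <- stats::rnorm(n_sim, model$mu_alpha, sqrt(model$sigma_alpha2))
    if (length(X_generator)) invisible(generate_covariates(X_generator, n_sim))
    eps <- matrix(stats::rnorm(n_sim * max_n, 0, se), n_sim, max_n)
    out <- numeric(max_n + 1L)
    out[1] <- mean(pwin(model$mu_alpha - alpha) >= pmax_target)
    if (max_n > 0) {
      cum <- apply(eps, 1L, cumsum)            # max_n x n_sim
      if (max_n == 1L) cum <- matrix(cum, 1L, n_sim)
      for (n in seq_len(max_n)) {
        rbar <- alpha + cum[n, ] / n
        ahat <- (model$sigma_eps2 * model$mu_alpha +
                   n * model$sigma_alpha2 * rbar) /
          (model$sigma_eps2 + n * model$sigma_alpha2)
        out[n + 1L] <- mean(pwin(ahat - alpha) >= pmax_target)
      }
    }
    out
  })
  hit <- which(fracs >= population_fraction)
  res <- if (length(hit)) as.integer(hit[1] - 1L) else max_n + 1L
  attr(res, "attained") <- length(hit) > 0
  attr(res, "fractions") <- stats::setNames(fracs, 0:max_n)
  res
}
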