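#' Population random-intercept model of a log-linear dose-response
#'
#' Constructs the population model
#' \deqn{\log Y_D = \alpha + \beta^T X + d \log D + \varepsilon,}
#' where \eqn{Y_D} is a stable (steady-state trough) pharmacokinetic or
#' pharmacodynamic response to dosage \eqn{D}, \eqn{X} is a vector of
#' patient covariates, \eqn{\alpha \sim N(\mu_\alpha, \sigma^2_\alpha)} is a
#' patient-specific random intercept, and
#' \eqn{\varepsilon \sim N(0, \sigma^2_\varepsilon)} is intra-patient error,
#' independent of \eqn{\alpha}.  \eqn{\sigma^2_\alpha} measures inter-patient
#' variability (the component usually attributed, at least in part, to
#' genetic heterogeneity), \eqn{\sigma^2_\varepsilon} intra-patient
#' variability.  All logarithms are natural.
#'
#' @param mu_alpha Population mean of the random intercept (log-response
#'   units).
#' @param sigma_alpha2 Inter-patient variance of \eqn{\alpha} (must be
#'   \eqn{\ge 0}).
#' @param sigma_eps2 Intra-patient error variance (must be \eqn{> 0}).
#' @param beta Numeric vector of fixed covariate coefficients
#'   (log-response units per covariate unit); may be empty.
#' @param d Dose exponent, the coefficient of \eqn{\log D}; \eqn{d = 1}
#'   corresponds to linear pharmacokinetics.  Must be \eqn{> 0}.
#' @param covariate_names Character labels matching `beta`; defaults to
#'   `names(beta)` or `X1, X2, ...`.
#'
#' @return An object of class `population_model`.
#' @examples
#' pm <- population_model(mu_alpha = 1, sigma_alpha2 = 0.09,
#'                        sigma_eps2 = 0.04, beta = c(smoker = 0.3))
#' pm
#' @export
population_model <- function(mu_alpha, sigma_alpha2, sigma_eps2,
                             beta = numeric(0), d = 1,
                             covariate_names = NULL) {
  beta <- as.numeric(beta0 <- beta)
  if (is.null(covariate_names)) {
    covariate_names <- names(beta0)
    if (is.null(covariate_names) && length(beta) > 0)
      covariate_names <- paste0("X", seq_along(beta))
  }
  covariate_names <- as.character(covariate_names %||% character(0))
  stopifnot(
    is.numeric(mu_alpha), length(mu_alpha) == 1L, is.finite(mu_alpha),
    is.numeric(sigma_alpha2), length(sigma_alpha2) == 1L,
    is.numeric(sigma_eps2), length(sigma_eps2) == 1L,
    is.numeric(d), length(d) == 1L
  )
  if (sigma_alpha2 < 0) stop("sigma_alpha2 must be >= 0")
  if (!(sigma_eps2 > 0)) stop("sigma_eps2 must be > 0")
  if (!(d > 0)) stop("d must be > 0")
  if (length(beta) != length(covariate_names))
    stop("length(beta) must equal length(covariate_names)")
  if (any(!is.finite(beta))) stop("beta must be finite")
  structure(
    list(mu_alpha = unname(mu_alpha),
         sigma_alpha2 = unname(sigma_alpha2),
         sigma_eps2 = unname(sigma_eps2),
         beta = stats::setNames(beta, covariate_names),
         d = unname(d),
         covariate_names = covariate_names),
    class = "population_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_model <- function(x, ...) {
  cat("Random-intercept log-linear dose-response model\n")
  cat(sprintf("  mu_alpha     = %.6g\n", x$mu_alpha))
  cat(sprintf("  sigma_alpha2 = %.6g  (inter-patient)\n", x$sigma_alpha2))
  cat(sprintf("  sigma_eps2   = %.6g  (intra-patient)\n", x$sigma_eps2))
  cat(sprintf("  d            = %.6g  (dose exponent)\n", x$d))
  if (length(x$beta)) {
    cat("  fixed covariate effects:\n")
    for (i in seq_along(x$beta))
      cat(sprintf("    %-12s %.6g\n", x$covariate_names[i], x$beta[i]))
  } else cat("  (no covariates)\n")
  invisible(x)
}

## Covariate conformity check shared by several operations.
check_covariates <- function(model, X) {
  X <- as.numeric(X)
  if (length(X) != length(model$beta))
    stop("covariate vector has length ", length(X),
         " but the model has ", length(model$beta), " covariates")
  X
}

#' Patient-level log-residuals under a population model
#'
#' Computes \eqn{r_j = \log Y_j - \beta^T X - d \log D_j}, the patient-level
#' signal \eqn{\alpha + \varepsilon_j} implied by the model after removing
#' all fixed effects except the intercept.  The mean of these residuals over
#' a patient's history is the sufficient statistic for empirical Bayes
#' prediction of \eqn{\alpha}.
#'
#' @param model A [population_model].
#' @param patient_covariates Numeric covariate vector \eqn{X}, conforming to
#'   the model.
#' @param doses,responses Positive numeric vectors of equal length.
#' @return Numeric vector of residuals, one per observation.
#' @export
log_residuals <- function(model, patient_covariates, doses, responses) {
  X <- check_covariates(model, patient_covariates)
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (any(doses <= 0) || any(responses <= 0))
    stop("doses and responses must be strictly positive")
  log(responses) - sum(model$beta * X) - model$d * log(doses)
}

#' Write / read a population model as JSON
#'
#' Serializes all `population_model` fields (plus optional fit metadata) to
#' a structured JSON text file that round-trips through [read_model_json()]
#' bit-exactly for the stored decimal representation.
#'
#' @param model A [population_model], or a [fit_random_intercept()] result
#'   (its model, method and log-likelihood are stored).
#' @param path File path to write to / read from.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a [population_model] with any stored metadata in
#'   `attr(, "fit_info")`.
#' @export
write_model_json <- function(model, path) {
  info <- NULL
  if (inherits(model, "eb_fit")) {
    info <- list(method = model$method, log_likelihood = model$log_likelihood,
                 n_patients = model$n_patients, n_obs = model$n_obs)
    model <- model$model
  }
  stopifnot(inherits(model, "population_model"))
  out <- list(mu_alpha = model$mu_alpha, sigma_alpha2 = model$sigma_alpha2,
              sigma_eps2 = model$sigma_eps2, beta = unname(model$beta),
              d = model$d, covariate_names = model$covariate_names)
  if (!is.null(info)) out <- c(out, info)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- population_model(x$mu_alpha, x$sigma_alpha2, x$sigma_eps2,
                        beta = as.numeric(x$beta %||% numeric(0)),
                        d = x$d,
                        covariate_names = as.character(x$covariate_names %||% character(0)))
  extra <- setdiff(names(x), c("mu_alpha", "sigma_alpha2", "sigma_eps2",
                               "beta", "d", "covariate_names"))
  if (length(extra)) attr(m, "fit_info") <- x[extra]
  m
}
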