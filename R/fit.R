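## Random-intercept linear mixed model fitting by profiled (RE)ML.
##
## For a fixed variance ratio lambda = sigma_alpha2 / sigma_eps2 the fixed
## effects have a closed-form GLS solution and sigma_eps2 a closed-form
## profile estimate, so the whole fit reduces to a 1-D optimization of the
## profiled deviance over log(lambda).  All per-evaluation quantities are
## assembled from patient-level sufficient statistics, making a single
## likelihood evaluation O(n_patients * p^2).

## Design-side sufficient statistics, computed once per (X, grouping).
make_ri_design <- function(X, id) {
  id <- factor(id)
  ni <- as.numeric(table(id))
  list(X = X, id = id, ni = ni, k = nlevels(id), N = nrow(X),
       p = ncol(X), XtX = crossprod(X), Sx = rowsum(X, id, reorder = TRUE))
}

## y-side statistics for a given response vector.
ri_ystats <- function(des, y) {
  list(Xty = crossprod(des$X, y), yty = sum(y * y),
       sy = rowsum(y, des$id, reorder = TRUE)[, 1L])
}

## Profiled -2 log (restricted) likelihood at variance ratio lambda,
## together with the GLS coefficients and profile sigma_eps2.
ri_profile <- function(des, ys, lambda, reml) {
  ci <- lambda / (1 + des$ni * lambda)
  A <- des$XtX - crossprod(des$Sx * ci, des$Sx)
  b <- ys$Xty - crossprod(des$Sx, ci * ys$sy)
  R <- chol(A)
  beta <- backsolve(R, forwardsolve(t(R), b))
  yWy <- ys$yty - sum(ci * ys$sy^2)
  Q <- max(yWy - sum(beta * b), 0)
  ldV <- sum(log1p(des$ni * lambda))
  if (reml) {
    df <- des$N - des$p
    s2 <- Q / df
    crit <- df * log(2 * pi * s2) + ldV + 2 * sum(log(diag(R))) + df
  } else {
    s2 <- Q / des$N
    crit <- des$N * log(2 * pi * s2) + ldV + des$N
  }
  list(crit = crit, beta = drop(beta), sigma_eps2 = s2, A = A, Q = Q)
}

## -2 log (restricted) likelihood at arbitrary (sigma_alpha2, sigma_eps2),
## fixed effects profiled out; used for observed-information standard errors.
ri_neg2ll <- function(des, ys, sa2, se2, reml) {
  lambda <- sa2 / se2
  ci <- lambda / (1 + des$ni * lambda)
  A <- des$XtX - crossprod(des$Sx * ci, des$Sx)
  b <- ys$Xty - crossprod(des$Sx, ci * ys$sy)
  R <- chol(A)
  beta <- backsolve(R, forwardsolve(t(R), b))
  Q <- max(ys$yty - sum(ci * ys$sy^2) - sum(beta * b), 0)
  ldV <- des$N * log(se2) + sum(log1p(des$ni * lambda))
  if (reml) {
    (des$N - des$p) * log(2 * pi) + ldV +
      (2 * sum(log(diag(R))) - des$p * log(se2)) + Q / se2
  } else {
    des$N * log(2 * pi) + ldV + Q / se2
  }
}

## Core fit on a prepared design; cheap to call repeatedly (bootstrap).
fit_ri_core <- function(des, y, reml = TRUE, interval = c(-30, 15)) {
  ys <- ri_ystats(des, y)
  obj <- function(loglam) ri_profile(des, ys, exp(loglam), reml)$crit
  opt <- stats::optimize(obj, interval = interval, tol = 1e-10)
  lam <- exp(opt$minimum)
  at0 <- ri_profile(des, ys, 0, reml)          # sigma_alpha2 = 0 boundary
  best <- ri_profile(des, ys, lam, reml)
  boundary <- FALSE
  if (at0$crit <= best$crit + 1e-10) {         # boundary truncation at zero
    lam <- 0; best <- at0; boundary <- TRUE
  }
  list(lambda = lam, beta = best$beta, sigma_eps2 = best$sigma_eps2,
       sigma_alpha2 = lam * best$sigma_eps2, crit = best$crit, A = best$A,
       boundary = boundary, ystats = ys,
       converged = is.finite(best$crit) && best$sigma_eps2 > 0)
}

#' Fit the random-intercept log-linear model by REML or ML
#'
#' Estimates \eqn{(\mu_\alpha, \beta, d, \sigma^2_\alpha,
#' \sigma^2_\varepsilon)} of the model
#' \eqn{\log Y_{ij} = \alpha_i + \beta^T X_i + d \log D_{ij} +
#' \varepsilon_{ij}} from a long-format repeated-measures table.  The fixed
#' effects are profiled out analytically and the deviance is optimized over
#' the variance ratio on the log scale, with the
#' \eqn{\hat\sigma^2_\alpha = 0} boundary handled explicitly.  Estimates are
#' deterministic given the data and method.
#'
#' @param data A [long_table] (or conforming data frame).  All columns
#'   beyond `patient_id`, `dose`, `response` enter as fixed-effect
#'   covariates.
#' @param fix_d_at_one If `TRUE`, constrains the dose exponent to
#'   \eqn{d = 1} (linear pharmacokinetics), i.e. models the log
#'   concentration-to-dose ratio; otherwise \eqn{d} is estimated as the
#'   coefficient of \eqn{\log D}.
#' @param method `"REML"` (default; less biased variance components) or
#'   `"ML"` (use for likelihood-ratio comparisons of fixed effects).
#' @param allow_time_varying Passed to [validate_long_table()].
#' @return An object of class `eb_fit`: a list with elements `model` (a
#'   [population_model] of point estimates), `standard_errors` (named;
#'   observed-information for the variance components, GLS for the fixed
#'   effects; `NA` for a boundary \eqn{\hat\sigma^2_\alpha = 0}),
#'   `log_likelihood`, `method`, `converged`, `n_patients`, `n_obs`.
#' @examples
#' cfg <- sim_config(population_model(1, 0.09, 0.04, beta = 0.3),
#'                   covariates = list(cov_binary("X1", 0.5)),
#'                   n_patients = 60, seed = 7)
#' fit <- fit_random_intercept(generate_long_table(cfg, doses_per_patient = 4))
#' fit
#' @export
fit_random_intercept <- function(data, fix_d_at_one = FALSE,
                                 method = c("REML", "ML"),
                                 allow_time_varying = FALSE) {
  method <- match.arg(method)
  validate_long_table(data, allow_time_varying = allow_time_varying)
  covs <- long_table_covariates(data)
  y <- log(data$response)
  X <- cbind(`(intercept)` = rep(1, nrow(data)),
             as.matrix(as.data.frame(data)[, covs, drop = FALSE]))
  if (length(covs)) colnames(X) <- c("(intercept)", covs)
  if (fix_d_at_one) {
    y <- y - log(data$dose)
  } else {
    X <- cbind(X, `log(dose)` = log(data$dose))
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: covariates (and log dose, if d is ",
         "estimated) are collinear")
  des <- make_ri_design(X, data$patient_id)
  core <- fit_ri_core(des, y, reml = (method == "REML"))

  p <- des$p
  coef_names <- colnames(X)
  beta_full <- stats::setNames(core$beta, coef_names)
  mu_alpha <- beta_full[["(intercept)"]]
  d_hat <- if (fix_d_at_one) 1 else beta_full[["log(dose)"]]
  beta_cov <- beta_full[covs]
  if (!fix_d_at_one && d_hat <= 0)
    warning("estimated dose exponent d is non-positive; ",
            "dose formulas require d > 0")

  ## standard errors: GLS for fixed effects, observed information (central
  ## finite differences of the profiled deviance) for variance components
  vc_fix <- core$sigma_eps2 * chol2inv(chol(core$A))
  se_fix <- stats::setNames(sqrt(pmax(diag(vc_fix), 0)), coef_names)
  se_vc <- c(sigma_alpha2 = NA_real_, sigma_eps2 = NA_real_)
  if (!core$boundary) {
    th <- c(core$sigma_alpha2, core$sigma_eps2)
    h <- pmax(1e-5, 1e-4 * th)
    f <- function(t) ri_neg2ll(des, core$ystats, t[1], t[2],
                               method == "REML") / 2
    H <- matrix(NA_real_, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                  f(th - ei + ej) + f(th - ei - ej)) / (4 * h[i] * h[j])
    }
    H <- (H + t(H)) / 2
    ok <- tryCatch({v <- diag(solve(H)); all(v > 0)}, error = function(e) FALSE)
    if (ok) se_vc <- stats::setNames(sqrt(diag(solve(H))),
                                     c("sigma_alpha2", "sigma_eps2"))
  } else {
    ## sigma_eps2 SE from the 1-D curvature along sigma_eps2 at the boundary
    se2 <- core$sigma_eps2; h <- 1e-4 * se2
    f1 <- function(s) ri_neg2ll(des, core$ystats, 0, s, method == "REML") / 2
    curv <- (f1(se2 + h) - 2 * f1(se2) + f1(se2 - h)) / h^2
    if (is.finite(curv) && curv > 0) se_vc["sigma_eps2"] <- 1 / sqrt(curv)
  }

  model <- population_model(mu_alpha = mu_alpha,
                            sigma_alpha2 = core$sigma_alpha2,
                            sigma_eps2 = core$sigma_eps2,
                            beta = unname(beta_cov), d = unname(d_hat),
                            covariate_names = covs)
  se <- c(mu_alpha = unname(se_fix[["(intercept)"]]),
          stats::setNames(se_fix[covs], covs),
          d = if (fix_d_at_one) 0 else unname(se_fix[["log(dose)"]]),
          se_vc)
  structure(
    list(model = model, standard_errors = se,
         log_likelihood = -core$crit / 2, method = method,
         converged = core$converged, boundary = core$boundary,
         n_patients = des$k, n_obs = des$N, n_fixed = p),
    class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat(sprintf("Random-intercept model fit (%s)\n", x$method))
  cat(sprintf("  %d patients, %d observations; log-likelihood %.4f%s\n",
              x$n_patients, x$n_obs, x$log_likelihood,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$boundary)
    cat("  note: sigma_alpha2 estimated at the zero boundary\n")
  est <- c(mu_alpha = x$model$mu_alpha,
           stats::setNames(unname(x$model$beta), x$model$covariate_names),
           d = x$model$d, sigma_alpha2 = x$model$sigma_alpha2,
           sigma_eps2 = x$model$sigma_eps2)
  tab <- data.frame(estimate = est, std.error = x$standard_errors[names(est)])
  print(round(tab, 6))
  invisible(x)
}

#' @export
logLik.eb_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_fixed + 2L,
            class = "logLik")
}
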