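#' Relative-percentile effect size of a covariate
#'
#' For a log-linear model, a regression coefficient \eqn{\beta^*} of a
#' covariate multiplies every percentile of the (lognormal) response
#' distribution by \eqn{e^{\beta^*}} - the same factor at every percentile,
#' which is what makes the effect size
#' \deqn{E = (e^{\beta^*} - 1) \times 100\%}
#' clinically interpretable: it is the percent shift of the whole response
#' distribution.  For steady-state drug levels, a positive \eqn{E} reads as
#' metabolism inhibition by the covariate, a negative \eqn{E} as induction.
#' The dose-correction factor \eqn{e^{-\beta^*}} is the multiplier to apply
#' to a patient's dosage when their covariate status changes from 0 to 1;
#' it satisfies \eqn{factor \cdot (1 + E/100) = 1} exactly.
#'
#' @param beta_star Regression coefficient (log-response units).
#' @param se Optional standard error of `beta_star`, for a delta-method
#'   (normal-on-the-log-scale) confidence interval for \eqn{E}.
#' @param level Confidence level (default 0.95).
#' @return An object of class `effect_size_report`: `coefficient`,
#'   `effect_percent`, `correction_factor`, and `ci_percent` (or `NULL`).
#' @examples
#' effect_size(log(2))     # +100% effect, dose-correction factor 0.5
#' @export
effect_size <- function(beta_star, se = NULL, level = 0.95) {
  stopifnot(is.finite(beta_star))
  ci <- NULL
  if (!is.null(se) && is.finite(se)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- (exp(beta_star + c(-1, 1) * z * se) - 1) * 100
  }
  structure(list(coefficient = beta_star,
                 effect_percent = (exp(beta_star) - 1) * 100,
                 correction_factor = exp(-beta_star),
                 ci_percent = ci),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  dir <- if (x$effect_percent > 0) "inhibition (+)"
         else if (x$effect_percent < 0) "induction (-)" else "no effect"
  cat(sprintf("Effect size E = %+.4g%%  [%s]\n", x$effect_percent, dir))
  cat(sprintf("  coefficient beta* = %.6g; dose-correction factor = %.6g\n",
              x$coefficient, x$correction_factor))
  if (!is.null(x$ci_percent))
    cat(sprintf("  CI for E: (%+.4g%%, %+.4g%%)\n",
                x$ci_percent[1], x$ci_percent[2]))
  invisible(x)
}

#' Stratum-specific effect size from main + interaction coefficients
#'
#' When a covariate's effect is modified by a second, binary covariate
#' (e.g. a comedication effect that differs between smokers and
#' non-smokers), the effect within stratum \eqn{s \in \{0, 1\}} has
#' coefficient \eqn{\beta^* = \beta_{main} + s\,\beta_{interaction}}, and
#' its effect size follows from [effect_size()].
#'
#' @param beta_main Main-effect coefficient (the stratum-0 effect).
#' @param beta_interaction Interaction coefficient.
#' @param stratum 0 or 1.
#' @inheritParams effect_size
#' @return An `effect_size_report` for the requested stratum.
#' @export
stratum_effect_size <- function(beta_main, beta_interaction, stratum,
                                se = NULL, level = 0.95) {
  if (!stratum %in% c(0, 1)) stop("stratum must be 0 or 1")
  effect_size(beta_main + stratum * beta_interaction, se = se, level = level)
}

#' Per-covariate effect-size table for a fitted model
#'
#' @param fit An [fit_random_intercept()] result.
#' @param level Confidence level for the delta-method CIs.
#' @return Data frame with one row per covariate: coefficient, standard
#'   error, effect percent, CI bounds, dose-correction factor.
#' @export
effect_size_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "eb_fit"))
  covs <- fit$model$covariate_names
  rows <- lapply(covs, function(cv) {
    es <- effect_size(fit$model$beta[[cv]], se = fit$standard_errors[[cv]],
                      level = level)
    data.frame(covariate = cv, coefficient = es$coefficient,
               std_error = fit$standard_errors[[cv]],
               effect_percent = es$effect_percent,
               ci_lower = if (is.null(es$ci_percent)) NA else es$ci_percent[1],
               ci_upper = if (is.null(es$ci_percent)) NA else es$ci_percent[2],
               correction_factor = es$correction_factor)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Three-condition variance-decomposition screen for a genetic covariate
#'
#' Implements the design principle that a genetic variant deserves
#' follow-up only if, with the relevant non-genetic covariates already in
#' the model, three facts hold simultaneously:
#' \enumerate{
#'   \item its regression coefficient differs significantly from 0
#'     (ML likelihood-ratio test);
#'   \item adding it significantly decreases the inter-patient variance
#'     \eqn{\sigma^2_\alpha} (genetic heterogeneity lives in the random
#'     intercept);
#'   \item adding it does \emph{not} significantly decrease the
#'     intra-patient variance \eqn{\sigma^2_\varepsilon} (genetic variation
#'     cannot explain within-patient fluctuation, so a drop there marks an
#'     artifact).
#' }
#' Conditions 2-3 use one-sided parametric-bootstrap null distributions of
#' the variance-component changes: datasets are simulated from the fitted
#' base (variant-free) model with the observed design and variant column,
#' and both models are refit to each.  The conjunction of the three
#' conditions is the overall verdict.
#'
#' @param data A [long_table] containing base covariates and the variant
#'   column.  The variant column may vary within a patient (so that
#'   observation-level artifacts can be screened out); base covariates may
#'   not.
#' @param base_covariates Character vector of non-genetic covariate
#'   columns.
#' @param variant_covariate Name of the candidate variant column.
#' @param alpha_level Significance level for all three conditions.
#' @param n_boot Parametric-bootstrap replicates (a value below 200 is
#'   accepted but flagged in the result).
#' @param seed Integer seed; the whole screen is deterministic given it.
#' @param fix_d_at_one Passed to the model fits.
#' @param margin Minimum practically relevant variance change, as a
#'   fraction of the base-model component (default 0.01): smaller observed
#'   changes are treated as zero when computing the one-sided bootstrap
#'   p-values, so that numerically negligible refit differences cannot
#'   masquerade as significant variance shifts.
#' @return An object of class `variant_screen`: coefficient and LRT
#'   p-value, observed variance-component changes (base minus augmented),
#'   their bootstrap p-values, the three condition verdicts and the
#'   overall verdict.
#' @export
screen_variant <- function(data, base_covariates, variant_covariate,
                           alpha_level = 0.05, n_boot = 500L, seed = 1L,
                           fix_d_at_one = FALSE, margin = 0.01) {
  stopifnot(length(variant_covariate) == 1L)
  cols0 <- c("patient_id", "dose", "response", base_covariates)
  if (!all(c(cols0, variant_covariate) %in% names(data)))
    stop("data must contain the base and variant covariate columns")
  base <- as.data.frame(data)[cols0]
  aug <- as.data.frame(data)[c(cols0, variant_covariate)]
  class(base) <- class(aug) <- c("long_table", "data.frame")
  warn_boot <- n_boot < 200L

  ## condition 1: ML likelihood-ratio test on the variant coefficient
  ml0 <- fit_random_intercept(base, fix_d_at_one, "ML")
  ml1 <- fit_random_intercept(aug, fix_d_at_one, "ML",
                              allow_time_varying = TRUE)
  lrt <- max(0, 2 * (ml1$log_likelihood - ml0$log_likelihood))
  p_coef <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)

  ## observed variance-component changes under REML
  r0 <- fit_random_intercept(base, fix_d_at_one, "REML")
  r1 <- fit_random_intercept(aug, fix_d_at_one, "REML",
                             allow_time_varying = TRUE)
  d_sa2 <- r0$model$sigma_alpha2 - r1$model$sigma_alpha2
  d_se2 <- r0$model$sigma_eps2 - r1$model$sigma_eps2

  ## parametric bootstrap of the changes under the base (null) model,
  ## reusing the two prepared designs for speed
  pm <- r0$model
  id <- factor(base$patient_id)
  covs <- base_covariates
  X0 <- cbind(1, as.matrix(base[, covs, drop = FALSE]))
  X1 <- cbind(1, as.matrix(aug[, c(covs, variant_covariate),
                               drop = FALSE]))
  ## The working response is log(Y) when d is estimated, log(Y) - log(D)
  ## when d is fixed at 1; `fixmean` is its fixed-effect mean either way.
  off <- log(base$dose)
  if (fix_d_at_one) {
    fixmean <- drop(X0 %*% c(pm$mu_alpha, unname(pm$beta)))
  } else {
    X0 <- cbind(X0, off); X1 <- cbind(X1, off)
    fixmean <- drop(X0 %*% c(pm$mu_alpha, unname(pm$beta), pm$d))
  }
  des0 <- make_ri_design(X0, id)
  des1 <- make_ri_design(X1, id)
  k <- nlevels(id); idx <- as.integer(id)
  N <- nrow(base)
  boot <- local_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      a <- stats::rnorm(k, 0, sqrt(pm$sigma_alpha2))
      ystar <- fixmean + a[idx] +
        stats::rnorm(N, 0, sqrt(pm$sigma_eps2))
      f0 <- fit_ri_core(des0, ystar, reml = TRUE)
      f1 <- fit_ri_core(des1, ystar, reml = TRUE)
      out[b, ] <- c(f0$sigma_alpha2 - f1$sigma_alpha2,
                    f0$sigma_eps2 - f1$sigma_eps2)
    }
    out
  })
  ## Meaningful-change margin: a variance-component reduction below
  ## `margin` (relative to the base-model estimate) is treated as no
  ## reduction when computing the one-sided bootstrap p-values.  Changes at
  ## that scale arise from numerical cross-talk between the two fits'
  ## variance-ratio optima and carry no information; a genuine reduction -
  ## a causal intercept covariate or an intra-patient artifact - is orders
  ## of magnitude larger.
  tol_a <- margin * max(r0$model$sigma_alpha2, r0$model$sigma_eps2)
  tol_e <- margin * r0$model$sigma_eps2
  p_alpha <- (1 + sum(boot[, 1] >= d_sa2 - tol_a)) / (n_boot + 1)
  p_eps <- (1 + sum(boot[, 2] >= d_se2 - tol_e)) / (n_boot + 1)

  cond1 <- p_coef <= alpha_level
  cond2 <- p_alpha <= alpha_level
  cond3 <- p_eps > alpha_level
  structure(
    list(variant = variant_covariate,
         coef = unname(ml1$model$beta[variant_covariate]),
         coef_p = p_coef,
         delta_sigma_alpha2 = d_sa2, delta_sigma_eps2 = d_se2,
         p_alpha_reduction = p_alpha, p_eps_reduction = p_eps,
         conditions = c(coefficient = cond1, alpha_reduction = cond2,
                        no_eps_reduction = cond3),
         pass = cond1 && cond2 && cond3,
         alpha_level = alpha_level, n_boot = as.integer(n_boot),
         low_boot_warning = warn_boot, seed = as.integer(seed)),
    class = "variant_screen")
}

#' @export
print.variant_screen <- function(x, ...) {
  cat(sprintf("Pharmacogenomic variant screen: '%s'\n", x$variant))
  cat(sprintf("  (1) coefficient %.4g, LRT p = %.4g  -> %s\n",
              x$coef, x$coef_p, ifelse(x$conditions[1], "PASS", "fail")))
  cat(sprintf("  (2) delta sigma_alpha2 = %.4g, bootstrap p = %.4g  -> %s\n",
              x$delta_sigma_alpha2, x$p_alpha_reduction,
              ifelse(x$conditions[2], "PASS", "fail")))
  cat(sprintf("  (3) delta sigma_eps2 = %.4g, bootstrap p = %.4g  -> %s\n",
              x$delta_sigma_eps2, x$p_eps_reduction,
              ifelse(x$conditions[3], "PASS", "fail")))
  cat(sprintf("  overall verdict: %s (alpha = %g, %d bootstrap reps%s)\n",
              if (x$pass) "CONSIDER FOR FOLLOW-UP" else "DO NOT PURSUE",
              x$alpha_level, x$n_boot,
              if (x$low_boot_warning) "; WARNING: n_boot < 200" else ""))
  invisible(x)
}
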