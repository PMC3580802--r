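## Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring
## the caller's stream afterwards (same discipline as stats::simulate).
local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Covariate distribution specifications
#'
#' Building blocks for the covariate generator used by the simulator:
#' `cov_binary` draws Bernoulli(p) indicators (e.g. smoking status, a
#' genetic variant carrier flag), `cov_normal` draws Normal(mean, sd)
#' values (e.g. a standardized clinical measurement).
#'
#' @param name Column label.
#' @param p Success probability for the binary covariate.
#' @param mean,sd Normal parameters.
#' @return A covariate spec (list) understood by [generate_covariates()].
#' @export
cov_binary <- function(name, p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  list(name = name, dist = "binary", p = p)
}

#' @rdname cov_binary
#' @export
cov_normal <- function(name, mean = 0, sd = 1) {
  stopifnot(sd >= 0)
  list(name = name, dist = "normal", mean = mean, sd = sd)
}

#' Draw a covariate matrix from a specification list
#' @param spec List of covariate specs ([cov_binary()], [cov_normal()]).
#' @param n Number of patients.
#' @return Numeric matrix `n x length(spec)` with named columns.
#' @export
generate_covariates <- function(spec, n) {
  cols <- lapply(spec, function(s) {
    switch(s$dist,
           binary = stats::rbinom(n, 1L, s$p),
           normal = stats::rnorm(n, s$mean, s$sd),
           stop("unknown covariate distribution '", s$dist, "'"))
  })
  m <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  colnames(m) <- vapply(spec, `[[`, "", "name")
  m
}

#' Simulation scenario configuration
#'
#' Describes a synthetic patient population and trial design: the
#' generating [population_model], covariate distributions, therapeutic
#' window, the \eqn{\omega} used for optimality accounting, trial size,
#' number of algorithm steps, competing strategies, and a mandatory seed.
#'
#' The package default scenario (all arguments at their defaults) is a
#' moderately variable drug with linear kinetics: \eqn{\mu_\alpha = 1},
#' \eqn{\sigma^2_\alpha = 0.09}, \eqn{\sigma^2_\varepsilon = 0.04},
#' one binary covariate with effect 0.3, \eqn{d = 1}, and a therapeutic
#' window with index \eqn{l_2/l_1 = 2}.
#'
#' @param population A [population_model].
#' @param covariates List of covariate specs, one per model covariate.
#' @param window A [therapeutic_window].
#' @param omega Optimality fraction in (0, 1).
#' @param n_patients,n_steps Trial size (>= 1 each).
#' @param strategies Character subset of `"empirical_bayes"`, `"tdm"`,
#'   `"fixed_population_dose"`.
#' @param seed Integer seed (mandatory).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(population = population_model(1, 0.09, 0.04,
                                                     beta = c(X1 = 0.3)),
                       covariates = list(cov_binary("X1", 0.5)),
                       window = therapeutic_window(2, 4),
                       omega = 0.9, n_patients = 2000L, n_steps = 6L,
                       strategies = c("empirical_bayes", "tdm",
                                      "fixed_population_dose"),
                       seed = NULL) {
  stopifnot(inherits(population, "population_model"),
            inherits(window, "therapeutic_window"))
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  if (length(covariates) != length(population$beta))
    stop("need one covariate spec per model covariate")
  strategies <- match.arg(strategies,
                          c("empirical_bayes", "tdm",
                            "fixed_population_dose"),
                          several.ok = TRUE)
  if (n_patients < 1 || n_steps < 1) stop("n_patients and n_steps must be >= 1")
  if (!(omega > 0 && omega < 1)) stop("omega must be in (0, 1)")
  structure(list(population = population, covariates = covariates,
                 window = window, omega = omega,
                 n_patients = as.integer(n_patients),
                 n_steps = as.integer(n_steps),
                 strategies = strategies, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a synthetic patient population
#'
#' Realizes the population the model describes: patient intercepts
#' \eqn{\alpha_i \sim N(\mu_\alpha, \sigma^2_\alpha)} and covariates from
#' the configured distributions.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return Data frame with column `true_alpha` followed by covariates.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pm <- config$population
  local_seed(config$seed, {
    alpha <- stats::rnorm(config$n_patients, pm$mu_alpha,
                          sqrt(pm$sigma_alpha2))
    X <- generate_covariates(config$covariates, config$n_patients)
    cbind(data.frame(true_alpha = alpha), as.data.frame(X))
  })
}

#' Simulate a steady-state response to an administered dose
#'
#' Draws \eqn{Y = \exp(\alpha + \beta^T X + d \log D + \varepsilon)} with
#' \eqn{\varepsilon \sim N(0, \sigma^2_\varepsilon)}, using the current RNG
#' stream.
#'
#' @param model A [population_model].
#' @param true_alpha Patient intercept.
#' @param X Covariate vector.
#' @param dose Positive dosage.
#' @param n Number of replicate draws (default 1).
#' @return Positive response(s).
#' @export
generate_response <- function(model, true_alpha, X, dose, n = 1L) {
  stopifnot(inherits(model, "population_model"))
  if (any(dose <= 0)) stop("dose must be > 0")
  X <- check_covariates(model, X)
  eta <- if (length(model$beta)) sum(model$beta * X) else 0
  exp(true_alpha + eta + model$d * log(dose) +
        stats::rnorm(n, 0, sqrt(model$sigma_eps2)))
}

#' Head-to-head trial of dosing strategies on a common population
#'
#' Runs each configured strategy on the same simulated patients under
#' common random numbers: all strategies see identical intercepts,
#' covariates, and per-(patient, step) intra-patient error draws, so they
#' differ only through the dosages they choose.  Each strategy starts from
#' the model-based initial dose; thereafter
#' \describe{
#'   \item{empirical_bayes}{updates the dose from the full history via
#'     [update_dose()] (Bayesian feedback);}
#'   \item{tdm}{applies the traditional proportional adjustment
#'     [tdm_update()] toward \eqn{C_0 = \sqrt{l_1 l_2}} using the latest
#'     measured level only;}
#'   \item{fixed_population_dose}{repeats the initial (average-patient)
#'     dose, as a no-feedback baseline.}
#' }
#' For every administered dose the known-\eqn{\alpha} window probability,
#' \eqn{\omega}-optimality flag and implied intercept prediction error are
#' recorded.
#'
#' @param config A [sim_config].
#' @return An object of class `trial_result`: `summary` is a tidy data
#'   frame (strategy, step, mean_window_probability, frac_omega_optimum,
#'   mean_abs_gamma_error, mean_posterior_variance), `trajectories` holds
#'   per-patient dose and probability matrices, `population` the generated
#'   patients, and `max_attainable` the ceiling probability.
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pm <- config$population
  win <- config$window
  n <- config$n_patients; K <- config$n_steps
  pop <- generate_population(config)
  alpha <- pop$true_alpha
  X <- as.matrix(pop[, -1, drop = FALSE])
  eta <- if (length(pm$beta)) drop(X %*% pm$beta) else numeric(n)
  se <- sqrt(pm$sigma_eps2)
  eps <- local_seed(config$seed + 1L,
                    matrix(stats::rnorm(n * K, 0, se), n, K))
  pmax_att <- max_attainable_probability(pm, win)
  thresh <- config$omega * pmax_att
  logg <- log(win$g)
  w2 <- log(win$l2 / win$l1) / 2
  sa2 <- pm$sigma_alpha2; se2 <- pm$sigma_eps2

  ## known-alpha window probability of a dose with log-mean m_i
  pwin <- function(m) stats::pnorm((logg + w2 - m) / se) -
    stats::pnorm((logg - w2 - m) / se)

  logD1 <- (logg - pm$mu_alpha - eta) / pm$d    # common initial dose
  out <- list(); traj <- list()
  for (strat in config$strategies) {
    logD <- matrix(NA_real_, n, K)
    ahat <- matrix(NA_real_, n, K)              # implied intercept predictor
    vpost <- matrix(NA_real_, n, K)
    logD[, 1] <- logD1
    ahat[, 1] <- pm$mu_alpha
    vpost[, 1] <- sa2
    if (K > 1) {
      if (strat == "empirical_bayes") {
        ## residual r_t = alpha + eps_t regardless of dose administered
        cum <- t(apply(eps, 1, cumsum))
        if (K == 1L) cum <- matrix(cum, n, 1L)
        for (t in 2:K) {
          nt <- t - 1
          rbar <- alpha + cum[, nt] / nt
          ahat[, t] <- (se2 * pm$mu_alpha + nt * sa2 * rbar) /
            (se2 + nt * sa2)
          vpost[, t] <- sa2 * se2 / (se2 + nt * sa2)
          logD[, t] <- (logg - ahat[, t] - eta) / pm$d
        }
      } else if (strat == "tdm") {
        for (t in 2:K) {
          logY <- alpha + eta + pm$d * logD[, t - 1] + eps[, t - 1]
          logD[, t] <- logD[, t - 1] + (logg - logY) / pm$d
          ahat[, t] <- logg - eta - pm$d * logD[, t]  # implied predictor
          vpost[, t] <- NA_real_
        }
      } else {                                   # fixed_population_dose
        for (t in 2:K) {
          logD[, t] <- logD1; ahat[, t] <- pm$mu_alpha; vpost[, t] <- sa2
        }
      }
    }
    m <- alpha + eta + pm$d * logD               # log-mean at each dose
    probs <- pwin(m)
    opt <- probs >= thresh
    gerr <- if (sa2 > 0) abs(ahat - alpha) / sqrt(sa2) else
      matrix(0, n, K)
    out[[strat]] <- data.frame(
      strategy = strat, step = seq_len(K),
      mean_window_probability = colMeans(probs),
      frac_omega_optimum = colMeans(opt),
      mean_abs_gamma_error = colMeans(gerr),
      mean_posterior_variance = colMeans(vpost))
    traj[[strat]] <- list(log_dose = logD, window_probability = probs,
                          alpha_hat = ahat)
  }
  structure(list(summary = do.call(rbind, c(out, make.row.names = FALSE)),
                 trajectories = traj, population = pop,
                 max_attainable = pmax_att, config = config),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "Dosing-strategy trial: %d patients, %d steps (max attainable P = %.4f)\n",
    x$config$n_patients, x$config$n_steps, x$max_attainable))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generate a long-format fitting table with known ground truth
#'
#' Produces a repeated-measures [long_table] from the configured
#' population: per-patient intercepts and covariates from
#' [generate_population()], doses drawn log-uniformly over `dose_range`
#' (so the dose exponent is identifiable), responses from the model.  The
#' generating parameters are attached as `attr(, "truth")`.
#'
#' @param config A [sim_config].
#' @param doses_per_patient Observations per patient (>= 1).
#' @param dose_range Positive range for the log-uniform dose draw.
#' @return A [long_table] (validation is skipped when
#'   `doses_per_patient = 1`, which yields a table that
#'   [fit_random_intercept()] rejects as inseparable - by design).
#' @export
generate_long_table <- function(config, doses_per_patient = 5L,
                                dose_range = c(0.5, 2)) {
  stopifnot(inherits(config, "sim_config"), doses_per_patient >= 1)
  pm <- config$population
  pop <- generate_population(config)
  n <- config$n_patients; m <- as.integer(doses_per_patient)
  X <- as.matrix(pop[, -1, drop = FALSE])
  eta <- if (length(pm$beta)) drop(X %*% pm$beta) else numeric(n)
  local_seed(config$seed + 2L, {
    logD <- matrix(stats::runif(n * m, log(dose_range[1]),
                                log(dose_range[2])), n, m)
    eps <- matrix(stats::rnorm(n * m, 0, sqrt(pm$sigma_eps2)), n, m)
    logY <- pop$true_alpha + eta + pm$d * logD + eps
    idx <- rep(seq_len(n), each = m)
    df <- long_table(
      patient_id = sprintf("P%04d", idx),
      dose = exp(t(logD))[seq_len(n * m)],
      response = exp(t(logY))[seq_len(n * m)],
      covariates = as.data.frame(X)[idx, , drop = FALSE],
      validate = m >= 2L && n >= 2L)
    attr(df, "truth") <- pm
    df
  })
}
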