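# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (closed forms, quadrature, brute-force grids).

# One-way random-effects ANOVA closed form on r_ij = log(Y_ij / D_ij) for a
# balanced, covariate-free design with m replicates per patient.
anova_oracle <- function(data) {
  r <- log(data$response / data$dose)
  id <- data$patient_id
  m <- unique(table(id))
  stopifnot(length(m) == 1L)
  k <- length(unique(id))
  ri <- tapply(r, id, mean)
  msb <- m * sum((ri - mean(r))^2) / (k - 1)
  msw <- sum((r - ri[id])^2) / (k * (m - 1))
  list(mu_alpha = mean(r), sigma_eps2 = msw,
       sigma_alpha2 = max(0, (msb - msw) / m))
}

# Normal-normal posterior of alpha by numerical quadrature: prior
# N(mu_alpha, sigma_alpha2), likelihood prod_j N(r_j; alpha, sigma_eps2).
quadrature_posterior <- function(model, r) {
  mu <- model$mu_alpha; sa <- sqrt(model$sigma_alpha2)
  se <- sqrt(model$sigma_eps2)
  logkern <- function(a)
    stats::dnorm(a, mu, sa, log = TRUE) +
      vapply(a, function(ai) sum(stats::dnorm(r, ai, se, log = TRUE)), 0)
  lo <- min(mu - 12 * sa, r) - 1; hi <- max(mu + 12 * sa, r) + 1
  grid <- seq(lo, hi, length.out = 20001)
  M <- max(logkern(grid))                    # log-space stabilization
  kern <- function(a) exp(logkern(a) - M)
  z0 <- stats::integrate(kern, lo, hi, rel.tol = 1e-12,
                         subdivisions = 2000L)$value
  m1 <- stats::integrate(function(a) a * kern(a), lo, hi, rel.tol = 1e-12,
                         subdivisions = 2000L)$value / z0
  m2 <- stats::integrate(function(a) (a - m1)^2 * kern(a), lo, hi,
                         rel.tol = 1e-12,
                         subdivisions = 2000L)$value / z0
  list(mean = m1, var = m2)
}

# Random model/window generators for property-style sweeps.
random_model <- function(n_cov = 0) {
  population_model(
    mu_alpha = stats::runif(1, -1, 2),
    sigma_alpha2 = stats::runif(1, 0.01, 0.5),
    sigma_eps2 = stats::runif(1, 0.01, 0.3),
    beta = if (n_cov) stats::runif(n_cov, -0.5, 0.5) else numeric(0),
    d = stats::runif(1, 0.5, 1.5))
}

random_window <- function() {
  l1 <- stats::runif(1, 0.2, 5)
  therapeutic_window(l1, l1 * stats::runif(1, 1.2, 4))
}

# Balanced covariate-free fixture on the concentration/dose-ratio scale.
balanced_table <- function(k = 20, m = 4, mu = 1, sa2 = 0.09, se2 = 0.04,
                           seed = 1) {
  cfg <- sim_config(population_model(mu, sa2, se2),
                    covariates = list(), n_patients = k, seed = seed)
  generate_long_table(cfg, doses_per_patient = m)
}

# Screen fixture: one binary base covariate (smoke) plus a candidate
# variant column g that is truly causal ("real"), pure noise ("null"), or
# an observation-level artifact tracking intra-patient error
# ("eps_artifact").
make_screen_data <- function(n_patients, m, variant = c("real", "null",
                                                        "eps_artifact"),
                             effect = 0.3, seed = 1) {
  variant <- match.arg(variant)
  set.seed(seed)
  g <- stats::rbinom(n_patients, 1L, 0.4)
  beta_g <- if (variant == "real") effect else 0
  idx <- rep(seq_len(n_patients), each = m)
  smoke <- stats::rbinom(n_patients, 1L, 0.5)
  alpha <- stats::rnorm(n_patients, 1, sqrt(0.04))
  logD <- stats::runif(n_patients * m, log(0.5), log(2))
  eps <- stats::rnorm(n_patients * m, 0, sqrt(0.04))
  logY <- alpha[idx] + 0.3 * smoke[idx] + beta_g * g[idx] + logD + eps
  gcol <- if (variant == "eps_artifact") {
    as.numeric(eps + stats::rnorm(n_patients * m, 0, 0.05) > 0)
  } else g[idx]
  long_table(sprintf("P%03d", idx), exp(logD), exp(logY),
             covariates = data.frame(smoke = smoke[idx], g = gcol),
             validate = FALSE)
}
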