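test_that("population_model enforces its invariants", {
  expect_error(population_model(0, -0.1, 0.04), "sigma_alpha2")
  expect_error(population_model(0, 0.1, 0), "sigma_eps2")
  expect_error(population_model(0, 0.1, 0.04, d = 0), "d must be")
  expect_error(population_model(0, 0.1, 0.04, beta = c(1, 2),
                                covariate_names = "a"),
               "length")
  pm <- population_model(1, 0.09, 0.04, beta = c(smoke = 0.3))
  expect_s3_class(pm, "population_model")
  expect_identical(pm$covariate_names, "smoke")
})

test_that("log_residuals matches hand values and round-trips", {
  pm <- population_model(0.7, 0.1, 0.05, beta = numeric(0), d = 1)
  expect_equal(log_residuals(pm, numeric(0), 1, exp(1)), 1)
  pm2 <- population_model(0, 0.1, 0.05, beta = 0.5, d = 1)
  expect_equal(log_residuals(pm2, 2, 1, exp(2)), 1.0)
  expect_error(log_residuals(pm2, 2, c(1, 2), 1), "equal length")
  expect_error(log_residuals(pm2, c(1, 2), 1, 1), "covariate vector")
  # round trip: exp(r + beta'X + d log D) reconstructs Y
  set.seed(11)
  for (i in 1:20) {
    pm3 <- random_model(n_cov = 2)
    X <- rnorm(2); D <- exp(runif(3, -1, 1)); Y <- exp(rnorm(3, 1, 1))
    r <- log_residuals(pm3, X, D, Y)
    expect_equal(exp(r + sum(pm3$beta * X) + pm3$d * log(D)), Y,
                 tolerance = 1e-12)
  }
})

test_that("balanced REML fit equals the one-way ANOVA closed form", {
  for (seed in c(2, 7, 19)) {
    lt <- balanced_table(k = 25, m = 4, seed = seed)
    fit <- fit_random_intercept(lt, fix_d_at_one = TRUE, method = "REML")
    oracle <- anova_oracle(lt)
    expect_true(fit$converged)
    expect_equal(fit$model$mu_alpha, oracle$mu_alpha, tolerance = 1e-6)
    expect_equal(fit$model$sigma_eps2, oracle$sigma_eps2, tolerance = 1e-6)
    expect_equal(fit$model$sigma_alpha2, oracle$sigma_alpha2,
                 tolerance = 1e-6)
  }
})

test_that("fit agrees with lme4 on unbalanced data with covariates", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(population_model(0.8, 0.12, 0.05,
                                     beta = c(0.3, -0.2), d = 0.9),
                    covariates = list(cov_binary("X1", 0.4),
                                      cov_normal("X2")),
                    n_patients = 80, seed = 21)
  lt <- generate_long_table(cfg, doses_per_patient = 4)
  lt <- lt[-seq(1, nrow(lt), by = 7), ]        # make it unbalanced
  class(lt) <- c("long_table", "data.frame")
  fit <- fit_random_intercept(lt, method = "REML")
  lmm <- lme4::lmer(log(response) ~ X1 + X2 + log(dose) +
                      (1 | patient_id), data = as.data.frame(lt),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  fe <- lme4::fixef(lmm)
  expect_equal(fit$model$mu_alpha, unname(fe["(Intercept)"]),
               tolerance = 1e-5)
  expect_equal(unname(fit$model$beta), unname(fe[c("X1", "X2")]),
               tolerance = 1e-5)
  expect_equal(fit$model$d, unname(fe["log(dose)"]), tolerance = 1e-5)
  expect_equal(fit$model$sigma_alpha2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$model$sigma_eps2, vc$vcov[2], tolerance = 1e-4)
  # ML route too
  fitml <- fit_random_intercept(lt, method = "ML")
  lmm_ml <- lme4::lmer(log(response) ~ X1 + X2 + log(dose) +
                         (1 | patient_id), data = as.data.frame(lt),
                       REML = FALSE)
  expect_equal(fitml$log_likelihood, as.numeric(stats::logLik(lmm_ml)),
               tolerance = 1e-6)
})

test_that("sigma_alpha2 = 0 data gives a boundary estimate", {
  cfg <- sim_config(population_model(1, 0, 0.04), covariates = list(),
                    n_patients = 40, seed = 5)
  lt <- generate_long_table(cfg, doses_per_patient = 4)
  fit <- fit_random_intercept(lt, fix_d_at_one = TRUE)
  expect_equal(fit$model$sigma_alpha2, 0)
  expect_true(fit$boundary)
  expect_true(fit$converged)
})

test_that("fit refuses degenerate inputs with informative errors", {
  cfg <- sim_config(population_model(1, 0.09, 0.04), covariates = list(),
                    n_patients = 10, seed = 3)
  singletons <- generate_long_table(cfg, doses_per_patient = 1)
  expect_error(fit_random_intercept(singletons), "not separable")
  lt <- balanced_table(k = 10, m = 3, seed = 4)
  lt$dup <- 1  # constant column collinear with the intercept
  class(lt) <- c("long_table", "data.frame")
  expect_error(fit_random_intercept(lt), "rank-deficient")
  bad <- balanced_table(k = 5, m = 3, seed = 6)
  bad$response[1] <- -1
  expect_error(fit_random_intercept(bad), "responses")
})

test_that("fit is scale-invariant and deterministic", {
  lt <- balanced_table(k = 30, m = 4, seed = 9)
  f1 <- fit_random_intercept(lt, fix_d_at_one = TRUE)
  lt2 <- lt; lt2$response <- lt$response * 100
  f2 <- fit_random_intercept(lt2, fix_d_at_one = TRUE)
  expect_equal(f2$model$mu_alpha, f1$model$mu_alpha + log(100),
               tolerance = 1e-6)
  expect_equal(f2$model$sigma_alpha2, f1$model$sigma_alpha2,
               tolerance = 1e-6)
  expect_equal(f2$model$sigma_eps2, f1$model$sigma_eps2, tolerance = 1e-6)
  f1b <- fit_random_intercept(lt, fix_d_at_one = TRUE)
  expect_identical(f1$model, f1b$model)
})

test_that("log-likelihood at the optimum beats the generating truth", {
  truth <- population_model(1, 0.09, 0.04, beta = 0.3)
  cfg <- sim_config(truth, covariates = list(cov_binary("X1", 0.5)),
                    n_patients = 60, seed = 13)
  lt <- generate_long_table(cfg, doses_per_patient = 4)
  fit <- fit_random_intercept(lt, method = "ML")
  # evaluate the ML criterion at the true parameters via the ML fit's own
  # scale: refit with data shifted is unavailable, so use lme4's deviance
  # machinery independently
  skip_if_not_installed("lme4")
  lmm <- lme4::lmer(log(response) ~ X1 + log(dose) + (1 | patient_id),
                    data = as.data.frame(lt), REML = FALSE)
  dev_true <- lme4::devfun2(lmm, useSc = TRUE, signames = FALSE)
  ll_true <- -dev_true(c(sqrt(truth$sigma_alpha2 / truth$sigma_eps2) *
                           sqrt(truth$sigma_eps2), sqrt(truth$sigma_eps2))) / 2
  expect_gte(fit$log_likelihood + 1e-6, ll_true)
})

test_that("model JSON serialization round-trips", {
  pm <- population_model(1.23456789, 0.0987654, 0.0456789,
                         beta = c(smoke = 0.31, sex = -0.22), d = 1.05)
  path <- tempfile(fileext = ".json")
  write_model_json(pm, path)
  back <- read_model_json(path)
  expect_equal(back[names(back)], pm[names(pm)], tolerance = 0)
  # fit metadata round-trip
  lt <- balanced_table(k = 10, m = 3, seed = 2)
  fit <- fit_random_intercept(lt, fix_d_at_one = TRUE)
  write_model_json(fit, path)
  back2 <- read_model_json(path)
  expect_equal(back2$mu_alpha, fit$model$mu_alpha)
  expect_equal(attr(back2, "fit_info")$method, "REML")
})

test_that("long-table CSV IO round-trips and validates", {
  cfg <- sim_config(n_patients = 15, seed = 8)
  lt <- generate_long_table(cfg, doses_per_patient = 3)
  path <- tempfile(fileext = ".csv")
  write_long_table(lt, path)
  back <- read_long_table(path)
  ref <- as.data.frame(lt)
  rownames(ref) <- NULL
  attr(ref, "truth") <- NULL
  expect_equal(as.data.frame(back), ref, tolerance = 1e-12)
  expect_error(long_table("a", 1, -2), "responses")
  expect_error(
    long_table(c("a", "a", "b", "b"), c(1, 1, 1, 1), c(1, 1, 1, 1),
               covariates = data.frame(g = c(0, 1, 0, 0))),
    "varies within")
})
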