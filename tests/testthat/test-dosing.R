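test_that("therapeutic_window enforces and derives its fields", {
  expect_error(therapeutic_window(2, 2), "l1 < l2")
  expect_error(therapeutic_window(0, 2), "l1 < l2")
  w <- therapeutic_window(2, 8)
  expect_equal(w$therapeutic_index, 4)
  expect_equal(w$g, 4)
})

test_that("initial dose matches the printed closed form", {
  pm <- population_model(0, 0.09, 0.04)
  expect_equal(initial_dose(pm, numeric(0), therapeutic_window(0.5, 2))$dose,
               1.0)
  pm2 <- population_model(0, 0.09, 0.04, d = 2)
  expect_equal(initial_dose(pm2, numeric(0),
                            therapeutic_window(0.5, 2))$dose, 1.0)
  expect_equal(initial_dose(pm2, numeric(0), therapeutic_window(2, 8))$dose,
               2.0)
  # covariates shift the dose by exp(-beta'X / d)
  pm3 <- population_model(0, 0.09, 0.04, beta = 0.5)
  expect_equal(initial_dose(pm3, 2, therapeutic_window(0.5, 2))$dose,
               exp(-1))
})

test_that("initial dose maximizes the prior-predictive window probability", {
  set.seed(71)
  for (i in 1:25) {
    pm <- random_model(n_cov = 1)
    w <- random_window()
    X <- rnorm(1)
    rec <- initial_dose(pm, X, w)
    grid <- rec$dose * exp(seq(-1, 1, length.out = 2001))
    pg <- window_probability(pm, pm$mu_alpha, pm$sigma_alpha2, X, grid, w)
    expect_gte(rec$predicted_window_probability, max(pg) - 1e-8)
  }
})

test_that("update_dose reduces to initial_dose and is Bayes-risk optimal", {
  pm <- population_model(1, 0.09, 0.04, beta = 0.3)
  w <- therapeutic_window(2, 4)
  rec0 <- update_dose(pm, patient_history(covariates = 1), w)
  expect_equal(rec0$dose, initial_dose(pm, 1, w)$dose)
  expect_identical(rec0$step, 1L)
  set.seed(72)
  for (i in 1:25) {
    pmr <- random_model(n_cov = 0)
    wr <- random_window()
    n <- sample(1:4, 1)
    D <- exp(runif(n, -1, 1))
    Y <- exp(rnorm(n, pmr$mu_alpha, 0.4))
    rec <- update_dose(pmr, patient_history(numeric(0), D, Y), wr)
    expect_identical(rec$step, n + 1L)
    grid <- rec$dose * exp(seq(-1, 1, length.out = 2001))
    pg <- window_probability(pmr, rec$posterior$alpha_hat,
                             rec$posterior$v, numeric(0), grid, wr)
    expect_gte(rec$predicted_window_probability, max(pg) - 1e-8)
  }
})

test_that("one on-target observation brackets the dose by shrinkage", {
  pm <- population_model(1, 0.09, 0.04)
  w <- therapeutic_window(2, 4)
  D1 <- initial_dose(pm, numeric(0), w)$dose
  Y1 <- w$g * 1.5                       # measured above target
  rec <- update_dose(pm, patient_history(numeric(0), D1, Y1), w)
  # naive single-sample dose: believe r1 = alpha exactly
  naive <- exp(log(w$g) - log_residuals(pm, numeric(0), D1, Y1))
  expect_true(rec$dose > min(D1, naive) && rec$dose < max(D1, naive))
  # exactly on-target measurement keeps alpha_hat between mu and r1 = mu
  rec2 <- update_dose(pm, patient_history(numeric(0), D1, w$g), w)
  expect_equal(rec2$posterior$alpha_hat, pm$mu_alpha, tolerance = 1e-12)
  expect_equal(rec2$dose, D1, tolerance = 1e-12)
})

test_that("window_probability matches symmetry, limits and Monte Carlo", {
  pm <- population_model(1, 0.09, 0.04)
  w <- therapeutic_window(2, 4)
  # dose centering the log-response hits the attainable maximum
  dstar <- exp(log(w$g) - 1)
  expect_equal(window_probability(pm, 1, 0, numeric(0), dstar, w),
               max_attainable_probability(pm, w), tolerance = 1e-12)
  # vanishing noise with the mean inside the window
  pm0 <- population_model(1, 0.09, 1e-12)
  expect_equal(window_probability(pm0, 1, 0, numeric(0), dstar, w), 1,
               tolerance = 1e-9)
  expect_error(window_probability(pm, 1, 0, numeric(0), -1, w), "> 0")
  # Monte Carlo oracle
  set.seed(91)
  pmc <- population_model(0.8, 0.05, 0.09, beta = 0.4)
  X <- 1; dose <- 2.2
  wmc <- therapeutic_window(5, 11)
  nmc <- 2e5
  y <- generate_response(pmc, 0.8, X, dose, n = nmc)
  emp <- mean(y > wmc$l1 & y < wmc$l2)
  p <- window_probability(pmc, 0.8, 0, X, dose, wmc)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / nmc))
})

test_that("max_attainable_probability limits and optimization oracle", {
  pm <- population_model(1, 0.09, 0.04)
  expect_lt(max_attainable_probability(
    pm, therapeutic_window(1, 1 + 1e-12)), 1e-6)
  tiny <- population_model(1, 0.09, 1e-12)
  expect_equal(max_attainable_probability(tiny, therapeutic_window(2, 4)),
               1, tolerance = 1e-9)
  set.seed(92)
  for (i in 1:20) {
    pmr <- random_model(); wr <- random_window()
    f <- function(ld) window_probability(pmr, pmr$mu_alpha, 0, numeric(0),
                                         exp(ld), wr)
    ld0 <- (log(wr$g) - pmr$mu_alpha) / pmr$d  # bracket around the peak
    sup <- stats::optimize(f, ld0 + c(-5, 5), maximum = TRUE,
                           tol = 1e-10)$objective
    expect_equal(max_attainable_probability(pmr, wr), sup,
                 tolerance = 1e-6)
    expect_lt(max_attainable_probability(pmr, wr), 1)
  }
})

test_that("omega-optimality flags flip exactly at the bisection boundary", {
  pm <- population_model(1, 0.09, 0.04)
  w <- therapeutic_window(2, 4)
  alpha <- 1.3
  omega <- 0.9
  dstar <- exp((log(w$g) - alpha) / pm$d)   # exact known-alpha optimum
  expect_true(is_omega_optimum(dstar, alpha, pm, numeric(0), w, omega))
  expect_false(is_omega_optimum(1e-9, alpha, pm, numeric(0), w, omega))
  # bisection for the upper boundary dose where P(dose) = omega * Pmax
  target <- omega * max_attainable_probability(pm, w)
  f <- function(d) window_probability(pm, alpha, 0, numeric(0), d, w) - target
  lo <- dstar; hi <- dstar * 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  eps <- 1e-6
  expect_true(is_omega_optimum(lo * (1 - eps), alpha, pm, numeric(0), w,
                               omega))
  expect_false(is_omega_optimum(hi * (1 + eps), alpha, pm, numeric(0), w,
                                omega))
  expect_error(is_omega_optimum(1, alpha, pm, numeric(0), w, 1.2),
               "omega")
})

test_that("tdm_update applies the proportional rule", {
  expect_equal(tdm_update(100, 3, 3), 100)
  expect_equal(tdm_update(100, 6, 3), 50)
  expect_equal(tdm_update(100, 1.5, 3), 200)
  expect_equal(tdm_update(100, 6, 3, d = 2), 100 / sqrt(2))
  expect_error(tdm_update(-1, 1, 1), "> 0")
  expect_error(tdm_update(1, 0, 1), "> 0")
})

test_that("minimum_samples boundary cases and monotonicity", {
  w <- therapeutic_window(2, 4)
  # no inter-patient variability: the initial dose is exact for everyone
  expect_identical(as.integer(minimum_samples(
    population_model(1, 0, 0.04), w, n_sim = 1000, seed = 2)), 0L)
  # very wide window relative to both variances
  wide <- therapeutic_window(0.01, 100)
  expect_identical(as.integer(minimum_samples(
    population_model(1, 0.02, 0.02), wide, n_sim = 1000, seed = 2)), 0L)
  pm <- population_model(1, 0.09, 0.04)
  ms <- function(omega, pf)
    as.integer(minimum_samples(pm, w, omega = omega,
                               population_fraction = pf,
                               max_n = 15, n_sim = 4000, seed = 42))
  # nonincreasing as omega decreases; nondecreasing in population_fraction
  by_omega <- sapply(c(0.95, 0.9, 0.8, 0.6), function(o) ms(o, 0.9))
  expect_true(all(diff(by_omega) <= 0))
  by_pf <- sapply(c(0.5, 0.7, 0.9, 0.95), function(pf) ms(0.9, pf))
  expect_true(all(diff(by_pf) >= 0))
  # determinism and sentinel behaviour
  expect_identical(ms(0.9, 0.9), ms(0.9, 0.9))
  unatt <- minimum_samples(pm, w, omega = 0.999,
                           population_fraction = 0.999, max_n = 3,
                           n_sim = 1000, seed = 1)
  expect_identical(as.integer(unatt), 4L)
  expect_false(attr(unatt, "attained"))
  expect_error(minimum_samples(pm, w, omega = 1.2), "\\(0, 1\\)")
})
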