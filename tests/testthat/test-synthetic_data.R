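test_that("generators are deterministic given the seed", {
  a <- simulate_covariates(covariate_sim_params(seed = 5), 20, 15)
  b <- simulate_covariates(covariate_sim_params(seed = 5), 20, 15)
  expect_identical(a, b)
  sa <- simulate_lek_counts(local_sim_params(n_leks = 20, n_years = 15,
                                             seed = 5),
                            a$disturbance, a$pdo)
  sb <- simulate_lek_counts(local_sim_params(n_leks = 20, n_years = 15,
                                             seed = 5),
                            b$disturbance, b$pdo)
  expect_identical(sa, sb)
})

test_that("climate index is stationary AR(1) with the stated moments", {
  p <- covariate_sim_params(pdo_rho = 0, pdo_sd = 0.8, seed = 2)
  cv <- simulate_covariates(p, n_leks = 1, n_years = 500)
  v <- cv$pdo$value
  n <- length(v)
  r1 <- cor(v[-1], v[-n])
  expect_lt(abs(r1), 3 / sqrt(n))
  expect_equal(sd(v), 0.8, tolerance = 0.15)
  # persistent version has positive lag-1 autocorrelation
  cv2 <- simulate_covariates(covariate_sim_params(pdo_rho = 0.6, seed = 2),
                             1, 500)
  v2 <- cv2$pdo$value
  expect_gt(cor(v2[-1], v2[-length(v2)]), 0.4)
})

test_that("disturbance trajectories are zero-before-buildout, monotone,
           right-skewed", {
  cv <- simulate_covariates(covariate_sim_params(seed = 9), n_leks = 200,
                            n_years = 30)
  d <- cv$disturbance
  mono <- tapply(d$proportion, d$lek_id, function(x) all(diff(x) >= 0))
  expect_true(all(mono))
  finals <- tapply(d$proportion, d$lek_id, max)
  # many near zero, few large: mean above median
  expect_gt(mean(finals), median(finals))
  z <- simulate_covariates(covariate_sim_params(n_pads_final = 0, seed = 9),
                           n_leks = 20, n_years = 10)
  expect_true(all(z$disturbance$proportion == 0))
})

test_that("negative binomial draws match the stated mean-variance relation", {
  set.seed(1)
  x <- rnb_mu_phi(1e5, mu = 10, phi = 0.5)
  expect_equal(mean(x), 10, tolerance = 0.02 * 10)
  # SD = sqrt(mu + phi mu^2) = sqrt(60)
  expect_equal(sd(x), sqrt(60), tolerance = 0.03 * sqrt(60))
  y <- rnb_mu_phi(1e5, mu = 4, phi = 0)
  expect_equal(var(y), 4, tolerance = 0.15)
})

test_that("simulated lek counts obey the model they claim to follow", {
  cv <- simulate_covariates(covariate_sim_params(seed = 3), n_leks = 400,
                            n_years = 25)
  # no effects, no heterogeneity: typical lek of ~10 birds
  sim <- simulate_lek_counts(
    local_sim_params(n_leks = 400, n_years = 25, beta0 = log(10), betaA = 0,
                     betaP = 0, sigmaL = 0, sigmaY = 0, phi = 1e-8,
                     seed = 3),
    cv$disturbance, cv$pdo)
  expect_equal(mean(sim$lek_years$count), 10, tolerance = 0.05)
  # lek heterogeneity only: between-lek variance of log mean counts ~ sigmaL^2
  sim2 <- simulate_lek_counts(
    local_sim_params(n_leks = 400, n_years = 25, beta0 = log(50), betaA = 0,
                     betaP = 0, sigmaL = 0.8, sigmaY = 0, phi = 1e-8,
                     seed = 3),
    cv$disturbance, cv$pdo)
  lm_ <- tapply(sim2$lek_years$count, sim2$lek_years$lek_id, mean)
  expect_equal(var(log(lm_[lm_ > 0])), 0.8^2, tolerance = 0.15)
})

test_that("population series converge to the carrying capacity", {
  # betaD = -1: full compensation, jumps to K in one step
  p <- pop_sim_params(n_groups = 1, n_years = 5, k_range = c(20, 20),
                      betaD = -1, betaA = 0, betaP = 0, sigmaG = 0,
                      sigmaY = 0, seed = 1)
  s <- simulate_population_series(p, noise = FALSE)
  d <- s$densities$density
  expect_equal(d[2], 20, tolerance = 1e-8)
  # weak density dependence: monotone convergence in |log d - log K|
  p2 <- pop_sim_params(n_groups = 1, n_years = 40, k_range = c(25, 25),
                       betaD = -0.38, betaA = 0, betaP = 0, sigmaG = 0,
                       sigmaY = 0, seed = 4)
  s2 <- simulate_population_series(p2, noise = FALSE)
  gap <- abs(log(s2$densities$density) - log(25))
  expect_true(all(diff(gap) <= 1e-12))
  expect_equal(tail(s2$densities$density, 1), 25, tolerance = 1e-6)
  # betaL < 0: process-error SD decreases with the number of leks
  p3 <- pop_sim_params(betaL = -0.3)
  sd_eta <- exp(p3$betaN + p3$betaL * log(1:50))
  expect_true(all(diff(sd_eta) < 0))
})

test_that("make_fixture writes identical clean files for identical seeds", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  m1 <- make_fixture(21, d1, n_groups = 2, leks_per_group = 6, n_years = 10)
  m2 <- make_fixture(21, d2, n_groups = 2, leks_per_group = 6, n_years = 10)
  for (f in c("lek_counts.csv", "lek_sites.csv", "well_pads.csv",
              "pdo_monthly.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  inputs <- read_inputs(d1)
  fr <- filter_records(inputs$lek_counts)
  expect_equal(sum(fr$report[1:5]), 0L)  # generator emits clean records
  prep <- prepare_data(inputs)
  expect_true(all(prep$group_density$density >= 0))
  expect_true(all(prep$group_density$n_leks >= 1))
  unlink(c(d1, d2), recursive = TRUE)
})
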