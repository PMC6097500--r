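test_that("nb_logpmf matches closed forms and normalizes", {
  # P(Y=0) = (1 + phi*mu)^(-1/phi): mu=2, phi=1 -> 1/3
  expect_equal(nb_logpmf(0, 2, 1), log(1 / 3), tolerance = 1e-12)
  expect_equal(nb_logpmf(0:10, 3, 0), dpois(0:10, 3, log = TRUE))
  total <- sum(exp(nb_logpmf(0:2000, mu = 10, phi = 0.5)))
  expect_equal(total, 1, tolerance = 1e-8)
  expect_error(nb_logpmf(1.5, 2, 1), "integer")
  # mean and variance of the pmf agree with mu and mu + phi mu^2
  y <- 0:4000
  p <- exp(nb_logpmf(y, 10, 0.5))
  expect_equal(sum(y * p), 10, tolerance = 1e-8)
  expect_equal(sum(y^2 * p) - 10^2, 10 + 0.5 * 100, tolerance = 1e-6)
})

test_that("marginal likelihood is exact without random effects", {
  des <- toy_design(c(3L, 7L, 5L, 9L), rep(c("A", "B"), 2),
                    rep(c(2000, 2001), each = 2), area = c(0, 1, -1, 0.5))
  p <- list(beta0 = 1.5, betaA = -0.3, sigmaL = 0, sigmaY = 0, phi = 0.4)
  direct <- sum(nb_logpmf(des$count, exp(1.5 - 0.3 * des$area_std), 0.4))
  expect_equal(local_marginal_loglik(p, des), direct, tolerance = 1e-12)
  # duplicating every row doubles the log-likelihood
  des2 <- rbind(des, des)
  expect_equal(local_marginal_loglik(p, des2), 2 * direct, tolerance = 1e-12)
})

test_that("Laplace marginal matches adaptive quadrature on a 3x3 toy", {
  set.seed(34)
  des <- toy_design(as.integer(rpois(9, 60)),
                    rep(c("A", "B", "C"), each = 3), rep(2000:2002, 3),
                    area = round(rnorm(9), 2), pdo = round(rnorm(9), 2))
  p <- list(beta0 = log(60), betaA = -0.1, betaP = 0.05, sigmaL = 0.1,
            sigmaY = 0.1, phi = 0.1)
  brute <- brute_local_loglik(p, des, n_nodes = 35)
  # the oracle itself is converged (node count does not matter)
  expect_equal(brute, brute_local_loglik(p, des, n_nodes = 25),
               tolerance = 1e-10)
  expect_lt(abs(local_marginal_loglik(p, des) - brute), 1e-4)
  # at field-typical random-effect SDs the Laplace error on so small a toy
  # grows to the 1e-2 scale (documented limitation; it shrinks with the
  # information per effect, i.e. with leks and years)
  p2 <- modifyList(p, list(sigmaL = 0.3, sigmaY = 0.25, phi = 0.2))
  err <- abs(local_marginal_loglik(p2, des) - brute_local_loglik(p2, des))
  expect_lt(err, 0.02)
})

test_that("Laplace with one variance at zero matches 1-D adaptive
           integration per lek", {
  set.seed(31)
  des <- toy_design(c(8L, 12L, 9L, 15L, 11L, 14L, 6L, 7L, 10L),
                    rep(c("A", "B", "C"), each = 3), rep(2000:2002, 3),
                    area = round(rnorm(9), 2), pdo = round(rnorm(9), 2))
  p <- list(beta0 = 2.2, betaA = -0.2, betaP = 0.1, sigmaL = 0.12,
            sigmaY = 0, phi = 0.2)
  # with sigmaY = 0 the leks are independent: exact product of 1-D integrals
  off <- p$beta0 + p$betaA * des$area_std + p$betaP * des$pdo_std
  ll_1d <- sum(vapply(unique(des$lek_id), function(l) {
    rows <- which(des$lek_id == l)
    f <- Vectorize(function(u) {
      exp(sum(nb_logpmf(des$count[rows], exp(off[rows] + u), p$phi))) *
        dnorm(u, 0, p$sigmaL)
    })
    log(integrate(f, -1.5, 1.5, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_lt(abs(local_marginal_loglik(p, des) - ll_1d), 1e-3)
})

test_that("likelihood profile is invariant to standardization swaps", {
  st <- sim_local_study(13, n_leks = 25, n_years = 10)
  des <- st$design
  p <- list(beta0 = 2.3, betaA = -0.25, betaP = 0.12, sigmaL = 0.5,
            sigmaY = 0.2, phi = 0.3)
  l1 <- local_marginal_loglik(p, des)
  des2 <- des
  des2$area_std <- des$area_std * 2.5
  p2 <- modifyList(p, list(betaA = p$betaA / 2.5))
  expect_equal(local_marginal_loglik(p2, des2), l1, tolerance = 1e-10)
})

test_that("ML fit beats the truth in likelihood and recovers it roughly", {
  st <- sim_local_study(17)
  fit <- fit_local(st$design, hessian = FALSE)
  truth <- st$truth$params
  tp <- list(beta0 = truth$beta0, betaA = truth$betaA, betaP = truth$betaP,
             sigmaL = truth$sigmaL, sigmaY = truth$sigmaY, phi = truth$phi)
  expect_gte(fit$loglik, local_marginal_loglik(tp, st$design) - 1e-6)
  # within ~3 sampling SDs at this study size (empirical SD ~ 0.043)
  expect_lt(abs(fit$params$betaA - truth$betaA), 0.13)
  expect_lt(abs(fit$params$phi - truth$phi), 0.15)
})

test_that("bias of the fixed effects shrinks with study size", {
  sizes <- c(15, 40, 100)
  err <- vapply(sizes, function(nl) {
    e <- vapply(1:3, function(s) {
      st <- sim_local_study(100 + s, n_leks = nl, n_years = 15)
      fit <- fit_local(st$design, hessian = FALSE)
      abs(fit$params$betaA - st$truth$params$betaA)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("predict_expected_count follows the link and the calibration", {
  fit <- structure(list(params = list(beta0 = log(10), betaA = -0.5,
                                      betaP = 0.2, sigmaL = 0.4,
                                      sigmaY = 0.2, phi = 0.3),
                        include_area = TRUE, include_pdo = TRUE),
                   class = "local_fit")
  expect_equal(predict_expected_count(fit), 10)
  # monotone decreasing in disturbance when betaA < 0
  a <- seq(-1, 3, 0.5)
  expect_true(all(diff(predict_expected_count(fit, area_std = a)) < 0))
  expect_equal(predict_expected_count(fit, area_std = 1, lek_effect = 0.1),
               exp(log(10) - 0.5 + 0.1))
})

test_that("observation-scale R2 matches a Monte-Carlo decomposition", {
  st <- sim_local_study(23, n_leks = 80, n_years = 20)
  fit <- fit_local(st$design, hessian = FALSE)
  r2 <- r2_observational(fit, st$design)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_gte(r2["conditional"], r2["marginal"])
  # MC oracle: simulate responses from the fitted model over the same rows
  set.seed(99)
  p <- fit$params
  nrep <- 400
  etaf <- log(predict_expected_count(fit, st$design$area_std,
                                     st$design$pdo_std))
  n <- length(etaf)
  mu_fix <- exp(etaf)
  draws <- replicate(nrep, {
    re <- rnorm(n, 0, p$sigmaL) + rnorm(n, 0, p$sigmaY)
    mu <- exp(etaf + re)
    rnb_mu_phi(n, mu, p$phi)
  })
  vtot <- var(as.vector(draws))
  vfix <- var(mu_fix * exp((p$sigmaL^2 + p$sigmaY^2) / 2)) * (n - 1) / n
  expect_equal(unname(r2["marginal"]), vfix / vtot, tolerance = 0.02)
  # degenerate cases
  fit0 <- fit
  fit0$params$sigmaL <- 0; fit0$params$sigmaY <- 0
  r20 <- r2_observational(fit0, st$design)
  expect_equal(unname(r20["marginal"]), unname(r20["conditional"]))
  fitf <- fit
  fitf$params$betaA <- 0; fitf$params$betaP <- 0
  expect_equal(unname(r2_observational(fitf, st$design)["marginal"]), 0)
})
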