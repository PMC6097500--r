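pop_design_direct <- function(gd, area = 0, pdo = 0) {
  gd <- gd[order(gd$group_id, gd$year), ]
  prev <- gd[, c("group_id", "year", "density")]
  prev$year <- prev$year + 1L
  names(prev)[3] <- "prev_density"
  rows <- merge(gd, prev, by = c("group_id", "year"))
  rows$log_prev <- log(rows$prev_density)
  rows$area_std <- area
  rows$pdo_std <- pdo
  attr(rows, "standardization") <- list(area = list(mean = 0, sd = 1),
                                        pdo = list(mean = 0, sd = 1))
  rows
}

test_that("pop_loglik reduces to the direct normal sum without random
           effects and matches a hand computation", {
  gd <- data.frame(group_id = "G1", year = 2000:2002,
                   density = c(10, 14, 12), n_leks = c(4L, 9L, 16L))
  des <- pop_design_direct(gd)
  p <- list(beta0 = 1.1, betaD = -0.4, betaA = 0.0, betaP = 0.0,
            betaN = log(0.2), betaL = -0.2, sigmaG = 0, sigmaY = 0)
  # two transitions, each a normal log-density of log density
  mu1 <- 1.1 + 0.6 * log(10); sd1 <- exp(log(0.2) - 0.2 * log(9))
  mu2 <- 1.1 + 0.6 * log(14); sd2 <- exp(log(0.2) - 0.2 * log(16))
  hand <- dnorm(log(14), mu1, sd1, log = TRUE) +
    dnorm(log(12), mu2, sd2, log = TRUE)
  expect_equal(pop_loglik(p, des), hand, tolerance = 1e-10)
  # betaL = 0: invariant to the number of leks
  p0 <- modifyList(p, list(betaL = 0))
  des2 <- des; des2$n_leks <- rep(1L, nrow(des))
  expect_equal(pop_loglik(p0, des), pop_loglik(p0, des2), tolerance = 1e-12)
})

test_that("random-effect marginalization is an exact Gaussian integral", {
  # oracle: the model is linear-Gaussian in (alphaG, alphaY), so the
  # marginal of the log densities is multivariate normal with covariance
  # Z diag(sigmaG^2, sigmaY^2) Z' + diag(sd_eta^2) -- a different route to
  # the same quantity than the mode-based computation under test
  gd <- data.frame(group_id = rep(c("G1", "G2"), each = 3),
                   year = rep(2000:2002, 2),
                   density = c(10, 13, 11, 25, 21, 27),
                   n_leks = c(5L, 8L, 6L, 12L, 10L, 14L))
  des <- pop_design_direct(gd, area = c(0.5, -0.5, 1, -1),
                           pdo = c(0.2, -0.2, 0.4, -0.4))
  p <- list(beta0 = 1.0, betaD = -0.35, betaA = -0.05, betaP = 0.1,
            betaN = log(0.25), betaL = -0.1, sigmaG = 0.15, sigmaY = 0.2)
  gi <- match(des$group_id, c("G1", "G2"))
  yrs <- sort(unique(des$year))
  yi <- match(des$year, yrs)
  n <- nrow(des)
  sd_eta <- exp(p$betaN + p$betaL * log(des$n_leks))
  base <- p$beta0 + (p$betaD + 1) * des$log_prev + p$betaA * des$area_std +
    p$betaP * des$pdo_std
  Z <- matrix(0, n, 2 + length(yrs))
  Z[cbind(seq_len(n), gi)] <- des$log_prev
  Z[cbind(seq_len(n), 2 + yi)] <- 1
  D <- diag(c(rep(p$sigmaG^2, 2), rep(p$sigmaY^2, length(yrs))))
  S <- Z %*% D %*% t(Z) + diag(sd_eta^2)
  r <- log(des$density) - base
  cS <- chol(S)
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(cS))) -
    0.5 * sum(backsolve(cS, r, transpose = TRUE)^2)
  expect_equal(pop_loglik(p, des), ll, tolerance = 1e-10)
})

test_that("the fast MCMC posterior path equals pop_loglik plus priors", {
  gd <- data.frame(group_id = rep(c("G1", "G2", "G3"), each = 4),
                   year = rep(2000:2003, 3),
                   density = c(10, 13, 11, 12, 25, 21, 27, 24, 17, 15, 19, 18),
                   n_leks = rep(c(5L, 8L, 6L, 9L), 3))
  des <- pop_design_direct(gd, area = rnorm(9), pdo = rnorm(9))
  idx <- lekdyn:::pop_indices(des)
  th <- c(beta0 = 1.0, betaD = -0.35, betaA = -0.05, betaP = 0.1,
          betaN = log(0.25), betaL = -0.1, log_sigmaG = log(0.15),
          log_sigmaY = log(0.2))
  p <- lekdyn:::pop_unpack(th, TRUE, TRUE)
  slow <- pop_loglik(p, des) + sum(dnorm(th, 0, 5, log = TRUE))
  fast <- lekdyn:::pop_logpost_fast(th, TRUE, TRUE, idx, 5)
  expect_equal(fast, slow, tolerance = 1e-10)
  # reduced model variant
  th2 <- th[c("beta0", "betaD", "betaN", "betaL", "log_sigmaG",
              "log_sigmaY")]
  p2 <- lekdyn:::pop_unpack(th2, FALSE, FALSE)
  slow2 <- pop_loglik(p2, des) + sum(dnorm(th2, 0, 5, log = TRUE))
  expect_equal(lekdyn:::pop_logpost_fast(th2, FALSE, FALSE, idx, 5), slow2,
               tolerance = 1e-10)
  expect_identical(lekdyn:::pop_logpost_fast(replace(th, 1, 100), TRUE,
                                             TRUE, idx, 5), -Inf)
})

test_that("predict_next_density reproduces the worked half-K example", {
  K <- 20
  betaD <- log(13 / 20) / log(10 / 20) - 1
  p <- list(beta0 = -betaD * log(K), betaD = betaD)
  expect_equal(predict_next_density(p, 10), 13, tolerance = 1e-9)
  expect_equal(predict_next_density(p, K), K, tolerance = 1e-9)
  # betaD = -1: next density independent of the current one
  p2 <- list(beta0 = log(20), betaD = -1)
  expect_equal(predict_next_density(p2, 5), predict_next_density(p2, 50))
})

test_that("carrying capacity is the closed form and the map's fixed point", {
  p <- list(beta0 = 1, betaD = -0.5)
  expect_equal(carrying_capacity(p)$value, exp(2), tolerance = 1e-12)
  p3 <- list(beta0 = 1.2, betaD = -0.38, betaA = -0.06, betaP = 0.08)
  for (a in c(-1, 0, 2)) for (q in c(-0.5, 1)) {
    k <- carrying_capacity(p3, area_std = a, pdo_std = q)$value
    expect_equal(predict_next_density(p3, k, area_std = a, pdo_std = q), k,
                 tolerance = 1e-8)
  }
  # N_inf decreases with disturbance when betaA < 0
  ks <- vapply(seq(0, 3, 0.5),
               function(a) carrying_capacity(p3, area_std = a)$value,
               numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_error(carrying_capacity(list(beta0 = 1, betaD = 0)), "carrying")
})

test_that("fit_population recovers the generator and the process-error
           slope sign", {
  ps <- pop_sim_params(n_groups = 12, n_years = 40, betaD = -0.38,
                       betaL = -0.3, betaN = log(0.2), seed = 8)
  s <- simulate_population_series(ps)
  gd <- s$densities
  dist <- data.frame(group_id = gd$group_id, radius_m = 3200,
                     year = gd$year, proportion = 0)
  set.seed(8)
  dist$proportion <- runif(nrow(dist), 0, 0.03)
  pdo <- data.frame(year = sort(unique(gd$year)), value = rnorm(40, 0, 0.8))
  des <- build_design(gd, dist, pdo, 3200, 1, 1)
  fit <- fit_population(des)
  expect_lt(abs(fit$params$betaD - (-0.38)), 0.12)
  expect_lt(fit$params$betaL, 0)
  # amplification identity on the fit: d log K / d area = -betaA/(betaD+aG)
  aG <- fit$ranef$group[1]
  k0 <- carrying_capacity(fit, area_std = 0,
                          group_id = names(fit$ranef$group)[1])$value
  k1 <- carrying_capacity(fit, area_std = 1,
                          group_id = names(fit$ranef$group)[1])$value
  expect_equal(log(k1) - log(k0),
               -fit$params$betaA / (fit$params$betaD + aG),
               tolerance = 1e-8, ignore_attr = TRUE)
})
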