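# Shared builders for small in-memory fixtures.

toy_records <- function() {
  data.frame(
    lek_id = c("A", "A", "A", "B", "B", "C", "C", "D"),
    group_id = "G1",
    date = c("1990-04-10", "1990-04-20", "1990-05-20", "1990-04-15",
             "1984-04-15", "1990-04-15", "1990-04-16", "not-a-date"),
    n_males = c(12L, 18L, 15L, 10L, 9L, 10L, 0L, 5L),
    n_unknown = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    is_ground = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    is_checked = TRUE, in_survey = TRUE,
    stringsAsFactors = FALSE)
}

# Minimal local design table built directly (bypasses the joins).
toy_design <- function(counts, lek_id, year, area = 0, pdo = 0) {
  d <- data.frame(lek_id = lek_id, year = year, count = counts,
                  area_std = area, pdo_std = pdo,
                  stringsAsFactors = FALSE)
  attr(d, "standardization") <- list(area = list(mean = 0, sd = 1),
                                     pdo = list(mean = 0, sd = 1))
  attr(d, "spec") <- list(radius_m = 3200, area_lag = 1, pdo_lag = 1,
                          family = "local")
  d
}

# A small simulated local-model study returned as (design, truth).
sim_local_study <- function(seed, n_leks = 60, n_years = 20, ...) {
  cv <- simulate_covariates(covariate_sim_params(seed = seed),
                            n_leks = n_leks, n_years = n_years)
  sim <- simulate_lek_counts(
    local_sim_params(n_leks = n_leks, n_years = n_years, seed = seed, ...),
    cv$disturbance, cv$pdo)
  des <- build_design(sim$lek_years, cv$disturbance, cv$pdo, 3200,
                      area_lag = 1, pdo_lag = 2)
  list(design = des, truth = sim$truth, covariates = cv)
}

# Brute-force marginal likelihood for tiny crossed designs: adaptive
# tensor-product Gauss-Hermite over the year effects, adaptive 1-D
# Gauss-Hermite per lek inside (conditional on years, leks are
# independent). Nodes are centred at the joint conditional mode and scaled
# by the conditional curvature, so the rule stays accurate when the
# conditional posterior is much narrower than the random-effect prior.
# Independent oracle for the Laplace approximation (only the change of
# variables comes from the implementation; the integration does not).
gh_nodes <- function(n) {
  # Golub-Welsch eigen decomposition of the Hermite Jacobi matrix
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

brute_local_loglik <- function(params, design, n_nodes = 35, inflate = 1.5) {
  leks <- sort(unique(design$lek_id))
  yrs <- sort(unique(design$year))
  nL <- length(leks); nY <- length(yrs)
  stopifnot(nY == 3)   # oracle written for the 3-year toy
  gh <- gh_nodes(n_nodes)
  sL <- params$sigmaL; sY <- params$sigmaY
  off <- params$beta0 +
    (if (!is.null(params$betaA)) params$betaA * design$area_std else 0) +
    (if (!is.null(params$betaP)) params$betaP * design$pdo_std else 0)
  nn <- n_nodes

  # adaptive centring/scaling from the conditional mode and curvature
  mode <- local_marginal_loglik(params, design, details = TRUE)
  curv_sd <- function(u_all_L, u_all_Y) {
    eta <- off + u_all_L[match(design$lek_id, leks)] +
      u_all_Y[match(design$year, yrs)]
    w <- lekdyn:::nb_eta_derivs(design$count, exp(eta), params$phi)$w
    list(L = 1 / sqrt(tapply(w, design$lek_id, sum) + 1 / sL^2),
         Y = 1 / sqrt(tapply(w, design$year, sum) + 1 / sY^2))
  }
  sc <- curv_sd(mode$uL, mode$uY)
  cL <- mode$uL; cY <- mode$uY
  hL <- pmin(as.numeric(sc$L) * inflate, sL)
  hY <- pmin(as.numeric(sc$Y) * inflate, sY)

  # 1-D adaptive rule: int f(u) N(u; 0, s) du =
  #   sum_j sqrt(2) h w_j e^{x_j^2} N(u_j; 0, s) f(u_j), u_j = c + sqrt2 h x_j
  nodes1 <- function(centre, h, s) {
    u <- centre + sqrt(2) * h * gh$x
    logw <- log(sqrt(2) * h) + log(gh$w) + gh$x^2 +
      stats::dnorm(u, 0, s, log = TRUE)
    list(u = u, logw = logw)
  }
  ny <- lapply(seq_len(nY), function(y) nodes1(cY[y], hY[y], sY))
  # per lek: integral over its effect at every year-node combination
  lek_int <- lapply(seq_len(nL), function(l) {
    nl <- nodes1(cL[l], hL[l], sL)
    A <- lapply(1:3, function(y) {
      r <- which(design$lek_id == leks[l] & design$year == yrs[y])
      outer(nl$u, ny[[y]]$u,
            function(uj, vm) nb_logpmf(design$count[r], exp(off[r] + uj + vm),
                                       params$phi))
    })
    res <- array(0, c(nn, nn, nn))
    for (j in seq_len(nn)) {
      l12 <- outer(A[[1]][j, ], A[[2]][j, ], "+")
      l123 <- outer(l12, A[[3]][j, ], "+")
      res <- res + exp(nl$logw[j] + l123)
    }
    res
  })
  wy3 <- exp(outer(outer(ny[[1]]$logw, ny[[2]]$logw, "+"), ny[[3]]$logw,
                   "+"))
  total <- sum(wy3 * Reduce(`*`, lek_int))
  log(total)
}
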