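#' @title Hierarchical Gompertz population-dynamic model
#' @description Group density transitions
#'   `log(M[g,y]) ~ Normal(log(mu[g,y]), sigma_eta[g,y])` with
#'   `log(mu) = beta0 + (betaD + 1 + alphaG[g]) * log(M[g,y-1]) +
#'   betaA*AREA + betaP*PDO + alphaY[y]` and process-error SD
#'   `log(sigma_eta) = betaN + betaL * log(LEKS[g,y])`. Observer error is
#'   fixed at exactly zero. The group effect acts on the density-dependence
#'   slope and the year effect on the intercept; conditional on the fixed
#'   parameters the model is linear-Gaussian in both random-effect vectors,
#'   so the Laplace "approximation" used to marginalize them is exact.
#' @name population_model
NULL

pop_indices <- function(design) {
  gi <- match(design$group_id, sort(unique(design$group_id)))
  yi <- match(design$year, sort(unique(design$year)))
  n <- length(gi)
  nG <- max(gi); nY <- max(yi)
  # dense indicator matrices: group/year sums become BLAS products
  Gm <- matrix(0, nG, n); Gm[cbind(gi, seq_len(n))] <- 1
  Ym <- matrix(0, nY, n); Ym[cbind(yi, seq_len(n))] <- 1
  list(gi = gi, yi = yi, nG = nG, nY = nY, Gm = Gm, Ym = Ym, Ymt = t(Ym),
       log_nl = log(design$n_leks), r0 = log(design$density),
       log_prev = design$log_prev, area = design$area_std,
       pdo = design$pdo_std)
}

pop_parts <- function(params, design, log_nl = log(design$n_leks)) {
  mean0 <- params$beta0 + (params$betaD + 1) * design$log_prev
  if (!is.null(params$betaA)) mean0 <- mean0 + params$betaA * design$area_std
  if (!is.null(params$betaP)) mean0 <- mean0 + params$betaP * design$pdo_std
  sd_eta <- exp(params$betaN + params$betaL * log_nl)
  list(mean0 = mean0, sd_eta = sd_eta)
}

#' Marginal log-likelihood of the population model
#'
#' Sums normal log-densities of the observed log density transitions, with
#' the group (density-dependence) and year (intercept) random effects
#' integrated out; the integral is an exact Gaussian one. A group-year with
#' no previous-year density contributes nothing (rows are transitions).
#'
#' @param params Named list: `beta0`, `betaD`, optional `betaA`, `betaP`,
#'   `betaN`, `betaL`, `sigmaG`, `sigmaY`.
#' @param design Transition table from [build_design()] on a group density
#'   response (columns `density`, `log_prev`, `n_leks`, `area_std`,
#'   `pdo_std`).
#' @param details Return the random-effect modes too.
#' @param idx Precomputed index structure (internal; avoids repeated factor
#'   matching inside optimization and sampling loops).
#' @return Log-likelihood, or a list when `details = TRUE`.
#' @export
pop_loglik <- function(params, design, details = FALSE, idx = NULL) {
  stopifnot(params$sigmaG >= 0, params$sigmaY >= 0)
  if (any(design$density <= 0)) stop("non-positive density in transitions")
  if (is.null(idx)) idx <- pop_indices(design)
  r0 <- idx$r0
  pp <- pop_parts(params, design, log_nl = idx$log_nl)
  v <- 1 / pp$sd_eta^2
  resid0 <- r0 - pp$mean0
  gi <- idx$gi; yi <- idx$yi; nG <- idx$nG; nY <- idx$nY
  sG <- params$sigmaG; sY <- params$sigmaY
  useG <- sG > 0; useY <- sY > 0
  x <- design$log_prev

  base_ll <- -0.5 * length(r0) * log(2 * pi) - sum(log(pp$sd_eta)) -
    0.5 * sum(v * resid0^2)
  if (!useG && !useY) {
    if (!details) return(base_ll)
    return(list(loglik = base_ll, uG = numeric(0), uY = numeric(0)))
  }

  Gm <- idx$Gm; Ym <- idx$Ym
  # Quadratic joint density: one Newton step from zero is exact.
  if (useG) {
    DG <- as.numeric(Gm %*% (x^2 * v)) + 1 / sG^2
    gG <- as.numeric(Gm %*% (x * v * resid0))
  }
  if (useY) {
    DY <- as.numeric(Ym %*% v) + 1 / sY^2
    gY <- as.numeric(Ym %*% (v * resid0))
  }
  if (useG && useY) {
    B <- Gm %*% (idx$Ymt * (x * v))
    S <- diag(DY, nY) - crossprod(B / DG, B)
    cS <- chol(S)
    rhs <- gY - as.numeric(crossprod(B, gG / DG))
    uY <- backsolve(cS, backsolve(cS, rhs, transpose = TRUE))
    uG <- (gG - as.numeric(B %*% uY)) / DG
    logdet <- sum(log(DG)) + 2 * sum(log(diag(cS)))
    quad_gain <- 0.5 * (sum(gG * uG) + sum(gY * uY))
  } else if (useG) {
    uG <- gG / DG; uY <- numeric(0)
    logdet <- sum(log(DG))
    quad_gain <- 0.5 * sum(gG * uG)
  } else {
    uY <- gY / DY; uG <- numeric(0)
    logdet <- sum(log(DY))
    quad_gain <- 0.5 * sum(gY * uY)
  }
  q <- useG * nG + useY * nY
  f0 <- base_ll +
    (if (useG) -nG * (log(sG) + 0.5 * log(2 * pi)) else 0) +
    (if (useY) -nY * (log(sY) + 0.5 * log(2 * pi)) else 0)
  ll <- f0 + quad_gain + 0.5 * q * log(2 * pi) - 0.5 * logdet
  if (!details) return(ll)
  list(loglik = ll, uG = uG, uY = uY)
}

# Hot path for MCMC: same quantity as pop_loglik + Normal(0, prior_sd)
# priors, computed straight from the transformed parameter vector with no
# list construction. Extreme parameters (|th| > 60, posterior mass ~0) are
# rejected outright, which also keeps the arithmetic overflow-free.
pop_logpost_fast <- function(th, ia, ip, idx, prior_sd) {
  if (any(abs(th) > 60)) return(-Inf)
  k <- 2L
  bA <- if (ia) th[[k <- k + 1L]] else 0
  bP <- if (ip) th[[k <- k + 1L]] else 0
  betaN <- th[[k + 1L]]; betaL <- th[[k + 2L]]
  sG <- exp(th[[k + 3L]]); sY <- exp(th[[k + 4L]])
  mean0 <- th[[1L]] + (th[[2L]] + 1) * idx$log_prev + bA * idx$area +
    bP * idx$pdo
  log_sd <- betaN + betaL * idx$log_nl
  v <- exp(-2 * log_sd)
  resid0 <- idx$r0 - mean0
  n <- length(resid0)
  base_ll <- -0.5 * n * log(2 * pi) - sum(log_sd) - 0.5 * sum(v * resid0^2)
  x <- idx$log_prev
  DG <- as.numeric(idx$Gm %*% (x^2 * v)) + 1 / sG^2
  gG <- as.numeric(idx$Gm %*% (x * v * resid0))
  DY <- as.numeric(idx$Ym %*% v) + 1 / sY^2
  gY <- as.numeric(idx$Ym %*% (v * resid0))
  B <- idx$Gm %*% (idx$Ymt * (x * v))
  S <- diag(DY, idx$nY) - crossprod(B / DG, B)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) return(-Inf)
  rhs <- gY - as.numeric(crossprod(B, gG / DG))
  uY <- backsolve(cS, backsolve(cS, rhs, transpose = TRUE))
  uG <- (gG - as.numeric(B %*% uY)) / DG
  logdet <- sum(log(DG)) + 2 * sum(log(diag(cS)))
  quad_gain <- 0.5 * (sum(gG * uG) + sum(gY * uY))
  f0 <- base_ll - idx$nG * (log(sG) + 0.5 * log(2 * pi)) -
    idx$nY * (log(sY) + 0.5 * log(2 * pi))
  ll <- f0 + quad_gain + 0.5 * (idx$nG + idx$nY) * log(2 * pi) -
    0.5 * logdet
  if (!is.finite(ll)) return(-Inf)
  ll - 0.5 * sum(th^2) / prior_sd^2 -
    length(th) * (log(prior_sd) + 0.5 * log(2 * pi))
}

pop_pack <- function(params, include_area, include_pdo) {
  th <- c(beta0 = params$beta0, betaD = params$betaD)
  if (include_area) th <- c(th, betaA = params$betaA)
  if (include_pdo) th <- c(th, betaP = params$betaP)
  c(th, betaN = params$betaN, betaL = params$betaL,
    log_sigmaG = log(max(params$sigmaG, 1e-8)),
    log_sigmaY = log(max(params$sigmaY, 1e-8)))
}

pop_unpack <- function(theta, include_area, include_pdo) {
  p <- list(beta0 = unname(theta["beta0"]), betaD = unname(theta["betaD"]),
            betaN = unname(theta["betaN"]), betaL = unname(theta["betaL"]),
            sigmaG = exp(unname(theta["log_sigmaG"])),
            sigmaY = exp(unname(theta["log_sigmaY"])))
  if (include_area) p$betaA <- unname(theta["betaA"])
  if (include_pdo) p$betaP <- unname(theta["betaP"])
  p
}

#' Fit the Gompertz population model
#'
#' Engines and conventions as in [fit_local()]; the Bayesian priors are
#' Normal(0, 5) on all betas (including the process-error coefficients
#' `betaN`, `betaL`) and on the log random-effect SDs. Warns if the implied
#' density dependence `betaD + alphaG` falls outside (-2, 0) for any group
#' (non-stationary dynamics).
#'
#' @inheritParams fit_local
#' @param design Transition table from [build_design()] on a density
#'   response.
#' @return Object of class `pop_fit`.
#' @export
fit_population <- function(design, include_area = TRUE, include_pdo = TRUE,
                           engine = c("ml", "bayes"), start = NULL,
                           mcmc = list(), hessian = TRUE) {
  engine <- match.arg(engine)
  stopifnot(nrow(design) >= 2)
  idx <- pop_indices(design)
  negll <- function(theta) {
    p <- pop_unpack(theta, include_area, include_pdo)
    ll <- tryCatch(pop_loglik(p, design, idx = idx),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  th0 <- if (!is.null(start)) start else {
    s <- c(beta0 = mean(log(design$density)) * 0.4, betaD = -0.4)
    if (include_area) s <- c(s, betaA = 0)
    if (include_pdo) s <- c(s, betaP = 0)
    c(s, betaN = log(max(stats::sd(log(design$density)), 0.1)), betaL = 0,
      log_sigmaG = log(0.1), log_sigmaY = log(0.1))
  }
  opt <- stats::nlminb(th0, negll, control = list(eval.max = 2000,
                                                  iter.max = 600,
                                                  rel.tol = 1e-10))
  if (opt$objective >= 1e10) {
    stop("population model failed to converge: ", opt$message, call. = FALSE)
  }
  theta <- opt$par
  params <- pop_unpack(theta, include_area, include_pdo)
  det_fit <- pop_loglik(params, design, details = TRUE)
  dd <- params$betaD + det_fit$uG
  if (length(dd) && (any(dd >= 0) || any(dd <= -2))) {
    warning("betaD + alphaG outside (-2, 0) for ", sum(dd >= 0 | dd <= -2),
            " group(s): non-stationary dynamics")
  }
  vc <- NULL
  if (hessian || engine == "bayes") {
    H <- numeric_hessian(negll, theta)
    vc <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-6, nrow(H))))
    dimnames(vc) <- list(names(theta), names(theta))
  }
  fit <- structure(list(
    params = params, theta = theta,
    include_area = include_area, include_pdo = include_pdo,
    loglik = det_fit$loglik, n_params = length(theta), n_obs = nrow(design),
    vcov = vc,
    ranef = list(group = stats::setNames(det_fit$uG,
                                         sort(unique(design$group_id))),
                 year = stats::setNames(det_fit$uY,
                                        sort(unique(design$year)))),
    standardization = attr(design, "standardization"),
    spec = attr(design, "spec"),
    engine = engine, convergence = opt$convergence),
    class = "pop_fit")

  if (engine == "bayes") {
    prior_sd <- if (is.null(mcmc$prior_sd)) 5 else mcmc$prior_sd
    logpost <- function(th) {
      pop_logpost_fast(th, include_area, include_pdo, idx, prior_sd)
    }
    samp <- mh_sample(logpost, mode = theta, vcov = vc, mcmc = mcmc)
    nat <- samp$draws
    for (cn in c("log_sigmaG", "log_sigmaY")) nat[, cn] <- exp(nat[, cn])
    colnames(nat) <- sub("^log_", "", colnames(nat))
    fit$draws <- nat
    fit$draws_transformed <- samp$draws
    fit$diagnostics <- samp$diagnostics
  }
  fit
}

#' @export
print.pop_fit <- function(x, ...) {
  cat("Hierarchical Gompertz population model (", x$engine, ")\n", sep = "")
  print(round(unlist(x$params), 4))
  cat("logLik:", format(x$loglik), " k:", x$n_params, " n:", x$n_obs, "\n")
  invisible(x)
}

#' Expected density next year given this year's density
#'
#' `exp(beta0 + (betaD + 1 + group_effect) * log(prev) + betaA*area +
#' betaP*pdo + year_effect)`.
#'
#' @param fit A `pop_fit`, or a bare named list of parameters.
#' @param prev_density Positive current density.
#' @param area_std,pdo_std Standardized covariates.
#' @param group_effect,year_effect Random-effect values (default 0, the
#'   typical group/year).
#' @return Expected density.
#' @export
predict_next_density <- function(fit, prev_density, area_std = 0, pdo_std = 0,
                                 group_effect = 0, year_effect = 0) {
  stopifnot(all(prev_density > 0))
  p <- if (inherits(fit, "pop_fit")) fit$params else fit
  eta <- p$beta0 + (p$betaD + 1 + group_effect) * log(prev_density) +
    year_effect
  if (!is.null(p$betaA)) eta <- eta + p$betaA * area_std
  if (!is.null(p$betaP)) eta <- eta + p$betaP * pdo_std
  exp(eta)
}

#' Carrying capacity (long-term expected density)
#'
#' Closed form `log(N_inf) = -(beta0 + betaA*AREA + betaP*PDO) /
#' (betaD + alphaG)`, the fixed point of the density map. Intervals come
#' from posterior draws for Bayesian fits or the delta method for ML fits.
#'
#' @param fit A `pop_fit` or bare parameter list.
#' @param area_std,pdo_std Evaluation covariates (standardized).
#' @param group_id A group name (uses its estimated `alphaG`) or `NULL` for
#'   the typical group (`alphaG = 0`).
#' @param level Interval coverage, default 0.95.
#' @return List: `value` (males per lek), `lower`, `upper`, `group_id`.
#' @export
carrying_capacity <- function(fit, area_std = 0, pdo_std = 0,
                              group_id = NULL, level = 0.95) {
  p <- if (inherits(fit, "pop_fit")) fit$params else fit
  aG <- 0
  if (!is.null(group_id) && inherits(fit, "pop_fit")) {
    aG <- unname(fit$ranef$group[group_id])
    if (is.na(aG)) stop("unknown group: ", group_id)
  }
  denom <- p$betaD + aG
  if (denom == 0) stop("betaD + alphaG = 0: no finite carrying capacity",
                       call. = FALSE)
  num <- p$beta0 +
    (if (!is.null(p$betaA)) p$betaA * area_std else 0) +
    (if (!is.null(p$betaP)) p$betaP * pdo_std else 0)
  value <- exp(-num / denom)

  lower <- upper <- NA_real_
  a2 <- (1 - level) / 2
  if (inherits(fit, "pop_fit") && !is.null(fit$draws)) {
    d <- fit$draws
    numd <- d[, "beta0"] +
      (if (fit$include_area) d[, "betaA"] * area_std else 0) +
      (if (fit$include_pdo) d[, "betaP"] * pdo_std else 0)
    kd <- exp(-numd / (d[, "betaD"] + aG))
    lower <- unname(stats::quantile(kd, a2))
    upper <- unname(stats::quantile(kd, 1 - a2))
  } else if (inherits(fit, "pop_fit") && !is.null(fit$vcov)) {
    # delta method on log(N_inf) in (beta0, betaA, betaP, betaD)
    nm <- c("beta0",
            if (fit$include_area) "betaA", if (fit$include_pdo) "betaP",
            "betaD")
    grad <- c(-1 / denom,
              if (fit$include_area) -area_std / denom,
              if (fit$include_pdo) -pdo_std / denom,
              num / denom^2)
    vc <- fit$vcov[nm, nm, drop = FALSE]
    se <- sqrt(max(0, drop(t(grad) %*% vc %*% grad)))
    z <- stats::qnorm(1 - a2)
    lower <- value * exp(-z * se)
    upper <- value * exp(z * se)
  }
  list(value = value, lower = lower, upper = upper,
       group_id = if (is.null(group_id)) "typical" else group_id,
       area_std = area_std, pdo_std = pdo_std)
}
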