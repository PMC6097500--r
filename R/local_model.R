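#' @title Negative-binomial lek-count mixed model
#' @description The lek-count model: counts `M[i,y] ~ NegBin(mu[i,y], phi)`
#'   with `log(mu) = beta0 + betaA*AREA + betaP*PDO + alphaL[i] + alphaY[y]`,
#'   crossed lek and year random effects `alphaL ~ N(0, sigmaL)`,
#'   `alphaY ~ N(0, sigmaY)` and `Var(M) = mu + phi*mu^2`. The marginal
#'   likelihood integrates the random effects out with a Laplace
#'   approximation over their joint conditional mode; the crossed structure
#'   (one observation per lek-year) is solved with a dense Schur complement
#'   on the smaller year block, so no sparse-matrix library is needed.
#' @name local_model
NULL

local_indices <- function(design) {
  li <- match(design$lek_id, sort(unique(design$lek_id)))
  yi <- match(design$year, sort(unique(design$year)))
  if (anyDuplicated(cbind(li, yi))) {
    stop("design must have at most one row per (lek, year)")
  }
  list(li = li, yi = yi, nL = max(li), nY = max(yi))
}

# Fast group-sum onto 1..n (rowsum without dimnames overhead).
gsum <- function(x, idx, n) {
  as.numeric(unname(rowsum.default(x, idx, reorder = TRUE)))
}

local_offset <- function(params, design) {
  off <- rep(params$beta0, nrow(design))
  if (!is.null(params$betaA)) off <- off + params$betaA * design$area_std
  if (!is.null(params$betaP)) off <- off + params$betaP * design$pdo_std
  off
}

# Penalized joint log-density of data and random effects.
local_joint_f <- function(uL, uY, y, off, li, yi, phi, sL, sY) {
  eta <- off
  if (length(uL)) eta <- eta + uL[li]
  if (length(uY)) eta <- eta + uY[yi]
  eta <- pmin(eta, 30)
  f <- sum(nb_ll(y, exp(eta), phi))
  if (length(uL)) f <- f + sum(stats::dnorm(uL, 0, sL, log = TRUE))
  if (length(uY)) f <- f + sum(stats::dnorm(uY, 0, sY, log = TRUE))
  f
}

#' Marginal log-likelihood of the lek-count model
#'
#' Random effects are integrated out by a Laplace approximation; when both
#' random-effect SDs are zero the value is the exact sum of [nb_logpmf()]
#' terms. Variance SDs of exactly zero drop the corresponding block from the
#' integral.
#'
#' @param params Named list: `beta0`, optional `betaA`, `betaP`, and
#'   `sigmaL`, `sigmaY`, `phi` (all on the natural scale).
#' @param design Analysis table from [build_design()] (columns `count`,
#'   `lek_id`, `year`, `area_std`, `pdo_std`).
#' @param u_start Optional warm start for the joint random-effect mode.
#' @param details If `TRUE` return a list with the mode and curvature.
#' @param idx Precomputed index structure (internal; used to avoid repeated
#'   factor matching inside optimization loops).
#' @return Log-likelihood (scalar), or a list when `details = TRUE`.
#' @export
local_marginal_loglik <- function(params, design, u_start = NULL,
                                  details = FALSE, idx = NULL) {
  stopifnot(params$sigmaL >= 0, params$sigmaY >= 0, params$phi >= 0)
  y <- design$count
  off <- local_offset(params, design)
  sL <- params$sigmaL; sY <- params$sigmaY; phi <- params$phi
  useL <- sL > 0; useY <- sY > 0
  if (!useL && !useY) {
    ll <- sum(nb_logpmf(y, exp(pmin(off, 30)), phi))
    if (!details) return(ll)
    return(list(loglik = ll, uL = numeric(0), uY = numeric(0)))
  }
  if (is.null(idx)) idx <- local_indices(design)
  li <- idx$li; yi <- idx$yi; nL <- idx$nL; nY <- idx$nY

  uL <- if (useL) (if (!is.null(u_start)) u_start$uL else numeric(nL)) else numeric(0)
  uY <- if (useY) (if (!is.null(u_start)) u_start$uY else numeric(nY)) else numeric(0)
  if (length(uL) != nL * useL) uL <- numeric(nL)
  if (length(uY) != nY * useY) uY <- numeric(nY)

  f <- local_joint_f(uL, uY, y, off, li, yi, phi, sL, sY)
  logdet <- NA_real_
  for (it in 1:60) {
    eta <- pmin(off + (if (useL) uL[li] else 0) + (if (useY) uY[yi] else 0), 30)
    d <- nb_eta_derivs(y, exp(eta), phi)
    g <- d$g; w <- pmax(d$w, 1e-12)
    if (useL) {
      DL <- as.numeric(rowsum(w, li, reorder = TRUE)) + 1 / sL^2
      gL <- as.numeric(rowsum(g, li, reorder = TRUE)) - uL / sL^2
    }
    if (useY) {
      DY <- as.numeric(rowsum(w, yi, reorder = TRUE)) + 1 / sY^2
      gY <- as.numeric(rowsum(g, yi, reorder = TRUE)) - uY / sY^2
    }
    if (useL && useY) {
      B <- matrix(0, nL, nY)
      B[cbind(li, yi)] <- w
      S <- diag(DY, nY) - crossprod(B / DL, B)   # t(B) %*% diag(1/DL) %*% B
      cS <- chol(S)
      rhs <- gY - as.numeric(crossprod(B, gL / DL))
      dY <- backsolve(cS, forwardsolve(t(cS), rhs))
      dL <- (gL - as.numeric(B %*% dY)) / DL
      gnorm <- max(abs(c(gL, gY)))
      logdet <- sum(log(DL)) + 2 * sum(log(diag(cS)))
    } else if (useL) {
      dL <- gL / DL; dY <- numeric(0)
      gnorm <- max(abs(gL))
      logdet <- sum(log(DL))
    } else {
      dY <- gY / DY; dL <- numeric(0)
      gnorm <- max(abs(gY))
      logdet <- sum(log(DY))
    }
    if (gnorm < 1e-8) break
    step <- 1
    repeat {
      uL2 <- if (useL) uL + step * dL else uL
      uY2 <- if (useY) uY + step * dY else uY
      f2 <- local_joint_f(uL2, uY2, y, off, li, yi, phi, sL, sY)
      if (is.finite(f2) && f2 >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (abs(f2 - f) < 1e-11 && gnorm < 1e-5) { uL <- uL2; uY <- uY2; f <- f2; break }
    uL <- uL2; uY <- uY2; f <- f2
  }
  q <- useL * nL + useY * nY
  ll <- f + 0.5 * q * log(2 * pi) - 0.5 * logdet
  if (!is.finite(ll)) {
    stop("non-finite marginal log-likelihood at params: ",
         paste(sprintf("%s=%.4g", names(params), unlist(params)),
               collapse = ", "), call. = FALSE)
  }
  if (!details) return(ll)
  list(loglik = ll, uL = uL, uY = uY, logdet = logdet, f = f)
}

local_pack <- function(params, include_area, include_pdo) {
  th <- c(beta0 = params$beta0)
  if (include_area) th <- c(th, betaA = params$betaA)
  if (include_pdo) th <- c(th, betaP = params$betaP)
  c(th, log_sigmaL = log(max(params$sigmaL, 1e-8)),
    log_sigmaY = log(max(params$sigmaY, 1e-8)),
    log_phi = log(max(params$phi, 1e-8)))
}

local_unpack <- function(theta, include_area, include_pdo) {
  p <- list(beta0 = unname(theta["beta0"]),
            sigmaL = exp(unname(theta["log_sigmaL"])),
            sigmaY = exp(unname(theta["log_sigmaY"])),
            phi = exp(unname(theta["log_phi"])))
  if (include_area) p$betaA <- unname(theta["betaA"])
  if (include_pdo) p$betaP <- unname(theta["betaP"])
  p
}

numeric_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  hi <- pmax(abs(x), 1) * h
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- hi[i]; ej[j] <- hi[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hi[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
             fn(x - ei - ej)) / (4 * hi[i] * hi[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Fit the lek-count model by maximum likelihood or MCMC
#'
#' ML maximizes the Laplace-marginalized likelihood with variance parameters
#' optimized on the log scale; the coefficient covariance comes from the
#' numerical Hessian at the optimum. The Bayesian engine places Normal(0, 5)
#' priors on the betas and on `log(sigmaL)`, `log(sigmaY)`, `log(phi)` and
#' samples the marginalized posterior with [mh_sample()] (pilot-matched
#' independence proposal, escalating to slice sampling when the convergence
#' rules fail); it retains the second halves of `mcmc$chains` chains and
#' fails unless Rhat <= 1.01 and the effective sample size is >= 1000 for
#' every structural parameter.
#'
#' @param design Analysis table from [build_design()].
#' @param include_area,include_pdo Include the disturbance / climate fixed
#'   effect.
#' @param engine `"ml"` or `"bayes"`.
#' @param start Optional named start vector (transformed scale) for warm
#'   starts.
#' @param mcmc List of MCMC settings: `chains` (3), `iter` (2400 per chain,
#'   second half retained), `seed`, `prior_sd` (5), `check` (enforce
#'   convergence rules).
#' @param hessian Compute the ML covariance matrix (default `TRUE`).
#' @return Object of class `local_fit`: estimates, `vcov`, `loglik`,
#'   `n_params`, `n_obs`, random-effect conditional modes, and for the
#'   Bayesian engine a matrix of posterior `draws` with convergence
#'   diagnostics.
#' @export
fit_local <- function(design, include_area = TRUE, include_pdo = TRUE,
                      engine = c("ml", "bayes"), start = NULL, mcmc = list(),
                      hessian = TRUE) {
  engine <- match.arg(engine)
  stopifnot(nrow(design) > 0)
  mode_env <- new.env(parent = emptyenv())
  mode_env$u <- NULL
  idx <- local_indices(design)
  negll <- function(theta) {
    p <- local_unpack(theta, include_area, include_pdo)
    res <- tryCatch(
      local_marginal_loglik(p, design, u_start = mode_env$u, details = TRUE,
                            idx = idx),
      error = function(e) NULL)
    if (is.null(res)) return(1e10)
    mode_env$u <- list(uL = res$uL, uY = res$uY)
    -res$loglik
  }
  th0 <- if (!is.null(start)) start else {
    s <- c(beta0 = log(mean(design$count) + 0.5))
    if (include_area) s <- c(s, betaA = 0)
    if (include_pdo) s <- c(s, betaP = 0)
    c(s, log_sigmaL = log(0.5), log_sigmaY = log(0.3), log_phi = log(0.3))
  }
  opt <- stats::nlminb(th0, negll, control = list(eval.max = 2000,
                                                  iter.max = 600,
                                                  rel.tol = 1e-10))
  if (!opt$convergence %in% c(0, 1) && opt$objective >= 1e10) {
    stop("local model failed to converge: ", opt$message, call. = FALSE)
  }
  theta <- opt$par
  params <- local_unpack(theta, include_area, include_pdo)
  det_fit <- local_marginal_loglik(params, design, u_start = mode_env$u,
                                   details = TRUE, idx = idx)
  vc <- NULL
  if (hessian || engine == "bayes") {
    H <- numeric_hessian(negll, theta)
    vc <- tryCatch(solve(H), error = function(e) {
      solve(H + diag(1e-6, nrow(H)))
    })
    dimnames(vc) <- list(names(theta), names(theta))
  }
  fit <- structure(list(
    params = params, theta = theta,
    include_area = include_area, include_pdo = include_pdo,
    loglik = det_fit$loglik, n_params = length(theta), n_obs = nrow(design),
    vcov = vc,
    ranef = list(lek = stats::setNames(det_fit$uL,
                                       sort(unique(design$lek_id))),
                 year = stats::setNames(det_fit$uY,
                                        sort(unique(design$year)))),
    standardization = attr(design, "standardization"),
    spec = attr(design, "spec"),
    engine = engine, convergence = opt$convergence),
    class = "local_fit")

  if (engine == "bayes") {
    logpost <- function(th) {
      if (any(abs(th) > 60)) return(-Inf)
      p <- local_unpack(th, include_area, include_pdo)
      ll <- tryCatch(local_marginal_loglik(p, design, u_start = mode_env$u,
                                           idx = idx),
                     error = function(e) -Inf)
      if (!is.finite(ll)) return(-Inf)
      prior_sd <- if (is.null(mcmc$prior_sd)) 5 else mcmc$prior_sd
      ll + sum(stats::dnorm(th, 0, prior_sd, log = TRUE))
    }
    samp <- mh_sample(logpost, mode = theta, vcov = vc, mcmc = mcmc)
    nat <- samp$draws
    for (cn in c("log_sigmaL", "log_sigmaY", "log_phi")) {
      nat[, cn] <- exp(nat[, cn])
    }
    colnames(nat) <- sub("^log_", "", colnames(nat))
    fit$draws <- nat
    fit$draws_transformed <- samp$draws
    fit$diagnostics <- samp$diagnostics
  }
  fit
}

#' @export
print.local_fit <- function(x, ...) {
  cat("Negative-binomial lek-count mixed model (", x$engine, ")\n", sep = "")
  est <- unlist(x$params)
  print(round(est, 4))
  cat("logLik:", format(x$loglik), " k:", x$n_params, " n:", x$n_obs, "\n")
  invisible(x)
}

#' Expected count at given standardized covariates
#'
#' `exp(beta0 + betaA*area_std + betaP*pdo_std + lek_effect + year_effect)`;
#' a "typical" lek and year have both effects 0.
#'
#' @param fit A `local_fit`.
#' @param area_std,pdo_std Standardized covariate values.
#' @param lek_effect,year_effect Random-effect values (default 0).
#' @return Expected count (vectorized).
#' @export
predict_expected_count <- function(fit, area_std = 0, pdo_std = 0,
                                   lek_effect = 0, year_effect = 0) {
  p <- fit$params
  eta <- p$beta0 + lek_effect + year_effect
  if (!is.null(p$betaA)) eta <- eta + p$betaA * area_std
  if (!is.null(p$betaP)) eta <- eta + p$betaP * pdo_std
  exp(eta)
}

#' Marginal and conditional R-squared on the observation scale
#'
#' Response-scale variance decomposition: with `F = exp(fixed linear
#' predictor)` varying over the analysis rows and `R = exp(alphaL + alphaY)`
#' lognormal, the total response variance is
#' `Var(F*R) + E[mu + phi*mu^2]` (the distribution variance implied by the
#' NB mean-variance relation). Marginal R2 is the variance attributable to
#' the fixed effects alone, `Var(F)*E[R]^2`, over the total; conditional R2
#' adds the random-effect variance, `Var(F*R)`, to the numerator.
#'
#' @param fit A `local_fit` (ML).
#' @param design The analysis table the model was fitted to.
#' @return Named vector `c(marginal, conditional)` (proportions).
#' @export
r2_observational <- function(fit, design) {
  p <- fit$params
  eta_f <- local_offset(p, design)
  s2 <- p$sigmaL^2 + p$sigmaY^2
  FF <- exp(eta_f)
  ER <- exp(s2 / 2)
  ER2 <- exp(2 * s2)
  var_fr <- mean(FF^2) * ER2 - (mean(FF) * ER)^2
  var_f <- stats::var(FF) * (length(FF) - 1) / length(FF) * ER^2
  Emu <- mean(FF) * ER
  Emu2 <- mean(FF^2) * ER2
  var_dist <- Emu + p$phi * Emu2
  tot <- var_fr + var_dist
  c(marginal = var_f / tot, conditional = var_fr / tot)
}
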