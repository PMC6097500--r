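#' @title AICc model selection, Akaike weights and model averaging
#' @name model_selection
NULL

#' Akaike's information criterion corrected for small samples
#'
#' `-2*loglik + 2k + 2k(k+1)/(n-k-1)`. `k` counts every estimated parameter
#' (fixed effects, variance components, overdispersion); `n` is the number
#' of likelihood terms (lek-years locally, transitions for the population
#' model).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Parameter count.
#' @param n Observation count, must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion values
#'
#' @param ic Vector of AICc (or AIC) values, all finite.
#' @return Weights `exp(-delta/2)` normalized to sum to 1.
#' @export
akaike_weights <- function(ic) {
  stopifnot(length(ic) >= 1, all(is.finite(ic)))
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Percent effect size per one-SD increase in a standardized predictor
#'
#' `100 * (exp(beta) - 1)`, applied identically to the interval endpoints.
#'
#' @param beta Log-scale coefficient (per +1 SD).
#' @param lower,upper Optional interval endpoints on the same scale.
#' @return List `percent`, `lower`, `upper`.
#' @export
effect_size <- function(beta, lower = NA_real_, upper = NA_real_) {
  list(percent = 100 * (exp(beta) - 1),
       lower = 100 * (exp(lower) - 1),
       upper = 100 * (exp(upper) - 1))
}

#' Fit every spatial-scale / time-lag combination and weight the models
#'
#' The local family crosses the buffer radii with independent 1-4 year lags
#' in disturbance and the climate index (4 x 4 x 4 = 64 models by default);
#' the population family holds the radius at the locally selected scale and
#' crosses the lags (16 models). All members are fitted by ML on the
#' identical response rows: the rows available under the maximum lag of the
#' grid (the common-data rule), so AICc values are comparable.
#'
#' @param response Lek-year table (local family) or group-density table
#'   (population family).
#' @param disturbance Lek- or group-level disturbance series matching the
#'   family.
#' @param pdo Annual index table.
#' @param radii_m Radii to scan (length 1 for the population family).
#' @param lags Integer lags for both covariates, default `1:4`.
#' @param progress Print one line per fitted member.
#' @return Data frame of class `model_scan`: one row per member with
#'   `radius_m`, `area_lag`, `pdo_lag`, `loglik`, `n_params`, `n_obs`,
#'   `aicc`, `weight`; fitted objects in `attr(, "fits")`.
#' @export
scan_models <- function(response, disturbance, pdo, radii_m,
                        lags = 1:4, progress = FALSE) {
  is_local <- "count" %in% names(response)
  max_lag <- max(lags)
  # Common rows: those joinable under the maximum lag at every radius.
  ref <- NULL
  for (r in radii_m) {
    d <- build_design(response, disturbance, pdo, r,
                      area_lag = max_lag, pdo_lag = max_lag)
    keyc <- if (is_local) "lek_id" else "group_id"
    k <- d[, c(keyc, "year")]
    ref <- if (is.null(ref)) k else merge(ref, k)
  }
  grid <- expand.grid(radius_m = radii_m, area_lag = lags, pdo_lag = lags)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  start <- NULL
  for (i in seq_len(nrow(grid))) {
    des <- build_design(response, disturbance, pdo, grid$radius_m[i],
                        area_lag = grid$area_lag[i],
                        pdo_lag = grid$pdo_lag[i], keep_rows = ref)
    fit <- tryCatch(
      if (is_local) {
        fit_local(des, engine = "ml", start = start, hessian = FALSE)
      } else {
        fit_population(des, engine = "ml", start = start, hessian = FALSE)
      },
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("scan member failed (radius ", grid$radius_m[i], ", area lag ",
           grid$area_lag[i], ", pdo lag ", grid$pdo_lag[i], "): ",
           conditionMessage(fit), call. = FALSE)
    }
    start <- fit$theta
    fits[[i]] <- fit
    rows[[i]] <- data.frame(radius_m = grid$radius_m[i],
                            area_lag = grid$area_lag[i],
                            pdo_lag = grid$pdo_lag[i],
                            loglik = fit$loglik, n_params = fit$n_params,
                            n_obs = fit$n_obs,
                            aicc = aicc(fit$loglik, fit$n_params, fit$n_obs))
    if (progress) {
      message(sprintf("fitted radius=%g area_lag=%d pdo_lag=%d logLik=%.2f",
                      grid$radius_m[i], grid$area_lag[i], grid$pdo_lag[i],
                      fit$loglik))
    }
  }
  out <- do.call(rbind, rows)
  out$weight <- akaike_weights(out$aicc)
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "grid") <- grid
  class(out) <- c("model_scan", class(out))
  out
}

#' Relative importance of the levels of a scan dimension
#'
#' Sums Akaike weights over the scan members sharing each level of a
#' dimension (e.g. each buffer radius, or each disturbance lag).
#'
#' @param scan A [scan_models()] result.
#' @param by One of `"radius_m"`, `"area_lag"`, `"pdo_lag"`, or a vector of
#'   levels (one per scan row) forming a partition.
#' @return Data frame `level`, `models`, `proportion`, `weight`, sorted by
#'   weight (descending).
#' @export
variable_importance <- function(scan, by) {
  lev <- if (is.character(by) && length(by) == 1L) {
    if (!by %in% names(scan)) stop("unknown dimension: ", by)
    scan[[by]]
  } else {
    if (length(by) != nrow(scan)) stop("levels do not partition the scan")
    by
  }
  agg <- stats::aggregate(scan$weight, list(level = lev), sum)
  cnt <- stats::aggregate(scan$weight, list(level = lev), length)
  out <- data.frame(level = agg$level, models = cnt$x,
                    proportion = cnt$x / nrow(scan), weight = agg$x)
  out[order(-out$weight), , drop = FALSE]
}

#' Fit the full model and its three reduced variants
#'
#' The family {both predictors, disturbance only, climate only, neither} on
#' identical rows, for predictor-importance weights and model averaging.
#'
#' @param design The selected final design table.
#' @param family `"local"` or `"population"`.
#' @param hessian Compute coefficient covariances (needed for averaging
#'   intervals).
#' @return List of four fits named `"both"`, `"area"`, `"pdo"`, `"none"`,
#'   with their `aicc` and Akaike `weights` attached.
#' @export
fit_reduced_family <- function(design, family = c("local", "population"),
                               hessian = TRUE) {
  family <- match.arg(family)
  f <- if (family == "local") fit_local else fit_population
  fits <- list(both = f(design, TRUE, TRUE, hessian = hessian),
               area = f(design, TRUE, FALSE, hessian = hessian),
               pdo = f(design, FALSE, TRUE, hessian = hessian),
               none = f(design, FALSE, FALSE, hessian = hessian))
  ic <- vapply(fits, function(x) aicc(x$loglik, x$n_params, x$n_obs),
               numeric(1))
  attr(fits, "aicc") <- ic
  attr(fits, "weights") <- akaike_weights(ic)
  fits
}

#' Predictor importance across the four-model reduced family
#'
#' The weight of a predictor is the summed Akaike weight of the two family
#' members that contain it.
#'
#' @param family Output of [fit_reduced_family()].
#' @return Named vector `c(area = , pdo = )`.
#' @export
predictor_weights <- function(family) {
  w <- attr(family, "weights")
  if (is.null(w) || length(w) != 4L ||
      !identical(sort(names(w)), sort(c("both", "area", "pdo", "none")))) {
    stop("expected the four-model family {both, area, pdo, none}",
         call. = FALSE)
  }
  c(area = unname(w["both"] + w["area"]),
    pdo = unname(w["both"] + w["pdo"]))
}

coef_and_var <- function(fit, name) {
  b <- fit$params[[name]]
  if (is.null(b)) return(c(0, 0))
  v <- if (!is.null(fit$vcov) && name %in% rownames(fit$vcov)) {
    fit$vcov[name, name]
  } else 0
  c(b, v)
}

#' Model-averaged effect sizes over the reduced family
#'
#' Coefficients are averaged on the log scale over all four models with zero
#' substituted where a predictor is absent (full-family averaging); the
#' unconditional variance follows the standard model-averaging formula
#' `[sum_w sqrt(var_m + (b_m - bbar)^2)]^2` and the averaged coefficient and
#' its normal interval are transformed with [effect_size()].
#'
#' @param family Output of [fit_reduced_family()].
#' @param level Interval coverage, default 0.95.
#' @return Data frame, one row per predictor: `beta`, `se`, `percent`,
#'   `lower`, `upper`, `weight`.
#' @export
model_average <- function(family, level = 0.95) {
  w <- attr(family, "weights")
  pw <- predictor_weights(family)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(c(area = "betaA", pdo = "betaP"), function(nm) {
    bv <- vapply(family, coef_and_var, numeric(2), name = nm)
    bbar <- sum(w * bv[1, ])
    se <- sum(w * sqrt(bv[2, ] + (bv[1, ] - bbar)^2))
    es <- effect_size(bbar, bbar - z * se, bbar + z * se)
    data.frame(beta = bbar, se = se, percent = es$percent,
               lower = es$lower, upper = es$upper)
  })
  out <- do.call(rbind, rows)
  out$predictor <- c("area", "pdo")
  out$weight <- pw[out$predictor]
  rownames(out) <- out$predictor
  out[, c("predictor", "beta", "se", "percent", "lower", "upper", "weight")]
}

#' Effect sizes with intervals from a single fit
#'
#' ML fits use Wald intervals from the coefficient covariance; Bayesian fits
#' use posterior quantiles of the draws.
#'
#' @param fit A `local_fit` or `pop_fit`.
#' @param level Interval coverage, default 0.95.
#' @return Data frame, one row per included predictor.
#' @export
fit_effect_sizes <- function(fit, level = 0.95) {
  a2 <- (1 - level) / 2
  z <- stats::qnorm(1 - a2)
  nms <- c(area = "betaA", pdo = "betaP")
  nms <- nms[c(fit$include_area, fit$include_pdo)]
  rows <- lapply(seq_along(nms), function(i) {
    nm <- nms[[i]]
    if (!is.null(fit$draws)) {
      d <- fit$draws[, nm]
      b <- stats::median(d)
      lo <- unname(stats::quantile(d, a2)); hi <- unname(stats::quantile(d, 1 - a2))
    } else {
      b <- fit$params[[nm]]
      se <- sqrt(fit$vcov[nm, nm])
      lo <- b - z * se; hi <- b + z * se
    }
    es <- effect_size(b, lo, hi)
    data.frame(predictor = names(nms)[i], beta = b,
               percent = es$percent, lower = es$lower, upper = es$upper)
  })
  do.call(rbind, rows)
}
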