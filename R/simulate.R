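#' @title Seed-reproducible synthetic data with the assumed structure
#' @description Generators for a climate index (stationary AR(1)), well-pad
#'   disturbance trajectories (zero before a lek's buildout, then monotone
#'   non-decreasing, right-skewed across leks), negative-binomial lek counts
#'   with crossed random effects, Gompertz group density series, and a
#'   complete toy study written in the raw input formats. All generators
#'   return the true parameter values alongside the data because
#'   parameter-recovery is the testing surface.
#' @name synthetic_data
NULL

#' Default covariate-generator settings
#'
#' `pdo_sd = 0.8` emulates the observed index SDs (0.82/0.86); `pdo_rho`
#' gives the index its decadal persistence; pads accumulate over
#' `buildout_years` with a right-skewed per-lek budget averaging
#' `n_pads_final`.
#'
#' @param pdo_rho AR(1) coefficient, `|pdo_rho| < 1`.
#' @param pdo_sd Marginal SD of the index.
#' @param n_pads_final Mean per-lek final pad count.
#' @param buildout_years Span over which a lek's pads accumulate.
#' @param seed Integer seed.
#' @return Named list of settings.
#' @export
covariate_sim_params <- function(pdo_rho = 0.5, pdo_sd = 0.8,
                                 n_pads_final = 15, buildout_years = 8,
                                 seed = 1) {
  stopifnot(abs(pdo_rho) < 1, pdo_sd > 0, n_pads_final >= 0,
            buildout_years >= 1)
  list(pdo_rho = pdo_rho, pdo_sd = pdo_sd, n_pads_final = n_pads_final,
       buildout_years = buildout_years, seed = seed)
}

#' Simulate the annual climate index and per-lek disturbance series
#'
#' The index is a stationary AR(1) with mean 0 and marginal SD
#' `pdo_sd`. Each lek draws a gamma-distributed pad budget (shape 0.5, so
#' many leks stay near zero and a few are heavily developed), a buildout
#' start year, and Poisson pad arrivals across the buildout span; cumulative
#' pads are converted to a buffer proportion with 60 m pad discs.
#'
#' @param params [covariate_sim_params()] list.
#' @param n_leks,n_years Dimensions of the study.
#' @param radius_m Buffer radius for the proportion, default 3200.
#' @param start_year First response year (series begin `lead_years`
#'   earlier so lagged joins do not drop rows).
#' @param lead_years Covariate lead-in, default 4.
#' @return List: `pdo` (data frame `year`, `value`), `disturbance`
#'   (data frame `lek_id`, `group_id`, `radius_m`, `year`, `proportion`).
#' @export
simulate_covariates <- function(params, n_leks, n_years, radius_m = 3200,
                                start_year = 1985, lead_years = 4) {
  set.seed(params$seed)
  years <- (start_year - lead_years):(start_year + n_years - 1)
  ny <- length(years)
  innov_sd <- params$pdo_sd * sqrt(1 - params$pdo_rho^2)
  v <- numeric(ny)
  v[1] <- stats::rnorm(1, 0, params$pdo_sd)
  for (t in 2:ny) v[t] <- params$pdo_rho * v[t - 1] +
      stats::rnorm(1, 0, innov_sd)
  pdo <- data.frame(year = years, value = v)

  lek_ids <- sprintf("L%03d", seq_len(n_leks))
  pad_area <- (60 / radius_m)^2
  out <- vector("list", n_leks)
  for (i in seq_len(n_leks)) {
    budget <- if (params$n_pads_final == 0) 0 else
      stats::rgamma(1, shape = 0.5, scale = params$n_pads_final / 0.5)
    start <- sample(seq_len(max(1, ny - params$buildout_years)), 1)
    arrivals <- numeric(ny)
    span <- start:min(ny, start + params$buildout_years - 1)
    if (budget > 0) {
      arrivals[span] <- stats::rpois(length(span), budget / length(span))
    }
    out[[i]] <- data.frame(lek_id = lek_ids[i], group_id = "G1",
                           radius_m = radius_m, year = years,
                           proportion = pmin(1, cumsum(arrivals) * pad_area),
                           stringsAsFactors = FALSE)
  }
  list(pdo = pdo, disturbance = do.call(rbind, out))
}

#' Default lek-count generator settings
#'
#' `beta0 = log(10)` gives the typical lek an expected count of about 10
#' males; the standardized disturbance and climate effects, random-effect
#' SDs and overdispersion default to values of the magnitude the lek-count
#' model estimates on real data.
#'
#' @param n_leks,n_years Dimensions.
#' @param beta0 Log-scale intercept.
#' @param betaA,betaP Standardized fixed effects.
#' @param sigmaL,sigmaY Random-effect SDs (`>= 0`).
#' @param phi Overdispersion (`>= 0`; 0 is Poisson).
#' @param area_lag,pdo_lag Covariate lags used when joining.
#' @param seed Integer seed.
#' @return Named list.
#' @export
local_sim_params <- function(n_leks = 100, n_years = 32, beta0 = log(10),
                             betaA = -0.2, betaP = 0.15, sigmaL = 0.6,
                             sigmaY = 0.2, phi = 0.3, area_lag = 1L,
                             pdo_lag = 2L, seed = 1) {
  stopifnot(sigmaL >= 0, sigmaY >= 0, phi >= 0)
  list(n_leks = n_leks, n_years = n_years, beta0 = beta0, betaA = betaA,
       betaP = betaP, sigmaL = sigmaL, sigmaY = sigmaY, phi = phi,
       area_lag = area_lag, pdo_lag = pdo_lag, seed = seed)
}

#' Simulate collapsed lek counts from the lek-count model
#'
#' Draws lek and year effects, forms the log mean on covariates standardized
#' over the analysis rows (exactly as [build_design()] will re-standardize
#' them), and draws counts from the gamma-Poisson mixture.
#'
#' @param params [local_sim_params()] list.
#' @param disturbance,pdo Covariate tables from [simulate_covariates()] (or
#'   real ones).
#' @return List: `lek_years` (lek_id, group_id, year, count, n_repeats),
#'   `truth` (parameters, random effects, standardization constants).
#' @export
simulate_lek_counts <- function(params, disturbance, pdo) {
  set.seed(params$seed + 1L)
  lek_ids <- sort(unique(disturbance$lek_id))
  n_leks <- length(lek_ids)
  resp_years <- (max(disturbance$year) - params$n_years + 1):
    max(disturbance$year)
  grid <- expand.grid(lek_id = lek_ids, year = resp_years,
                      stringsAsFactors = FALSE)
  a <- disturbance[, c("lek_id", "year", "proportion")]
  a$year <- a$year + params$area_lag
  names(a)[3] <- "area_raw"
  grid <- merge(grid, a, by = c("lek_id", "year"))
  p <- pdo[, c("year", "value")]
  p$year <- p$year + params$pdo_lag
  names(p)[2] <- "pdo_raw"
  grid <- merge(grid, p, by = "year")
  sa <- standardize_col(grid$area_raw, "area")
  sp <- standardize_col(grid$pdo_raw, "pdo")
  li <- match(grid$lek_id, lek_ids)
  yi <- match(grid$year, sort(unique(grid$year)))
  alphaL <- stats::rnorm(n_leks, 0, params$sigmaL)
  alphaY <- stats::rnorm(length(unique(yi)), 0, params$sigmaY)
  eta <- params$beta0 + params$betaA * sa$std + params$betaP * sp$std +
    alphaL[li] + alphaY[yi]
  counts <- rnb_mu_phi(nrow(grid), exp(eta), params$phi)
  gmap <- disturbance$group_id[match(grid$lek_id, disturbance$lek_id)]
  lek_years <- data.frame(lek_id = grid$lek_id, group_id = gmap,
                          year = grid$year, count = counts, n_repeats = 1L,
                          stringsAsFactors = FALSE)
  lek_years <- lek_years[order(lek_years$lek_id, lek_years$year), ]
  rownames(lek_years) <- NULL
  list(lek_years = lek_years,
       truth = list(params = params, alphaL = alphaL, alphaY = alphaY,
                    area = list(mean = sa$mean, sd = sa$sd),
                    pdo = list(mean = sp$mean, sd = sp$sd)))
}

#' Default population-series generator settings
#'
#' Weak density dependence `betaD = -0.38` (half the carrying capacity
#' recovers to 13/20 of it in one year), carrying capacities spread over
#' roughly 13-35 males per lek, and process error shrinking with the number
#' of leks surveyed.
#'
#' @param n_groups,n_years Dimensions.
#' @param k_range Carrying-capacity range (males per lek), spread
#'   log-uniformly over the groups.
#' @param betaD Typical density dependence, in (-2, 0).
#' @param betaA,betaP Standardized fixed effects on the density change.
#' @param betaN,betaL Process-error log-SD intercept and log-leks slope.
#' @param sigmaG,sigmaY Random-effect SDs.
#' @param leks_per_group Integer range of leks counted per group-year.
#' @param seed Integer seed.
#' @return Named list.
#' @export
pop_sim_params <- function(n_groups = 8, n_years = 32, k_range = c(13, 35),
                           betaD = -0.38, betaA = -0.03, betaP = 0.08,
                           betaN = log(0.15), betaL = -0.1,
                           sigmaG = 0.05, sigmaY = 0.1,
                           leks_per_group = c(10, 60), area_lag = 1L,
                           pdo_lag = 1L, seed = 1) {
  stopifnot(betaD > -2, betaD < 0, sigmaG >= 0, sigmaY >= 0)
  list(n_groups = n_groups, n_years = n_years, k_range = k_range,
       betaD = betaD, betaA = betaA, betaP = betaP, betaN = betaN,
       betaL = betaL, sigmaG = sigmaG, sigmaY = sigmaY,
       leks_per_group = leks_per_group, area_lag = area_lag,
       pdo_lag = pdo_lag, seed = seed)
}

#' Simulate group density series from the Gompertz model
#'
#' Iterates the density map forward with process noise whose SD depends on
#' the number of leks surveyed. The intercept is set from the typical
#' carrying capacity `K` as `beta0 = -betaD * log(K)`; group-to-group spread
#' in `K` comes from the group effect on the density-dependence slope.
#' Covariates are standardized over the simulated group-years. With
#' `noise = FALSE` the deterministic map is iterated (used by convergence
#' tests).
#'
#' @param params [pop_sim_params()] list.
#' @param disturbance Group-level disturbance (columns `group_id`, `year`,
#'   `proportion`) or `NULL` for none.
#' @param pdo Annual index or `NULL` for none.
#' @param noise Draw process error (default `TRUE`).
#' @return List: `densities` (group_id, year, density, n_leks), `truth`.
#' @export
simulate_population_series <- function(params, disturbance = NULL,
                                       pdo = NULL, noise = TRUE) {
  set.seed(params$seed + 2L)
  ng <- params$n_groups
  gids <- sprintf("G%d", seq_len(ng))
  # K typical at the geometric mid of k_range; group spread via alphaG
  k_typ <- exp(mean(log(params$k_range)))
  beta0 <- -params$betaD * log(k_typ)
  k_g <- exp(seq(log(params$k_range[1]), log(params$k_range[2]),
                 length.out = ng))
  # alphaG chosen so each group's no-covariate fixed point is k_g:
  # -beta0/(betaD + aG) = log(k_g)  =>  aG = -beta0/log(k_g) - betaD
  alphaG <- -beta0 / log(k_g) - params$betaD
  if (params$sigmaG > 0) alphaG <- alphaG + stats::rnorm(ng, 0, params$sigmaG)

  years <- seq_len(params$n_years)
  year_labels <- if (!is.null(pdo)) {
    (max(pdo$year) - params$n_years + 1):max(pdo$year)
  } else 1984 + years
  alphaY <- if (params$sigmaY > 0 && noise) {
    stats::rnorm(params$n_years, 0, params$sigmaY)
  } else numeric(params$n_years)

  cov_for <- function(g, y_lab) {
    a_raw <- 0; p_raw <- 0
    if (!is.null(disturbance)) {
      hit <- disturbance$group_id == g &
        disturbance$year == y_lab - params$area_lag
      if (any(hit)) a_raw <- disturbance$proportion[hit][1]
    }
    if (!is.null(pdo)) {
      hit <- pdo$year == y_lab - params$pdo_lag
      if (any(hit)) p_raw <- pdo$value[hit][1]
    }
    c(a_raw, p_raw)
  }
  raw <- array(0, c(ng, params$n_years, 2))
  for (g in seq_len(ng)) {
    for (t in years) raw[g, t, ] <- cov_for(gids[g], year_labels[t])
  }
  std <- raw
  for (j in 1:2) {
    vals <- as.vector(raw[, , j])
    s <- stats::sd(vals)
    std[, , j] <- if (is.finite(s) && s > 0) (raw[, , j] - mean(vals)) / s
    else 0
  }

  nl <- matrix(sample(params$leks_per_group[1]:params$leks_per_group[2],
                      ng * params$n_years, replace = TRUE),
               ng, params$n_years)
  dens <- matrix(NA_real_, ng, params$n_years)
  dens[, 1] <- k_g * exp(stats::rnorm(ng, 0, if (noise) 0.2 else 0))
  for (t in 2:params$n_years) {
    lmu <- beta0 + (params$betaD + 1 + alphaG) * log(dens[, t - 1]) +
      params$betaA * std[, t, 1] + params$betaP * std[, t, 2] + alphaY[t]
    sd_eta <- exp(params$betaN + params$betaL * log(nl[, t]))
    dens[, t] <- exp(lmu + if (noise) stats::rnorm(ng, 0, sd_eta) else 0)
  }
  densities <- data.frame(
    group_id = rep(gids, params$n_years),
    year = rep(year_labels, each = ng),
    density = as.vector(dens), n_leks = as.vector(nl),
    stringsAsFactors = FALSE)
  densities <- densities[order(densities$group_id, densities$year), ]
  rownames(densities) <- NULL
  list(densities = densities,
       truth = list(params = params, beta0 = beta0, alphaG = alphaG,
                    alphaY = alphaY, k_g = k_g))
}

#' Write a complete synthetic toy study in the raw input formats
#'
#' Builds a spatial world -- working groups on a coarse grid, leks scattered
#' within each group, well pads arriving in bursts around a right-skewed
#' subset of leks -- and generates counts from a two-layer model: each
#' group's no-disturbance baseline density follows the Gompertz map (typical
#' density dependence -0.38, carrying capacities spread over ~13-35 males
#' per lek, climate effect on the change), and each lek's expected count
#' scatters around the baseline with a lognormal lek effect and a raw-scale
#' disturbance effect calibrated so that 3% areal disturbance at 3.2 km
#' (lag 1) halves the expected count. Repeat visits within the spring
#' window are drawn per lek-year, so the filtering and collapsing rules are
#' exercised. Identical seeds give identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param n_groups,leks_per_group,n_years Study dimensions (defaults 8, 40,
#'   32).
#' @param pads_per_lek Mean per-lek pad budget (gamma-distributed across
#'   leks, shape 0.4: most leks stay near zero while heavily developed ones
#'   reach buffer disturbances of 10-20% at 3.2 km, the range seen around
#'   intensively drilled leks).
#' @param start_year First response year, default 1985.
#' @return Invisibly, the manifest list (true parameters, seed, paths);
#'   also written to `manifest.json` in `dir`.
#' @export
make_fixture <- function(seed, dir, n_groups = 8, leks_per_group = 40,
                         n_years = 32, pads_per_lek = 80, start_year = 1985) {
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  years <- start_year:(start_year + n_years - 1)
  lead <- (start_year - 4):(start_year - 1)

  # --- spatial world -------------------------------------------------------
  gids <- sprintf("G%d", seq_len(n_groups))
  gx <- ((seq_len(n_groups) - 1) %% 4) * 2e5
  gy <- ((seq_len(n_groups) - 1) %/% 4) * 2e5
  n_leks <- n_groups * leks_per_group
  lek_group <- rep(gids, each = leks_per_group)
  ang <- stats::runif(n_leks, 0, 2 * pi)
  rad <- 3e4 * sqrt(stats::runif(n_leks))
  sites <- data.frame(lek_id = sprintf("L%04d", seq_len(n_leks)),
                      group_id = lek_group,
                      x_m = gx[match(lek_group, gids)] + rad * cos(ang),
                      y_m = gy[match(lek_group, gids)] + rad * sin(ang),
                      stringsAsFactors = FALSE)

  # right-skewed development: gamma budgets, most leks near zero
  budget <- stats::rgamma(n_leks, shape = 0.4, scale = pads_per_lek / 0.4)
  pads <- list()
  pid <- 0L
  for (i in seq_len(n_leks)) {
    np <- stats::rpois(1, budget[i])
    if (np == 0) next
    start_b <- sample(years[1:(n_years - 4)], 1)
    burst_years <- sort(sample(start_b:min(max(years), start_b + 6),
                               min(np, 3), replace = TRUE))
    yr <- sample(burst_years, np, replace = TRUE)
    aa <- stats::runif(np, 0, 2 * pi)
    rr <- 3000 * sqrt(stats::runif(np))
    pads[[length(pads) + 1L]] <- data.frame(
      pad_id = sprintf("P%05d", pid + seq_len(np)),
      x_m = sites$x_m[i] + rr * cos(aa),
      y_m = sites$y_m[i] + rr * sin(aa),
      spud_year = yr, stringsAsFactors = FALSE)
    pid <- pid + np
  }
  pads <- if (length(pads)) do.call(rbind, pads) else
    data.frame(pad_id = character(0), x_m = numeric(0), y_m = numeric(0),
               spud_year = integer(0))

  # --- climate index -------------------------------------------------------
  all_years <- c(lead, years)
  rho <- 0.5; psd <- 0.8
  v <- numeric(length(all_years))
  v[1] <- stats::rnorm(1, 0, psd)
  for (t in 2:length(v)) v[t] <- rho * v[t - 1] +
      stats::rnorm(1, 0, psd * sqrt(1 - rho^2))
  pdo_monthly <- data.frame(year = rep(all_years, each = 12),
                            month = rep(1:12, length(all_years)),
                            value = rep(v, each = 12) +
                              stats::rnorm(12 * length(all_years), 0, 0.4))
  pdo_annual <- data.frame(year = all_years, value = v)

  # --- true disturbance covariate (3.2 km, computed from the pads) --------
  dist32 <- disturbance_series(sites, pads, 3200, all_years)

  # --- group Gompertz baselines -------------------------------------------
  betaD <- -0.38
  k_g <- exp(seq(log(13), log(35), length.out = n_groups))
  k_typ <- exp(mean(log(k_g)))
  beta0 <- -betaD * log(k_typ)
  alphaG <- -beta0 / log(k_g) - betaD
  betaP_pop <- 0.08
  pdo_sd_obs <- stats::sd(v)
  sigma_eta <- 0.12
  B <- matrix(NA_real_, n_groups, n_years)
  B[, 1] <- k_g
  for (t in 2:n_years) {
    pstd <- (v[match(years[t] - 1, all_years)] - mean(v)) / pdo_sd_obs
    lmu <- beta0 + (betaD + 1 + alphaG) * log(B[, t - 1]) + betaP_pop * pstd
    B[, t] <- exp(lmu + stats::rnorm(n_groups, 0, sigma_eta))
  }

  # --- lek counts with repeat visits --------------------------------------
  betaA_raw <- log(0.5) / 0.03   # 3% disturbance halves the expected count
  sigmaL <- 0.55
  sigmaY <- 0.15   # region-wide annual shocks beyond the climate index
  phi <- 0.25
  alphaL <- stats::rnorm(n_leks, 0, sigmaL) - sigmaL^2 / 2
  alphaY <- stats::rnorm(n_years, 0, sigmaY)
  window_days <- seq(as.Date("2000-04-01"), as.Date("2000-05-07"), by = 1)
  md <- format(window_days, "%m-%d")
  recs <- vector("list", n_leks)
  dmap <- dist32
  for (i in seq_len(n_leks)) {
    g <- match(lek_group[i], gids)
    di <- dmap[dmap$lek_id == sites$lek_id[i], ]
    a_by_year <- di$proportion[match(years - 1, di$year)]  # lag 1
    mu <- B[g, ] * exp(alphaL[i] + alphaY + betaA_raw * a_by_year)
    # survey coverage varies: not every lek is counted every year, so the
    # number of leks behind each group density fluctuates (process-error
    # model needs log LEKS to vary)
    surveyed <- stats::runif(n_years) < 0.8
    if (!any(surveyed)) surveyed[sample(n_years, 1)] <- TRUE
    nv <- ifelse(surveyed, sample(1:3, n_years, replace = TRUE), 0L)
    total <- sum(nv)
    yrep <- rep(years, nv)
    murep <- rep(mu, nv)
    cnt <- rnb_mu_phi(total, murep, phi)
    recs[[i]] <- data.frame(
      lek_id = sites$lek_id[i], group_id = lek_group[i],
      date = paste0(yrep, "-", sample(md, total, replace = TRUE)),
      n_males = cnt, n_unknown = 0L,
      is_ground = TRUE, is_checked = TRUE, in_survey = TRUE,
      stringsAsFactors = FALSE)
  }
  lek_counts <- do.call(rbind, recs)

  wr <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  wr(lek_counts, "lek_counts.csv")
  wr(sites, "lek_sites.csv")
  wr(pads, "well_pads.csv")
  wr(pdo_monthly, "pdo_monthly.csv")
  manifest <- list(seed = seed, n_groups = n_groups,
                   leks_per_group = leks_per_group, n_years = n_years,
                   start_year = start_year,
                   truth = list(betaD = betaD, beta0 = beta0,
                                k_g = as.list(stats::setNames(round(k_g, 3),
                                                              gids)),
                                betaA_raw_per_proportion = betaA_raw,
                                betaP_pop = betaP_pop, sigmaL = sigmaL,
                                sigmaY = sigmaY,
                                phi = phi, sigma_eta = sigma_eta,
                                true_radius_m = 3200, true_area_lag = 1,
                                true_pdo_lag = 1, pdo_rho = rho,
                                pdo_sd = psd))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
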