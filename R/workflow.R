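#' @title Configuration, orchestration and command-line interface
#' @name workflow
NULL

#' Validated run configuration
#'
#' @param input_dir Directory with the four raw CSV inputs.
#' @param output_dir Directory for all run artifacts.
#' @param radii_km Buffer radii in kilometres, default
#'   `c(0.8, 1.6, 3.2, 6.4)`.
#' @param lags Candidate covariate lags, default `1:4`.
#' @param window Spring date window (month-day), inclusive.
#' @param unknown_frac Unknown-sex threshold.
#' @param stat Collapse statistic `"mean"` or `"max"`.
#' @param start_year First admissible year.
#' @param bayes Also fit the final models by MCMC (default `TRUE`).
#' @param mcmc MCMC settings: `chains`, `iter`, `seed`.
#' @param sensitivity Run the sensitivity suite (default `TRUE`).
#' @param seed Master seed for all stochastic stages.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       radii_km = c(0.8, 1.6, 3.2, 6.4), lags = 1:4,
                       window = c("04-01", "05-07"), unknown_frac = 0.05,
                       stat = "mean", start_year = 1985, bayes = TRUE,
                       mcmc = list(chains = 3, iter = 2400), sensitivity = TRUE,
                       seed = 1) {
  if (!is.numeric(radii_km) || any(radii_km <= 0.06) || any(radii_km > 50)) {
    stop("radii_km must be kilometres in (0.06, 50]", call. = FALSE)
  }
  stopifnot(all(lags >= 1), length(window) == 2, unknown_frac > 0,
            unknown_frac <= 1, stat %in% c("mean", "max"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 radii_m = radii_km * 1000, lags = as.integer(lags),
                 window = window, unknown_frac = unknown_frac, stat = stat,
                 start_year = start_year, bayes = isTRUE(bayes),
                 mcmc = mcmc, sensitivity = isTRUE(sensitivity),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(log, name, t0) {
  entry <- list(stage = name, seconds = round(as.numeric(Sys.time()) - t0, 2))
  message(sprintf("[%s] %.1fs", name, entry$seconds))
  c(log, list(entry))
}

#' Run the full two-scale analysis pipeline
#'
#' prepare -> local scale/lag scan -> final local model (reduced family,
#' effect sizes, observation-scale R2, optional MCMC) -> population lag scan
#' at the selected scale -> final population model -> carrying capacities ->
#' impacts on both bases -> sensitivity suite. Every table is written to
#' `output_dir` together with the verbatim config, the filter report and
#' per-stage timings; a failure preserves partial outputs and writes
#' `error.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(out, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  wc <- function(x, f) utils::write.csv(x, file.path(out, f),
                                        row.names = FALSE)
  wj(unclass(config), "config.json")
  log <- list()
  res <- tryCatch({
    set.seed(config$seed)
    t0 <- as.numeric(Sys.time())
    inputs <- read_inputs(config$input_dir)
    prep <- prepare_data(inputs, radii_m = config$radii_m,
                         stat = config$stat, min_year = config$start_year,
                         max_lag = max(config$lags), window = config$window,
                         unknown_frac = config$unknown_frac)
    wc(prep$lek_years, "lek_years.csv")
    wc(prep$disturbance, "disturbance.csv")
    wc(prep$group_density, "group_density.csv")
    wj(as.list(prep$filter_report), "filter_report.json")
    log <- stage_log(log, "prepare", t0)

    t0 <- as.numeric(Sys.time())
    scan_l <- scan_models(prep$lek_years, prep$disturbance, prep$pdo,
                          radii_m = config$radii_m, lags = config$lags)
    wc(as.data.frame(scan_l), "scan_local.csv")
    for (dim in c("radius_m", "area_lag", "pdo_lag")) {
      wc(variable_importance(scan_l, dim),
         paste0("importance_local_", dim, ".csv"))
    }
    top <- scan_l[1, ]
    log <- stage_log(log, "scan_local", t0)

    t0 <- as.numeric(Sys.time())
    des_l <- build_design(prep$lek_years, prep$disturbance, prep$pdo,
                          top$radius_m, top$area_lag, top$pdo_lag)
    fam_l <- fit_reduced_family(des_l, "local")
    pw_l <- predictor_weights(fam_l)
    avg_l <- model_average(fam_l)
    es_l <- fit_effect_sizes(fam_l$both)
    r2_l <- r2_observational(fam_l$both, des_l)
    wc(avg_l, "effects_local_averaged.csv")
    wc(es_l, "effects_local_full_ml.csv")
    wj(list(spec = as.list(top[c("radius_m", "area_lag", "pdo_lag")]),
            predictor_weights = as.list(pw_l),
            r2 = as.list(r2_l)), "local_summary.json")
    fit_l_b <- NULL
    if (config$bayes) {
      mc <- config$mcmc; mc$seed <- config$seed
      fit_l_b <- fit_local(des_l, engine = "bayes", mcmc = mc)
      wc(as.data.frame(fit_l_b$draws), "draws_local.csv")
      wc(fit_effect_sizes(fit_l_b), "effects_local_full_bayes.csv")
    }
    log <- stage_log(log, "fit_local_final", t0)

    t0 <- as.numeric(Sys.time())
    scan_p <- scan_models(prep$group_density, prep$group_disturbance,
                          prep$pdo, radii_m = top$radius_m,
                          lags = config$lags)
    wc(as.data.frame(scan_p), "scan_population.csv")
    for (dim in c("area_lag", "pdo_lag")) {
      wc(variable_importance(scan_p, dim),
         paste0("importance_population_", dim, ".csv"))
    }
    topp <- scan_p[1, ]
    log <- stage_log(log, "scan_population", t0)

    t0 <- as.numeric(Sys.time())
    des_p <- build_design(prep$group_density, prep$group_disturbance,
                          prep$pdo, top$radius_m, topp$area_lag,
                          topp$pdo_lag)
    fam_p <- fit_reduced_family(des_p, "population")
    wc(model_average(fam_p), "effects_population_averaged.csv")
    wc(fit_effect_sizes(fam_p$both), "effects_population_full_ml.csv")
    wj(list(spec = as.list(topp[c("radius_m", "area_lag", "pdo_lag")]),
            predictor_weights = as.list(predictor_weights(fam_p))),
       "population_summary.json")
    fit_p <- fam_p$both
    fit_p_b <- NULL
    if (config$bayes) {
      mc <- config$mcmc; mc$seed <- config$seed + 1L
      fit_p_b <- fit_population(des_p, engine = "bayes", mcmc = mc)
      wc(as.data.frame(fit_p_b$draws), "draws_population.csv")
      wc(fit_effect_sizes(fit_p_b), "effects_population_full_bayes.csv")
    }
    gids <- sort(unique(des_p$group_id))
    kc <- do.call(rbind, lapply(c("typical", gids), function(g) {
      k <- carrying_capacity(if (config$bayes) fit_p_b else fit_p,
                             group_id = if (g == "typical") NULL else g)
      data.frame(group_id = g, carrying_capacity = k$value,
                 lower = k$lower, upper = k$upper)
    }))
    wc(kc, "carrying_capacity.csv")
    log <- stage_log(log, "fit_population_final", t0)

    t0 <- as.numeric(Sys.time())
    final_year <- max(prep$lek_years$year)
    dist_top <- prep$disturbance[prep$disturbance$radius_m == top$radius_m &
                                   prep$disturbance$year == final_year, ]
    lfit <- if (config$bayes) fit_l_b else fam_l$both
    pfit <- if (config$bayes) fit_p_b else fit_p
    imp <- do.call(rbind, lapply(gids, function(g) {
      dg <- dist_top[dist_top$group_id == g, ]
      la <- stats::setNames(dg$proportion, dg$lek_id)
      i1 <- local_population_impact(lfit, la)
      i2 <- carrying_capacity_impact(pfit, mean(dg$proportion),
                                     group_id = g)
      data.frame(group_id = g, basis = c("local_sum", "carrying_capacity"),
                 percent = c(i1$percent, i2$percent),
                 lower = c(i1$lower, i2$lower),
                 upper = c(i1$upper, i2$upper),
                 year = final_year, radius_m = top$radius_m)
    }))
    wc(imp, "impacts.csv")
    log <- stage_log(log, "impacts", t0)

    if (config$sensitivity) {
      t0 <- as.numeric(Sys.time())
      sens <- sensitivity_suite(inputs, top$radius_m, topp$area_lag,
                                topp$pdo_lag)
      wc(sens, "sensitivity.csv")
      log <- stage_log(log, "sensitivity", t0)
    }
    wj(log, "timings.json")
    TRUE
  }, error = function(e) {
    wj(list(error = conditionMessage(e),
            stages_completed = vapply(log, `[[`, "", "stage")),
       "error.json")
    stop(e)
  })
  invisible(out)
}

#' Command-line entry point
#'
#' Verbs: `simulate --seed S --dir D [--groups G --leks L --years Y]`,
#' `run-all --config C.json`, `prepare --config C.json`. The config file is
#' JSON with the [run_config()] fields (`input_dir`, `output_dir`,
#' optionally `radii_km`, `lags`, `stat`, `start_year`, `bayes`, `seed`,
#' `mcmc`).
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly `NULL`; called for its side effects.
#' @export
lekdyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: lekdyn <simulate|prepare|run-all> [--seed S --dir D | --config C.json]"
  if (length(args) < 1) stop(usage, call. = FALSE)
  verb <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (verb == "simulate") {
    seed <- as.integer(opt("seed", "1"))
    dir <- opt("dir")
    if (is.null(dir)) stop("simulate requires --dir", call. = FALSE)
    make_fixture(seed, dir,
                 n_groups = as.integer(opt("groups", "8")),
                 leks_per_group = as.integer(opt("leks", "40")),
                 n_years = as.integer(opt("years", "32")))
    message("fixture written to ", dir)
  } else if (verb %in% c("prepare", "run-all")) {
    cf <- opt("config")
    if (is.null(cf)) stop(verb, " requires --config", call. = FALSE)
    raw <- jsonlite::read_json(cf, simplifyVector = TRUE)
    allowed <- setdiff(names(formals(run_config)), c("input_dir", "output_dir"))
    extra <- raw[intersect(names(raw), allowed)]
    config <- do.call(run_config, c(list(input_dir = raw$input_dir,
                                         output_dir = raw$output_dir), extra))
    if (verb == "prepare") {
      inputs <- read_inputs(config$input_dir)
      prep <- prepare_data(inputs, radii_m = config$radii_m,
                           stat = config$stat, min_year = config$start_year,
                           window = config$window,
                           unknown_frac = config$unknown_frac)
      if (!dir.exists(config$output_dir)) dir.create(config$output_dir, TRUE)
      utils::write.csv(prep$lek_years,
                       file.path(config$output_dir, "lek_years.csv"),
                       row.names = FALSE)
      utils::write.csv(prep$group_density,
                       file.path(config$output_dir, "group_density.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(prep$filter_report),
                           file.path(config$output_dir, "filter_report.json"),
                           auto_unbox = TRUE)
    } else {
      run_pipeline(config)
    }
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(NULL)
}
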