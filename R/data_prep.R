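#' @title Data preparation: from raw records to model-ready design tables
#' @description Ingest, filter and transform raw lek count records, well-pad
#'   locations and a monthly climate index into the tables consumed by the
#'   local (lek count) and population (group density) models.
#' @name data_prep
NULL

#' Filter raw lek count records to the reliable peak-season subset
#'
#' Keeps only ground counts from checked leks that were part of a survey,
#' recorded in 1985 or later within a spring date window, and whose number of
#' unknown-sex birds is below a fraction of the male count (records with zero
#' males and zero unknowns are retained). Rules are applied sequentially and
#' drops are counted per rule.
#'
#' @param records Data frame with columns `lek_id`, `group_id`, `date`
#'   (ISO-8601 string or `Date`), `n_males`, `n_unknown`, `is_ground`,
#'   `is_checked`, `in_survey`.
#' @param window Length-2 character vector of month-day bounds, inclusive;
#'   default `c("04-01", "05-07")`.
#' @param unknown_frac Threshold in (0, 1]; records with
#'   `n_unknown >= unknown_frac * n_males` are dropped. Default 0.05.
#' @param min_year First admissible calendar year. Default 1985.
#' @return List with `records` (the retained rows, with a `year` column) and
#'   `report` (named integer vector of drops per rule, plus input/output
#'   sizes).
#' @export
filter_records <- function(records, window = c("04-01", "05-07"),
                           unknown_frac = 0.05, min_year = 1985) {
  stopifnot(is.data.frame(records), length(window) == 2L,
            unknown_frac > 0, unknown_frac <= 1)
  need <- c("lek_id", "group_id", "date", "n_males", "n_unknown",
            "is_ground", "is_checked", "in_survey")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  n_in <- nrow(records)
  report <- c(malformed_date = 0L, before_min_year = 0L, unreliable_flags = 0L,
              outside_window = 0L, unknown_sex = 0L)
  if (n_in == 0L) {
    records$year <- integer(0)
    return(list(records = records,
                report = c(report, n_input = 0L, n_output = 0L)))
  }

  # explicit ISO format: as.Date's format sniffing errors outright when the
  # first element is malformed
  d <- as.Date(as.character(records$date), format = "%Y-%m-%d")
  bad <- is.na(d)
  report["malformed_date"] <- sum(bad)
  rejected <- records[bad, , drop = FALSE]
  records <- records[!bad, , drop = FALSE]
  d <- d[!bad]

  yr <- as.integer(format(d, "%Y"))
  keep <- yr >= min_year
  report["before_min_year"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]; d <- d[keep]; yr <- yr[keep]

  keep <- as.logical(records$is_ground) & as.logical(records$is_checked) &
    as.logical(records$in_survey)
  keep[is.na(keep)] <- FALSE
  report["unreliable_flags"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]; d <- d[keep]; yr <- yr[keep]

  md <- format(d, "%m-%d")
  keep <- md >= window[1] & md <= window[2]
  report["outside_window"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]; d <- d[keep]; yr <- yr[keep]

  keep <- records$n_unknown < unknown_frac * records$n_males |
    (records$n_males == 0 & records$n_unknown == 0)
  report["unknown_sex"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]; yr <- yr[keep]

  records$year <- yr
  rownames(records) <- NULL
  list(records = records,
       report = c(report, n_input = n_in, n_output = nrow(records)),
       rejected_dates = rejected)
}

#' Collapse repeated within-season counts to one count per lek-year
#'
#' @param records Filtered records (output of [filter_records()]), must carry
#'   a `year` column.
#' @param stat `"mean"` (rounded half-to-even, the default) or `"max"`.
#' @return Data frame with one row per (lek_id, year): `lek_id`, `group_id`,
#'   `year`, `count` (integer), `n_repeats`.
#' @export
collapse_counts <- function(records, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(records), "year" %in% names(records))
  if (nrow(records) == 0L) {
    return(data.frame(lek_id = character(0), group_id = character(0),
                      year = integer(0), count = integer(0),
                      n_repeats = integer(0)))
  }
  key <- interaction(records$lek_id, records$year, drop = TRUE)
  f <- if (stat == "mean") function(x) as.integer(round(mean(x))) else
    function(x) as.integer(max(x))
  counts <- tapply(records$n_males, key, f)
  reps <- tapply(records$n_males, key, length)
  first <- !duplicated(key)
  out <- data.frame(lek_id = as.character(records$lek_id[first]),
                    group_id = as.character(records$group_id[first]),
                    year = records$year[first],
                    count = as.integer(counts[as.character(key[first])]),
                    n_repeats = as.integer(reps[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lek_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annualize a monthly climate index
#'
#' One value per calendar year, the arithmetic mean of that year's monthly
#' values. Years with fewer than 12 months are flagged incomplete.
#'
#' @param monthly Data frame with columns `year`, `month`, `value`.
#' @return Data frame `year`, `value`, `n_months`, `complete`.
#' @export
annualize_pdo <- function(monthly) {
  stopifnot(is.data.frame(monthly),
            all(c("year", "month", "value") %in% names(monthly)))
  if (anyDuplicated(monthly[c("year", "month")])) {
    stop("duplicate (year, month) entries in monthly index", call. = FALSE)
  }
  yrs <- sort(unique(monthly$year))
  val <- tapply(monthly$value, monthly$year, mean)
  n <- tapply(monthly$value, monthly$year, length)
  data.frame(year = yrs,
             value = as.numeric(val[as.character(yrs)]),
             n_months = as.integer(n[as.character(yrs)]),
             complete = as.integer(n[as.character(yrs)]) == 12L)
}

#' Proportional areal disturbance around a site
#'
#' Fraction of a circular buffer of radius `radius_m` around `(x, y)` covered
#' by well-pad discs of radius `pad_radius_m`. A pad contributes from its
#' spud year onward (no reclamation); inclusion is centre-in-circle, whole-pad
#' area is counted, overlaps are double-counted, and the result is capped
#' at 1.
#'
#' @param x,y Site coordinates in planar metres.
#' @param pads Data frame with columns `x_m`, `y_m`, `spud_year`.
#' @param radius_m Buffer radius in metres (> `pad_radius_m`).
#' @param year Calendar year(s) at which to evaluate.
#' @param pad_radius_m Pad disc radius, default 60 m.
#' @return Numeric vector of proportions, one per `year`.
#' @export
areal_disturbance <- function(x, y, pads, radius_m, year, pad_radius_m = 60) {
  stopifnot(radius_m > pad_radius_m, is.finite(x), is.finite(y))
  if (nrow(pads) == 0L) return(rep(0, length(year)))
  d2 <- (pads$x_m - x)^2 + (pads$y_m - y)^2
  inr <- d2 <= radius_m^2
  if (!any(inr)) return(rep(0, length(year)))
  spud <- pads$spud_year[inr]
  counts <- vapply(year, function(yy) sum(spud <= yy), integer(1))
  pmin(1, counts * (pad_radius_m / radius_m)^2)
}

#' Annual disturbance series for every lek and every buffer radius
#'
#' @param sites Data frame `lek_id`, `group_id`, `x_m`, `y_m` (one row per
#'   lek).
#' @param pads Data frame `pad_id`, `x_m`, `y_m`, `spud_year`.
#' @param radii_m Numeric vector of buffer radii in metres.
#' @param years Integer vector of calendar years.
#' @param pad_radius_m Pad disc radius, default 60 m.
#' @return Long data frame `lek_id`, `group_id`, `radius_m`, `year`,
#'   `proportion`.
#' @export
disturbance_series <- function(sites, pads, radii_m, years,
                               pad_radius_m = 60) {
  stopifnot(!anyDuplicated(sites$lek_id))
  out <- vector("list", nrow(sites) * length(radii_m))
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    for (r in radii_m) {
      k <- k + 1L
      p <- areal_disturbance(sites$x_m[i], sites$y_m[i], pads, r, years,
                             pad_radius_m)
      out[[k]] <- data.frame(lek_id = sites$lek_id[i],
                             group_id = sites$group_id[i],
                             radius_m = r, year = years, proportion = p,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Group-level disturbance: average across a group's leks, per year
#'
#' @param disturbance Lek-level output of [disturbance_series()].
#' @return Data frame `group_id`, `radius_m`, `year`, `proportion`.
#' @export
group_disturbance <- function(disturbance) {
  agg <- stats::aggregate(proportion ~ group_id + radius_m + year,
                          data = disturbance, FUN = mean)
  agg[order(agg$group_id, agg$radius_m, agg$year), , drop = FALSE]
}

#' Population density index: mean males per lek per working group per year
#'
#' @param lek_years Output of [collapse_counts()].
#' @return Data frame `group_id`, `year`, `density`, `n_leks`. Group-years
#'   with no counted leks are absent.
#' @export
group_density <- function(lek_years) {
  stopifnot(is.data.frame(lek_years), nrow(lek_years) >= 0)
  if (nrow(lek_years) == 0L) {
    return(data.frame(group_id = character(0), year = integer(0),
                      density = numeric(0), n_leks = integer(0)))
  }
  key <- interaction(lek_years$group_id, lek_years$year, drop = TRUE)
  dens <- tapply(lek_years$count, key, mean)
  n <- tapply(lek_years$count, key, length)
  first <- !duplicated(key)
  out <- data.frame(group_id = as.character(lek_years$group_id[first]),
                    year = lek_years$year[first],
                    density = as.numeric(dens[as.character(key[first])]),
                    n_leks = as.integer(n[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

standardize_col <- function(x, name) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("predictor `", name, "` has zero variance", call. = FALSE)
  }
  list(std = (x - m) / s, mean = m, sd = s)
}

#' Join responses to lagged, standardized covariates
#'
#' Builds the analysis table for either model. For lek-year responses the
#' row's disturbance is the lek's own buffer proportion `area_lag` years
#' earlier; for group densities it is the group mean proportion and the table
#' holds one row per observed year-to-year transition (`log_prev` is the
#' previous year's log density; gaps in a group's series break the chain).
#' Covariates are standardized (sample SD, n-1) over the final analysis rows;
#' the constants are returned so raw-scale effects are recoverable. Rows
#' lacking a lagged covariate are dropped and counted.
#'
#' @param response Either a lek-year table ([collapse_counts()]) or a group
#'   density table ([group_density()]); detected by its columns.
#' @param disturbance [disturbance_series()] output (lek responses) or
#'   [group_disturbance()] output (density responses).
#' @param pdo Annual index, [annualize_pdo()] output.
#' @param radius_m Buffer radius to select from `disturbance`.
#' @param area_lag,pdo_lag Lags in years (response year y uses covariate year
#'   y - lag).
#' @param keep_rows Optional data frame of (`lek_id`|`group_id`, `year`) keys
#'   restricting the response rows (the common-data rule for scans).
#' @return Data frame with standardized `area_std`, `pdo_std` columns and
#'   attributes `standardization` (means/SDs), `spec`, and `n_dropped`.
#' @export
build_design <- function(response, disturbance, pdo, radius_m,
                         area_lag = 1L, pdo_lag = 1L, keep_rows = NULL) {
  stopifnot(area_lag >= 1L, pdo_lag >= 1L)
  is_local <- "count" %in% names(response)
  keycol <- if (is_local) "lek_id" else "group_id"

  dd <- disturbance[disturbance$radius_m == radius_m, , drop = FALSE]
  if (nrow(dd) == 0L) stop("no disturbance rows at radius ", radius_m)

  if (is_local) {
    rows <- response
  } else {
    # transitions: consecutive years within group
    response <- response[order(response$group_id, response$year), ,
                         drop = FALSE]
    if (any(response$density < 0)) stop("negative density")
    zero <- response$density == 0
    if (any(zero)) {
      warning(sum(zero), " zero-density group-years excluded (log undefined)")
      response <- response[!zero, , drop = FALSE]
    }
    prev <- response[, c("group_id", "year", "density")]
    prev$year <- prev$year + 1L
    names(prev)[3] <- "prev_density"
    rows <- merge(response, prev, by = c("group_id", "year"))
    if (nrow(rows) == 0L) stop("no consecutive-year transitions available")
    rows$log_prev <- log(rows$prev_density)
  }

  if (!is.null(keep_rows)) {
    rows <- merge(rows, unique(keep_rows[, c(keycol, "year")]),
                  by = c(keycol, "year"))
  }

  n0 <- nrow(rows)
  a <- dd[, c(keycol, "year", "proportion")]
  a$year <- a$year + area_lag
  names(a)[3] <- "area_raw"
  rows <- merge(rows, a, by = c(keycol, "year"))
  p <- pdo[, c("year", "value")]
  p$year <- p$year + pdo_lag
  names(p)[2] <- "pdo_raw"
  rows <- merge(rows, p, by = "year")
  n_dropped <- n0 - nrow(rows)
  if (nrow(rows) == 0L) stop("no rows left after lag joins")

  sa <- standardize_col(rows$area_raw, "area")
  sp <- standardize_col(rows$pdo_raw, "pdo")
  rows$area_std <- sa$std
  rows$pdo_std <- sp$std
  rows <- rows[order(rows[[keycol]], rows$year), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "standardization") <- list(
    area = list(mean = sa$mean, sd = sa$sd),
    pdo = list(mean = sp$mean, sd = sp$sd))
  attr(rows, "spec") <- list(radius_m = radius_m, area_lag = area_lag,
                             pdo_lag = pdo_lag,
                             family = if (is_local) "local" else "population")
  attr(rows, "n_dropped") <- n_dropped
  rows
}

#' Read the four raw input files
#'
#' @param dir Directory holding `lek_counts.csv`, `lek_sites.csv`,
#'   `well_pads.csv`, `pdo_monthly.csv`.
#' @return Named list of data frames.
#' @export
read_inputs <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(lek_counts = rd("lek_counts.csv"),
       lek_sites = rd("lek_sites.csv"),
       well_pads = rd("well_pads.csv"),
       pdo_monthly = rd("pdo_monthly.csv"))
}

#' Run the full data-preparation stage
#'
#' Filters records, collapses repeats, computes lek- and group-level
#' disturbance at all configured radii, annualizes the climate index and
#' derives group densities.
#'
#' @param inputs List from [read_inputs()].
#' @param radii_m Buffer radii in metres; default `c(800, 1600, 3200, 6400)`.
#' @param stat Collapse statistic, `"mean"` or `"max"`.
#' @param min_year First admissible year (sensitivity variants use 1997 or
#'   2005).
#' @param max_lag Largest covariate lag that must be joinable; disturbance is
#'   computed back to `min(year) - max_lag`.
#' @param window,unknown_frac Passed to [filter_records()].
#' @return List: `lek_years`, `disturbance`, `group_disturbance`,
#'   `group_density`, `pdo`, `filter_report`.
#' @export
prepare_data <- function(inputs, radii_m = c(800, 1600, 3200, 6400),
                         stat = "mean", min_year = 1985, max_lag = 4L,
                         window = c("04-01", "05-07"), unknown_frac = 0.05) {
  pads <- inputs$well_pads
  pads <- pads[!is.na(pads$spud_year) & pads$spud_year >= 1900 &
                 pads$spud_year <= 2016, , drop = FALSE]
  fr <- filter_records(inputs$lek_counts, window = window,
                       unknown_frac = unknown_frac, min_year = min_year)
  ly <- collapse_counts(fr$records, stat = stat)
  if (nrow(ly) == 0L) stop("no lek-years survive filtering")
  years <- (min(ly$year) - max_lag):max(ly$year)
  sites <- inputs$lek_sites[inputs$lek_sites$lek_id %in% unique(ly$lek_id), ,
                            drop = FALSE]
  dist <- disturbance_series(sites, pads, radii_m, years)
  gd <- group_disturbance(dist)
  dens <- group_density(ly)
  pdo <- annualize_pdo(inputs$pdo_monthly)
  list(lek_years = ly, disturbance = dist, group_disturbance = gd,
       group_density = dens, pdo = pdo, filter_report = fr$report)
}
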