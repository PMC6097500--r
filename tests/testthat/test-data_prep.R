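test_that("filter_records applies every rule and accounts for each drop", {
  fr <- filter_records(toy_records())
  r <- fr$report
  # May 20 outside the window; 1984 before the period; 10% unknowns >= 5%;
  # one malformed date
  expect_equal(unname(r["outside_window"]), 1L)
  expect_equal(unname(r["before_min_year"]), 1L)
  expect_equal(unname(r["unknown_sex"]), 1L)
  expect_equal(unname(r["malformed_date"]), 1L)
  expect_equal(unname(r["n_output"]), nrow(fr$records))
  expect_equal(unname(r["n_input"]) - sum(r[1:5]), unname(r["n_output"]))
  # zero males / zero unknowns retained
  expect_true(any(fr$records$lek_id == "C" & fr$records$n_males == 0))
  # n_males=10, n_unknown=0 retained
  expect_true(any(fr$records$n_males == 10 & fr$records$n_unknown == 0))
})

test_that("filter_records is order-invariant and handles empty input", {
  rec <- toy_records()
  a <- filter_records(rec)
  b <- filter_records(rec[sample(nrow(rec)), ])
  expect_equal(a$report, b$report)
  key <- function(x) sort(paste(x$lek_id, x$date, x$n_males))
  expect_equal(key(a$records), key(b$records))
  e <- filter_records(rec[0, ])
  expect_equal(nrow(e$records), 0L)
  expect_equal(sum(e$report[1:5]), 0L)
})

test_that("collapse_counts takes the rounded mean or the maximum", {
  rec <- data.frame(lek_id = c("A", "A", "A", "B", "B"), group_id = "G1",
                    n_males = c(12L, 18L, 15L, 3L, 2L),
                    year = 1990L, stringsAsFactors = FALSE)
  m <- collapse_counts(rec, "mean")
  expect_equal(m$count[m$lek_id == "A"], 15L)
  # 2.5 rounds to 2 under half-to-even
  expect_equal(m$count[m$lek_id == "B"], 2L)
  expect_equal(m$n_repeats, c(3L, 2L))
  x <- collapse_counts(rec, "max")
  expect_equal(x$count[x$lek_id == "A"], 18L)
})

test_that("max-based collapse never falls below mean-based (upward bias)", {
  set.seed(42)
  rec <- data.frame(lek_id = sample(letters[1:8], 200, TRUE),
                    group_id = "G1",
                    year = sample(1990:1994, 200, TRUE),
                    n_males = rpois(200, 12), stringsAsFactors = FALSE)
  m <- collapse_counts(rec, "mean")
  x <- collapse_counts(rec, "max")
  expect_true(all(x$count >= m$count))
})

test_that("annualize_pdo averages months and flags incomplete years", {
  m <- data.frame(year = rep(2000:2001, each = 12), month = rep(1:12, 2),
                  value = c(rep(1.5, 12), 1:12))
  a <- annualize_pdo(m)
  expect_equal(a$value, c(1.5, 6.5))
  expect_true(all(a$complete))
  a2 <- annualize_pdo(m[-1, ])
  expect_false(a2$complete[1])
  expect_error(annualize_pdo(rbind(m, m[1, ])), "duplicate")
})

test_that("areal_disturbance follows the area-ratio geometry", {
  pads <- data.frame(x_m = 1000, y_m = 0, spud_year = 2000)
  expect_equal(areal_disturbance(0, 0, pads[0, ], 3200, 2005), 0)
  expect_equal(areal_disturbance(0, 0, pads, 3200, 2005), (60 / 3200)^2)
  # not yet constructed
  expect_equal(areal_disturbance(0, 0, pads, 3200, 1999), 0)
  # outside the buffer
  expect_equal(areal_disturbance(0, 0, pads, 800, 2005), 0)
  # capped at 1
  many <- data.frame(x_m = rep(0, 5000), y_m = 0, spud_year = 1990)
  expect_equal(areal_disturbance(0, 0, many, 800, 2000), 1)
})

test_that("disturbance is monotone in year and in radius (single pad)", {
  set.seed(7)
  pads <- data.frame(x_m = runif(30, -3000, 3000),
                     y_m = runif(30, -3000, 3000),
                     spud_year = sample(1990:2010, 30, TRUE))
  p <- areal_disturbance(0, 0, pads, 3200, 1985:2015)
  expect_true(all(diff(p) >= 0))
  # one pad in range of every radius: proportion decreases with radius
  one <- data.frame(x_m = 500, y_m = 0, spud_year = 1990)
  props <- vapply(c(800, 1600, 3200, 6400),
                  function(r) areal_disturbance(0, 0, one, r, 2000),
                  numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("group_density averages lek counts unweighted", {
  ly <- data.frame(lek_id = c("A", "B", "C", "D", "E", "F"),
                   group_id = c("G1", "G1", "G2", "G3", "G3", "G3"),
                   year = 1990L, count = c(10L, 20L, 7L, 0L, 0L, 9L),
                   n_repeats = 1L, stringsAsFactors = FALSE)
  gd <- group_density(ly)
  expect_equal(gd$density[gd$group_id == "G1"], 15)
  expect_equal(gd$n_leks[gd$group_id == "G1"], 2L)
  expect_equal(gd$density[gd$group_id == "G2"], 7)
  expect_equal(gd$density[gd$group_id == "G3"], 3)
  # no counted leks in G4 that year: absent, not zero
  expect_false("G4" %in% gd$group_id)
})

test_that("build_design standardizes over the analysis rows and lags joins", {
  ly <- data.frame(lek_id = rep(c("A", "B"), each = 3), group_id = "G1",
                   year = rep(2001:2003, 2), count = c(5L, 6L, 7L, 8L, 9L, 10L),
                   n_repeats = 1L, stringsAsFactors = FALSE)
  dist <- expand.grid(lek_id = c("A", "B"), year = 1998:2003,
                      stringsAsFactors = FALSE)
  dist$group_id <- "G1"; dist$radius_m <- 3200
  dist$proportion <- (dist$year - 1998) * 0.001 +
    ifelse(dist$lek_id == "A", 0, 0.005)
  pdo <- data.frame(year = 1998:2003, value = c(0.1, -0.4, 0.8, 0.2, -0.1, 0.5))
  des <- build_design(ly, dist, pdo, 3200, area_lag = 1, pdo_lag = 2)
  expect_equal(nrow(des), 6L)
  expect_equal(mean(des$area_std), 0, tolerance = 1e-10)
  expect_equal(sd(des$area_std), 1, tolerance = 1e-10)
  expect_equal(mean(des$pdo_std), 0, tolerance = 1e-10)
  expect_equal(sd(des$pdo_std), 1, tolerance = 1e-10)
  # response year y carries the year y-1 disturbance
  s <- attr(des, "standardization")
  raw <- des$area_std * s$area$sd + s$area$mean
  expect_equal(raw[des$lek_id == "A" & des$year == 2001],
               dist$proportion[dist$lek_id == "A" & dist$year == 2000])
  # and the year y-2 index value
  rawp <- des$pdo_std * s$pdo$sd + s$pdo$mean
  expect_equal(rawp[des$year == 2003][1], pdo$value[pdo$year == 2001])
  # constant predictor errors
  dist2 <- dist; dist2$proportion <- 0.25
  expect_error(build_design(ly, dist2, pdo, 3200, 1, 2), "area")
})

test_that("build_design on densities forms transitions and breaks gaps", {
  gd <- data.frame(group_id = c(rep("G1", 4), rep("G2", 3)),
                   year = c(2001, 2002, 2004, 2005, 2001, 2002, 2003),
                   density = c(10, 12, 11, 13, 20, 18, 22),
                   n_leks = 5L, stringsAsFactors = FALSE)
  dist <- expand.grid(group_id = c("G1", "G2"), year = 1998:2005,
                      stringsAsFactors = FALSE)
  dist$radius_m <- 3200
  dist$proportion <- dist$year * 1e-4
  pdo <- data.frame(year = 1998:2005, value = rnorm(8))
  des <- build_design(gd, dist, pdo, 3200, 1, 1)
  # G1: 2001->2002 and 2004->2005 (2002->2004 is a gap); G2: two transitions
  expect_equal(nrow(des), 4L)
  expect_equal(sort(des$year[des$group_id == "G1"]), c(2002, 2005))
  expect_equal(des$log_prev[des$group_id == "G1" & des$year == 2002],
               log(10))
})
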