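# Fully synthetic study generator: a seasonal gridded exposure field, a
# worker cohort with employment spells, and injuries drawn from the same
# conditional-logistic law the estimator assumes. Everything is a pure
# function of the configuration and seed.

# Evaluate expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Configuration of the synthetic study
#'
#' Bundles every parameter of the synthetic world. The defaults describe a
#' semi-arid mid-latitude growing region at the scale of the motivating
#' study: about 12,000 injured workers over a 13-year window, seasonal
#' employment peaking in early summer, a 1/16-degree exposure grid whose
#' within-stratum dispersion of daily maximum Humidex averages about 4.8,
#' and true effects of 1.14 / 1.15 / 1.10 for the three warm exposure
#' categories (reference `<25`) with a duration-of-employment odds ratio of
#' 0.994 per day.
#'
#' @param seed Base RNG seed; all generator operations derive their streams
#'   from it.
#' @param n_workers Number of workers in the cohort.
#' @param region Bounding box `c(lat_min, lat_max, lon_min, lon_max)` in
#'   WGS84 degrees.
#' @param grid_step Grid centroid spacing in degrees (default 1/16).
#' @param date_range Length-2 `Date` vector, study window.
#' @param exposure_field List: `annual_mean` (degC), `seasonal_amplitude`
#'   (degC), `peak_doy` (day of year of the seasonal maximum),
#'   `spatial_gradient` (degC per degree latitude), `daily_noise_sd` (degC),
#'   `rh_mean`, `rh_sd` (percent, truncated to 5-100).
#' @param true_or Named odds ratios for the `25-29`, `30-33` and `>=34`
#'   categories (reference `<25` is 1).
#' @param duration_or_per_day Odds ratio per additional day of employment.
#' @param baseline_daily_injury_odds Odds of injury on an employed reference
#'   day (`<25`, zero days employed). Must keep expected events per
#'   worker-month below 0.2 (the rare-event regime the design assumes).
#' @param employment List: `mean_spell_days`, `start_doy_mean`,
#'   `start_doy_sd` (seasonal hiring), `p_quarters_bad` (fraction of claims
#'   flagged as not employed in the qualifying quarters).
#' @param cherry_or_multiplier Multiplier on the category odds ratios for
#'   cherry-harvest workers in June-July (1 = no duty effect; used by the
#'   `cherry_like` fixture to exercise the stratified analyses).
#' @param month_weights,weekday_weights Sampling weights for
#'   [simulate_strata()]; defaults follow the seasonal (June-October-heavy)
#'   and weekday (work-week-heavy) injury profile typical of outdoor
#'   agriculture.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 20160101L,
    n_workers = 60000L,
    region = c(46.0, 47.5, -120.8, -119.3),
    grid_step = 1 / 16,
    date_range = as.Date(c("2000-01-01", "2012-12-31")),
    exposure_field = list(annual_mean = 16, seasonal_amplitude = 13,
                          peak_doy = 205, spatial_gradient = -1.5,
                          daily_noise_sd = 3.25, rh_mean = 45, rh_sd = 8),
    true_or = c("25-29" = 1.14, "30-33" = 1.15, ">=34" = 1.10),
    duration_or_per_day = 0.994,
    baseline_daily_injury_odds = 0.0026,
    employment = list(mean_spell_days = 160, start_doy_mean = 135,
                      start_doy_sd = 45, p_quarters_bad = 0.02),
    cherry_or_multiplier = 1,
    month_weights = c(4, 5, 6, 5, 5, 12, 13, 12, 19, 13, 4, 3) / 101,
    weekday_weights = c(18, 17, 16, 16, 17, 11, 5) / 100) {
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3],
            all(true_or > 0), duration_or_per_day > 0,
            baseline_daily_injury_odds > 0)
  # rare-event regime: expected events per worker-month must stay small
  if (baseline_daily_injury_odds * max(true_or) * 30.44 >= 0.2) {
    stop("baseline_daily_injury_odds too large: expected events per ",
         "worker-month must stay below 0.2")
  }
  cfg <- list(seed = as.integer(seed), n_workers = as.integer(n_workers),
              region = region, grid_step = grid_step,
              date_range = as.Date(date_range),
              exposure_field = exposure_field, true_or = true_or,
              duration_or_per_day = duration_or_per_day,
              baseline_daily_injury_odds = baseline_daily_injury_odds,
              employment = employment,
              cherry_or_multiplier = cherry_or_multiplier,
              month_weights = month_weights,
              weekday_weights = weekday_weights)
  class(cfg) <- "sim_config"
  cfg
}

# Mean field surface: seasonal sinusoid plus a latitude gradient.
.field_mean <- function(cfg, doy, lat) {
  f <- cfg$exposure_field
  phase <- f$peak_doy - 365 / 4
  f$annual_mean +
    f$seasonal_amplitude * sin(2 * pi * (doy - phase) / 365) +
    f$spatial_gradient * (lat - mean(cfg$region[1:2]))
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate the gridded daily exposure field
#'
#' Daily maximum air temperature on a regular centroid grid:
#' `tmax(cell, day) = annual_mean + seasonal_amplitude *
#' sin(2*pi*(doy - phase)/365) + spatial_gradient*(lat - lat_mid) +
#' Normal(0, daily_noise_sd)`, with mean relative humidity drawn as a
#' truncated normal per cell-day. Daily maximum Humidex is derived through
#' the same dew-point and Humidex code the analysis pipeline uses.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [exposure_grid()] covering the configured region and dates.
#' @export
simulate_exposure_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$region
  lats <- seq(r[1], r[2], by = config$grid_step)
  lons <- seq(r[3], r[4], by = config$grid_step)
  if (length(lats) < 1 || length(lons) < 1) {
    stop("degenerate region: zero area")
  }
  dates <- seq(config$date_range[1], config$date_range[2], by = "1 day")
  cells <- expand.grid(lon = lons, lat = lats)[, c("lat", "lon")]
  cells <- cells[order(cells$lat, cells$lon), ]
  cells <- data.frame(cell_id = seq_len(nrow(cells)),
                      lat = cells$lat, lon = cells$lon)
  doy <- as.POSIXlt(dates)$yday + 1L
  n_c <- nrow(cells)
  n_d <- length(dates)
  f <- config$exposure_field
  .with_seed(config$seed, {
    mu <- outer(config$exposure_field$spatial_gradient *
                  (cells$lat - mean(r[1:2])),
                .field_mean(config, doy, mean(r[1:2])), "+")
    tmax <- mu + matrix(stats::rnorm(n_c * n_d, 0, f$daily_noise_sd),
                        n_c, n_d)
    rh <- matrix(.truncnorm(n_c * n_d, f$rh_mean, f$rh_sd, 5, 100), n_c, n_d)
    tdew <- matrix(dewpoint_from_rh(as.vector(tmax), as.vector(rh)),
                   n_c, n_d)
    hmax <- matrix(humidex(as.vector(tmax), as.vector(tdew)), n_c, n_d)
    structure(list(cells = cells, dates = dates, tmax = tmax, tdew = tdew,
                   hmax = hmax, humidity = "rh"),
              class = "exposure_grid")
  })
}

# Category log-odds (length 4, reference first) from an OR mapping.
.log_or_by_cat <- function(true_or) {
  lv <- humidex_categories()
  b <- c(0, log(true_or[lv[-1]]))
  names(b) <- lv
  b
}

#' Simulate a worker cohort and its injury claims
#'
#' Each worker receives a fixed location in the region and one employment
#' spell (seasonal start date, geometric-like spell length). On every
#' employed day the worker is injured with odds
#' `baseline * OR(category of that day's hmax) * duration_or^(days employed)`
#' (times the cherry multiplier for cherry-harvest workers in June-July);
#' the first injury ends the worker's at-risk time and becomes a claim with
#' `duration_at_injury` equal to the true days employed and
#' `reported_start_date` equal to the true spell start. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param grid The exposure grid from [simulate_exposure_field()] (or any
#'   `exposure_grid` covering the region and dates).
#' @return A claims data frame in the [claims_schema()] layout.
#' @export
simulate_claims <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "exposure_grid"))
  r <- config$region
  emp <- config$employment
  .with_seed(config$seed + 1L, {
    n <- config$n_workers
    lat <- stats::runif(n, r[1], r[2])
    lon <- stats::runif(n, r[3], r[4])
    cell <- nearest_cell(lat, lon, grid)
    years <- seq(as.POSIXlt(config$date_range[1])$year,
                 as.POSIXlt(config$date_range[2])$year) + 1900L
    yr <- sample(years, n, replace = TRUE)
    doy0 <- pmin(pmax(round(stats::rnorm(n, emp$start_doy_mean,
                                         emp$start_doy_sd)), 1L), 350L)
    start <- as.Date(sprintf("%d-01-01", yr)) + (doy0 - 1L)
    start <- pmin(pmax(start, config$date_range[1]), config$date_range[2])
    len <- pmax(14L, 1L + stats::rgeom(n, 1 / emp$mean_spell_days))
    end <- pmin(start + len - 1L, config$date_range[2])
    len <- as.integer(end - start) + 1L

    start_mon <- as.POSIXlt(start)$mon + 1L
    duty <- rep("other", n)
    u <- stats::runif(n)
    duty[start_mon %in% c(5L, 6L) & u < 0.15] <- "cherry_harvest"
    duty[start_mon %in% 7:10 & u < 0.45] <- "apple_harvest"

    # expand to worker-days
    w <- rep.int(seq_len(n), len)
    day <- start[w] + (sequence(len) - 1L)
    dur <- as.integer(day - start[w])
    ci <- match(cell[w], grid$cells$cell_id)
    di <- match(as.numeric(day), as.numeric(grid$dates))
    h <- grid$hmax[cbind(ci, di)]
    if (anyNA(h)) stop("simulate_claims: grid does not cover region/dates")
    cat_i <- findInterval(h, c(25, 30, 34)) + 1L  # 1..4
    logb <- .log_or_by_cat(config$true_or)
    eta <- log(config$baseline_daily_injury_odds) + logb[cat_i] +
      log(config$duration_or_per_day) * dur
    if (config$cherry_or_multiplier != 1) {
      mon_by_date <- as.POSIXlt(grid$dates)$mon + 1L
      mon <- mon_by_date[di]
      hot <- duty[w] == "cherry_harvest" & mon %in% c(6L, 7L) & cat_i > 1L
      eta[hot] <- eta[hot] + log(config$cherry_or_multiplier)
    }
    injured <- stats::runif(length(eta)) < stats::plogis(eta)
    # first injury ends the worker's at-risk time
    inj_rows <- which(injured)
    inj_rows <- inj_rows[!duplicated(w[inj_rows])]
    nc <- length(inj_rows)
    if (nc == 0L) {
      stop("simulate_claims: no injuries generated; raise ",
           "baseline_daily_injury_odds or cohort size")
    }
    ww <- w[inj_rows]
    claims <- data.frame(
      claim_id = sprintf("W%06d", ww),
      injury_date = day[inj_rows],
      injury_time = sprintf("%02d:%02d",
                            (m <- pmin(pmax(round(stats::rnorm(nc, 660, 180)),
                                            300), 1170)) %/% 60, m %% 60),
      latitude = lat[ww],
      longitude = lon[ww],
      location_basis = sample(c("accident", "business", "healthcare"), nc,
                              replace = TRUE, prob = c(0.70, 0.16, 0.14)),
      geocode_accuracy = round(stats::rbeta(nc, 8, 1), 3),
      granularity = sample(c("full_address", "street", "intersection",
                             "city", "zip"), nc, replace = TRUE,
                           prob = c(0.57, 0.06, 0.01, 0.07, 0.29)),
      duration_at_injury = dur[inj_rows],
      reported_start_date = start[ww],
      employed_quarters_ok = stats::runif(nc) >= emp$p_quarters_bad,
      duty = duty[ww],
      time_loss_days = ifelse(stats::runif(nc) < 0.74, 0L,
                              stats::rgeom(nc, 1 / 26) + 1L),
      days_to_first_healthcare = ifelse(
        stats::runif(nc) < 0.03, NA_integer_,
        ifelse(stats::runif(nc) < 0.60, 0L, stats::rgeom(nc, 0.5) + 1L)),
      death = stats::runif(nc) < 5e-4,
      stringsAsFactors = FALSE
    )
    claims$injury_time[stats::runif(nc) < 0.05] <- NA_character_
    claims
  })
}

#' Simulate case-crossover strata directly from the conditional model
#'
#' Draws strata without instantiating a cohort: each stratum samples a
#' calendar month, weekday and latitude, takes all same-weekday days of the
#' month as its days, generates their exposures from the configured field
#' law, and selects the case day from the exact conditional probability
#' (softmax of the true log-odds). Conditioning each injury on its
#' month-by-weekday stratum makes this precisely the data-generating process
#' the estimator assumes, which is what makes it suitable for coverage, bias
#' and type-I-error studies at scale.
#'
#' @param config A [sim_config()].
#' @param n_strata Number of strata to draw.
#' @param seed RNG seed for this draw (defaults to `config$seed + 2`).
#' @return A `cc_strata`-compatible data frame (`claim_id`, `role`, `date`,
#'   `hmax`, `tmax`, `category`, `duration_days`).
#' @export
simulate_strata <- function(config, n_strata, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"), n_strata >= 1)
  f <- config$exposure_field
  r <- config$region
  dates_all <- seq(config$date_range[1], config$date_range[2], by = "1 day")
  lt <- as.POSIXlt(dates_all)
  iso_wd <- ((lt$wday + 6L) %% 7L) + 1L              # 1 = Monday
  key <- paste(lt$year + 1900L, lt$mon + 1L, iso_wd, sep = "-")
  days_by_key <- split(dates_all, key)
  years <- unique(lt$year + 1900L)

  .with_seed(seed, {
    yr <- sample(years, n_strata, replace = TRUE)
    mo <- sample.int(12L, n_strata, replace = TRUE,
                     prob = config$month_weights)
    wd <- sample.int(7L, n_strata, replace = TRUE,
                     prob = config$weekday_weights)
    lat <- stats::runif(n_strata, r[1], r[2])
    dur0 <- pmax(0L, round(stats::rlnorm(n_strata, log(61), 2)))

    skey <- paste(yr, mo, wd, sep = "-")
    sdays <- days_by_key[skey]
    sizes <- lengths(sdays)
    stopifnot(all(sizes >= 4L))
    sid <- rep.int(seq_len(n_strata), sizes)
    date <- as.Date(unlist(sdays, use.names = FALSE),
                    origin = "1970-01-01")
    doy <- as.POSIXlt(date)$yday + 1L
    nrow_t <- length(date)

    tmax <- .field_mean(config, doy, lat[sid]) +
      stats::rnorm(nrow_t, 0, f$daily_noise_sd)
    rh <- .truncnorm(nrow_t, f$rh_mean, f$rh_sd, 5, 100)
    h <- humidex(tmax, dewpoint_from_rh(tmax, rh))
    cat_i <- findInterval(h, c(25, 30, 34)) + 1L
    first_date <- rep.int(date[!duplicated(sid)], sizes)
    dur <- dur0[sid] + as.integer(date - first_date)

    logb <- .log_or_by_cat(config$true_or)
    eta <- logb[cat_i] + log(config$duration_or_per_day) * dur
    # Gumbel-max trick: argmax(eta + gumbel) ~ softmax(eta), per stratum
    g <- eta - log(-log(stats::runif(nrow_t)))
    o <- order(sid, g)
    case_rows <- o[!duplicated(sid[o], fromLast = TRUE)]
    role <- rep("referent", nrow_t)
    role[case_rows] <- "index"

    out <- data.frame(
      claim_id = sprintf("S%06d", sid),
      role = role,
      date = date,
      cell_id = NA_integer_,
      hmax = h,
      tmax = tmax,
      category = factor(humidex_categories()[cat_i],
                        levels = humidex_categories()),
      duration_days = dur,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cc_strata", "data.frame")
    out
  })
}

.fixture_configs <- function() {
  list(
    tiny = sim_config(
      seed = 101L, n_workers = 60L,
      region = c(46.5, 46.75, -120.25, -120.0),
      date_range = as.Date(c("2006-06-01", "2006-07-31")),
      baseline_daily_injury_odds = 0.005,
      employment = list(mean_spell_days = 45, start_doy_mean = 155,
                        start_doy_sd = 5, p_quarters_bad = 0)),
    null = sim_config(
      seed = 202L, n_workers = 4000L,
      region = c(46.5, 47.0, -120.5, -120.0),
      date_range = as.Date(c("2006-01-01", "2008-12-31")),
      true_or = c("25-29" = 1, "30-33" = 1, ">=34" = 1),
      duration_or_per_day = 1,
      baseline_daily_injury_odds = 0.004),
    primary_recovery = sim_config(
      seed = 303L, n_workers = 20000L,
      region = c(46.0, 47.0, -120.5, -119.5),
      date_range = as.Date(c("2004-01-01", "2009-12-31")),
      baseline_daily_injury_odds = 0.004),
    cherry_like = sim_config(
      seed = 404L, n_workers = 20000L,
      region = c(46.0, 47.0, -120.5, -119.5),
      date_range = as.Date(c("2004-01-01", "2009-12-31")),
      baseline_daily_injury_odds = 0.004,
      cherry_or_multiplier = 1.6)
  )
}

#' Write a named deterministic fixture
#'
#' Generates one of the packaged fixture datasets (`tiny`, `null`,
#' `primary_recovery`, `cherry_like`) into `dir`: a grid CSV and claims CSV
#' in the dialects the pipeline consumes, plus an `expected.json` recording
#' the seed, the true parameters and the tolerance bands the test suite
#' checks against. Regenerating a fixture from its seed is byte-identical.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the config used.
#' @export
make_fixture <- function(name, dir = tempfile("fixture_")) {
  cfgs <- .fixture_configs()
  if (!name %in% names(cfgs)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(cfgs), collapse = ", "))
  }
  cfg <- cfgs[[name]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- simulate_exposure_field(cfg)
  claims <- simulate_claims(cfg, grid)
  grid_path <- file.path(dir, paste0(name, "_grid.csv"))
  claims_path <- file.path(dir, paste0(name, "_claims.csv"))
  expected_path <- file.path(dir, paste0(name, "_expected.json"))
  write_grid_csv(grid, grid_path)
  write_claims_csv(claims, claims_path)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("make_fixture needs the jsonlite package to write expected.json")
  }
  expected <- list(
    name = name, seed = cfg$seed, n_claims = nrow(claims),
    true_or = as.list(cfg$true_or),
    duration_or_per_day = cfg$duration_or_per_day,
    cherry_or_multiplier = cfg$cherry_or_multiplier,
    tolerance = list(log_or_abs = 3, note = paste(
      "fitted log-ORs should fall within 3 standard errors of the true",
      "values; null fixtures should not reject OR = 1 at the 0.05 level",
      "in most replicates"))
  )
  jsonlite::write_json(expected, expected_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(grid = grid_path, claims = claims_path,
                 expected = expected_path, config = cfg))
}
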