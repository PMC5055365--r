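# In-code fixtures used across the suite.

# A small deterministic grid with a closed-form field (no RNG): hmax varies
# linearly with day index and latitude, so expected values are computable.
toy_grid <- function(lats = c(46.0, 46.0625, 46.125),
                     lons = c(-120.125, -120.0625, -120.0),
                     dates = seq(as.Date("2010-06-01"),
                                 as.Date("2010-07-31"), by = "1 day"),
                     tmax_fun = function(day_index, lat)
                       20 + 0.2 * day_index + 10 * (lat - 46),
                     rh = 50) {
  cells <- expand.grid(lat = lats, lon = lons)
  rows <- expand.grid(ci = seq_len(nrow(cells)), di = seq_along(dates))
  exposure_grid(data.frame(
    date = dates[rows$di],
    lat = cells$lat[rows$ci],
    lon = cells$lon[rows$ci],
    tmax_c = tmax_fun(rows$di, cells$lat[rows$ci]),
    rh_pct = rh
  ))
}

# A minimal valid claim record; override fields as needed.
toy_claim <- function(claim_id = "C1", injury_date = as.Date("2010-07-14"),
                      latitude = 46.06, longitude = -120.06,
                      duration_at_injury = 61L,
                      reported_start_date = NA, employed_quarters_ok = TRUE,
                      injury_time = "09:30", location_basis = "accident",
                      geocode_accuracy = 0.95, granularity = "full_address",
                      duty = "other", time_loss_days = 0L,
                      days_to_first_healthcare = 0L, death = FALSE) {
  data.frame(claim_id = claim_id, injury_date = as.Date(injury_date),
             injury_time = injury_time, latitude = latitude,
             longitude = longitude, location_basis = location_basis,
             geocode_accuracy = geocode_accuracy, granularity = granularity,
             duration_at_injury = duration_at_injury,
             reported_start_date = as.Date(reported_start_date),
             employed_quarters_ok = employed_quarters_ok, duty = duty,
             time_loss_days = time_loss_days,
             days_to_first_healthcare = days_to_first_healthcare,
             death = death, stringsAsFactors = FALSE)
}

toy_claims <- function(n, dates, grid, seed = 1, ...) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    toy_claim(claim_id = sprintf("C%03d", i),
              injury_date = sample(dates, 1),
              latitude = runif(1, min(grid$cells$lat), max(grid$cells$lat)),
              longitude = runif(1, min(grid$cells$lon), max(grid$cells$lon)),
              ...)
  }))
}

# 1:1 matched binary-exposure strata: n10 strata with the case exposed and
# the referent not, n01 with the reverse, n_conc concordant pairs.
binary_pairs <- function(n10, n01, n_conc = 0) {
  mk <- function(n, x_case, x_ref, tag) {
    if (n == 0) return(NULL)
    data.frame(
      stratum = rep(paste0(tag, seq_len(n)), each = 2),
      case = rep(c(TRUE, FALSE), n),
      x = rep(c(x_case, x_ref), n))
  }
  rbind(mk(n10, 1, 0, "d10_"), mk(n01, 0, 1, "d01_"),
        mk(n_conc, 1, 1, "conc_"))
}

# Random small conditional-logistic problems for oracle comparisons.
random_clogit_problem <- function(n_strata = 30, p = 2, seed = 1) {
  set.seed(seed)
  sizes <- sample(2:5, n_strata, replace = TRUE)
  sid <- rep(seq_len(n_strata), sizes)
  X <- matrix(rnorm(length(sid) * p), ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta_true <- rnorm(p, 0, 0.5)
  eta <- drop(X %*% beta_true)
  case <- logical(length(sid))
  for (s in seq_len(n_strata)) {
    rows <- which(sid == s)
    pr <- exp(eta[rows] - max(eta[rows]))
    case[sample(rows, 1, prob = pr)] <- TRUE
  }
  list(X = X, stratum = sid, case = case, beta_true = beta_true)
}
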