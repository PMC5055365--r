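# Stratum construction: employment exclusions, duration covariate, and the
# assembled case-crossover strata.

test_that("employment exclusions drop pre-start days and bad quarters", {
  days <- as.Date(c("2010-07-07", "2010-07-21", "2010-07-28"))
  cl <- toy_claim(reported_start_date = NA)
  expect_equal(apply_employment_exclusions(days, cl), days)
  cl <- toy_claim(reported_start_date = "2010-07-10")
  expect_equal(apply_employment_exclusions(days, cl), days[2:3])
  cl <- toy_claim(employed_quarters_ok = FALSE)
  expect_length(apply_employment_exclusions(days, cl), 0)
})

test_that("duration covariate shifts by the signed day gap", {
  cl <- toy_claim(injury_date = "2010-07-14", duration_at_injury = 61L)
  expect_equal(duration_covariate(cl, as.Date("2010-07-07")), 54L)
  expect_equal(duration_covariate(cl, as.Date("2010-07-21")), 68L)
  expect_equal(duration_covariate(cl, as.Date("2010-07-14")), 61L)
  # a negative duration is exactly what the start-date rule removes
  cl2 <- toy_claim(injury_date = "2010-07-14", duration_at_injury = 5L,
                   reported_start_date = "2010-07-09")
  d <- as.Date("2010-07-07")
  expect_lt(duration_covariate(cl2, d), 0)
  expect_false(d %in% apply_employment_exclusions(
    referent_days(cl2$injury_date), cl2))
})

test_that("built strata satisfy the stratum invariants", {
  g <- toy_grid()
  claims <- toy_claims(40, g$dates, g, seed = 3)
  st <- build_strata(claims, g)
  expect_s3_class(st, "cc_strata")
  for (id in unique(st$claim_id)) {
    s <- st[st$claim_id == id, ]
    idx <- s[s$role == "index", ]
    ref <- s[s$role == "referent", ]
    expect_equal(nrow(idx), 1)
    expect_true(nrow(ref) >= 1 && nrow(ref) <= 4)
    expect_false(any(duplicated(s$date)))
    expect_equal(length(unique(s$cell_id)), 1)
    expect_equal(unique(format(s$date, "%Y-%m")),
                 format(idx$date, "%Y-%m"))
    expect_equal(unique(as.POSIXlt(s$date)$wday),
                 as.POSIXlt(idx$date)$wday)
    # exposure annotations agree with direct grid lookups
    expect_equal(s$hmax, daily_max_humidex(g, s$cell_id, s$date))
    expect_equal(as.character(s$category),
                 as.character(categorize_humidex(s$hmax)))
    cl <- claims[claims$claim_id == id, ]
    expect_equal(s$duration_days, duration_covariate(cl, s$date))
  }
})

test_that("strata construction is deterministic", {
  g <- toy_grid()
  claims <- toy_claims(25, g$dates, g, seed = 5)
  expect_identical(build_strata(claims, g), build_strata(claims, g))
})

test_that("claims failing the quarter-employment rule yield no stratum", {
  g <- toy_grid()
  claims <- rbind(toy_claim("A", "2010-06-16"),
                  toy_claim("B", "2010-06-16",
                            employed_quarters_ok = FALSE))
  st <- build_strata(claims, g)
  expect_true("A" %in% st$claim_id)
  expect_false("B" %in% st$claim_id)
  expect_equal(attr(st, "counts")$dropped_quarters, 1L)
})

test_that("a start date late in the month can empty the referent set", {
  g <- toy_grid()
  # injured on the last Wednesday of June; started the Monday before
  claims <- toy_claim("L", "2010-06-30", reported_start_date = "2010-06-28")
  st <- build_strata(claims, g)
  expect_equal(nrow(st), 0)
  expect_equal(attr(st, "counts")$dropped_no_referents, 1L)
})

test_that("claims outside the grid's date span go to the rejects report", {
  g <- toy_grid()
  claims <- rbind(toy_claim("in", "2010-06-16"),
                  toy_claim("out", "2011-06-15"))
  st <- build_strata(claims, g)
  rj <- attr(st, "rejects")
  expect_equal(rj$claim_id, "out")
  expect_false("out" %in% st$claim_id)
  expect_true("in" %in% st$claim_id)
})

test_that("a constant field yields single-category strata", {
  g <- toy_grid(tmax_fun = function(di, lat) 28, rh = 50)
  claims <- toy_claims(10, g$dates, g, seed = 9)
  st <- build_strata(claims, g)
  expect_equal(length(unique(st$category)), 1)
  expect_equal(length(unique(round(st$hmax, 10))), 1)
})

test_that("strata CSV export carries the documented columns", {
  g <- toy_grid()
  st <- build_strata(toy_claims(5, g$dates, g, seed = 2), g)
  path <- tempfile(fileext = ".csv")
  write_strata_csv(st, path)
  df <- read.csv(path)
  expect_equal(names(df), c("claim_id", "role", "date", "cell_id", "hmax",
                            "category", "duration_days"))
  expect_equal(nrow(df), nrow(st))
})
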