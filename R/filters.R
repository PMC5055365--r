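# Sensitivity-analysis exclusion rules: pure predicates on claim fields.
# Each rule removes injuries (and with them their whole strata) from the
# primary analysis; filters compose and are order-independent.

.parse_minutes <- function(hhmm) {
  out <- rep(NA_real_, length(hhmm))
  ok <- !is.na(hhmm) & grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", hhmm)
  if (any(ok)) {
    parts <- strsplit(hhmm[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) 60 * as.numeric(p[1]) +
                        as.numeric(p[2]), numeric(1))
  }
  out
}

.time_window_keep <- function(claims, lo_min, hi_min) {
  m <- .parse_minutes(claims$injury_time)
  n_miss <- sum(is.na(m))
  if (n_miss > 0) {
    message(n_miss, " claim(s) with missing injury time excluded by the ",
            "time-window rule")
  }
  !is.na(m) & m >= lo_min & m <= hi_min
}

.sensitivity_predicates <- list(
  # Saturday/Sunday injuries removed
  weekends = function(claims) !.is_weekend(claims$injury_date),
  # US public holiday injuries removed
  holidays = function(claims) !is_us_public_holiday(claims$injury_date),
  # locations known only to zip-code or city granularity removed
  zip_or_city_location = function(claims)
    !claims$granularity %in% c("zip", "city"),
  # locations imputed from the first healthcare provider's address removed
  healthcare_location = function(claims)
    claims$location_basis != "healthcare",
  # poorly geocoded locations removed
  geocode_lt_080 = function(claims) claims$geocode_accuracy >= 0.80,
  # injury time outside 5:30-16:30 removed (missing times excluded too)
  time_0530_1630 = function(claims)
    .time_window_keep(claims, 5 * 60 + 30, 16 * 60 + 30),
  # injury time outside 5:30-12:30 removed
  time_0530_1230 = function(claims)
    .time_window_keep(claims, 5 * 60 + 30, 12 * 60 + 30),
  # more than seven days of compensated lost work time removed
  timeloss_gt7 = function(claims) claims$time_loss_days <= 7,
  # more than one day between injury and first healthcare visit removed
  gap_gt1day = function(claims)
    !is.na(claims$days_to_first_healthcare) &
      claims$days_to_first_healthcare <= 1,
  # fatal injuries removed
  death = function(claims) !claims$death,
  # exposure swap (maximum dry air temperature instead of Humidex);
  # not a claim filter - the pipeline refits with the tmax exposure
  dry_temp = function(claims) rep(TRUE, nrow(claims))
)

#' Names of the sensitivity-analysis rules
#'
#' @return Character vector of valid `rule_id`s for [sensitivity_filter()].
#' @export
sensitivity_rules <- function() names(.sensitivity_predicates)

#' Apply one sensitivity exclusion to a claims table
#'
#' Each rule is a pure predicate on claim fields, so rules compose and the
#' order of composition does not matter. The `dry_temp` rule removes nothing:
#' it marks an exposure swap (dry air temperature instead of Humidex) that
#' [run_sensitivity_suite()] performs at fit time.
#'
#' @param claims Claims data frame.
#' @param rule_id One of [sensitivity_rules()].
#' @return The claims surviving the exclusion.
#' @export
sensitivity_filter <- function(claims, rule_id) {
  if (length(rule_id) != 1L || !rule_id %in% names(.sensitivity_predicates)) {
    stop("unknown sensitivity rule '", paste(rule_id, collapse = ","),
         "'; valid rules: ", paste(sensitivity_rules(), collapse = ", "))
  }
  keep <- .sensitivity_predicates[[rule_id]](claims)
  claims[keep, , drop = FALSE]
}
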