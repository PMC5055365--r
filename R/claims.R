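# Claims table: one record per traumatic injury, with the fields the referent
# construction, adjustment and sensitivity exclusions need.

#' Claims table column schema
#'
#' @return Data frame describing the expected columns: name, type, and
#'   whether missing values are allowed.
#' @export
claims_schema <- function() {
  data.frame(
    column = c("claim_id", "injury_date", "injury_time", "latitude",
               "longitude", "location_basis", "geocode_accuracy",
               "granularity", "duration_at_injury", "reported_start_date",
               "employed_quarters_ok", "duty", "time_loss_days",
               "days_to_first_healthcare", "death"),
    type = c("character", "date", "time", "numeric", "numeric", "enum",
             "numeric", "enum", "integer", "date", "logical", "enum",
             "integer", "integer", "logical"),
    allow_missing = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

.location_bases <- c("accident", "business", "healthcare")
.granularities <- c("full_address", "street", "intersection", "city", "zip")
.duties <- c("cherry_harvest", "apple_harvest", "other")

#' Read a claims CSV
#'
#' Reads a claims table (ISO-8601 dates, 24-hour `HH:MM` clock times, WGS84
#' decimal degrees). `col_map` adapts externally named columns: a named
#' character vector mapping schema names to the file's column names, for
#' deposited datasets whose headers differ from the canonical schema.
#'
#' @param path File path.
#' @param col_map Optional named character vector, e.g.
#'   `c(injury_date = "INJ_DATE")`.
#' @return Data frame with canonical column names and parsed types.
#' @export
read_claims_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop("read_claims_csv: mapped column not in file: ", src)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  need <- claims_schema()$column
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("read_claims_csv: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$injury_date <- as.Date(df$injury_date)
  df$reported_start_date <- as.Date(.na_if_empty(df$reported_start_date))
  df$injury_time <- .na_if_empty(df$injury_time)
  for (col in c("latitude", "longitude", "geocode_accuracy")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("duration_at_injury", "time_loss_days",
                "days_to_first_healthcare")) {
    df[[col]] <- as.integer(.na_if_empty(df[[col]]))
  }
  for (col in c("employed_quarters_ok", "death")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

.na_if_empty <- function(x) {
  x[!nzchar(trimws(x))] <- NA_character_
  x
}

#' Write a claims table as CSV
#'
#' @param claims Claims data frame.
#' @param path Output file path.
#' @export
write_claims_csv <- function(claims, path) {
  utils::write.csv(claims, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a claims table against the schema
#'
#' Checks column presence, types, value domains (enums, geocode accuracy in
#' [0,1], non-negative durations and counts, parseable clock times) and
#' reports violations per column.
#'
#' @param claims Claims data frame.
#' @param study_window Optional `Date` vector of length 2; injury dates must
#'   fall inside it.
#' @return Invisibly, a data frame of violations (column, n_bad, message);
#'   zero rows means the table is valid. Printed as a summary.
#' @export
validate_claims <- function(claims, study_window = NULL) {
  v <- list()
  note <- function(column, bad, message) {
    n <- sum(bad, na.rm = TRUE)
    if (n > 0) v[[length(v) + 1L]] <<- data.frame(
      column = column, n_bad = n, message = message)
  }
  missing_cols <- setdiff(claims_schema()$column, names(claims))
  if (length(missing_cols)) {
    stop("validate_claims: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  note("claim_id", duplicated(claims$claim_id), "duplicate claim_id")
  note("injury_date", is.na(claims$injury_date), "missing/unparseable date")
  if (!is.null(study_window)) {
    note("injury_date",
         claims$injury_date < study_window[1] |
           claims$injury_date > study_window[2],
         "injury date outside study window")
  }
  note("latitude", !is.finite(claims$latitude) |
         abs(claims$latitude) > 90, "latitude not in [-90, 90]")
  note("longitude", !is.finite(claims$longitude) |
         abs(claims$longitude) > 180, "longitude not in [-180, 180]")
  note("location_basis", !claims$location_basis %in% .location_bases,
       paste("not one of:", paste(.location_bases, collapse = ", ")))
  note("geocode_accuracy", !is.finite(claims$geocode_accuracy) |
         claims$geocode_accuracy < 0 | claims$geocode_accuracy > 1,
       "not in [0, 1]")
  note("granularity", !claims$granularity %in% .granularities,
       paste("not one of:", paste(.granularities, collapse = ", ")))
  note("duration_at_injury", is.na(claims$duration_at_injury) |
         claims$duration_at_injury < 0, "missing or negative")
  note("duty", !claims$duty %in% .duties,
       paste("not one of:", paste(.duties, collapse = ", ")))
  note("time_loss_days", is.na(claims$time_loss_days) |
         claims$time_loss_days < 0, "missing or negative")
  note("days_to_first_healthcare",
       !is.na(claims$days_to_first_healthcare) &
         claims$days_to_first_healthcare < 0, "negative")
  note("injury_time", !is.na(claims$injury_time) &
         !grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", claims$injury_time),
       "not a 24-h HH:MM time")
  note("employed_quarters_ok", is.na(claims$employed_quarters_ok),
       "missing flag")
  note("death", is.na(claims$death), "missing flag")

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(column = character(), n_bad = integer(), message = character())
  if (nrow(out) == 0) {
    message("claims table valid: ", nrow(claims), " records, no violations")
  } else {
    message("claims table has violations:")
    for (i in seq_len(nrow(out))) {
      message(sprintf("  %s: %d rows %s", out$column[i], out$n_bad[i],
                      out$message[i]))
    }
  }
  invisible(out)
}
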