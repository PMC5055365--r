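# Case-crossover stratum construction: each injury day is matched to the
# other same-weekday days of its calendar month at the same location, after
# employment-based exclusions.

#' Employment-based referent exclusions
#'
#' Drops candidate referent days the claimant could not have been at work for
#' the employer of injury: if the claimant was not employed there in the
#' quarter of and the quarter before the injury (`employed_quarters_ok`
#' false), every day is removed and the stratum becomes uninformative;
#' otherwise, days strictly before the reported employment start date are
#' removed (equivalently, days whose derived duration-of-employment covariate
#' would be negative). A missing start date removes nothing.
#'
#' @param days `Date` vector of candidate referent days.
#' @param claim A single claim: a list or one-row data frame with
#'   `employed_quarters_ok` and `reported_start_date`.
#' @return The surviving `Date` vector.
#' @export
apply_employment_exclusions <- function(days, claim) {
  if (!isTRUE(as.logical(claim$employed_quarters_ok))) {
    return(days[0])
  }
  start <- as.Date(claim$reported_start_date)
  if (length(start) == 1L && !is.na(start)) {
    days <- days[days >= start]
  }
  days
}

#' Duration-of-employment covariate for a stratum day
#'
#' The self-reported duration of employment at injury, shifted by the signed
#' day gap between the stratum day and the injury day: referent days before
#' the injury subtract the gap, days after add it. On the injury day itself
#' it equals `duration_at_injury`. May be negative for days preceding the
#' reported start of work; such days are removed by
#' [apply_employment_exclusions()].
#'
#' @param claim A single claim with `duration_at_injury` and `injury_date`.
#' @param day `Date` vector of stratum days.
#' @return Integer days of employment on each day.
#' @export
duration_covariate <- function(claim, day) {
  as.integer(claim$duration_at_injury) +
    as.integer(as.Date(day) - as.Date(claim$injury_date))
}

#' Build case-crossover strata
#'
#' For each claim: the injury location is joined to its nearest grid cell,
#' referent days are selected time-stratified (same weekday, same month) and
#' filtered by the employment exclusions, and every retained day is annotated
#' with that cell's daily maximum Humidex, dry air temperature, exposure
#' category and duration-of-employment covariate.
#'
#' Claims whose injury day has no exposure (outside the grid's span) are
#' recorded in a rejects report rather than raising an error; referent days
#' with missing exposure are dropped from their stratum with a logged count;
#' strata left with zero referents are dropped and counted.
#'
#' @param claims Claims data frame (see [claims_schema()]).
#' @param grid An [exposure_grid()].
#' @return An object of class `cc_strata`: a data frame with one row per
#'   stratum day (`claim_id, role, date, cell_id, hmax, tmax, category,
#'   duration_days`) and attributes `counts` (claims in/dropped at each
#'   stage, referent days excluded by the start-date rule) and `rejects`.
#' @export
build_strata <- function(claims, grid) {
  stopifnot(inherits(grid, "exposure_grid"))
  n_in <- nrow(claims)
  counts <- list(claims_in = n_in, dropped_quarters = 0L,
                 days_excluded_start = 0L, candidate_referent_days = 0L,
                 days_missing_exposure = 0L, dropped_no_referents = 0L,
                 rejected_no_index_exposure = 0L)
  rejects <- list()

  keep <- as.logical(claims$employed_quarters_ok)
  counts$dropped_quarters <- sum(!keep)
  claims <- claims[keep, , drop = FALSE]
  if (nrow(claims) == 0L) {
    return(.empty_strata(counts, rejects))
  }

  n <- nrow(claims)
  cell <- nearest_cell(claims$latitude, claims$longitude, grid)

  # referent sets depend only on the injury date; compute once per unique date
  udates <- unique(claims$injury_date)
  ref_by_date <- lapply(udates, referent_days)
  ref_idx <- match(as.numeric(claims$injury_date), as.numeric(udates))

  # expand to one row per claim-referent-day and apply the start-date rule
  nref <- lengths(ref_by_date)[ref_idx]
  counts$candidate_referent_days <- sum(nref)
  rci <- rep.int(seq_len(n), nref)               # claim index per referent row
  rdate <- as.Date(unlist(ref_by_date[ref_idx], use.names = FALSE),
                   origin = "1970-01-01")
  start <- claims$reported_start_date[rci]
  keep_ref <- is.na(start) | rdate >= start
  counts$days_excluded_start <- sum(!keep_ref)
  rci <- rci[keep_ref]
  rdate <- rdate[keep_ref]

  # one table of all stratum days, index rows first within each claim
  ci_all <- c(seq_len(n), rci)
  day_all <- c(claims$injury_date, rdate)
  role_all <- rep(c("index", "referent"), c(n, length(rci)))
  o <- order(ci_all, role_all != "index", day_all)
  ci_all <- ci_all[o]; day_all <- day_all[o]; role_all <- role_all[o]

  h <- .grid_try_lookup(grid, cell[ci_all], day_all, "hmax")

  # claims whose injury day has no exposure go to the rejects report
  idx_rows <- role_all == "index"
  bad_claim <- ci_all[idx_rows][is.na(h[idx_rows])]
  counts$rejected_no_index_exposure <- length(bad_claim)
  if (length(bad_claim)) {
    rejects[[1L]] <- data.frame(
      claim_id = claims$claim_id[bad_claim],
      date = claims$injury_date[bad_claim],
      reason = "no exposure for injury day")
  }
  drop_row <- ci_all %in% bad_claim
  # referent days with missing exposure are dropped from their stratum
  miss_ref <- is.na(h) & !drop_row
  counts$days_missing_exposure <- sum(miss_ref)
  if (counts$days_missing_exposure > 0L) {
    warning(counts$days_missing_exposure,
            " referent day(s) dropped for missing exposure")
  }
  keep <- !drop_row & !miss_ref
  ci_all <- ci_all[keep]; day_all <- day_all[keep]
  role_all <- role_all[keep]; h <- h[keep]

  # strata left with zero referents carry no likelihood information
  n_ref_by_claim <- tabulate(ci_all[role_all == "referent"], n)
  n_any_by_claim <- tabulate(ci_all, n)
  empty <- n_any_by_claim > 0L & n_ref_by_claim == 0L
  counts$dropped_no_referents <- sum(empty)
  keep <- !empty[ci_all]
  ci_all <- ci_all[keep]; day_all <- day_all[keep]
  role_all <- role_all[keep]; h <- h[keep]

  if (length(ci_all) == 0L) return(.empty_strata(counts, rejects))
  out <- data.frame(
    claim_id = claims$claim_id[ci_all],
    role = role_all,
    date = day_all,
    cell_id = cell[ci_all],
    hmax = h,
    tmax = .grid_try_lookup(grid, cell[ci_all], day_all, "tmax"),
    category = categorize_humidex(h),
    duration_days = claims$duration_at_injury[ci_all] +
      as.integer(day_all - claims$injury_date[ci_all]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  .as_cc_strata(out, counts, rejects)
}

.grid_try_lookup <- function(grid, cell_id, date, what) {
  date <- as.Date(date)
  ci <- match(cell_id, grid$cells$cell_id)
  di <- match(as.numeric(date), as.numeric(grid$dates))
  v <- rep(NA_real_, length(ci))
  ok <- !is.na(ci) & !is.na(di)
  v[ok] <- grid[[what]][cbind(ci[ok], di[ok])]
  v
}

.as_cc_strata <- function(df, counts, rejects) {
  attr(df, "counts") <- counts
  attr(df, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(claim_id = character(), date = as.Date(character()),
               reason = character())
  class(df) <- c("cc_strata", "data.frame")
  df
}

.empty_strata <- function(counts, rejects) {
  df <- data.frame(
    claim_id = character(), role = character(), date = as.Date(character()),
    cell_id = integer(), hmax = numeric(), tmax = numeric(),
    category = factor(character(), levels = humidex_categories()),
    duration_days = integer())
  .as_cc_strata(df, counts, rejects)
}

#' Number of strata and referent-day summary
#' @param x A `cc_strata` object.
#' @param ... Unused.
#' @export
print.cc_strata <- function(x, ...) {
  n_strata <- length(unique(x$claim_id))
  n_ref <- sum(x$role == "referent")
  counts <- attr(x, "counts")
  cat("Case-crossover strata:", n_strata, "strata,", nrow(x), "days\n")
  if (n_strata > 0) {
    cat(sprintf("  mean referent days per stratum: %.2f\n", n_ref / n_strata))
  }
  if (!is.null(counts)) {
    cat("  claims in:", counts$claims_in,
        "| dropped (quarter employment):", counts$dropped_quarters,
        "| dropped (no referents):", counts$dropped_no_referents,
        "| rejected (no exposure):", counts$rejected_no_index_exposure, "\n")
    if (counts$candidate_referent_days > 0) {
      cat(sprintf("  referent days excluded by start-date rule: %d (%.1f%%)\n",
                  counts$days_excluded_start,
                  100 * counts$days_excluded_start /
                    counts$candidate_referent_days))
    }
  }
  invisible(x)
}

#' Write strata as CSV
#'
#' One row per stratum day:
#' `claim_id,role,date,cell_id,hmax,category,duration_days`.
#'
#' @param strata A `cc_strata` object.
#' @param path Output file path.
#' @export
write_strata_csv <- function(strata, path) {
  df <- as.data.frame(strata)[c("claim_id", "role", "date", "cell_id",
                                "hmax", "category", "duration_days")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
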