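# End-to-end analysis suite: primary model, secondary panels, the
# sensitivity-exclusion suite, and descriptive exposure summaries.

# One results table in the layout of a published OR table: one row per model
# term with day counts and unadjusted/adjusted ORs side by side.
.fit_table <- function(analysis, fit_unadj, fit_adj) {
  stopifnot(identical(names(fit_unadj$beta)[seq_along(fit_unadj$beta)],
                      names(fit_adj$beta)[seq_along(fit_unadj$beta)]))
  terms <- names(fit_unadj$beta)
  nd <- fit_unadj$n_days_by_category
  n_for_term <- function(term) {
    switch(term,
           h25_29 = nd[["25-29"]], h30_33 = nd[["30-33"]],
           h34plus = nd[[">=34"]],
           h25plus = sum(nd[c("25-29", "30-33", ">=34")]),
           fit_unadj$n_days)
  }
  ref <- data.frame(
    analysis = analysis, term = "reference_lt25",
    n_days = if (fit_unadj$coding %in% c("categorical", "dichotomous"))
      nd[["<25"]] else NA_integer_,
    or_unadjusted = 1, ci_low = NA_real_, ci_high = NA_real_,
    or_adjusted = 1, aci_low = NA_real_, aci_high = NA_real_)
  rows <- data.frame(
    analysis = analysis, term = terms,
    n_days = vapply(terms, n_for_term, numeric(1)),
    or_unadjusted = fit_unadj$or[terms],
    ci_low = fit_unadj$ci[terms, "low"],
    ci_high = fit_unadj$ci[terms, "high"],
    or_adjusted = fit_adj$or[terms],
    aci_low = fit_adj$ci[terms, "low"],
    aci_high = fit_adj$ci[terms, "high"])
  out <- if (fit_unadj$coding %in% c("categorical", "dichotomous"))
    rbind(ref, rows) else rows
  rownames(out) <- NULL
  out
}

# Fit one coding both unadjusted and duration-adjusted.
.fit_pair <- function(strata, coding, ci_level = 0.95, exposure = "hmax") {
  fu <- fit_clogit(strata, coding, adjust_duration = FALSE,
                   ci_level = ci_level, exposure = exposure)
  fa <- fit_clogit(strata, coding, adjust_duration = TRUE,
                   ci_level = ci_level, exposure = exposure)
  list(fit_unadjusted = fu, fit_adjusted = fa)
}

#' Primary analysis: categorical Humidex odds ratios
#'
#' Builds the case-crossover strata and fits the categorical exposure model
#' (reference `<25`), unadjusted and adjusted for duration of employment,
#' emitting a results table with per-category day counts.
#'
#' @param claims Claims data frame.
#' @param grid An [exposure_grid()].
#' @param ci_level Confidence level.
#' @return List: `strata`, `fit_unadjusted`, `fit_adjusted`, `table`.
#' @export
run_primary <- function(claims, grid, ci_level = 0.95) {
  strata <- build_strata(claims, grid)
  pair <- .fit_pair(strata, "categorical", ci_level)
  list(strata = strata,
       fit_unadjusted = pair$fit_unadjusted,
       fit_adjusted = pair$fit_adjusted,
       table = .fit_table("primary", pair$fit_unadjusted,
                          pair$fit_adjusted))
}

.secondary_panels <- c("dichotomous", "continuous", "may_sept",
                       "cherry_jun_jul", "apple_aug_oct")

# Subset claims for a stratified panel; referents are selected within the
# injury's own month, so subsetting injuries keeps whole strata in-window.
.panel_claims <- function(claims, panel) {
  mon <- as.POSIXlt(claims$injury_date)$mon + 1L
  switch(panel,
         may_sept = claims[mon %in% 5:9, , drop = FALSE],
         cherry_jun_jul = claims[claims$duty == "cherry_harvest" &
                                   mon %in% 6:7, , drop = FALSE],
         apple_aug_oct = claims[claims$duty == "apple_harvest" &
                                  mon %in% 8:10, , drop = FALSE],
         claims)
}

#' Secondary analyses: alternative codings and stratified panels
#'
#' Re-runs the conditional-logistic fit with dichotomous (`>=25` vs `<25`)
#' and continuous exposure codings, restricted to the May-September period,
#' and stratified by cherry-harvest (June-July) and apple-harvest
#' (August-October) duties. Stratified panels subset claims before stratum
#' construction, so referent days always come from the injury's own month.
#' The seasonal panels are fitted with all three codings. A panel left empty
#' by its subset is skipped with a warning.
#'
#' @param claims Claims data frame.
#' @param grid An [exposure_grid()].
#' @param panels Subset of
#'   `c("dichotomous", "continuous", "may_sept", "cherry_jun_jul",
#'   "apple_aug_oct")`.
#' @param ci_level Confidence level.
#' @return Named list per panel: fits plus a results table; panel tables
#'   row-bound in `$table`.
#' @export
run_secondary <- function(claims, grid, panels = .secondary_panels,
                          ci_level = 0.95) {
  panels <- match.arg(panels, .secondary_panels, several.ok = TRUE)
  out <- list()
  strata_all <- NULL
  for (panel in panels) {
    cl <- .panel_claims(claims, panel)
    if (nrow(cl) == 0L) {
      warning("secondary panel '", panel, "' is empty after subsetting; ",
              "skipped")
      next
    }
    if (panel %in% c("dichotomous", "continuous")) {
      if (is.null(strata_all)) strata_all <- build_strata(claims, grid)
      strata <- strata_all
      pair <- .fit_pair(strata, panel, ci_level)
      out[[panel]] <- c(pair, list(
        table = .fit_table(panel, pair$fit_unadjusted, pair$fit_adjusted)))
    } else {
      strata <- build_strata(cl, grid)
      fits <- lapply(c("categorical", "dichotomous", "continuous"),
                     function(cd) .fit_pair(strata, cd, ci_level))
      names(fits) <- c("categorical", "dichotomous", "continuous")
      tab <- do.call(rbind, lapply(names(fits), function(cd) {
        .fit_table(paste(panel, cd, sep = ":"),
                   fits[[cd]]$fit_unadjusted, fits[[cd]]$fit_adjusted)
      }))
      out[[panel]] <- list(fits = fits, strata = strata, table = tab)
    }
  }
  out$table <- do.call(rbind, lapply(out, `[[`, "table"))
  rownames(out$table) <- NULL
  out
}

#' Sensitivity-exclusion suite
#'
#' Repeats the adjusted primary analysis under each named exclusion rule
#' (see [sensitivity_rules()]); the `dry_temp` rule swaps maximum dry air
#' temperature in place of Humidex (same category cutpoints) instead of
#' filtering claims. Per-rule failures are isolated: the suite continues and
#' the failing rule's rows carry `NA`.
#'
#' @param claims Claims data frame.
#' @param grid An [exposure_grid()].
#' @param rules Rules to run; default all, preceded by the unfiltered
#'   primary analysis.
#' @param ci_level Confidence level.
#' @return List: `fits` (per rule) and `table`, a forest-plot-style long
#'   table with one row per rule and exposure category
#'   (`rule, n_days, term, or, ci_low, ci_high`, adjusted estimates).
#' @export
run_sensitivity_suite <- function(claims, grid, rules = sensitivity_rules(),
                                  ci_level = 0.95) {
  bad <- setdiff(rules, sensitivity_rules())
  if (length(bad)) {
    stop("unknown sensitivity rule(s): ", paste(bad, collapse = ", "),
         "; valid rules: ", paste(sensitivity_rules(), collapse = ", "))
  }
  all_rules <- c("primary", rules)
  fits <- list()
  rows <- list()
  for (rule in all_rules) {
    res <- tryCatch({
      cl <- if (rule == "primary") claims else sensitivity_filter(claims, rule)
      exposure <- if (rule == "dry_temp") "tmax" else "hmax"
      strata <- build_strata(cl, grid)
      fit <- fit_clogit(strata, "categorical", adjust_duration = TRUE,
                        ci_level = ci_level, exposure = exposure)
      list(fit = fit, n_days = fit$n_days)
    }, error = function(e) {
      warning("sensitivity rule '", rule, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      rows[[rule]] <- data.frame(rule = rule, n_days = NA_integer_,
                                 term = NA_character_, or = NA_real_,
                                 ci_low = NA_real_, ci_high = NA_real_)
      next
    }
    fits[[rule]] <- res$fit
    cat_terms <- c("h25_29", "h30_33", "h34plus")
    rows[[rule]] <- data.frame(
      rule = rule, n_days = res$n_days, term = cat_terms,
      or = res$fit$or[cat_terms],
      ci_low = res$fit$ci[cat_terms, "low"],
      ci_high = res$fit$ci[cat_terms, "high"])
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(fits = fits, table = table)
}

#' Exposure summary over built strata
#'
#' Descriptive statistics in the layout of a published exposure table: mean
#' (SD) and median (IQR) of daily maximum Humidex for injury days and
#' referent days separately, the mean of within-stratum standard deviations,
#' and per-category counts: number of strata containing each category and
#' numbers of injury and referent days in each category.
#'
#' @param strata A `cc_strata` object.
#' @return An object of class `cc_exposure_summary` (a list).
#' @export
summarize_exposure <- function(strata) {
  idx <- strata$role == "index"
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  day_stats <- function(x) {
    qq <- q(x)
    list(n = length(x), mean = mean(x), sd = stats::sd(x),
         median = qq[2], q25 = qq[1], q75 = qq[3])
  }
  within_sd <- tapply(strata$hmax, strata$claim_id, stats::sd)
  lv <- humidex_categories()
  per_cat <- lapply(lv, function(l) {
    in_cat <- strata$category == l
    list(category = l,
         n_strata = length(unique(strata$claim_id[in_cat])),
         n_injury_days = sum(in_cat & idx),
         n_referent_days = sum(in_cat & !idx))
  })
  structure(
    list(injury_days = day_stats(strata$hmax[idx]),
         referent_days = day_stats(strata$hmax[!idx]),
         mean_within_stratum_sd = mean(within_sd, na.rm = TRUE),
         by_category = do.call(rbind, lapply(per_cat, as.data.frame)),
         n_strata = length(unique(strata$claim_id)),
         n_days = nrow(strata)),
    class = "cc_exposure_summary")
}

#' @export
print.cc_exposure_summary <- function(x, ...) {
  fmt <- function(s) sprintf("n = %d, mean (SD) %.1f (%.1f), median (IQR) %.1f (%.1f, %.1f)",
                             s$n, s$mean, s$sd, s$median, s$q25, s$q75)
  cat("Daily maximum Humidex on stratum days\n")
  cat("  injury days  :", fmt(x$injury_days), "\n")
  cat("  referent days:", fmt(x$referent_days), "\n")
  cat(sprintf("  mean of within-stratum SDs = %.1f\n",
              x$mean_within_stratum_sd))
  cat("  per category (strata containing; injury days; referent days):\n")
  for (i in seq_len(nrow(x$by_category))) {
    b <- x$by_category[i, ]
    cat(sprintf("    %-6s %6d (%5d; %6d)\n", b$category, b$n_strata,
                b$n_injury_days, b$n_referent_days))
  }
  invisible(x)
}
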