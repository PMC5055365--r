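# Conditional logistic regression for case-crossover strata, from first
# principles. With exactly one case per stratum the exact conditional
# likelihood reduces to a multinomial-logit (softmax) form over the stratum's
# days:
#   l(beta) = sum_s [ x_case,s . beta - log sum_{j in s} exp(x_j . beta) ]
# so no tie-handling machinery (Breslow/Efron) is needed or implemented.

#' Exact conditional log-likelihood, score and information
#'
#' Evaluates the one-case-per-stratum conditional log-likelihood together
#' with its analytic gradient (score) and Hessian. The Hessian is the
#' negative of the observed information and is negative semidefinite
#' everywhere (the log-likelihood is concave).
#'
#' Within-stratum mean-centering of the linear predictor is used before
#' exponentiation for numerical stability; the returned log-likelihood is on
#' the uncentred scale.
#'
#' @param beta Coefficient vector, length `ncol(X)`.
#' @param X Design matrix, one row per stratum day.
#' @param stratum Stratum identifier per row (any type; coerced to factor).
#' @param case Logical per row: `TRUE` for the stratum's case (index) day.
#' @return List with `loglik` (scalar), `gradient` (length-p vector) and
#'   `hessian` (p x p matrix).
#' @export
conditional_loglik <- function(beta, X, stratum, case) {
  X <- as.matrix(X)
  d <- .cl_design(X, stratum, case)
  .cl_eval(beta, d)
}

# Validate and pre-index a design once; reused across Newton iterations.
.cl_design <- function(X, stratum, case) {
  gid <- as.integer(factor(stratum, levels = unique(stratum)))
  S <- max(gid, 0L)
  if (S == 0L || nrow(X) == 0L) stop("conditional likelihood: no strata")
  case <- as.logical(case)
  sizes <- tabulate(gid, S)
  if (any(sizes < 2L)) {
    stop("stratum with fewer than two days (case plus at least one referent ",
         "required); drop it upstream")
  }
  ncase <- tabulate(gid[case], S)
  if (any(ncase != 1L)) {
    stop("each stratum must contain exactly one case day")
  }
  if (!all(is.finite(X))) stop("non-finite covariates in design")
  # centre covariates within stratum: the conditional likelihood is exactly
  # invariant to stratum-constant shifts, and centring avoids catastrophic
  # cancellation in the score when a covariate (e.g. employment duration)
  # has large between-stratum magnitude
  n_g <- tabulate(gid, S)
  Xc <- X - (rowsum(X, gid, reorder = FALSE) / n_g)[gid, , drop = FALSE]
  list(X = Xc, gid = gid, case = case, S = S, p = ncol(X))
}

.cl_eval <- function(beta, d, want_hessian = TRUE) {
  eta <- drop(d$X %*% beta)
  n_g <- tabulate(d$gid, d$S)
  gmean <- drop(rowsum(eta, d$gid, reorder = FALSE)) / n_g
  eta_c <- eta - gmean[d$gid]
  w <- exp(eta_c)
  denom <- drop(rowsum(w, d$gid, reorder = FALSE))
  p <- w / denom[d$gid]
  loglik <- sum(eta[d$case]) - sum(log(denom) + gmean)
  pX <- p * d$X
  gradient <- colSums(d$X[d$case, , drop = FALSE]) - colSums(pX)
  out <- list(loglik = loglik, gradient = gradient)
  if (want_hessian) {
    G <- rowsum(pX, d$gid, reorder = FALSE)
    out$hessian <- -(crossprod(d$X, pX) - crossprod(G))
  }
  out
}

# Columns with any within-stratum variation (only these are estimable).
.cl_varying_cols <- function(d) {
  n_g <- tabulate(d$gid, d$S)
  m1 <- rowsum(d$X, d$gid, reorder = FALSE) / n_g
  m2 <- rowsum(d$X^2, d$gid, reorder = FALSE) / n_g
  colSums(pmax(m2 - m1^2, 0)) > 1e-12
}

#' Newton-Raphson fit of the exact conditional likelihood
#'
#' Maximises the one-case-per-stratum conditional log-likelihood by
#' Newton-Raphson from `beta = 0` with step-halving, declaring convergence
#' when the score's max-norm falls below `tol`. Standard errors come from the
#' inverse observed information at the optimum; confidence intervals are Wald
#' on the log-odds scale, exponentiated.
#'
#' Strata whose covariate rows are all identical carry no information and are
#' removed before fitting (their likelihood contribution is constant); a
#' design with no informative stratum is an error. Covariates with no
#' within-stratum variation anywhere are inestimable and reported as `NA`.
#' Separation (a coefficient diverging beyond `separation_bound`) is reported
#' as an error naming the offending coefficient, not regularised away.
#'
#' @param X Design matrix (columns should be named).
#' @param stratum Stratum id per row.
#' @param case Logical case indicator per row (one `TRUE` per stratum).
#' @param ci_level Confidence level, default 0.95.
#' @param tol Convergence tolerance on `max(abs(score))`.
#' @param max_iter Iteration cap.
#' @param separation_bound Declare separation when any `|beta|` exceeds this.
#' @return A `cc_fit`: coefficients, standard errors, odds ratios, Wald CIs,
#'   maximised log-likelihood, counts and convergence diagnostics.
#' @export
clogit_newton <- function(X, stratum, case, ci_level = 0.95, tol = 1e-8,
                          max_iter = 100L, separation_bound = 15) {
  stopifnot(ci_level > 0, ci_level < 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  d_all <- .cl_design(X, stratum, case)

  # total-count bookkeeping before dropping uninformative strata
  n_strata <- d_all$S
  n_days <- nrow(X)

  n_g <- tabulate(d_all$gid, d_all$S)
  m1 <- rowsum(d_all$X, d_all$gid, reorder = FALSE) / n_g
  m2 <- rowsum(d_all$X^2, d_all$gid, reorder = FALSE) / n_g
  within_var <- pmax(m2 - m1^2, 0)
  informative <- rowSums(within_var > 1e-12) > 0
  if (!any(informative)) {
    stop("no discordant information: covariates are constant within every ",
         "stratum")
  }
  keep <- informative[d_all$gid]
  d <- .cl_design(X[keep, , drop = FALSE], d_all$gid[keep], d_all$case[keep])

  est <- colSums(within_var > 1e-12) > 0  # estimable columns
  if (!all(est)) {
    warning("no within-stratum variation for: ",
            paste(colnames(X)[!est], collapse = ", "), "; reported as NA")
    d$X <- d$X[, est, drop = FALSE]
    d$p <- ncol(d$X)
  }

  beta <- rep(0, d$p)
  ev <- .cl_eval(beta, d)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ev$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$hessian, -ev$gradient),
                     error = function(e) stop(
                       "information matrix is singular; model not estimable"))
    if (max(abs(ev$gradient)) < 1e-3) {
      # quadratic regime: the expected gain can fall below the numerical
      # resolution of the log-likelihood, so take the undamped Newton step
      cand <- beta + step
      ev_cand <- .cl_eval(cand, d)
    } else {
      # step-halving: accept the first step that does not decrease the
      # loglik beyond its numerical resolution
      slack <- max(1e-12, abs(ev$loglik) * 1e-13)
      lambda <- 1
      repeat {
        cand <- beta + lambda * step
        ev_cand <- .cl_eval(cand, d)
        if (is.finite(ev_cand$loglik) &&
            ev_cand$loglik >= ev$loglik - slack) {
          break
        }
        lambda <- lambda / 2
        if (lambda < 1e-10) stop("step-halving failed to improve the ",
                                 "conditional log-likelihood")
      }
    }
    beta <- cand
    ev <- ev_cand
    if (any(abs(beta) > separation_bound)) {
      worst <- colnames(d$X)[which.max(abs(beta))]
      stop("separation detected: coefficient '", worst,
           "' diverging (|beta| > ", separation_bound, ")")
    }
  }
  if (!converged && max(abs(ev$gradient)) < tol) converged <- TRUE
  if (!converged) {
    stop("Newton-Raphson did not converge in ", max_iter, " iterations ",
         "(max |score| = ", format(max(abs(ev$gradient))), ")")
  }
  vcov_est <- solve(-ev$hessian)
  se_est <- sqrt(pmax(diag(vcov_est), 0))

  full_beta <- rep(NA_real_, ncol(X))
  full_se <- rep(NA_real_, ncol(X))
  names(full_beta) <- names(full_se) <- colnames(X)
  full_beta[est] <- beta
  full_se[est] <- se_est

  ci <- wald_ci(full_beta, full_se, ci_level)
  structure(
    list(beta = full_beta, se = full_se, or = exp(full_beta), ci = ci,
         vcov = vcov_est, loglik = ev$loglik,
         n_strata = n_strata, n_informative_strata = sum(informative),
         n_days = n_days, converged = converged, iterations = iter,
         ci_level = ci_level,
         max_score = max(abs(ev$gradient))),
    class = "cc_fit"
  )
}

#' Wald confidence interval on the odds-ratio scale
#'
#' `(exp(beta - z se), exp(beta + z se))` with `z` the standard-normal
#' quantile for the level. `NA` coefficients give `NA` bounds.
#'
#' @param beta Log-odds coefficient(s).
#' @param se Standard error(s); must be positive where `beta` is not `NA`.
#' @param level Confidence level in (0, 1).
#' @return Matrix with columns `low`, `high` (odds-ratio scale).
#' @export
wald_ci <- function(beta, se, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(!is.na(beta) & (is.na(se) | se <= 0))) {
    stop("wald_ci: se must be positive")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(low = exp(beta - z * se), high = exp(beta + z * se))
}

#' Fit a conditional logistic model to case-crossover strata
#'
#' Builds the design for the requested exposure coding and maximises the
#' exact conditional likelihood over the strata.
#'
#' Codings:
#' * `categorical` - indicator terms for the `25-29`, `30-33` and `>=34`
#'   exposure categories, reference `<25`;
#' * `dichotomous` - a single indicator for exposure `>= 25`;
#' * `continuous` - the exposure value itself (per-unit odds ratio).
#'
#' `adjust_duration = TRUE` adds the duration-of-employment covariate in days
#' (untransformed, so its odds ratio reads per additional day employed).
#' `exposure = "tmax"` swaps in maximum dry air temperature, with the same
#' category cutpoints, for the dry-temperature sensitivity analysis.
#'
#' @param strata A `cc_strata` object from [build_strata()] (or any data
#'   frame with `claim_id`, `role`, `hmax`, `tmax`, `duration_days`).
#' @param coding Exposure coding; see above.
#' @param adjust_duration Adjust for duration of employment?
#' @param ci_level Confidence level for Wald intervals.
#' @param exposure `"hmax"` (Humidex, default) or `"tmax"` (dry temperature).
#' @param ... Passed to [clogit_newton()].
#' @return A `cc_fit`; see [clogit_newton()].
#' @export
fit_clogit <- function(strata, coding = c("categorical", "dichotomous",
                                          "continuous"),
                       adjust_duration = FALSE, ci_level = 0.95,
                       exposure = c("hmax", "tmax"), ...) {
  coding <- match.arg(coding)
  exposure <- match.arg(exposure)
  des <- build_design(strata, coding, adjust_duration, exposure)
  fit <- clogit_newton(des$X, des$stratum, des$case, ci_level = ci_level, ...)
  fit$coding <- coding
  fit$exposure <- exposure
  fit$adjust_duration <- adjust_duration
  fit$n_days_by_category <- des$n_days_by_category
  fit
}

#' Design matrix for a conditional-logistic fit
#'
#' @inheritParams fit_clogit
#' @return List: `X` (design matrix), `stratum`, `case`, and
#'   `n_days_by_category` (stratum-day counts per exposure category under the
#'   chosen exposure).
#' @export
build_design <- function(strata, coding = c("categorical", "dichotomous",
                                            "continuous"),
                         adjust_duration = FALSE,
                         exposure = c("hmax", "tmax")) {
  coding <- match.arg(coding)
  exposure <- match.arg(exposure)
  x <- strata[[exposure]]
  if (is.null(x)) stop("strata lack the '", exposure, "' column")
  cat4 <- categorize_humidex(x)
  lv <- humidex_categories()
  X <- switch(
    coding,
    categorical = {
      m <- sapply(lv[-1], function(l) as.numeric(cat4 == l))
      colnames(m) <- c("h25_29", "h30_33", "h34plus")
      m
    },
    dichotomous = matrix(as.numeric(x >= 25), ncol = 1,
                         dimnames = list(NULL, "h25plus")),
    continuous = matrix(as.numeric(x), ncol = 1,
                        dimnames = list(NULL, exposure))
  )
  if (adjust_duration) {
    X <- cbind(X, duration_days = as.numeric(strata$duration_days))
  }
  list(X = X, stratum = strata$claim_id, case = strata$role == "index",
       n_days_by_category = table(cat4))
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional logistic fit (exact conditional likelihood)\n")
  cat(sprintf("  strata: %d (%d informative), days: %d\n",
              x$n_strata, x$n_informative_strata, x$n_days))
  cat(sprintf("  log-likelihood: %.4f | converged in %d iterations ",
              x$loglik, x$iterations))
  cat(sprintf("(max |score| = %.2e)\n", x$max_score))
  lvl <- paste0(format(100 * x$ci_level), "%")
  tab <- data.frame(
    beta = round(x$beta, 4), se = round(x$se, 4),
    OR = round(x$or, 3),
    low = round(x$ci[, "low"], 3), high = round(x$ci[, "high"], 3))
  names(tab)[4:5] <- paste0(lvl, c(" low", " high"))
  print(tab)
  invisible(x)
}
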