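# The exact conditional likelihood and its Newton-Raphson maximiser.

test_that("the log-likelihood at beta = 0 is minus the sum of log stratum
           sizes", {
  pr <- random_clogit_problem(25, p = 2, seed = 101)
  sizes <- table(pr$stratum)
  ev <- conditional_loglik(c(0, 0), pr$X, pr$stratum, pr$case)
  expect_equal(ev$loglik, -sum(log(sizes)), tolerance = 1e-12)
})

test_that("analytic score matches central finite differences", {
  for (seed in 1:5) {
    pr <- random_clogit_problem(20, p = 3, seed = seed)
    beta <- rnorm(3, 0, 0.7)
    ev <- conditional_loglik(beta, pr$X, pr$stratum, pr$case)
    h <- 1e-6
    fd <- vapply(seq_along(beta), function(j) {
      e <- numeric(length(beta)); e[j] <- h
      (conditional_loglik(beta + e, pr$X, pr$stratum, pr$case)$loglik -
         conditional_loglik(beta - e, pr$X, pr$stratum, pr$case)$loglik) /
        (2 * h)
    }, numeric(1))
    expect_equal(unname(ev$gradient), fd, tolerance = 1e-6)
  }
})

test_that("the Hessian is the finite-difference Jacobian of the score and is
           negative semidefinite", {
  pr <- random_clogit_problem(15, p = 3, seed = 7)
  beta <- c(0.4, -0.2, 0.1)
  ev <- conditional_loglik(beta, pr$X, pr$stratum, pr$case)
  h <- 1e-5
  fd <- sapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (conditional_loglik(beta + e, pr$X, pr$stratum, pr$case)$gradient -
       conditional_loglik(beta - e, pr$X, pr$stratum, pr$case)$gradient) /
      (2 * h)
  })
  expect_equal(unname(ev$hessian), unname(fd), tolerance = 1e-5)
  for (b in list(c(0, 0, 0), beta, c(-1, 2, 0.5))) {
    ew <- eigen(conditional_loglik(b, pr$X, pr$stratum, pr$case)$hessian,
                symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ew < 1e-10))
  }
})

test_that("stratum-constant covariate shifts leave likelihood and fit
           unchanged", {
  pr <- random_clogit_problem(30, p = 2, seed = 12)
  shift <- rnorm(length(unique(pr$stratum)))[
    match(pr$stratum, unique(pr$stratum))]
  X2 <- pr$X + cbind(shift, 2 * shift)
  beta <- c(0.3, -0.4)
  expect_equal(conditional_loglik(beta, pr$X, pr$stratum, pr$case)$loglik,
               conditional_loglik(beta, X2, pr$stratum, pr$case)$loglik,
               tolerance = 1e-10)
  f1 <- clogit_newton(pr$X, pr$stratum, pr$case)
  f2 <- clogit_newton(X2, pr$stratum, pr$case)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$se, f2$se, tolerance = 1e-7)
})

test_that("the fit is invariant to referent-day ordering", {
  pr <- random_clogit_problem(30, p = 2, seed = 13)
  set.seed(1)
  perm <- order(pr$stratum, runif(length(pr$stratum)))
  f1 <- clogit_newton(pr$X, pr$stratum, pr$case)
  f2 <- clogit_newton(pr$X[perm, ], pr$stratum[perm], pr$case[perm])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("1:1 binary discordant pairs reproduce the closed form
           ln(n10/n01)", {
  d <- binary_pairs(20, 10)
  f <- clogit_newton(matrix(d$x, dimnames = list(NULL, "x")),
                     d$stratum, d$case)
  expect_equal(unname(f$beta), log(2), tolerance = 1e-9)
  expect_equal(unname(f$or), 2, tolerance = 1e-8)
  # concordant pairs carry no information: same estimate, counted anyway
  d2 <- binary_pairs(20, 10, n_conc = 15)
  f2 <- clogit_newton(matrix(d2$x, dimnames = list(NULL, "x")),
                      d2$stratum, d2$case)
  expect_equal(unname(f2$beta), log(2), tolerance = 1e-9)
  expect_equal(f2$n_strata, 45)
  expect_equal(f2$n_informative_strata, 30)
  # closed-form SE of the discordant-pair estimator: sqrt(1/n10 + 1/n01)
  expect_equal(unname(f$se), sqrt(1 / 20 + 1 / 10), tolerance = 1e-6)
})

test_that("all-concordant designs raise the no-discordant-information
           error", {
  d <- binary_pairs(0, 0, n_conc = 12)
  expect_error(clogit_newton(matrix(d$x, dimnames = list(NULL, "x")),
                             d$stratum, d$case),
               "no discordant information")
})

test_that("separation is reported, not regularised", {
  # case always exposed, referents never: beta diverges
  d <- binary_pairs(40, 0)
  expect_error(clogit_newton(matrix(d$x, dimnames = list(NULL, "x")),
                             d$stratum, d$case),
               "separation")
})

test_that("degenerate strata are rejected upfront", {
  expect_error(conditional_loglik(0, matrix(1), stratum = 1, case = TRUE),
               "fewer than two days")
  X <- matrix(rnorm(4), 4, 1)
  expect_error(conditional_loglik(0, X, c(1, 1, 2, 2),
                                  c(TRUE, TRUE, FALSE, FALSE)),
               "exactly one case")
})

test_that("Newton solution agrees with a derivative-free optimiser", {
  for (seed in 1:8) {
    pr <- random_clogit_problem(40, p = 2, seed = 100 + seed)
    fit <- clogit_newton(pr$X, pr$stratum, pr$case)
    nm <- optim(c(0, 0), function(b)
      -conditional_loglik(b, pr$X, pr$stratum, pr$case)$loglik,
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000))
    expect_lt(max(abs(unname(fit$beta) - nm$par)), 1e-4)
    expect_lt(fit$max_score, 1e-8)
  }
})

test_that("estimates match an established conditional-logistic
           implementation", {
  library(survival)
  pr <- random_clogit_problem(80, p = 3, seed = 55)
  fit <- clogit_newton(pr$X, pr$stratum, pr$case)
  df <- data.frame(case = pr$case, pr$X, sid = pr$stratum)
  ref <- survival::clogit(case ~ x1 + x2 + x3 + strata(sid), data = df,
                          method = "exact")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("Wald intervals are exp(beta +/- z se) and always contain the OR", {
  ci <- wald_ci(0, 1, 0.95)
  expect_equal(unname(ci[1, ]), c(exp(-qnorm(0.975)), exp(qnorm(0.975))),
               tolerance = 1e-12)
  expect_equal(round(unname(ci[1, ]), 3), c(0.141, 7.099))
  set.seed(3)
  b <- rnorm(20); s <- rexp(20)
  ci <- wald_ci(b, s, 0.9)
  expect_true(all(ci[, "low"] < exp(b) & exp(b) < ci[, "high"]))
  expect_error(wald_ci(1, 0, 0.95), "positive")
  expect_error(wald_ci(1, 1, 1.2), "level")
})

test_that("codings build the documented design columns", {
  g <- toy_grid()
  st <- build_strata(toy_claims(25, g$dates, g, seed = 21), g)
  d_cat <- build_design(st, "categorical", adjust_duration = TRUE)
  expect_equal(colnames(d_cat$X),
               c("h25_29", "h30_33", "h34plus", "duration_days"))
  expect_equal(rowSums(d_cat$X[, 1:3]) == 0, st$category == "<25")
  d_di <- build_design(st, "dichotomous")
  expect_equal(drop(d_di$X), as.numeric(st$hmax >= 25))
  d_co <- build_design(st, "continuous")
  expect_equal(drop(d_co$X), st$hmax)
  # the dry-temperature swap applies the same cutpoints to tmax
  d_dry <- build_design(st, "dichotomous", exposure = "tmax")
  expect_equal(drop(d_dry$X), as.numeric(st$tmax >= 25))
  expect_equal(sum(d_cat$n_days_by_category), nrow(st))
})
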