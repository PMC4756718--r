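test_that("Kaplan-Meier matches the hand product-limit on simple data", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(attr(km, "median"), 2)  # first time S <= 0.5

  km2 <- km_fit(c(5, 8, 13), c(0, 0, 0))
  expect_equal(km2$surv, rep(1, 3))
  expect_true(is.na(attr(km2, "median")))
})

test_that("Kaplan-Meier matches a brute-force product-limit recomputation", {
  set.seed(21)
  time <- round(rexp(20, 0.05), 1)
  event <- rbinom(20, 1, 0.7)
  km <- km_fit(time, event)
  # independent oracle: loop over distinct times
  ut <- sort(unique(time))
  s <- 1
  oracle <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    oracle[k] <- s
  }
  expect_equal(km$surv, oracle[match(km$time, ut)], tolerance = 1e-12)
})

test_that("log-rank is null on duplicated groups and matches a hand computation", {
  time <- c(3, 5, 8, 10); event <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(time, time), c(event, event),
                      rep(c("A", "B"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # small two-group instance vs hand observed-minus-expected sums
  time <- c(1, 2, 4, 5, 7, 9); event <- c(1, 1, 1, 1, 1, 0)
  grp <- c(0, 1, 0, 1, 0, 1)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_chisq <- o_minus_e^2 / v
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, oracle_chisq, tolerance = 1e-9)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), "two")
})

test_that("Cox fit is null for identical-survival groups", {
  time <- c(2, 4, 6, 9); event <- c(1, 1, 1, 0)
  X <- matrix(rep(c(0, 1), each = 4), ncol = 1, dimnames = list(NULL, "g"))
  fit <- cox_fit(c(time, time), c(event, event), X)
  expect_equal(fit$coefficients$beta, 0, tolerance = 1e-6)
  expect_equal(fit$coefficients$hr, 1, tolerance = 1e-6)
})

test_that("Cox coefficient matches a 1-D grid search of the partial likelihood", {
  # tiny untied instance, single binary covariate
  time <- c(1.5, 2.1, 3.3, 4.8, 6.2, 7.7, 9.1, 11.4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  grid <- seq(-3, 3, by = 1e-4)
  nll <- vapply(grid, neg_log_partial_lik, 0, time = time, event = event, x = x)
  beta_oracle <- grid[which.min(nll)]
  fit <- cox_fit(time, event, matrix(x, ncol = 1))
  expect_lt(abs(fit$coefficients$beta - beta_oracle), 1e-4)
})

test_that("Cox score equation root agrees with a bisection oracle (untied, binary)", {
  # smallest instance with an interior maximum: alternating group deaths
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(0, 1, 1, 0)
  score <- function(b) {
    # derivative of log PL for untied data
    s <- 0
    for (i in which(event == 1)) {
      r <- time >= time[i]
      s <- s + x[i] - sum(x[r] * exp(b * x[r])) / sum(exp(b * x[r]))
    }
    s
  }
  lo <- -5; hi <- 5
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) lo <- mid else hi <- mid
  }
  fit <- cox_fit(time, event, matrix(x, ncol = 1))
  expect_equal(fit$coefficients$beta, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("exp(beta) converges to the generating hazard ratio with n", {
  err <- vapply(c(400, 4000), function(n) {
    set.seed(n)
    d <- make_ph_data(n, beta = log(2),
                      X = matrix(rbinom(n, 1, 0.5), ncol = 1), seed = n + 1)
    fit <- cox_fit(d$time, d$event, d$X)
    abs(fit$coefficients$beta - log(2))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1)
})

test_that("cox_fit requires events and complete cases", {
  expect_error(cox_fit(c(1, 2), c(0, 0), matrix(c(0, 1))), "no events")
  expect_error(cox_fit(c(1, NA), c(1, 0), matrix(c(0, 1))), "missing")
})

test_that("predicted survival behaves as the PH model dictates", {
  d <- make_ph_data(150, beta = 0.7, seed = 5)
  fit <- cox_fit(d$time, d$event, d$X)
  s0 <- predicted_survival(fit, 0)
  expect_equal(s0$surv, exp(-fit$basehaz$hazard), tolerance = 1e-12)
  # monotone: raising a positive-beta covariate lowers S everywhere
  s1 <- predicted_survival(fit, 1)
  s2 <- predicted_survival(fit, 2)
  expect_true(all(s2$surv <= s1$surv & s1$surv <= s0$surv))
  expect_error(predicted_survival(fit, c(1, 2)), "does not match")
})

test_that("restricted mean integrates step functions exactly", {
  expect_equal(rms(list(time = c(10, 20), surv = c(0.5, 0.2)), tau = 0), 0)
  # S == 1 on [0, 60] attains the upper bound
  expect_equal(rms(list(time = 30, surv = 1), tau = 60), 60)
  # hand rectangle: 1 on [0,10), 0.5 on [10,20), 0.2 on [20,60]
  expect_equal(rms(list(time = c(10, 20), surv = c(0.5, 0.2)), tau = 60),
               10 + 5 + 8)
  expect_error(rms(list(time = 1, surv = 1.2)), "outside")
})

test_that("RMS of a fine exponential grid matches the closed form", {
  tgrid <- seq(0.0005, 60, by = 0.001)
  surv <- list(time = tgrid, surv = exp(-tgrid / 30))
  expect_equal(rms(surv, tau = 60), 30 * (1 - exp(-2)), tolerance = 1e-3)
})

test_that("RMS of a KM curve equals brute-force rectangle summation", {
  set.seed(33)
  time <- rexp(25, 0.04); event <- rbinom(25, 1, 0.8)
  km <- km_fit(time, event)
  # independent rectangles
  tt <- c(0, km$time[km$time <= 60], 60)
  ss <- c(1, km$surv[km$time <= 60])
  oracle <- 0
  for (k in seq_along(ss)) oracle <- oracle + ss[k] * (tt[k + 1] - tt[k])
  expect_equal(rms(km, tau = 60), oracle, tolerance = 1e-12)
})

test_that("RMS is monotone in tau and in the survival function", {
  s_hi <- list(time = c(10, 30), surv = c(0.8, 0.5))
  s_lo <- list(time = c(10, 30), surv = c(0.6, 0.2))
  taus <- c(5, 20, 40, 60)
  r_hi <- vapply(taus, function(t) rms(s_hi, t), 0)
  expect_true(all(diff(r_hi) > 0))
  expect_true(all(r_hi <= taus))
  expect_true(all(r_hi >= vapply(taus, function(t) rms(s_lo, t), 0)))
})

test_that("covariate encoding produces ordered scores and one-hot race", {
  cl <- make_test_clinical(12, seed = 13)
  X <- encode_covariates(cl, c("age", "stage", "grade", "cytoreduction", "race"))
  expect_equal(X[, "age"], cl$age)
  expect_equal(X[, "stage"], as.integer(cl$stage))
  expect_equal(X[, "grade"], as.integer(cl$grade))
  expect_true(all(X[, "cytoreduction"] %in% 0:1))
  expect_true(any(grepl("^race_", colnames(X))))
})
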