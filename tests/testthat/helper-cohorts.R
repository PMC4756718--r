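options(rmsperm.quiet = TRUE)

## small deterministic clinical table used across io tests
make_test_clinical <- function(n = 10, seed = 42) {
  set.seed(seed)
  data.frame(
    case_id = sprintf("C%02d", seq_len(n)),
    route = rep(c("IP", "IV"), length.out = n),
    age = round(rnorm(n, 60, 8), 1),
    stage = factor(sample(c("IIA/B/C", "IIIA/B", "IIIC", "IV"), n, TRUE),
                   levels = c("IIA/B/C", "IIIA/B", "IIIC", "IV"),
                   ordered = TRUE),
    grade = factor(sample(c("G2", "G3"), n, TRUE), levels = c("G2", "G3")),
    cytoreduction = factor(sample(c("optimal", "suboptimal"), n, TRUE),
                           levels = c("optimal", "suboptimal")),
    race = factor(sample(c("White", "Black"), n, TRUE)),
    pfs_months = round(rexp(n, 1 / 20), 2),
    pfs_event = sample(c(TRUE, FALSE), n, TRUE),
    os_months = round(rexp(n, 1 / 35), 2),
    os_event = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
}

## simple PH exponential data with one covariate matrix, for oracle tests
make_ph_data <- function(n, beta, X = NULL, rate = 0.05, cens_rate = 0.01,
                         seed = 1) {
  set.seed(seed)
  if (is.null(X)) X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  lp <- as.vector(X %*% beta)
  t_ev <- rexp(n, rate * exp(lp))
  t_c <- rexp(n, cens_rate)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), X = X)
}

## exact Cox partial likelihood (Breslow form; no ties in the data we feed
## it) -- the independent oracle for the fitter
neg_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}
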