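test_that("relative quantile normalization follows the rank formula", {
  expect_equal(normalize_relative_expression(c(5, 1, 9)), c(0.5, 0, 1))
  # two tied minima among n = 3: average rank 1.5 -> q = 0.25
  expect_equal(normalize_relative_expression(c(1, 1, 2)), c(0.25, 0.25, 1))
  # invariant to strictly monotone transforms
  set.seed(5)
  x <- rnorm(40)
  expect_equal(normalize_relative_expression(x),
               normalize_relative_expression(exp(2 * x + 1)))
  expect_error(normalize_relative_expression(rep(2, 5)), "identical")
  expect_error(normalize_relative_expression(3), "at least 2")
})

test_that("quantile windows select about a tenth of tie-free cases", {
  set.seed(6)
  for (n in c(50, 200, 488)) {
    q <- normalize_relative_expression(rnorm(n))
    picked <- sum(q >= 0.9 & q <= 1)
    expect_lte(abs(picked - ceiling(0.1 * n)), 1)
  }
})

## helper: build a percase-like frame without model fitting
fake_percase <- function(q, arm, rms) {
  structure(data.frame(case_id = as.character(seq_along(q)), arm = arm,
                       q = q, rms = rms, stringsAsFactors = FALSE))
}

test_that("window delta is the IP-minus-IV mean and is antisymmetric", {
  pc <- fake_percase(q = c(0.95, 0.92, 0.97, 0.91, 0.5),
                     arm = c("IP", "IP", "IV", "IV", "IP"),
                     rms = c(40, 30, 20, 10, 55))
  wd <- window_delta(pc, c(0.9, 1))
  expect_equal(wd$delta, mean(c(40, 30)) - mean(c(20, 10)))
  expect_equal(wd$n_ip, 2); expect_equal(wd$n_iv, 2)
  # window [0, 1] selects everyone
  expect_equal(length(window_delta(pc, c(0, 1))$members), 5)
  # swapping arm labels negates the difference
  pc_swap <- pc
  pc_swap$arm <- ifelse(pc$arm == "IP", "IV", "IP")
  expect_equal(window_delta(pc_swap, c(0.9, 1))$delta, -wd$delta)
  # empty arm in window -> flagged not computable
  wd0 <- window_delta(pc[pc$arm == "IP", ], c(0.9, 1))
  expect_false(wd0$computable)
  expect_true(is.na(wd0$delta))
})

test_that("fixed-value permutation p matches exact enumeration on 3 vs 3", {
  vals <- c(12, 25, 31, 8, 17, 40)
  arm <- c("IP", "IP", "IP", "IV", "IV", "IV")
  got <- permutation_test(vals, arm, exact = TRUE)
  # independent oracle: enumerate all 2^6 label vectors with three IPs
  labs <- expand.grid(rep(list(c(TRUE, FALSE)), 6))
  labs <- labs[rowSums(labs) == 3, ]
  dobs <- mean(vals[arm == "IP"]) - mean(vals[arm == "IV"])
  dstar <- apply(labs, 1, function(l) mean(vals[l]) - mean(vals[!l]))
  p_oracle <- mean(abs(dstar) >= abs(dobs) - 1e-12)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(got$n_perm, choose(6, 3))
  # Monte-Carlo version agrees within its resolution
  mc <- permutation_test(vals, arm, n_perm = 4000, seed = 3)
  expect_lt(abs(mc$p_value - p_oracle),
            3 * sqrt(p_oracle * (1 - p_oracle) / 4000) + 1 / 4000)
})

test_that("permutation p is deterministic in the seed and near 1 for identical arms", {
  vals <- c(10, 20, 30, 10, 20, 30)
  arm <- rep(c("IP", "IV"), each = 3)
  p1 <- permutation_test(vals, arm, n_perm = 500, seed = 11)$p_value
  p2 <- permutation_test(vals, arm, n_perm = 500, seed = 11)$p_value
  expect_identical(p1, p2)
  expect_equal(permutation_test(vals, arm, exact = TRUE)$p_value, 1)
  # degenerate: a single possible assignment
  deg <- permutation_test(c(5, 6), c("IP", "IV"), n_perm = 100, seed = 1)
  expect_false(deg$degenerate)  # C(2,1) = 2 assignments exist
  expect_error(permutation_test(5, "IP"), "per arm")
})

test_that("rms curves are flat for null genes and decrease for hazardous ones", {
  # strong planted effect, no covariates or route effect
  cfg <- sim_config(n_ip = 400, n_iv = 400, n_genes = 3,
                    prognostic_genes = c(BAD = 1.2), route_log_hr = 0,
                    covariate_log_hr = c(age = 0, stage = 0, grade = 0,
                                         cytoreduction = 0),
                    missingness = c(pfs = 0, os = 0), platform_overlap = 1,
                    seed = 3)
  co <- simulate_cohort(cfg)
  cl <- truncate_survival(co$clinical)
  up <- rms_curve(cl, co$microarray, "BAD", "IV", "pfs", B = 0)
  expect_true(all(diff(up$rms) < 0))
  expect_true(all(up$rms >= 0 & up$rms <= 60))

  flat <- rms_curve(cl, co$microarray, "GENE001", "IV", "pfs", B = 0)
  base_rms <- rms(km_fit(cl$pfs_months[cl$route == "IV"],
                         cl$pfs_event[cl$route == "IV"]), 60)
  expect_lt(max(abs(flat$rms - base_rms)), 2.5)
  expect_lt(diff(range(flat$rms)), diff(range(up$rms)))
})

test_that("rms curve bootstrap bands bracket the estimate and honor the seed", {
  co <- make_fixture("predictive_gene_demo", seed = 4)
  cl <- truncate_survival(co$clinical)
  c1 <- rms_curve(cl, co$microarray, "IVRES1", "IV", "pfs", B = 40, seed = 7,
                  grid = seq(0, 1, 0.1))
  c2 <- rms_curve(cl, co$microarray, "IVRES1", "IV", "pfs", B = 40, seed = 7,
                  grid = seq(0, 1, 0.1))
  expect_identical(c1$lower, c2$lower)
  expect_true(all(c1$lower <= c1$rms + 1e-9 & c1$rms <= c1$upper + 1e-9))
  expect_true(all(c1$lower >= 0 & c1$upper <= 60))
})

test_that("predicted RMS from an exponential PH fit matches the closed form", {
  # near-exact check on the composition rms(predicted_survival(fit, q)):
  # large-n exponential data, single q covariate with known effect
  lambda <- 1 / 25; beta <- 0.9
  set.seed(44)
  n <- 6000
  q <- runif(n)
  tev <- rexp(n, lambda * exp(beta * q))
  fit <- cox_fit(tev, rep(1, n), matrix(q, ncol = 1, dimnames = list(NULL, "q")))
  for (qq in c(0.1, 0.5, 0.9)) {
    got <- rms(predicted_survival(fit, qq), tau = 60)
    lam_q <- lambda * exp(beta * qq)
    closed <- (1 - exp(-lam_q * 60)) / lam_q
    expect_lt(abs(got - closed), 1.2)
  }
})

test_that("per-case adjusted RMS is bounded and consistent with the KM curve", {
  co <- make_fixture("predictive_gene_demo", seed = 9)
  cl <- truncate_survival(co$clinical)
  pc <- adjusted_rms_per_case(cl, co$microarray, "IVRES1", "pfs")
  expect_true(all(pc$rms > 0 & pc$rms <= 60))
  for (a in c("IP", "IV")) {
    i <- cl$route == a
    km_rms <- rms(km_fit(cl$pfs_months[i], cl$pfs_event[i]), 60)
    expect_lt(abs(mean(pc$rms[pc$arm == a]) - km_rms), 2.5)
  }
})

test_that("window permutation p matches exact enumeration for small windows", {
  # construct a cohort whose top decile is small enough to enumerate
  cfg <- sim_config(n_ip = 22, n_iv = 38, n_genes = 3, route_log_hr = log(0.5),
                    missingness = c(pfs = 0, os = 0), platform_overlap = 1,
                    seed = 13)
  co <- simulate_cohort(cfg)
  cl <- truncate_survival(co$clinical)
  res_ex <- test_window_permutation(cl, co$microarray, "GENE001", "pfs",
                                    window = c(0.9, 1), mode = "fixed",
                                    exact = TRUE)
  expect_lte(res_ex$n_ip + res_ex$n_iv, 10)
  # oracle: enumerate assignments over the fixed per-case RMS values
  pc <- adjusted_rms_per_case(cl, co$microarray, "GENE001", "pfs")
  wd <- window_delta(pc, c(0.9, 1))
  v <- pc$rms[wd$members]; a <- pc$arm[wd$members]
  labs <- expand.grid(rep(list(c("IP", "IV")), length(v)))
  labs <- labs[rowSums(labs == "IP") == sum(a == "IP"), , drop = FALSE]
  dstar <- apply(labs, 1, function(l) mean(v[l == "IP"]) - mean(v[l == "IV"]))
  p_oracle <- mean(abs(dstar) >= abs(wd$delta) - 1e-12)
  expect_equal(res_ex$p_value, p_oracle, tolerance = 1e-12)

  # Monte-Carlo fixed mode approaches the same exact p
  res_mc <- test_window_permutation(cl, co$microarray, "GENE001", "pfs",
                                    window = c(0.9, 1), mode = "fixed",
                                    n_perm = 4000, seed = 2)
  expect_lt(abs(res_mc$p_value - p_oracle),
            3 * sqrt(p_oracle * (1 - p_oracle) / 4000) + 1 / 4000)
})

test_that("refit-mode window permutation is deterministic and well formed", {
  co <- make_fixture("predictive_gene_demo", seed = 16)
  cl <- truncate_survival(co$clinical)
  r1 <- test_window_permutation(cl, co$microarray, "IVRES1", "pfs",
                                window = c(0, 0.1), n_perm = 80, seed = 5)
  r2 <- test_window_permutation(cl, co$microarray, "IVRES1", "pfs",
                                window = c(0, 0.1), n_perm = 80, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_equal(r1$mode, "refit")
  expect_lte(abs(r1$delta), 60)
})

test_that("fixed-value permutation of model-predicted RMS is anticonservative", {
  # negative control motivating the refit default: per-case RMS values are
  # per-arm model predictions, so shuffling labels over fixed values
  # ignores arm-level estimation noise and rejects far too often on null
  # cohorts
  pvals <- vapply(1:60, function(r) {
    cfg <- sim_config(n_ip = 100, n_iv = 100, n_genes = 1, route_log_hr = 0,
                      seed = 3000 + r)
    co <- simulate_cohort(cfg)
    cl <- truncate_survival(co$clinical)
    test_window_permutation(cl, co$microarray, "GENE001", "pfs",
                            window = c(0.9, 1), n_perm = 300, seed = 40 + r,
                            mode = "fixed")$p_value
  }, 0)
  expect_gt(mean(pvals < 0.05), 0.15)
})

test_that("candidate calling encodes the no-IP-benefit decision logic", {
  pr <- function(gene, delta_m, p_m, delta_r, p_r) {
    list(
      micro = data.frame(gene = gene, endpoint = "PFS", q_lo = 0.9, q_hi = 1,
                         delta = delta_m, p_value = p_m, computable = TRUE,
                         stringsAsFactors = FALSE),
      rna = data.frame(gene = gene, endpoint = "PFS", q_lo = 0.9, q_hi = 1,
                       delta = delta_r, p_value = p_r, computable = TRUE,
                       stringsAsFactors = FALSE))
  }
  # clear IP benefit on both platforms -> not a candidate
  x <- pr("BENEFIT", 10, 0.001, 8, 0.004)
  expect_false(call_candidates(x$micro, x$rna)$candidate)
  # non-significant difference on one platform, significant IP harm on the
  # other -> candidate (both flag)
  x <- pr("STT3A_LIKE", 1.4, 0.4101, -6.2, 0.0046)
  expect_true(call_candidates(x$micro, x$rna)$candidate)
  # significant IP harm on both -> candidate
  x <- pr("HARM", -7.2, 1e-4, -17.9, 1e-4)
  expect_true(call_candidates(x$micro, x$rna)$candidate)
  # benefit on one platform blocks candidacy even if the other is null
  x <- pr("MIXED", 12, 0.0003, 0.5, 0.9)
  expect_false(call_candidates(x$micro, x$rna)$candidate)
  # not computable windows propagate as non-candidates
  x <- pr("EMPTY", NA, NA, -5, 0.01)
  x$micro$computable <- FALSE
  expect_false(call_candidates(x$micro, x$rna)$candidate)
})
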