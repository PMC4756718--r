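## Restricted-mean-survival analysis over rank-normalized expression and the
## quantile-window permutation test of the IP-minus-IV difference in
## Cox-adjusted RMS -- the candidate-biomarker machinery.

#' Rank-normalize expression to relative quantiles in [0, 1]
#'
#' Orders the values from least to greatest and assigns each a continuous
#' relative quantile `q = (rank - 1) / (n - 1)` with average ranks for ties,
#' so the minimum maps to 0, the maximum to 1, and `q` is invariant to any
#' strictly monotone transform of the raw values.
#'
#' @param values numeric vector (>= 2 values, not all identical); names are
#'   preserved.
#' @export
normalize_relative_expression <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) < 2) stop("all values identical: no ordering exists")
  (rank(values, ties.method = "average") - 1) / (length(values) - 1)
}

## shared preparation: match cases to expression, listwise-delete on the
## endpoint and covariates, normalize the gene over the pooled analyzed
## cohort, and build per-case design rows (q first column)
prep_gene_data <- function(clinical, expr, gene, endpoint, covariates, tau = 60) {
  stopifnot(gene %in% rownames(expr))
  endpoint <- match.arg(endpoint, c("pfs", "os"))
  clinical <- clinical[clinical$case_id %in% colnames(expr), , drop = FALSE]
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  sub <- analysis_subset(clinical, c(tcol, ecol, covariates))
  if (nrow(sub) < 2) stop("analysis subset too small for gene ", gene)
  q <- normalize_relative_expression(expr[gene, sub$case_id])
  X <- if (length(covariates)) {
    cbind(q = q, encode_covariates(sub, covariates))
  } else matrix(q, ncol = 1, dimnames = list(NULL, "q"))
  list(case_id = sub$case_id, arm = sub$route, time = sub[[tcol]],
       event = as.integer(sub[[ecol]]), q = q, X = X, tau = tau,
       n_omitted = attr(sub, "n_omitted"),
       platform = attr(expr, "platform"), gene = gene,
       endpoint = toupper(endpoint))
}

#' RMS-versus-expression curve for one gene and arm
#'
#' Fits a univariate Cox model of the endpoint on the relative expression
#' quantile `q` within one arm (`q` normalized over the pooled analyzed
#' IP+IV cohort), then evaluates the restricted mean of the predicted
#' survival `S(t | q)` on a grid of `q` values. Pointwise confidence bands
#' come from a seeded case-resampling bootstrap within the arm (percentile
#' method).
#'
#' @param clinical cohort data frame (truncated; see [truncate_survival()]).
#' @param expr an [expression_matrix()].
#' @param gene gene symbol.
#' @param arm `"IP"` or `"IV"`.
#' @param endpoint `"pfs"` or `"os"`.
#' @param grid quantile grid for the curve.
#' @param tau restriction time, months.
#' @param B bootstrap replicates (0 skips the band).
#' @param conf_level pointwise band level.
#' @param seed bootstrap seed.
#' @return class `rms_curve`: data frame `q`, `rms`, `lower`, `upper`, with
#'   gene/arm/endpoint/platform metadata attributes.
#' @export
rms_curve <- function(clinical, expr, gene, arm, endpoint = c("pfs", "os"),
                      grid = seq(0, 1, by = 0.02), tau = 60, B = 200,
                      conf_level = 0.95, seed = 1L) {
  endpoint <- match.arg(endpoint)
  d <- prep_gene_data(clinical, expr, gene, endpoint, character(), tau)
  i <- d$arm == arm
  if (sum(d$event[i]) < 1) stop("no events in arm ", arm)
  Xg <- matrix(grid, ncol = 1, dimnames = list(NULL, "q"))
  f <- cox_quick(d$X[i, , drop = FALSE], d$time[i], d$event[i])
  if (is.null(f)) stop("Cox fit failed for gene ", gene, " in arm ", arm)
  est <- rms_quick(f, Xg, tau)
  lower <- upper <- rep(NA_real_, length(grid))
  if (B > 0) {
    set.seed(seed)
    idx <- which(i)
    boot <- matrix(NA_real_, B, length(grid))
    for (b in seq_len(B)) {
      j <- sample(idx, length(idx), replace = TRUE)
      fb <- cox_quick(d$X[j, , drop = FALSE], d$time[j], d$event[j])
      if (!is.null(fb)) boot[b, ] <- rms_quick(fb, Xg, tau)
    }
    a <- (1 - conf_level) / 2
    lower <- apply(boot, 2, quantile, probs = a, na.rm = TRUE)
    upper <- apply(boot, 2, quantile, probs = 1 - a, na.rm = TRUE)
  }
  structure(data.frame(q = grid, rms = est, lower = lower, upper = upper),
            gene = gene, arm = arm, endpoint = toupper(endpoint),
            platform = attr(expr, "platform"), tau = tau, beta = f$beta[1],
            class = c("rms_curve", "data.frame"))
}

#' @export
plot.rms_curve <- function(x, col = "steelblue", add = FALSE, ...) {
  if (!add) {
    plot(x$q, x$rms, type = "n", ylim = c(0, attr(x, "tau")),
         xlab = "Relative expression quantile",
         ylab = sprintf("RMS %s (months)", attr(x, "endpoint")), ...)
  }
  if (!all(is.na(x$lower))) {
    graphics::polygon(c(x$q, rev(x$q)), c(x$lower, rev(x$upper)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  graphics::lines(x$q, x$rms, col = col, lwd = 2)
  invisible(x)
}

#' Covariate-adjusted per-case RMS within each arm
#'
#' Fits, within each chemotherapy arm, a multivariate Cox model of the
#' endpoint on the relative expression quantile plus clinical covariates,
#' and integrates each case's predicted survival to the restriction time.
#' These per-case RMS values feed the quantile-window comparison.
#'
#' @inheritParams rms_curve
#' @param covariates adjustment covariates.
#' @return data frame `case_id`, `arm`, `q`, `rms`; the fitted per-arm
#'   models and design data are attached as attribute `data` for reuse by
#'   the permutation test.
#' @export
adjusted_rms_per_case <- function(clinical, expr, gene,
                                  endpoint = c("pfs", "os"),
                                  covariates = c("age", "stage", "grade"),
                                  tau = 60) {
  endpoint <- match.arg(endpoint)
  d <- prep_gene_data(clinical, expr, gene, endpoint, covariates, tau)
  rmsv <- rep(NA_real_, length(d$time))
  for (a in unique(d$arm)) {
    i <- d$arm == a
    f <- cox_quick(d$X[i, , drop = FALSE], d$time[i], d$event[i])
    if (is.null(f)) stop("Cox fit failed in arm ", a, " for gene ", gene)
    rmsv[i] <- rms_quick(f, d$X[i, , drop = FALSE], tau)
  }
  structure(data.frame(case_id = d$case_id, arm = d$arm, q = d$q, rms = rmsv,
                       stringsAsFactors = FALSE),
            data = d, gene = gene, endpoint = toupper(endpoint),
            platform = d$platform, tau = tau)
}

#' IP-minus-IV difference in mean adjusted RMS within a quantile window
#'
#' Selects the cases whose relative expression quantile lies in the closed
#' window and returns the difference in mean per-case adjusted RMS,
#' IP minus IV.
#'
#' @param percase an [adjusted_rms_per_case()] result.
#' @param window `c(lo, hi)` inside `[0, 1]`, `lo < hi`; both ends closed.
#' @return list: `delta` (months; `NA` with `computable = FALSE` when a
#'   window is empty in either arm), `n_ip`, `n_iv`, `members` (row index
#'   into `percase`).
#' @export
window_delta <- function(percase, window = c(0.9, 1)) {
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= 1)
  m <- which(percase$q >= window[1] & percase$q <= window[2])
  n_ip <- sum(percase$arm[m] == "IP"); n_iv <- sum(percase$arm[m] == "IV")
  if (n_ip == 0 || n_iv == 0) {
    return(list(delta = NA_real_, n_ip = n_ip, n_iv = n_iv, members = m,
                computable = FALSE))
  }
  delta <- mean(percase$rms[m][percase$arm[m] == "IP"]) -
    mean(percase$rms[m][percase$arm[m] == "IV"])
  list(delta = delta, n_ip = n_ip, n_iv = n_iv, members = m,
       computable = TRUE)
}

#' Permutation test of a group difference in fixed per-case values
#'
#' Shuffles arm labels over a fixed vector of per-case values and compares
#' the observed IP-minus-IV mean difference against the permutation
#' distribution; two-tailed `p = (1 + #{|D*| >= |D|}) / (n_perm + 1)`.
#' With `exact = TRUE` all distinct label assignments are enumerated and
#' `p` is the exact proportion with `|D*| >= |D|` (the identity assignment
#' counts, so `p > 0`). This is the label-permutation core; note that when
#' the values are model predictions the [test_window_permutation()] refit
#' mode is the calibrated test.
#'
#' @param values per-case values (e.g. adjusted RMS, months).
#' @param arm label vector, `"IP"`/`"IV"`.
#' @param n_perm permutation replicates.
#' @param seed permutation seed.
#' @param exact enumerate all `choose(n, n_ip)` assignments instead.
#' @return list: `delta`, `p_value`, `n_perm` (or number of enumerated
#'   assignments), `n_ip`, `n_iv`, `seed`, `degenerate`.
#' @export
permutation_test <- function(values, arm, n_perm = 10000, seed = 1L,
                             exact = FALSE) {
  stopifnot(length(values) == length(arm))
  is_ip <- arm == "IP"
  n1 <- sum(is_ip); n0 <- sum(!is_ip); n <- n1 + n0
  if (n1 < 1 || n0 < 1) stop("need at least one member per arm")
  dobs <- mean(values[is_ip]) - mean(values[!is_ip])
  if (choose(n, n1) < 2) {
    return(list(delta = dobs, p_value = 1, n_perm = 0L, n_ip = n1, n_iv = n0,
                seed = seed, degenerate = TRUE))
  }
  if (exact) {
    sets <- combn(n, n1)
    tot <- sum(values)
    dstar <- apply(sets, 2, function(ix) {
      s1 <- sum(values[ix]); s1 / n1 - (tot - s1) / n0
    })
    p <- mean(abs(dstar) >= abs(dobs) - 1e-12)
    return(list(delta = dobs, p_value = p, n_perm = ncol(sets), n_ip = n1,
                n_iv = n0, seed = seed, degenerate = FALSE, exact = TRUE))
  }
  set.seed(seed)
  tot <- sum(values)
  dstar <- vapply(seq_len(n_perm), function(b) {
    ix <- sample.int(n, n1)
    s1 <- sum(values[ix])
    s1 / n1 - (tot - s1) / n0
  }, 0)
  p <- (1 + sum(abs(dstar) >= abs(dobs) - 1e-12)) / (n_perm + 1)
  list(delta = dobs, p_value = p, n_perm = n_perm, n_ip = n1, n_iv = n0,
       seed = seed, degenerate = FALSE, exact = FALSE)
}

## recompute the window delta for one label assignment by refitting the
## per-arm Cox models (labels outside the window stay fixed)
refit_window_delta <- function(d, arm_labels, members, tau) {
  rms_m <- rep(NA_real_, length(members))
  for (a in c("IP", "IV")) {
    i <- arm_labels == a
    f <- cox_quick(d$X[i, , drop = FALSE], d$time[i], d$event[i])
    if (is.null(f)) return(NA_real_)
    mi <- members[arm_labels[members] == a]
    rms_m[match(mi, members)] <- rms_quick(f, d$X[mi, , drop = FALSE], tau)
  }
  mean(rms_m[arm_labels[members] == "IP"]) -
    mean(rms_m[arm_labels[members] == "IV"])
}

#' Quantile-window permutation test of the IP-minus-IV RMS difference
#'
#' End-to-end test for one gene, endpoint, platform and expression window:
#' normalizes expression over the pooled analyzed cohort, computes per-case
#' Cox-adjusted RMS within each arm, takes the observed IP-minus-IV mean
#' difference among window members, and tests it by permuting the arm
#' labels of window members.
#'
#' Two permutation modes are provided. `"refit"` (default) refits the
#' per-arm Cox models under every permuted labeling before recomputing the
#' window difference, so the permutation distribution reflects the full
#' estimation pipeline; this is the calibrated test. `"fixed"` holds the
#' observed per-case RMS values fixed and only shuffles labels; it is much
#' faster but anticonservative, because per-arm model predictions carry
#' arm-level estimation noise that label shuffling cannot reproduce (see
#' the methods vignette for measurements).
#'
#' @inheritParams adjusted_rms_per_case
#' @param window closed quantile window `c(lo, hi)`.
#' @param n_perm permutations (10000 for reported analyses; reduce for
#'   exploration).
#' @param seed permutation seed.
#' @param mode `"refit"` or `"fixed"`.
#' @param exact enumerate all label assignments (refit or fixed according
#'   to `mode`); intended for small windows.
#' @return class `perm_result` (one-row data frame): gene, platform,
#'   endpoint, window bounds, `delta` (months), `p_value`, `n_perm`,
#'   `n_ip`, `n_iv`, `mode`, `seed`, `computable`.
#' @export
test_window_permutation <- function(clinical, expr, gene,
                                    endpoint = c("pfs", "os"),
                                    window = c(0.9, 1),
                                    covariates = c("age", "stage", "grade"),
                                    n_perm = 10000, seed = 1L,
                                    mode = c("refit", "fixed"),
                                    exact = FALSE, tau = 60) {
  endpoint <- match.arg(endpoint); mode <- match.arg(mode)
  percase <- adjusted_rms_per_case(clinical, expr, gene, endpoint,
                                   covariates, tau)
  d <- attr(percase, "data")
  wd <- window_delta(percase, window)
  res <- data.frame(gene = gene, platform = attr(percase, "platform"),
                    endpoint = toupper(endpoint),
                    q_lo = window[1], q_hi = window[2],
                    delta = wd$delta, p_value = NA_real_,
                    n_perm = 0L, n_ip = wd$n_ip, n_iv = wd$n_iv,
                    mode = mode, seed = seed, computable = wd$computable,
                    stringsAsFactors = FALSE)
  class(res) <- c("perm_result", "data.frame")
  if (!wd$computable) return(res)
  members <- wd$members
  if (mode == "fixed") {
    pt <- permutation_test(percase$rms[members], percase$arm[members],
                           n_perm = n_perm, seed = seed, exact = exact)
    res$p_value <- pt$p_value
    res$n_perm <- pt$n_perm
    if (pt$degenerate) res$p_value <- 1
    return(res)
  }
  ## refit mode
  labels0 <- d$arm
  n_m <- length(members); n1 <- wd$n_ip
  if (choose(n_m, n1) < 2) {
    res$p_value <- 1
    return(res)
  }
  if (exact) {
    sets <- combn(n_m, n1)
    dstar <- apply(sets, 2, function(ix) {
      lab <- labels0
      lab[members] <- "IV"
      lab[members[ix]] <- "IP"
      refit_window_delta(d, lab, members, tau)
    })
    res$p_value <- mean(abs(dstar) >= abs(wd$delta) - 1e-12, na.rm = TRUE)
    res$n_perm <- ncol(sets)
    return(res)
  }
  set.seed(seed)
  dstar <- vapply(seq_len(n_perm), function(b) {
    lab <- labels0
    lab[members] <- sample(labels0[members])
    refit_window_delta(d, lab, members, tau)
  }, 0)
  res$p_value <- (1 + sum(abs(dstar) >= abs(wd$delta) - 1e-12, na.rm = TRUE)) /
    (n_perm + 1)
  res$n_perm <- n_perm
  res
}

#' Candidate-biomarker calls from dual-platform window tests
#'
#' Encodes the selection logic for candidate biomarkers of (lack of) IP
#' benefit: within a window, a platform flags a gene when IP survival is
#' either significantly *decreased* relative to IV (`delta < 0` with
#' `p < alpha`) or *not significantly different* (`p >= alpha`); a clear
#' significant IP benefit (`delta > 0`, `p < alpha`) does not flag. A gene
#' is a candidate for an endpoint and window when both the microarray and
#' RNA-Seq analyses flag it.
#'
#' @param micro,rnaseq `perm_result` tables covering the same
#'   gene/endpoint/window combinations.
#' @param alpha permutation significance threshold.
#' @return data frame: gene, endpoint, window, per-platform delta/p/flag,
#'   `candidate`.
#' @export
call_candidates <- function(micro, rnaseq, alpha = 0.05) {
  key <- function(x) paste(x$gene, x$endpoint, x$q_lo, x$q_hi, sep = "|")
  m <- micro; r <- rnaseq
  common <- intersect(key(m), key(r))
  flag <- function(delta, p, computable) {
    ifelse(!computable | is.na(p), NA,
           (delta < 0 & p < alpha) | p >= alpha)
  }
  rows <- lapply(common, function(k) {
    mi <- m[key(m) == k, ][1, ]; ri <- r[key(r) == k, ][1, ]
    fm <- flag(mi$delta, mi$p_value, mi$computable)
    fr <- flag(ri$delta, ri$p_value, ri$computable)
    data.frame(gene = mi$gene, endpoint = mi$endpoint,
               q_lo = mi$q_lo, q_hi = mi$q_hi,
               delta_microarray = mi$delta, p_microarray = mi$p_value,
               delta_rnaseq = ri$delta, p_rnaseq = ri$p_value,
               flagged_microarray = fm, flagged_rnaseq = fr,
               candidate = isTRUE(fm) & isTRUE(fr),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), endpoint = character(),
               q_lo = numeric(), q_hi = numeric(),
               delta_microarray = numeric(), p_microarray = numeric(),
               delta_rnaseq = numeric(), p_rnaseq = numeric(),
               flagged_microarray = logical(), flagged_rnaseq = logical(),
               candidate = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
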