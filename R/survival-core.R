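## Survival machinery behind the pipeline: Kaplan-Meier and log-rank wrappers,
## covariate-adjusted Cox fits with a Breslow-type baseline cumulative hazard,
## predicted survival step functions, and exact restricted-mean integration.

#' Kaplan-Meier curve
#'
#' Product-limit estimate with a Greenwood-based (log-transformed) 95%
#' confidence band. The median is read directly off the step function as the
#' first event time at which survival drops to 0.5 or below, with no
#' interpolation; it is `NA` when the curve never reaches 0.5.
#'
#' @param time,event numeric times (months) and 0/1 or logical event
#'   indicators.
#' @param conf_level confidence level for the band.
#' @return object of class `km_curve`: data frame columns `time`, `n_risk`,
#'   `n_event`, `surv`, `lower`, `upper`; attributes `median` and `n`.
#' @export
km_fit <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  event <- as.integer(event)
  if (any(is.na(time)) || any(is.na(event))) stop("missing survival data")
  if (any(time < 0)) stop("negative survival time")
  if (all(time == 0 & event == 0)) stop("all observations censored at 0")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log", conf.int = conf_level)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv,
                    lower = ifelse(is.na(sf$lower), 0, sf$lower),
                    upper = ifelse(is.na(sf$upper), 1, sf$upper))
  med <- if (any(out$surv <= 0.5)) min(out$time[out$surv <= 0.5]) else NA_real_
  structure(out, median = med, n = length(time),
            class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, median = %s months\n",
              attr(x, "n"), sum(x$n_event > 0),
              format(attr(x, "median"))))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event survival data as in [km_fit()].
#' @param group two-level grouping vector.
#' @return list with `statistic` (chi-square, 1 df) and `p_value` (two-tailed).
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) < 1)) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  sd0 <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  chisq <- unname(sd0$chisq)
  list(statistic = chisq, df = 1L, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

## Breslow-type baseline cumulative hazard at the fitted coefficients:
## H0(t) = sum over event times <= t of d_i / sum_{at risk} exp(lp).
breslow_cumhaz <- function(time, event, lp) {
  o <- order(time)
  time <- time[o]; event <- as.integer(event)[o]; w <- exp(lp[o])
  # risk-set denominators via reverse cumulative sum
  denom_all <- rev(cumsum(rev(w)))
  et <- time[event == 1]
  r <- rle(et)
  ut <- r$values; d <- r$lengths
  den <- denom_all[match(ut, time)]
  data.frame(time = ut, hazard = cumsum(d / den))
}

#' Covariate-adjusted Cox proportional-hazards fit
#'
#' Maximizes the Efron-tie-corrected partial likelihood (Breslow correction
#' available via `ties`) through `survival::coxph`, and computes a
#' Breslow-type baseline cumulative hazard at the fitted coefficients, taken
#' at covariate value zero (uncentered). Callers must pass a complete-case
#' covariate table (see [analysis_subset()]); missing values are an error.
#'
#' @param time,event survival data (months, 0/1).
#' @param covariates numeric matrix or data frame of covariates (already
#'   encoded; see [encode_covariates()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level level for hazard-ratio confidence intervals.
#' @return object of class `cox_fit`: `coefficients` data frame (`term`,
#'   `beta`, `se`, `hr`, `lower`, `upper`, `p`), `basehaz` (Breslow-type
#'   cumulative hazard step function), `n`, `n_event`, `ties`, plus an
#'   `unstable` flag when coefficients appear to diverge (separation).
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (anyNA(X) || anyNA(time) || anyNA(event)) {
    stop("missing values: apply analysis_subset() before fitting")
  }
  event <- as.integer(event)
  if (sum(event) < 1) stop("no events in analysis subset")
  unstable <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations|beta may be",
                conditionMessage(w))) {
        unstable <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!isTRUE(fit$info$convergence == 0) && is.null(fit$coefficients)) {
    stop("Cox fit failed to converge")
  }
  beta <- unname(coef(fit))
  aliased <- is.na(beta)
  # constant/collinear columns: no estimable effect, excluded from the
  # linear predictor; reported with NA standard error
  beta[aliased] <- 0
  se <- sqrt(diag(fit$var))  # full-dimension, zeros at aliased positions
  se[aliased] <- NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = colnames(X), beta = beta, se = se,
                      hr = exp(beta), lower = exp(beta - z * se),
                      upper = exp(beta + z * se),
                      p = 2 * pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE)
  if (unstable) pipe_log("cox_fit: unstable estimate (possible separation)")
  lp <- as.vector(X %*% beta)
  structure(list(coefficients = coefs, basehaz = breslow_cumhaz(time, event, lp),
                 n = length(time), n_event = sum(event), ties = ties,
                 conf_level = conf_level, unstable = unstable,
                 terms = colnames(X)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n, x$n_event,
              x$ties, if (x$unstable) " [unstable]" else ""))
  print(cbind(x$coefficients[1], round(x$coefficients[-1], digits)))
  invisible(x)
}

#' Predicted survival step function from a Cox fit
#'
#' `S(t | x) = exp(-H0(t) * exp(beta' x))` evaluated on the fit's event-time
#' grid. With `newx = 0` this is the baseline survival.
#'
#' @param fit a [cox_fit()] object.
#' @param newx covariate vector matching the fit's terms.
#' @return object of class `surv_step`: list with `time` and `surv`
#'   (right-continuous step function, starting from S(0) = 1).
#' @export
predicted_survival <- function(fit, newx) {
  stopifnot(inherits(fit, "cox_fit"))
  newx <- as.numeric(newx)
  if (length(newx) != length(fit$terms)) {
    stop("covariate vector length ", length(newx), " does not match fit (",
         length(fit$terms), " terms)")
  }
  risk <- exp(sum(fit$coefficients$beta * newx))
  structure(list(time = fit$basehaz$time,
                 surv = exp(-fit$basehaz$hazard * risk)),
            class = "surv_step")
}

#' Restricted mean survival time
#'
#' Exact area under a right-continuous survival step function from 0 to
#' `tau`: the sum of step widths times heights, with the last value carried
#' forward to `tau`. Works on `surv_step` objects, `km_curve` objects, or any
#' list with `time` and `surv` components.
#'
#' @param surv survival step function.
#' @param tau restriction time in months (default 60).
#' @return restricted mean in months, in `[0, tau]`.
#' @export
rms <- function(surv, tau = 60) {
  stopifnot(tau >= 0)
  if (tau == 0) return(0)
  time <- surv$time
  s <- surv$surv
  if (any(s < 0 | s > 1)) stop("survival values outside [0, 1]")
  o <- order(time)
  time <- time[o]; s <- s[o]
  keep <- time <= tau
  grid <- c(0, time[keep], tau)
  height <- c(1, s[keep])
  sum(diff(grid) * height)
}

## fast numeric core used inside bootstrap/permutation loops
rms_num <- function(time, surv, tau) {
  keep <- time <= tau
  sum(diff(c(0, time[keep], tau)) * c(1, surv[keep]))
}

## Low-overhead Cox fit for resampling loops: coefficients via
## survival::coxph.fit, baseline via breslow_cumhaz. Returns NULL when the
## fit fails (degenerate resample).
cox_quick <- function(X, time, event, ties = "efron") {
  y <- survival::Surv(time, event)
  f <- tryCatch(
    suppressWarnings(survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                                         init = NULL,
                                         control = survival::coxph.control(),
                                         weights = NULL, method = ties,
                                         rownames = NULL)),
    error = function(e) NULL)
  if (is.null(f) || all(is.na(f$coefficients))) return(NULL)
  beta <- as.numeric(f$coefficients)
  # aliased (constant/collinear) columns come back NA; treat as dropped
  beta[is.na(beta)] <- 0
  lp <- as.vector(X %*% beta)
  bh <- breslow_cumhaz(time, event, lp)
  list(beta = beta, time = bh$time, hazard = bh$hazard)
}

## predicted RMS values for rows of X under a cox_quick fit
rms_quick <- function(qf, X, tau) {
  risks <- exp(as.vector(X %*% qf$beta))
  keep <- qf$time <= tau
  widths <- diff(c(0, qf$time[keep], tau))
  h <- c(0, qf$hazard[keep])
  # columns: cases; rows: step segments
  as.vector(widths %*% exp(outer(h, risks, function(a, b) -a * b)))
}

#' Encode clinical covariates for Cox regression
#'
#' Stage and grade enter as ordered integer scores, cytoreduction as a binary
#' indicator (suboptimal = 1), race as one-hot indicators against the most
#' frequent level, age as-is. The encoding is a modelling choice; any numeric
#' column is passed through unchanged.
#'
#' @param clinical cohort data frame (complete cases for `covariates`).
#' @param covariates clinical fields to encode.
#' @return numeric matrix with one row per record.
#' @export
encode_covariates <- function(clinical, covariates = c("age", "stage", "grade")) {
  stopifnot(all(covariates %in% names(clinical)))
  cols <- list()
  for (v in covariates) {
    x <- clinical[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else if (v %in% c("stage", "grade")) {
      cols[[v]] <- as.integer(factor(x, levels = levels(x), ordered = TRUE))
    } else if (v == "cytoreduction") {
      cols[[v]] <- as.integer(x == "suboptimal")
    } else {
      xf <- droplevels(factor(x))
      ref <- names(which.max(table(xf)))
      for (lv in setdiff(levels(xf), ref)) {
        cols[[paste0(v, "_", lv)]] <- as.integer(xf == lv)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}
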