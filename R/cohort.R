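## Clinical cohort input, truncation, listwise deletion and Table-1-style
## descriptive summaries.

STAGE_LEVELS <- c("IIA/B/C", "IIIA/B", "IIIC", "IV")
GRADE_LEVELS <- c("G2", "G3")
CYTO_LEVELS  <- c("optimal", "suboptimal")

#' Read a clinical table into a validated cohort data frame
#'
#' Reads a TSV/CSV clinical table (one row per case) and returns a cohort
#' data frame with canonical columns: `case_id`, `route` (`"IP"` if the case
#' received any intraperitoneal chemotherapy, else `"IV"`), `age`, `stage`
#' (ordered factor IIA/B/C < IIIA/B < IIIC < IV), `grade`,
#' `cytoreduction` (optimal means residual disease <= 10 mm), `race`,
#' `pfs_months`/`pfs_event` and `os_months`/`os_event`. Optional fields that
#' fail to parse become `NA`; rows lacking a case id or a route, and cases
#' flagged as neoadjuvant, are rejected with a logged reason.
#'
#' @param path path to a delimited file with a header row. `.csv` is read
#'   comma-separated, anything else tab-separated.
#' @param schema named character vector mapping canonical field names to the
#'   file's column names, e.g. `c(case_id = "bcr_patient_barcode", ...)`.
#'   Fields omitted from the schema (other than `case_id` and `route`) are
#'   filled with `NA`. An optional `neoadjuvant` mapping names a
#'   logical/0-1 column used to exclude neoadjuvant cases.
#' @return data frame of clinical records, with attributes `n_rejected` and
#'   `rejected` (data frame of case id / reason).
#' @export
load_clinical <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "", "null"))
  canonical <- c("case_id", "route", "age", "stage", "grade", "cytoreduction",
                 "race", "pfs_months", "pfs_event", "os_months", "os_event")
  schema <- schema %||% setNames(canonical, canonical)
  for (f in c("case_id", "route")) {
    if (!f %in% names(schema) || !schema[[f]] %in% names(raw)) {
      stop("schema error: required column for '", f, "' not found in ", path)
    }
  }
  pick <- function(f) {
    if (f %in% names(schema) && schema[[f]] %in% names(raw)) raw[[schema[[f]]]]
    else rep(NA, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  bool <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "t", "yes", "event", "progressed", "deceased")] <- TRUE
    out[x %in% c("0", "false", "f", "no", "censored", "living")] <- FALSE
    out
  }
  route_raw <- toupper(trimws(as.character(pick("route"))))
  rec <- data.frame(
    case_id = as.character(pick("case_id")),
    # a case is IP if any administered route mentions IP (IP group is IP +/- IV)
    route = ifelse(grepl("IP", route_raw), "IP",
                   ifelse(grepl("IV", route_raw), "IV", NA)),
    age = num(pick("age")),
    stage = factor(as.character(pick("stage")), levels = STAGE_LEVELS, ordered = TRUE),
    grade = factor(as.character(pick("grade")), levels = GRADE_LEVELS),
    cytoreduction = factor(as.character(pick("cytoreduction")), levels = CYTO_LEVELS),
    race = factor(as.character(pick("race"))),
    pfs_months = num(pick("pfs_months")),
    pfs_event = bool(pick("pfs_event")),
    os_months = num(pick("os_months")),
    os_event = bool(pick("os_event")),
    stringsAsFactors = FALSE
  )
  neo <- bool(pick("neoadjuvant"))
  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(rec$case_id) | rec$case_id == ""] <- "missing case_id"
  reason[is.na(reason) & is.na(rec$route)] <- "missing or unrecognized route"
  reason[is.na(reason) & !is.na(neo) & neo] <- "neoadjuvant chemotherapy"
  reason[is.na(reason) & duplicated(rec$case_id)] <- "duplicate case_id"
  keep <- is.na(reason)
  if (anyDuplicated(rec$case_id[keep])) stop("input error: duplicate case_id")
  bad_t <- keep & ((rec$pfs_months < 0) %in% TRUE | (rec$os_months < 0) %in% TRUE)
  if (any(bad_t)) stop("input error: negative survival time")
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "rejected") <- data.frame(case_id = rec$case_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  pipe_log("load_clinical: %d records kept, %d rejected", nrow(out), sum(!keep))
  for (f in setdiff(canonical, c("case_id", "route"))) {
    nmiss <- sum(is.na(out[[f]]))
    if (nmiss > 0) pipe_log("load_clinical: field '%s' missing for %d cases", f, nmiss)
  }
  out
}

#' Administratively truncate survival endpoints at a horizon
#'
#' Times beyond `horizon` months are set to `horizon` and the corresponding
#' event indicators to censored; events at or before the horizon are kept.
#' Truncation is idempotent. The default horizon matches the 60-month
#' restriction time used for all restricted-mean-survival calculations, so
#' long survivors do not dominate route comparisons.
#'
#' @param clinical cohort data frame (see [load_clinical()]).
#' @param horizon months, > 0.
#' @return the cohort with `pfs_months`/`pfs_event` and `os_months`/`os_event`
#'   truncated.
#' @export
truncate_survival <- function(clinical, horizon = 60) {
  stopifnot(horizon > 0)
  for (ep in c("pfs", "os")) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    t <- clinical[[tcol]]
    if (any(t < 0, na.rm = TRUE)) stop("input error: negative survival time")
    over <- !is.na(t) & t > horizon
    clinical[[ecol]][over] <- FALSE
    clinical[[tcol]][over] <- horizon
  }
  clinical
}

#' Listwise-deletion analysis subset
#'
#' Returns the records with all `required` fields non-missing, mirroring the
#' per-model exclusion of incompletely reported cases. The omitted count is
#' logged and attached as attribute `n_omitted`.
#'
#' @param clinical cohort data frame.
#' @param required character vector of column names the analysis needs.
#' @export
analysis_subset <- function(clinical, required = character()) {
  stopifnot(all(required %in% names(clinical)))
  if (length(required) == 0) {
    attr(clinical, "n_omitted") <- 0L
    return(clinical)
  }
  ok <- complete.cases(clinical[, required, drop = FALSE])
  out <- clinical[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_omitted") <- sum(!ok)
  pipe_log("analysis_subset: %d omitted (missing %s)", sum(!ok),
           paste(required, collapse = "/"))
  out
}

## Fisher's exact for 2 x k; exact when feasible, seeded Monte Carlo otherwise
fisher_2xk <- function(tab, mc_threshold = 1e6, seed = 1L) {
  if (prod(dim(tab)) <= 4 || sum(tab) <= 200 && prod(dim(tab)) <= 12) {
    ft <- tryCatch(fisher.test(tab, workspace = 2e7),
                   error = function(e) NULL)
    if (!is.null(ft)) return(ft)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
}

#' Descriptive cohort comparison by chemotherapy route
#'
#' Produces a Table-1-style comparison of the IP and IV arms. Continuous
#' variables are compared with a two-sample t-test, ordered categorical
#' variables (stage, grade) with a Kruskal-Wallis test on the level scores
#' (standard tie correction), and unordered categorical variables with
#' Fisher's exact test (exact enumeration when feasible, seeded Monte Carlo
#' otherwise). Missing values are excluded per comparison, so percentages use
#' non-missing denominators and cell counts sum to at most the arm size.
#'
#' @param clinical cohort data frame.
#' @param variables variables to summarize; defaults to the standard set.
#' @param seed seed for Monte Carlo Fisher p-values on large tables.
#' @return data frame with one row per variable (and per level for
#'   categorical variables): arm summaries, test name, statistic and p-value.
#'   A variable entirely missing in one arm yields `computable = FALSE`.
#' @export
summarize_cohort <- function(clinical,
                             variables = c("age", "stage", "grade", "race",
                                           "cytoreduction"),
                             seed = 1L) {
  stopifnot(all(variables %in% names(clinical)),
            all(table(clinical$route) >= 2))
  route <- factor(clinical$route, levels = c("IP", "IV"))
  rows <- list()
  for (v in variables) {
    x <- clinical[[v]]
    ok <- !is.na(x)
    computable <- all(tapply(ok, route, sum) > 0)
    if (is.numeric(x)) {
      test <- "t-test"
      if (computable) {
        tt <- t.test(x[ok & route == "IP"], x[ok & route == "IV"])
        stat <- unname(tt$statistic); p <- tt$p.value
      } else stat <- p <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, test = test,
        ip_n = sum(ok & route == "IP"), iv_n = sum(ok & route == "IV"),
        ip_value = mean(x[ok & route == "IP"]),
        iv_value = mean(x[ok & route == "IV"]),
        statistic = stat, p_value = p, computable = computable,
        stringsAsFactors = FALSE)
    } else {
      xf <- droplevels(factor(x[ok]))
      rf <- droplevels(route[ok])
      computable <- computable && nlevels(rf) == 2 && nlevels(xf) >= 2
      if (is.ordered(x)) {
        test <- "Kruskal-Wallis"
        if (computable) {
          kw <- kruskal.test(as.integer(factor(x[ok], levels = levels(x),
                                               ordered = TRUE)), rf)
          stat <- unname(kw$statistic); p <- kw$p.value
        } else stat <- p <- NA_real_
      } else {
        test <- "Fisher's exact"
        if (computable) {
          ft <- fisher_2xk(table(rf, xf), seed = seed)
          stat <- NA_real_; p <- ft$p.value
        } else stat <- p <- NA_real_
      }
      tab <- table(route[ok], factor(x[ok], levels = levels(droplevels(factor(x[ok])))))
      denom <- rowSums(tab)
      for (lv in colnames(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, test = test,
          ip_n = tab["IP", lv], iv_n = tab["IV", lv],
          ip_value = 100 * tab["IP", lv] / denom[["IP"]],
          iv_value = 100 * tab["IV", lv] / denom[["IV"]],
          statistic = stat, p_value = p, computable = computable,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
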