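## End-to-end orchestration: cohort -> route survival comparison ->
## PFS-stratified discovery -> dual-platform validation -> quantile-window
## RMS permutation -> candidate calls, with seeded stages, TSV/JSON tables
## and a run manifest.

#' Pipeline configuration
#'
#' All thresholds default to the analysis' reported values: 60-month
#' truncation/restriction, 12-month PFS cutoff, alpha 0.05, windows
#' `[0, 0.1]` and `[0.9, 1]`, 10,000 permutations. Every stochastic stage
#' receives a seed derived from the root seed.
#'
#' @param horizon truncation/restriction time, months.
#' @param pfs_cutoff PFS stratification cutoff, months.
#' @param alpha significance threshold used by discovery, validation and
#'   candidate calling.
#' @param windows list of quantile windows.
#' @param n_perm permutations per window test.
#' @param bootstrap_B bootstrap replicates for RMS curve bands.
#' @param perm_mode `"refit"` (calibrated, default) or `"fixed"` (fast
#'   approximation).
#' @param covariates_route covariates for the route Cox comparison.
#' @param covariates_validation covariates for per-gene validation Cox.
#' @param covariates_rms covariates behind the adjusted per-case RMS.
#' @param gene_universe optional gene list for discovery (default: all
#'   genes on the microarray).
#' @param seed root seed.
#' @export
pipeline_config <- function(horizon = 60, pfs_cutoff = 12, alpha = 0.05,
                            windows = list(c(0, 0.1), c(0.9, 1)),
                            n_perm = 10000, bootstrap_B = 200,
                            perm_mode = c("refit", "fixed"),
                            covariates_route = c("age", "stage", "grade",
                                                 "cytoreduction", "race"),
                            covariates_validation = c("age", "stage", "grade"),
                            covariates_rms = c("age", "stage", "grade"),
                            gene_universe = NULL, seed = 1L) {
  cfg <- list(horizon = horizon, pfs_cutoff = pfs_cutoff, alpha = alpha,
              windows = windows, n_perm = n_perm, bootstrap_B = bootstrap_B,
              perm_mode = match.arg(perm_mode),
              covariates_route = covariates_route,
              covariates_validation = covariates_validation,
              covariates_rms = covariates_rms,
              gene_universe = gene_universe, seed = as.integer(seed))
  stopifnot(cfg$horizon > 0, cfg$pfs_cutoff > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_perm >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Route-level survival comparison
#'
#' For each endpoint: per-arm Kaplan-Meier medians (on the cases with
#' observed outcome data), the two-group log-rank test, and the
#' covariate-adjusted Cox hazard ratio for IP versus IV with its
#' listwise-deletion case counts.
#'
#' @param clinical truncated cohort data frame.
#' @param covariates adjustment covariates for the Cox model.
#' @param conf_level hazard-ratio confidence level.
#' @return data frame with one row per endpoint.
#' @export
compare_routes <- function(clinical,
                           covariates = c("age", "stage", "grade",
                                          "cytoreduction", "race"),
                           conf_level = 0.95) {
  rows <- list()
  for (ep in c("pfs", "os")) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    km_sub <- analysis_subset(clinical, c(tcol, ecol))
    km_omitted <- attr(km_sub, "n_omitted")
    med <- vapply(c("IP", "IV"), function(a) {
      i <- km_sub$route == a
      attr(km_fit(km_sub[[tcol]][i], km_sub[[ecol]][i]), "median")
    }, 0)
    lr <- logrank_test(km_sub[[tcol]], km_sub[[ecol]], km_sub$route)
    cox_sub <- analysis_subset(clinical, c(tcol, ecol, covariates))
    X <- cbind(route_ip = as.integer(cox_sub$route == "IP"),
               encode_covariates(cox_sub, covariates))
    fit <- cox_fit(cox_sub[[tcol]], cox_sub[[ecol]], X,
                   conf_level = conf_level)
    co <- fit$coefficients[1, ]
    rows[[ep]] <- data.frame(
      endpoint = toupper(ep), median_ip = med[["IP"]], median_iv = med[["IV"]],
      logrank_p = lr$p_value, hr = co$hr, hr_lower = co$lower,
      hr_upper = co$upper, cox_p = co$p, n_km = nrow(km_sub),
      n_km_omitted = km_omitted, n_cox = fit$n,
      n_cox_omitted = attr(cox_sub, "n_omitted"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes cohort preparation (truncation), the Table-1-style route
#' comparison, route survival analysis, PFS-stratified discovery on the
#' microarray, per-gene dual-platform Cox validation, and the quantile
#' window RMS permutation stage with candidate calls. Writes
#' `cohort_summary.tsv`, `route_survival.tsv`, `discovery.tsv`,
#' `validation.tsv`, `window_tests.tsv`, `candidates.tsv`, a full-precision
#' `results.json` and a `manifest.json` (seeds, stage case counts, package
#' version) into `outdir`.
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `clinical`,
#'   `microarray`, `rnaseq` (cohort data frame plus two
#'   [expression_matrix()]s).
#' @param config a [pipeline_config()].
#' @param outdir output directory; `NULL` skips writing.
#' @return list with all stage results (invisibly when `outdir` is set).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4)
  names(seeds) <- c("summary", "bootstrap", "perm_micro", "perm_rnaseq")
  clinical <- truncate_survival(cohort$clinical, config$horizon)
  micro <- cohort$microarray; rna <- cohort$rnaseq

  summary_tab <- summarize_cohort(clinical, seed = seeds[["summary"]])
  route_tab <- compare_routes(clinical, config$covariates_route)

  strat <- stratify_pfs(clinical, config$pfs_cutoff)
  de_tests <- gene_ttest(micro, strat, config$gene_universe)
  de <- call_de(de_tests, config$alpha)
  de_table <- attr(de, "table")
  de_genes <- unique(unlist(de))

  validation <- list()
  verdicts <- NULL
  window_tests <- list()
  candidates <- NULL
  if (length(de_genes)) {
    assoc <- list()
    for (pl in c("microarray", "rnaseq")) {
      expr <- if (pl == "microarray") micro else rna
      per_gene <- list()
      for (g in de_genes) {
        arm <- names(de)[vapply(de, function(v) g %in% v, TRUE)][1]
        for (ep in c("pfs", "os")) {
          per_gene[[paste(g, ep)]] <- gene_cox(
            clinical, expr, g, ep, arm = arm,
            covariates = config$covariates_validation)
        }
      }
      assoc[[pl]] <- do.call(rbind, per_gene)
      rownames(assoc[[pl]]) <- NULL
    }
    validation <- assoc
    verdicts <- dual_validate(assoc$microarray, assoc$rnaseq, config$alpha)

    for (pl in c("microarray", "rnaseq")) {
      expr <- if (pl == "microarray") micro else rna
      sd_perm <- if (pl == "microarray") seeds[["perm_micro"]] else
        seeds[["perm_rnaseq"]]
      res <- list()
      k <- 0L
      for (g in de_genes) for (ep in c("pfs", "os")) {
        for (w in config$windows) {
          k <- k + 1L
          res[[k]] <- test_window_permutation(
            clinical, expr, g, ep, window = w,
            covariates = config$covariates_rms, n_perm = config$n_perm,
            seed = (sd_perm + k) %% (.Machine$integer.max - 1L),
            mode = config$perm_mode, tau = config$horizon)
        }
      }
      window_tests[[pl]] <- do.call(rbind, res)
    }
    candidates <- call_candidates(window_tests$microarray,
                                  window_tests$rnaseq, config$alpha)
  } else {
    candidates <- call_candidates(
      data.frame(gene = character(), endpoint = character(), q_lo = numeric(),
                 q_hi = numeric(), delta = numeric(), p_value = numeric(),
                 computable = logical()),
      data.frame(gene = character(), endpoint = character(), q_lo = numeric(),
                 q_hi = numeric(), delta = numeric(), p_value = numeric(),
                 computable = logical()))
  }

  manifest <- list(
    package_version = as.character(packageVersion("rmsperm")),
    seed = config$seed, stage_seeds = as.list(seeds),
    config = unclass(config),
    n_cases = nrow(clinical),
    n_ip = sum(clinical$route == "IP"), n_iv = sum(clinical$route == "IV"),
    pfs_strata = as.list(as.data.frame(attr(strat, "counts"))),
    n_de_genes = lapply(de, length),
    n_candidates = if (is.null(candidates)) 0L else sum(candidates$candidate),
    omitted = list(
      km_pfs = route_tab$n_km_omitted[route_tab$endpoint == "PFS"],
      km_os = route_tab$n_km_omitted[route_tab$endpoint == "OS"],
      cox_pfs = route_tab$n_cox_omitted[route_tab$endpoint == "PFS"],
      cox_os = route_tab$n_cox_omitted[route_tab$endpoint == "OS"]))

  results <- list(summary = summary_tab, route_survival = route_tab,
                  discovery = de_table, de_genes = de,
                  validation = validation, verdicts = verdicts,
                  window_tests = window_tests, candidates = candidates,
                  manifest = manifest)
  if (!is.null(outdir)) {
    render_tables(results, outdir)
    return(invisible(results))
  }
  results
}

round_df <- function(df, digits) {
  for (col in names(digits)) {
    if (col %in% names(df)) df[[col]] <- round(df[[col]], digits[[col]])
  }
  df
}

#' Write pipeline result tables
#'
#' Human-readable TSVs are rounded near the precision the analysis tables
#' print (deltas to 0.1 months, p-values to 4 digits, hazard ratios to 2);
#' `results.json` keeps full precision.
#'
#' @param results a [run_pipeline()] result list.
#' @param outdir output directory (created if needed).
#' @export
render_tables <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    write.table(df, file.path(outdir, file), sep = "\t", row.names = FALSE,
                quote = FALSE, na = "")
  }
  wt(round_df(results$summary, c(ip_value = 1, iv_value = 1, statistic = 3,
                                 p_value = 4)), "cohort_summary.tsv")
  wt(round_df(results$route_survival,
              c(median_ip = 1, median_iv = 1, logrank_p = 4, hr = 2,
                hr_lower = 2, hr_upper = 2, cox_p = 4)), "route_survival.tsv")
  wt(round_df(results$discovery, c(t = 3, p = 4, p_adj = 4, fold_change = 3,
                                   mean_ge12 = 3, mean_lt12 = 3)),
     "discovery.tsv")
  if (length(results$validation)) {
    val <- do.call(rbind, results$validation)
    rownames(val) <- NULL
    wt(round_df(val, c(hr = 2, lower = 2, upper = 2, p = 4)), "validation.tsv")
    wt(results$verdicts, "verdicts.tsv")
  }
  if (length(results$window_tests)) {
    wtab <- do.call(rbind, results$window_tests)
    rownames(wtab) <- NULL
    wt(round_df(wtab, c(delta = 1, p_value = 4)), "window_tests.tsv")
  }
  wt(round_df(results$candidates,
              c(delta_microarray = 1, p_microarray = 4, delta_rnaseq = 1,
                p_rnaseq = 4)), "candidates.tsv")
  jsonlite::write_json(results[setdiff(names(results), "manifest")],
                       file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  jsonlite::write_json(results$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(outdir)
}
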