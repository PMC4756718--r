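## PFS-stratified differential expression: within each chemotherapy arm,
## cases are split at 12 months of progression-free survival (tumors
## progressing earlier are taken as chemoresistant) and each gene is compared
## between strata by a two-sample t-test with Benjamini-Hochberg adjustment.

#' Stratify cases by progression-free survival at a cutoff
#'
#' Cases with observed PFS below `cutoff` months go to stratum `"lt12"`,
#' cases at or above it to `"ge12"`; the boundary belongs to the upper
#' stratum. The observed (possibly censored) PFS time is used; cases with
#' missing PFS are left unassigned.
#'
#' @param clinical cohort data frame.
#' @param cutoff months, > 0 (default 12).
#' @return data frame `case_id`, `arm`, `stratum`, one row per case with
#'   non-missing PFS; per-arm stratum counts in attribute `counts`.
#' @export
stratify_pfs <- function(clinical, cutoff = 12) {
  stopifnot(cutoff > 0)
  ok <- !is.na(clinical$pfs_months)
  out <- data.frame(case_id = clinical$case_id[ok],
                    arm = clinical$route[ok],
                    stratum = ifelse(clinical$pfs_months[ok] < cutoff,
                                     "lt12", "ge12"),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$arm, out$stratum)
  attr(out, "cutoff") <- cutoff
  out
}

#' Per-gene differential expression between PFS strata
#'
#' For each gene and each arm, compares expression between the `ge12` and
#' `lt12` strata with a two-sample t-test (Welch by default; the strata are
#' typically very unbalanced). Fold change is the ratio of arithmetic means,
#' `ge12 / lt12`, on the expression scale supplied. Genes in
#' `gene_universe` but absent from the matrix are skipped with a log
#' message; genes with zero variance in both strata get `t = 0, p = 1` and
#' a `degenerate` flag.
#'
#' @param expr an [expression_matrix()].
#' @param strat a [stratify_pfs()] result.
#' @param gene_universe genes to test (default: all matrix genes). A
#'   stand-in for a pathway-derived gene list.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data frame: `gene`, `arm`, group sizes and means, `t`, `p`,
#'   `fold_change`, `degenerate`.
#' @export
gene_ttest <- function(expr, strat, gene_universe = NULL, var_equal = FALSE) {
  genes <- gene_universe %||% rownames(expr)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes)) {
    pipe_log("gene_ttest: %d genes not in %s matrix, skipped",
             length(missing_genes), attr(expr, "platform"))
    genes <- setdiff(genes, missing_genes)
  }
  strat <- strat[strat$case_id %in% colnames(expr), , drop = FALSE]
  rows <- list()
  for (arm in unique(strat$arm)) {
    lt <- strat$case_id[strat$arm == arm & strat$stratum == "lt12"]
    ge <- strat$case_id[strat$arm == arm & strat$stratum == "ge12"]
    if (length(lt) < 2 || length(ge) < 2) {
      stop("arm ", arm, ": each PFS stratum needs >= 2 samples with expression")
    }
    for (g in genes) {
      x_ge <- expr[g, ge]; x_lt <- expr[g, lt]
      degenerate <- sd(x_ge) == 0 && sd(x_lt) == 0
      if (degenerate) {
        tstat <- 0; p <- 1
      } else {
        tt <- t.test(x_ge, x_lt, var.equal = var_equal)
        tstat <- unname(tt$statistic); p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, arm = arm, n_ge12 = length(ge), n_lt12 = length(lt),
        mean_ge12 = mean(x_ge), mean_lt12 = mean(x_lt),
        t = tstat, p = p, fold_change = mean(x_ge) / mean(x_lt),
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforced (as in
#' `p.adjust(method = "BH")`). Inputs outside `[0, 1]` or non-finite are an
#' error.
#'
#' @param p numeric vector of raw p-values.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(!is.finite(p))) stop("NaN/NA p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes per arm
#'
#' Adjusts the raw t-test p-values within each arm (Benjamini-Hochberg) and
#' returns the genes whose adjusted p falls below `alpha`.
#'
#' @param results a [gene_ttest()] data frame.
#' @param alpha threshold on the adjusted p-value (default 0.05).
#' @return named list of gene vectors, one per arm; the input table with an
#'   added `p_adj` column is attached as attribute `table`.
#' @export
call_de <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) > 0)
  results$p_adj <- NA_real_
  for (arm in unique(results$arm)) {
    i <- results$arm == arm
    results$p_adj[i] <- fdr_adjust(results$p[i])
  }
  out <- lapply(split(results, results$arm),
                function(d) d$gene[d$p_adj < alpha])
  attr(out, "table") <- results
  out
}
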