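## Validation of discovered genes: per-gene Cox regression of PFS and OS on
## expression (entered as a continuous covariate, scaled so hazard ratios
## are per 1 SD of expression) with clinical covariates, run separately on
## the microarray and RNA-Seq platforms, then the dual-platform
## positive-discovery gate.

#' Scale expression values per standard deviation
#'
#' Divides by the sample SD (no centering; Cox partial likelihood is
#' location-invariant) so fitted hazard ratios read per 1 SD of expression.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @export
scale_per_sd <- function(values) {
  s <- sd(values)
  if (length(unique(values)) < 2 || s == 0) {
    stop("zero variance: cannot scale per SD")
  }
  values / s
}

#' Per-gene Cox regression of survival on expression
#'
#' Fits a covariate-adjusted Cox model of the chosen endpoint on one gene's
#' expression within one chemotherapy arm (the validation models are
#' per-arm). Expression enters as a continuous covariate scaled by the SD
#' computed on the analysis subset (after listwise deletion), so the
#' reported hazard ratio is per 1 SD of expression and invariant to linear
#' rescaling of the raw values.
#'
#' @param clinical cohort data frame.
#' @param expr an [expression_matrix()].
#' @param gene gene symbol (must be in `expr`).
#' @param endpoint `"pfs"` or `"os"`.
#' @param arm restrict to one route (`"IP"`/`"IV"`); `NULL` pools both arms.
#' @param covariates clinical covariates to adjust for.
#' @param conf_level hazard-ratio confidence level.
#' @return one-row data frame: `gene`, `platform`, `endpoint`, `arm`, `hr`
#'   (per SD), `lower`, `upper`, `p`, `n_used`, `n_omitted`.
#' @export
gene_cox <- function(clinical, expr, gene, endpoint = c("pfs", "os"),
                     arm = NULL, covariates = c("age", "stage", "grade"),
                     conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  stopifnot(gene %in% rownames(expr))
  if (!is.null(arm)) clinical <- clinical[clinical$route == arm, , drop = FALSE]
  clinical <- clinical[clinical$case_id %in% colnames(expr), , drop = FALSE]
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  sub <- analysis_subset(clinical, c(tcol, ecol, covariates))
  n_omit <- attr(sub, "n_omitted")
  if (nrow(sub) == 0) stop("empty analysis subset for gene ", gene)
  x <- scale_per_sd(expr[gene, sub$case_id])
  X <- cbind(expression = x, encode_covariates(sub, covariates))
  fit <- cox_fit(sub[[tcol]], sub[[ecol]], X, conf_level = conf_level)
  co <- fit$coefficients[fit$coefficients$term == "expression", ]
  data.frame(gene = gene, platform = attr(expr, "platform"),
             endpoint = toupper(endpoint), arm = arm %||% "both",
             hr = co$hr, lower = co$lower, upper = co$upper, p = co$p,
             n_used = fit$n, n_omitted = n_omit, stringsAsFactors = FALSE)
}

#' Dual-platform positive-discovery gate
#'
#' A gene passes one platform when its Cox association reaches `p < alpha`
#' for at least one endpoint (OS and/or PFS) on that platform; a positive
#' discovery requires passing both the microarray and RNA-Seq validations.
#' With `match_endpoint = TRUE` the same endpoint must be significant on
#' both platforms.
#'
#' @param micro,rnaseq [gene_cox()] result tables (rows per gene/endpoint)
#'   for the two platforms.
#' @param alpha significance threshold on the raw Cox p-value.
#' @param match_endpoint require endpoint-matched significance.
#' @return data frame: `gene`, `passed_microarray`, `passed_rnaseq`,
#'   `positive_discovery`, `untestable` (gene missing on a platform).
#' @export
dual_validate <- function(micro, rnaseq, alpha = 0.05, match_endpoint = FALSE) {
  genes <- unique(c(micro$gene, rnaseq$gene))
  rows <- lapply(genes, function(g) {
    m <- micro[micro$gene == g, , drop = FALSE]
    r <- rnaseq[rnaseq$gene == g, , drop = FALSE]
    untestable <- nrow(m) == 0 || nrow(r) == 0
    if (match_endpoint && !untestable) {
      eps <- intersect(m$endpoint[m$p < alpha], r$endpoint[r$p < alpha])
      pm <- any(m$p < alpha); pr <- any(r$p < alpha)
      pos <- length(eps) > 0
    } else {
      pm <- nrow(m) > 0 && any(m$p < alpha)
      pr <- nrow(r) > 0 && any(r$p < alpha)
      pos <- !untestable && pm && pr
    }
    data.frame(gene = g, passed_microarray = pm, passed_rnaseq = pr,
               positive_discovery = pos, untestable = untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
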