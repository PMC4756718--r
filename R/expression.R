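#' Platform-tagged expression matrix
#'
#' Thin wrapper around a genes x samples numeric matrix carrying a platform
#' tag (`"microarray"` or `"rnaseq"`). Gene symbols are row names, case ids
#' column names; both must be unique and all values finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @export
expression_matrix <- function(values, platform = c("microarray", "rnaseq")) {
  platform <- match.arg(platform)
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(values))) stop("duplicate case_ids")
  if (!all(is.finite(values))) stop("non-finite expression values")
  structure(values, platform = platform, class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d genes x %d samples\n",
              attr(x, "platform"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression TSV (first column gene symbol, remaining case ids)
#'
#' @param path TSV file path.
#' @param platform platform tag.
#' @param clinical optional cohort data frame; samples without a clinical
#'   record are logged and kept, available via `attr(, "unmatched")`.
#' @export
load_expression <- function(path, platform = c("microarray", "rnaseq"),
                            clinical = NULL) {
  platform <- match.arg(platform)
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  storage.mode(m) <- "double"
  out <- expression_matrix(m, platform)
  unmatched <- character()
  if (!is.null(clinical)) {
    unmatched <- setdiff(colnames(out), clinical$case_id)
    if (length(unmatched)) {
      pipe_log("load_expression(%s): %d samples unmatched to clinical records",
               platform, length(unmatched))
    }
  }
  attr(out, "unmatched") <- unmatched
  pipe_log("load_expression(%s): %d genes x %d samples", platform,
           nrow(out), ncol(out))
  out
}
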