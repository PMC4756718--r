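#' @importFrom stats rnorm rexp rbinom runif sd t.test kruskal.test fisher.test
#'   pchisq pnorm qnorm quantile median p.adjust complete.cases setNames coef
#'   cor rmultinom
#' @importFrom utils read.delim write.table combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent seed streams from one root seed
#'
#' Each stochastic stage of the pipeline (cohort generation, expression noise,
#' censoring, missingness, bootstrap, permutation) receives its own seed so
#' that stages are individually reproducible. Streams are drawn once from the
#' root seed; the mapping is fixed by `n` and the stream index.
#'
#' @param seed integer root seed.
#' @param n number of streams.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## lightweight logging: informative by default, silenced via option
pipe_log <- function(...) {
  if (isTRUE(getOption("rmsperm.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(...))
}
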