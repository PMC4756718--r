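#!/usr/bin/env Rscript
## Stage 1: generate the two synthetic study cohorts used by the analysis.
##
## * `tcga_like`  -- a cohort with the TCGA study's arm sizes (90 IP / 398 IV),
##   platform coverage (RNA-Seq on 34 and 187 cases), route hazard ratio
##   0.45 and no gene effects: the backdrop for the route-level survival
##   analysis.
## * `biomarker_demo` -- the same cohort structure with planted biology:
##   one gene whose expression confers chemoresistance in the IV arm only
##   (IVRES1, log HR 0.8 per SD in IV, 0 in IP), and one prognostic gene
##   acting in both arms (PROG1, log HR 0.5 per SD). This is the cohort the
##   discovery/validation/permutation stages analyze.
##
## Writes TSV inputs (the same formats the loaders read) plus truth.json
## under results/data/.

library(rmsperm)

seed <- 20160217  # fixed root seed for the whole analysis
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

tcga_like <- make_fixture("tcga_like", seed = seed)
write_cohort(tcga_like, "results/data/tcga_like")

demo_cfg <- sim_config(
  predictive_genes = list(IVRES1 = c(ip = 0, iv = 0.8)),
  prognostic_genes = c(PROG1 = 0.5),
  seed = seed + 1)
biomarker_demo <- simulate_cohort(demo_cfg)
write_cohort(biomarker_demo, "results/data/biomarker_demo")

for (co in list(tcga_like = tcga_like, biomarker_demo = biomarker_demo)) {
  print(co)
}
cat("censored OS fraction (tcga_like):",
    round(mean(!tcga_like$clinical$os_event, na.rm = TRUE), 3), "\n")
cat("wrote results/data/{tcga_like,biomarker_demo}\n")
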