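# Shared settings for the analysis scripts: one simulated two-species
# experiment (control + salt library per species) at the default study
# conditions.  Every script sources this file, so the whole workflow is
# reproducible from a single seed.

library(saltdge)

cfg <- sim_config(seed = 1)

res_dir <- file.path("results")
sim_dir <- file.path(res_dir, "01_simulation")
expr_dir <- file.path(res_dir, "02_expression")
deg_dir <- file.path(res_dir, "03_deg")
enrich_dir <- file.path(res_dir, "04_enrichment")
splice_dir <- file.path(res_dir, "05_splicing")
report_dir <- file.path(res_dir, "06_report")

for (d in c(
  sim_dir, expr_dir, deg_dir, enrich_dir, splice_dir, report_dir
)) {
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
}
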