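#!/usr/bin/env Rscript
# Consensus DEG calling per species (Poisson-ratio and Fisher metrics,
# BH FDR, all-metric intersection), eight-cluster cross-species
# classification, category tabulation, and qPCR cross-validation of the
# RNA-seq fold changes.

source(file.path("analysis", "00_config.R"))
suppressPackageStartupMessages(library(dplyr))

expr <- readr::read_tsv(
  file.path(expr_dir, "expression.tsv"),
  show_col_types = FALSE
)
truth_genes <- readr::read_tsv(
  file.path(sim_dir, "truth_genes.tsv"),
  show_col_types = FALSE
)

species <- cfg$species
calls <- list()
for (s in seq_along(species)) {
  ctrl <- cfg$libraries[2 * s - 1]
  salt <- cfg$libraries[2 * s]
  pair <- expr |> filter(library_id %in% c(ctrl, salt))
  pair <- expression_filter(pair)
  wide <- full_join(
    expr |> filter(library_id == ctrl) |>
      select(transcript_id, C_ctrl = C, N_ctrl = N, FPKM_ctrl = FPKM),
    expr |> filter(library_id == salt) |>
      select(transcript_id, C_salt = C, N_salt = N, FPKM_salt = FPKM),
    by = "transcript_id"
  ) |>
    filter(transcript_id %in% unique(pair$transcript_id))
  calls[[species[s]]] <- call_degs(wide, species = species[s])
  message(
    species[s], ": ", sum(calls[[species[s]]]$status == "up"), " up, ",
    sum(calls[[species[s]]]$status == "down"), " down of ",
    nrow(wide), " expressed transcripts"
  )
}

cl <- classify_clusters(calls[[1]], calls[[2]], species)
readr::write_tsv(
  bind_rows(calls) |>
    left_join(cl$assignments, by = "transcript_id"),
  file.path(deg_dir, "deg_calls.tsv")
)
readr::write_tsv(
  tibble::tibble(cluster = names(cl$sizes), n = as.integer(cl$sizes)),
  file.path(deg_dir, "deg_clusters.tsv")
)
message(
  "clusters: ", paste(names(cl$sizes), cl$sizes, collapse = ", "),
  "; union ", unname(cl$totals["union"]), ", common ",
  unname(cl$totals["common"])
)

# rebuild the truth object only to drive the synthetic qPCR assay
ann <- generate_annotation(cfg)
truth <- plant_truth(ann$models, cfg)
cmap <- simulate_category_map(truth)
readr::write_tsv(
  categorize_degs(calls, cmap), file.path(deg_dir, "deg_categories.tsv")
)

ct <- simulate_qpcr(truth)
fc <- list()
for (s in seq_along(species)) {
  ctrl <- cfg$libraries[2 * s - 1]
  salt <- cfg$libraries[2 * s]
  rel <- ddct(ct[ct$sample %in% c(ctrl, salt), ], "actin", ctrl)
  rel <- rel[rel$sample == salt, ]
  fc[[species[s]]] <- rel |>
    inner_join(
      calls[[species[s]]] |> select(transcript_id, log2_ratio),
      by = c(gene = "transcript_id")
    )
}
fc <- bind_rows(fc, .id = "species")
readr::write_tsv(fc, file.path(deg_dir, "qpcr_validation.tsv"))
r <- validate_correlation(log2(fc$rel_expr), fc$log2_ratio)
message(
  "qPCR vs RNA-seq log2 fold change: Pearson r = ", round(r, 3),
  " over ", nrow(fc), " gene x species points"
)
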