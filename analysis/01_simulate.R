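#!/usr/bin/env Rscript
# Simulate the four-library experiment: toy genome, single-isoform gene
# models, planted DE classes and splicing events, and FASTQ reads per
# library.  Everything downstream reads the files written here.

source(file.path("analysis", "00_config.R"))

ann <- generate_annotation(cfg)
truth <- plant_truth(ann$models, cfg)

write_genome_fasta(ann$genome, file.path(sim_dir, "genome.fa"))
write_annotation_gff3(ann$models, file.path(sim_dir, "models.gff3"))
write_truth(truth, sim_dir)
readr::write_tsv(
  truth$novel_junctions, file.path(sim_dir, "novel_junctions.tsv")
)

for (lib in cfg$libraries) {
  rd <- simulate_reads(ann$genome, ann$models, truth, lib, cfg)
  write_fastq(rd, file.path(sim_dir, paste0(lib, ".fastq")))
  message(lib, ": ", length(rd), " reads")
}

n_de <- sum(!is.na(truth$genes$de_class))
message(
  "simulated ", cfg$n_genes, " genes on ",
  length(ann$genome), " contig(s); planted ", n_de, " DE genes and ",
  nrow(truth$as_events), " AS events (",
  paste(names(table(truth$as_events$type)),
    table(truth$as_events$type),
    sep = "=", collapse = ", "
  ), ")"
)
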