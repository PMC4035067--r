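#!/usr/bin/env Rscript
# Splice-junction analysis: enumerate all annotated exon-pair junctions,
# merge the novel-junction file, extract 65-base flanks, validate by
# >= 2 anchored reads at <= 1 mismatch per library, call retained
# introns from boundary reads, classify the six event types and
# aggregate the per-type x per-library table.

source(file.path("analysis", "00_config.R"))
suppressPackageStartupMessages(library(dplyr))

models <- read_annotation_gff3(file.path(sim_dir, "models.gff3"))
genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
novel <- read_junctions_tsv(file.path(sim_dir, "novel_junctions.tsv"))

annotated <- enumerate_annotated_junctions(models)
merged <- merge_junctions(annotated, novel)
flanked <- extract_flanks(merged, genome, models, w = 65)
message(
  nrow(annotated), " annotated + ", nrow(novel), " novel junctions -> ",
  nrow(merged), " after deduplication"
)

events <- list()
for (lib in cfg$libraries) {
  rd <- read_fastq(file.path(sim_dir, paste0(lib, ".fastq")))
  rd <- clean_reads(rd)$reads
  vj <- validate_junctions(rd, flanked)
  ri <- detect_retained_introns(rd, models, genome)
  events[[lib]] <- classify_events(
    vj[vj$validated, ], models, ri, lib
  )
  message(
    lib, ": ", sum(vj$validated), " validated junctions, ",
    sum(ri$called), " retained introns, ",
    nrow(events[[lib]]), " events"
  )
}

all_events <- bind_rows(events)
agg <- aggregate_as(
  all_events, cfg$libraries,
  species_map = setNames(rep(cfg$species, each = 2), cfg$libraries),
  condition_map = setNames(
    rep(c("control", "salt"), 2), cfg$libraries
  )
)
readr::write_tsv(all_events, file.path(splice_dir, "as_events.tsv"))
readr::write_tsv(
  agg$by_type, file.path(splice_dir, "as_events_by_type.tsv")
)
readr::write_tsv(
  tibble::tibble(
    library = names(agg$loci), loci = as.integer(agg$loci)
  ),
  file.path(splice_dir, "as_loci.tsv")
)
message(
  "distinct events across libraries: ",
  unname(agg$total_events["Total"]), " at ",
  unname(agg$loci["Total"]), " loci; ",
  "loci common to both species: ", agg$locus_overlap$common
)
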