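test_that("annotated junction enumeration follows n(n-1)/2", {
  m <- tiny_models() # genes with 3, 2, 1 exons
  j <- enumerate_annotated_junctions(m)
  expect_equal(sum(j$gene_id == "gA"), 3)
  expect_equal(sum(j$gene_id == "gB"), 1)
  expect_equal(sum(j$gene_id == "gC"), 0)
  expect_true(all(j$donor_end < j$acceptor_start))
  # formula over a generated annotation
  cfg <- sim_config(n_genes = 40, seed = 12)
  ann <- generate_annotation(cfg)
  jj <- enumerate_annotated_junctions(ann$models)
  n_i <- table(ann$models$gene_id)
  expect_equal(nrow(jj), sum(n_i * (n_i - 1) / 2))
  cfg5 <- sim_config(n_genes = 6, exons_per_gene = c(5, 5), seed = 1)
  ann5 <- generate_annotation(cfg5)
  j5 <- enumerate_annotated_junctions(ann5$models)
  expect_true(all(table(j5$gene_id) == 10))
})

test_that("junction merging dedupes on identity with annotated priority", {
  ann <- enumerate_annotated_junctions(tiny_models())
  # novel copy of an annotated junction plus two genuinely new ones
  novel <- tibble::tibble(
    contig = "ctg01",
    donor_end = c(ann$donor_end[1], 55L, 300L),
    acceptor_start = c(ann$acceptor_start[1], 121L, 331L),
    strand = c("+", "+", "+")
  )
  merged <- merge_junctions(ann, novel)
  expect_equal(nrow(merged), nrow(ann) + 2)
  key <- paste(merged$donor_end, merged$acceptor_start)
  dup_row <- merged[key == paste(ann$donor_end[1], ann$acceptor_start[1]), ]
  expect_equal(nrow(dup_row), 1)
  expect_equal(dup_row$origin, "annotated")
  # novel junctions inside a gene span attach to it
  expect_equal(
    merged$gene_id[merged$donor_end == 55L], "gA"
  )
  # empty novel file: annotated list unchanged
  expect_identical(merge_junctions(ann, novel[0, ]), ann)
})

test_that("flank extraction truncates at exon and contig boundaries", {
  genome <- tiny_genome(len = 600)
  m <- tiny_models()
  j <- enumerate_annotated_junctions(m)
  # gA exons are 30 bp: both sides truncate to the exon
  fl <- extract_flanks(j[1, ], genome, m, w = 65)
  expect_equal(fl$donor_flank, 30)
  expect_equal(nchar(fl$flank_seq), 60)
  # wide exons give the full 2w
  wide <- tibble::tibble(
    gene_id = "gW", transcript_id = "gW.1", contig = "ctg01",
    strand = "+", exon = 1:2,
    start = c(11L, 301L), end = c(200L, 500L)
  )
  jw <- enumerate_annotated_junctions(wide)
  flw <- extract_flanks(jw, genome, wide, w = 65)
  expect_equal(nchar(flw$flank_seq), 130)
  expect_equal(flw$donor_flank, 65)
  # w = 1: just the two boundary bases
  fl1 <- extract_flanks(jw, genome, wide, w = 1)
  expect_equal(nchar(fl1$flank_seq), 2)
  # flank sequence equals the spliced boundary context
  ctg <- as.character(genome[["ctg01"]])
  expect_equal(
    flw$flank_seq,
    paste0(substr(ctg, 200 - 64, 200), substr(ctg, 301, 301 + 64))
  )
  # a junction outside contig bounds errors
  bad <- jw
  bad$acceptor_start <- 9999L
  expect_error(extract_flanks(bad, genome, wide), "off contig")
})

test_that("junction validation needs two anchored reads within 1 mismatch", {
  genome <- tiny_genome(len = 600)
  wide <- tibble::tibble(
    gene_id = "gW", transcript_id = "gW.1", contig = "ctg01",
    strand = "+", exon = 1:2,
    start = c(11L, 301L), end = c(200L, 500L)
  )
  j <- extract_flanks(
    enumerate_annotated_junctions(wide), genome, wide, 65
  )
  span <- function(offset) substring(j$flank_seq, offset, offset + 39)
  # offset 30..69 spans boundary 65 with 36 left but only 4 right: the
  # anchor rule (>= 8 on each side) rejects it
  v0 <- validate_junctions(
    c(a = span(30)), j,
    min_anchor = 8, min_reads = 1
  )
  expect_equal(v0$support, 0)
  # reads with >= 8 bases each side
  rds <- c(x = span(40), y = span(50))
  v1 <- validate_junctions(rds, j, min_anchor = 8, min_reads = 2)
  expect_true(v1$validated)
  v2 <- validate_junctions(rds[1], j, min_anchor = 8, min_reads = 2)
  expect_false(v2$validated)
  # two mismatches disqualify a read
  mut <- span(40)
  substr(mut, 5, 5) <- "N"
  substr(mut, 12, 12) <- "N"
  v3 <- validate_junctions(
    c(m = mut, y = span(50)), j,
    min_anchor = 8, min_reads = 2
  )
  expect_false(v3$validated)
  # anchor rule: a read touching the boundary by < min_anchor not counted
  edge <- span(62) # covers 62..101: 4 bases left of boundary 65
  v4 <- validate_junctions(
    c(e = edge), j,
    min_anchor = 8, min_reads = 1
  )
  expect_equal(v4$support, 0)
})

test_that("validation support agrees with a brute-force flank scan", {
  set.seed(33)
  genome <- tiny_genome(seed = 33, len = 2000)
  ctg <- as.character(genome[["ctg01"]])
  models <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 3),
    transcript_id = rep(c("g1.1", "g2.1"), each = 3),
    contig = "ctg01", strand = "+",
    exon = rep(1:3, 2),
    start = c(21L, 321L, 621L, 1021L, 1321L, 1621L),
    end = c(220L, 520L, 820L, 1220L, 1520L, 1820L)
  )
  j <- extract_flanks(
    enumerate_annotated_junctions(models), genome, models, 65
  )
  reads <- character(0)
  for (i in seq_len(nrow(j))) {
    for (off in c(20, 35, 50)) {
      reads <- c(reads, substring(j$flank_seq[i], off, off + 49))
    }
  }
  reads <- c(reads, vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  }, ""))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  got <- validate_junctions(reads, j, 1, 8, 2)
  # oracle: brute Hamming scan + anchor arithmetic
  flanks <- setNames(j$flank_seq, j$junction_id)
  hits <- brute_hamming(as.list(reads), as.list(flanks), mm = 1)
  d <- setNames(j$donor_flank, j$junction_id)
  wr <- nchar(reads)[match(hits$read_id, names(reads))]
  ok <- hits$start <= d[hits$subject_id] - 8 + 1 &
    hits$start + wr - 1 >= d[hits$subject_id] + 8
  sup <- table(hits$subject_id[ok][!duplicated(
    paste(hits$read_id, hits$subject_id)[ok]
  )])
  want <- as.integer(sup[got$junction_id])
  want[is.na(want)] <- 0L
  expect_equal(got$support, want)
})

test_that("retained introns need reads across both boundaries", {
  genome <- tiny_genome(seed = 5, len = 1200)
  ctg <- as.character(genome[["ctg01"]])
  models <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.1", contig = "ctg01",
    strand = "+", exon = 1:2, start = c(101L, 501L),
    end = c(300L, 700L)
  )
  # intron: 301..500; boundaries after 300 and after 500
  both <- c(
    b5a = substr(ctg, 270, 319), b5b = substr(ctg, 280, 329),
    b3a = substr(ctg, 470, 519), b3b = substr(ctg, 480, 529)
  )
  ri <- detect_retained_introns(both, models, genome, w = 65)
  expect_equal(nrow(ri), 1)
  expect_true(ri$called)
  only5 <- detect_retained_introns(
    both[1:2], models, genome,
    w = 65
  )
  expect_false(only5$called)
  # intron-less gene: no candidates
  single <- models[1, ]
  none <- detect_retained_introns(both, single, genome, w = 65)
  expect_equal(nrow(none), 0)
})

test_that("event classification applies the geometric rules", {
  genome <- tiny_genome(seed = 14, len = 3000)
  models <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.1", contig = "ctg01",
    strand = "+", exon = 1:3,
    start = c(101L, 601L, 1101L), end = c(300L, 800L, 1300L)
  )
  vj <- function(d, a) {
    tibble::tibble(
      contig = "ctg01", donor_end = d, acceptor_start = a,
      strand = "+", gene_id = "g1", origin = "annotated",
      validated = TRUE
    )
  }
  # trio (1,2), (2,3), (1,3): exactly one SE (exon 2 skipped by (1,3))
  trio <- dplyr::bind_rows(
    vj(300L, 601L), vj(800L, 1101L), vj(300L, 1101L)
  )
  ev <- classify_events(trio, models, library_id = "L")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SE")
  expect_equal(ev$skipped_exons, "2")
  # shared acceptor, donors 10 bp apart in the same exon: one A5SS
  a5 <- dplyr::bind_rows(vj(300L, 601L), vj(290L, 601L))
  ev5 <- classify_events(a5, models, library_id = "L")
  expect_equal(ev5$type, "A5SS")
  # on a minus-strand gene the same shape is an A3SS
  models_m <- models
  models_m$strand <- "-"
  a5m <- a5
  a5m$strand <- "-"
  ev5m <- classify_events(a5m, models_m, library_id = "L")
  expect_equal(ev5m$type, "A3SS")
  # shared donor, acceptors in the same exon: A3SS on plus strand
  a3 <- dplyr::bind_rows(vj(300L, 601L), vj(300L, 611L))
  ev3 <- classify_events(a3, models, library_id = "L")
  expect_equal(ev3$type, "A3SS")
  # no validated junctions: no events
  expect_equal(
    nrow(classify_events(trio[0, ], models, library_id = "L")), 0
  )
})

test_that("alternative first/last exons require unconnected donor exons", {
  models <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.1", contig = "ctg01",
    strand = "+", exon = 1:4,
    start = c(101L, 601L, 1101L, 1601L),
    end = c(300L, 800L, 1300L, 1800L)
  )
  vj <- function(d, a) {
    tibble::tibble(
      contig = "ctg01", donor_end = d, acceptor_start = a,
      strand = "+", gene_id = "g1", origin = "annotated",
      validated = TRUE
    )
  }
  # donors in exons 1 and 2 share acceptor exon 3; exon 2 is not the
  # acceptor of any validated junction -> AFE (and no SE from (1,3))
  afe <- dplyr::bind_rows(vj(300L, 1101L), vj(800L, 1101L))
  ev <- classify_events(afe, models, library_id = "L")
  expect_equal(sort(unique(ev$type)), "AFE")
  # adding validated (1,2) connects exon 2: the pair is no longer AFE,
  # and the (1,3) junction reverts to a skipped-exon call
  not_afe <- dplyr::bind_rows(afe, vj(300L, 601L))
  ev2 <- classify_events(not_afe, models, library_id = "L")
  expect_false("AFE" %in% ev2$type)
  expect_true("SE" %in% ev2$type)
  # symmetric ALE at the genomic-right end
  ale <- dplyr::bind_rows(vj(800L, 1101L), vj(800L, 1601L))
  ev3 <- classify_events(ale, models, library_id = "L")
  expect_equal(sort(unique(ev3$type)), "ALE")
  # minus strand swaps the labels
  models_m <- models
  models_m$strand <- "-"
  afe_m <- afe
  afe_m$strand <- "-"
  ev4 <- classify_events(afe_m, models_m, library_id = "L")
  expect_equal(sort(unique(ev4$type)), "ALE")
})

test_that("aggregation uses union semantics for the Total column", {
  ev1 <- tibble::tibble(
    library_id = "L1", type = "SE", gene_id = "g1", contig = "c",
    strand = "+", event_id = "SE:g1:1:2", donor_1 = 1L,
    acceptor_1 = 2L, donor_2 = NA_integer_, acceptor_2 = NA_integer_,
    skipped_exons = "2"
  )
  evs <- dplyr::bind_rows(
    ev1,
    ev1 |> dplyr::mutate(library_id = "L2"),
    ev1 |> dplyr::mutate(library_id = "L3"),
    ev1 |> dplyr::mutate(library_id = "L4")
  )
  agg <- aggregate_as(evs, paste0("L", 1:4))
  bt <- agg$by_type
  expect_equal(unname(unlist(bt[bt$type == "SE", paste0("L", 1:4)])),
    rep(1L, 4)
  )
  expect_equal(bt$Total[bt$type == "SE"], 1)
  expect_equal(unname(agg$total_events["Total"]), 1)
  # empty input: all zeros
  agg0 <- aggregate_as(evs[0, ], paste0("L", 1:4))
  expect_true(all(agg0$by_type$Total == 0))
  expect_equal(unname(agg0$total_events["Total"]), 0)
  # locus overlap bookkeeping
  ev_b <- ev1 |>
    dplyr::mutate(
      library_id = "L3", gene_id = "g2", event_id = "SE:g2:9:10"
    )
  agg2 <- aggregate_as(
    dplyr::bind_rows(evs, ev_b), paste0("L", 1:4),
    species_map = c(L1 = "A", L2 = "A", L3 = "B", L4 = "B"),
    condition_map = c(
      L1 = "control", L2 = "salt", L3 = "control", L4 = "salt"
    )
  )
  expect_equal(unname(agg2$locus_overlap$common), 1) # g1 in both species
  expect_equal(unname(agg2$locus_overlap$salt_only["A"]), 0)
})

test_that("BED12 junction records parse to donor/acceptor coordinates", {
  # two 20-bp anchors around a junction: donor ends at base 100,
  # acceptor starts at base 201 (1-based)
  bed <- paste(
    "ctg01", 80, 220, "JUNC0001", 25, "+", 80, 220, "255,0,0",
    2, "20,20", "0,120",
    sep = "\t"
  )
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed, path)
  j <- read_junctions_bed12(path)
  expect_equal(nrow(j), 1)
  expect_equal(j$contig, "ctg01")
  expect_equal(j$donor_end, 100)
  expect_equal(j$acceptor_start, 201)
  expect_equal(j$strand, "+")
  # a single-block record encodes no junction
  writeLines(paste(
    "ctg01", 80, 100, "J2", 0, "+", 80, 100, "0", 1, "20", "0",
    sep = "\t"
  ), path)
  expect_equal(nrow(read_junctions_bed12(path)), 0)
})

test_that("TSV junction files validate their columns and coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    contig = "ctg01", donor_end = 100L, acceptor_start = 201L,
    strand = "+"
  ), path)
  j <- read_junctions_tsv(path)
  expect_equal(j$donor_end, 100)
  readr::write_tsv(tibble::tibble(
    contig = "ctg01", donor_end = 300L, acceptor_start = 200L,
    strand = "+"
  ), path)
  expect_error(read_junctions_tsv(path), "malformed junction at line 2")
})
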