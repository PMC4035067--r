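test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_genes = 10), "sim_config")
  expect_error(sim_config(de_log2_effect = 1), "exceed 1")
  expect_error(
    sim_config(de_fraction_per_class = c(
      a_up_only = 0.5, b_up_only = 0.6, a_down_only = 0,
      b_down_only = 0, co_up = 0, co_down = 0,
      a_up_b_down = 0, a_down_b_up = 0
    )),
    "sum"
  )
  expect_error(sim_config(read_len = 10, min_anchor = 8), "twice")
})

test_that("annotation generation handles the empty case", {
  cfg <- sim_config(n_genes = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$models), 0)
  expect_gt(sum(Biostrings::width(ann$genome)), 0)
})

test_that("annotation generation is seed-deterministic, byte for byte", {
  cfg <- sim_config(n_genes = 15, seed = 1)
  d1 <- withr::local_tempdir()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$models, a2$models)
  f1 <- file.path(d1, "g1.fa")
  f2 <- file.path(d1, "g2.fa")
  write_genome_fasta(a1$genome, f1)
  write_genome_fasta(a2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- file.path(d1, "m1.gff3")
  g2 <- file.path(d1, "m2.gff3")
  write_annotation_gff3(a1$models, g1)
  write_annotation_gff3(a2$models, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("exon count range is respected and geometry is consistent", {
  cfg <- sim_config(n_genes = 10, exons_per_gene = c(3, 3), seed = 5)
  ann <- generate_annotation(cfg)
  per_gene <- split(ann$models, ann$models$gene_id)
  expect_true(all(vapply(per_gene, nrow, integer(1)) == 3))
  for (ex in per_gene) {
    ex <- ex[order(ex$start), ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end >= ex$start))
    # introns exist between consecutive exons
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)] + 1))
  }
  # genes do not overlap on their contig
  spans <- ann$models |>
    dplyr::group_by(gene_id, contig) |>
    dplyr::summarise(
      lo = min(start), hi = max(end), .groups = "drop"
    ) |>
    dplyr::arrange(contig, lo)
  same <- spans$contig[-1] == spans$contig[-nrow(spans)]
  expect_true(all(spans$lo[-1][same] > spans$hi[-nrow(spans)][same]))
})

test_that("GFF3 round trip reproduces the models exactly", {
  cfg <- sim_config(n_genes = 8, seed = 11)
  ann <- generate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann$models, path)
  back <- read_annotation_gff3(path)
  expect_equal(
    as.data.frame(back), as.data.frame(ann$models),
    ignore_attr = TRUE
  )
})

test_that("truth planting draws DE classes at the configured rate", {
  fr <- c(
    a_up_only = 0, b_up_only = 0, a_down_only = 0, b_down_only = 0,
    co_up = 0.1, co_down = 0, a_up_b_down = 0, a_down_b_up = 0
  )
  cfg <- sim_config(
    n_genes = 1000, de_fraction_per_class = fr,
    as_plant_rates = c(
      SE = 0, RI = 0, A5SS = 0, A3SS = 0, AFE = 0, ALE = 0
    ),
    seed = 3
  )
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  n_coup <- sum(truth$genes$de_class == "co_up", na.rm = TRUE)
  expect_true(all(
    is.na(truth$genes$de_class) | truth$genes$de_class == "co_up"
  ))
  sd3 <- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(n_coup - 100), sd3)
})

test_that("zero DE fractions give a truth table with no DE labels", {
  fr <- c(
    a_up_only = 0, b_up_only = 0, a_down_only = 0, b_down_only = 0,
    co_up = 0, co_down = 0, a_up_b_down = 0, a_down_b_up = 0
  )
  cfg <- sim_config(n_genes = 50, de_fraction_per_class = fr, seed = 2)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  expect_true(all(is.na(truth$genes$de_class)))
  expect_true(all(truth$genes$log2_effect == 0))
})

test_that("planted DE genes carry the promised effect and expression", {
  cfg <- sim_config(n_genes = 300, seed = 8)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  g <- truth$genes
  de <- g[!is.na(g$de_class), ]
  expect_gt(nrow(de), 0)
  eff <- pmax(abs(de$expected_log2_a), abs(de$expected_log2_b))
  expect_true(all(eff >= cfg$de_log2_effect))
  mu_ctrl <- pmin(de[[paste0("mu_", cfg$libraries[1])]],
    de[[paste0("mu_", cfg$libraries[3])]]
  )
  expect_true(all(mu_ctrl >= cfg$de_min_expected - 1e-6))
})

test_that("a planted SE event's exclusion junction spans the skipped exon", {
  cfg <- sim_config(
    n_genes = 120,
    as_plant_rates = c(
      SE = 0.3, RI = 0, A5SS = 0, A3SS = 0, AFE = 0, ALE = 0
    ),
    seed = 4
  )
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  se <- truth$as_events[truth$as_events$type == "SE", ]
  expect_gt(nrow(se), 0)
  for (i in seq_len(nrow(se))) {
    ex <- ann$models[ann$models$gene_id == se$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    skipped <- ex[ex$exon == se$skipped_exon[i], ]
    k <- which(ex$start == skipped$start)
    expect_equal(se$j1_donor[i], ex$end[k - 1])
    expect_equal(se$j1_acceptor[i], ex$start[k + 1])
    expect_true(
      skipped$start > se$j1_donor[i] &&
        skipped$end < se$j1_acceptor[i]
    )
  }
})

test_that("simulated fragment counts track the planted expectation", {
  cfg <- sim_config(
    n_genes = 4, library_size = 400, count_noise = 0.02,
    de_fraction_per_class = c(
      a_up_only = 0, b_up_only = 0, a_down_only = 0, b_down_only = 0,
      co_up = 0, co_down = 0, a_up_b_down = 0, a_down_b_up = 0
    ),
    as_plant_rates = c(
      SE = 0, RI = 0, A5SS = 0, A3SS = 0, AFE = 0, ALE = 0
    ),
    qc_contamination = c(duplicate = 0, n_rich = 0, low_quality = 0),
    seed = 6
  )
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  target <- truth$genes$transcript_id[1]
  mu <- truth$genes[[paste0("mu_", cfg$libraries[1])]][1]
  txs <- transcript_seqs(ann$genome, ann$models)
  # Monte-Carlo over seeds: mean observed count within 3 s.e.
  counts <- vapply(1:50, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- 1000L + s
    rd <- simulate_reads(ann$genome, ann$models, truth,
      cfg$libraries[1], cfg_s
    )
    hits <- match_reads(rd, txs[target])
    length(unique(hits$read_id))
  }, numeric(1))
  se3 <- 3 * sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), se3 + 1e-9)
})

test_that("zero library size yields an empty read set", {
  cfg <- sim_config(n_genes = 5, library_size = 0, seed = 2)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  rd <- simulate_reads(ann$genome, ann$models, truth, "PeuC", cfg)
  expect_length(rd, 0)
})

test_that("planted duplicate fraction matches the configured rate", {
  cfg <- sim_config(
    n_genes = 40, library_size = 5000, exon_len = c(600, 900),
    qc_contamination = c(duplicate = 0.1, n_rich = 0, low_quality = 0),
    as_plant_rates = c(
      SE = 0, RI = 0, A5SS = 0, A3SS = 0, AFE = 0, ALE = 0
    ),
    seed = 9
  )
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  rd <- simulate_reads(ann$genome, ann$models, truth, "PeuC", cfg)
  dup_frac <- mean(duplicated(as.character(rd)))
  # planted 10% on top of a small natural collision background
  expect_gt(dup_frac, 0.07)
  expect_lt(dup_frac, 0.15)
})

test_that("identical config gives byte-identical FASTQ", {
  cfg <- sim_config(n_genes = 10, library_size = 500, seed = 21)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  d <- withr::local_tempdir()
  r1 <- simulate_reads(ann$genome, ann$models, truth, "PprS", cfg)
  r2 <- simulate_reads(ann$genome, ann$models, truth, "PprS", cfg)
  write_fastq(r1, file.path(d, "a.fq"))
  write_fastq(r2, file.path(d, "b.fq"))
  expect_identical(
    readLines(file.path(d, "a.fq")), readLines(file.path(d, "b.fq"))
  )
})

test_that("planted junctions receive at least two spanning reads", {
  cfg <- sim_config(n_genes = 150, seed = 17)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann$models, cfg)
  expect_gt(nrow(truth$support_junctions), 0)
  rd <- simulate_reads(ann$genome, ann$models, truth, "PeuC", cfg)
  sup <- truth$support_junctions
  jx <- tibble::tibble(
    contig = sup$contig, donor_end = sup$donor,
    acceptor_start = sup$acceptor, strand = "+", gene_id = sup$gene_id,
    origin = "planted"
  )
  fl <- extract_flanks(jx, ann$genome, ann$models, cfg$flank_width)
  vj <- validate_junctions(rd, fl,
    min_anchor = cfg$min_anchor, min_reads = 2
  )
  expect_true(all(vj$support >= 2))
})
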