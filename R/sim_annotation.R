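#' Generate a synthetic genome and gene models
#'
#' Lays non-overlapping genes (one transcript each; alternative isoforms
#' arise downstream only through planted junction reads) onto random
#' contigs.  Exon/intron lengths and exon counts are drawn uniformly from
#' the configured ranges.  Strand is random.  Exons are recorded in
#' transcription order (`exon` 1 is the 5' exon, i.e. the genomic
#' rightmost interval on the minus strand).
#'
#' @param config a [sim_config()].
#' @param genes_per_contig genes placed per contig before a new contig is
#'   started.
#' @param contig_len optional fixed contig length (bp); an error is raised
#'   if the requested genes do not fit.  By default contigs are sized to
#'   fit their genes.
#' @return a list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `models`, a tibble with one row per exon: `gene_id`, `transcript_id`,
#'   `contig`, `strand`, `exon` (transcription rank), `start`, `end`
#'   (1-based inclusive genomic coordinates).
#' @examples
#' ann <- generate_annotation(sim_config(n_genes = 5, seed = 1))
#' ann$models
#' @export
generate_annotation <- function(config, genes_per_contig = 100L,
                                contig_len = NULL) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 0L), {
    n <- config$n_genes
    if (n == 0) {
      genome <- random_contigs(c(ctg01 = 10000L))
      return(list(genome = genome, models = empty_models()))
    }
    n_ex <- sample_range(config$exons_per_gene, n)
    rows <- vector("list", n)
    contig_of <- character(n)
    cursor <- 0L
    contig_idx <- 1L
    contig_ends <- integer(0)
    for (g in seq_len(n)) {
      if ((g - 1L) %% genes_per_contig == 0L && g > 1L) {
        contig_ends[contig_idx] <- cursor + sample_range(c(200L, 500L), 1L)
        contig_idx <- contig_idx + 1L
        cursor <- 0L
      }
      gap <- sample_range(c(200L, 500L), 1L)
      ex_w <- sample_range(config$exon_len, n_ex[g])
      in_w <- if (n_ex[g] > 1) {
        sample_range(config$intron_len, n_ex[g] - 1L)
      } else {
        integer(0)
      }
      starts <- cursor + gap + 1L +
        cumsum(c(0L, head(ex_w, -1) + in_w))
      ends <- starts + ex_w - 1L
      cursor <- ends[n_ex[g]]
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("SYNT_%04d", g)
      rank <- if (strand == "+") seq_len(n_ex[g]) else rev(seq_len(n_ex[g]))
      contig_of[g] <- sprintf("ctg%02d", contig_idx)
      rows[[g]] <- tibble(
        gene_id = gene_id,
        transcript_id = paste0(gene_id, ".1"),
        contig = contig_of[g],
        strand = strand,
        exon = rank,
        start = as.integer(starts),
        end = as.integer(ends)
      )
    }
    contig_ends[contig_idx] <- cursor + sample_range(c(200L, 500L), 1L)
    models <- bind_rows(rows) %>%
      arrange(.data$gene_id, .data$exon)

    lens <- setNames(
      contig_ends,
      sprintf("ctg%02d", seq_along(contig_ends))
    )
    if (!is.null(contig_len)) {
      if (any(lens > contig_len)) {
        stop("contig too short to place requested genes (need ",
          max(lens), " bp, have ", contig_len, ")",
          call. = FALSE
        )
      }
      lens[] <- as.integer(contig_len)
    }
    genome <- random_contigs(lens)
    list(genome = genome, models = models)
  })
}

empty_models <- function() {
  tibble(
    gene_id = character(), transcript_id = character(),
    contig = character(), strand = character(), exon = integer(),
    start = integer(), end = integer()
  )
}

sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(as.integer(rng[1]), n) else
    sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

random_contigs <- function(lens) {
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(lens)))
}

#' Transcript lengths from gene models
#'
#' @param models exon table as returned by [generate_annotation()].
#' @return tibble with `gene_id`, `transcript_id`, `length`.
#' @export
transcript_lengths <- function(models) {
  models %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(length = sum(.data$end - .data$start + 1L), .groups = "drop")
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand genes, so the returned sequence reads 5' to 3'.
#'
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param models exon table.
#' @param isoforms optional named list (`gene_id` -> integer vector of
#'   transcription-order exon ranks) selecting an exon subset per gene;
#'   genes not listed use all exons.
#' @return a named `DNAStringSet` keyed by `transcript_id`.
#' @export
transcript_seqs <- function(genome, models, isoforms = NULL) {
  if (nrow(models) == 0) {
    return(Biostrings::DNAStringSet())
  }
  contig_chr <- as.character(genome)
  per_gene <- split(models, models$gene_id)
  out <- vapply(per_gene, function(mx) {
    if (!is.null(isoforms) && !is.null(isoforms[[mx$gene_id[1]]])) {
      mx <- mx[mx$exon %in% isoforms[[mx$gene_id[1]]], , drop = FALSE]
    }
    mx <- mx[order(mx$start), , drop = FALSE]
    paste(
      substring(contig_chr[[mx$contig[1]]], mx$start, mx$end),
      collapse = ""
    )
  }, character(1))
  names(out) <- vapply(
    per_gene, function(mx) mx$transcript_id[1], character(1)
  )
  seqs <- Biostrings::DNAStringSet(out)
  minus <- vapply(per_gene, function(mx) mx$strand[1] == "-", logical(1))
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  seqs
}

#' Write and read gene models as GFF3
#'
#' GFF3 is written 1-based inclusive with `gene`, `mRNA` and `exon`
#' features; reading it back reproduces the exon table exactly.
#'
#' @param models exon table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(models, path) {
  if (nrow(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  genes <- models %>%
    group_by(
      .data$gene_id, .data$transcript_id, .data$contig, .data$strand
    ) %>%
    summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  gr_gene <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end), genes$strand,
    type = "gene", ID = genes$gene_id, Parent = NA_character_
  )
  gr_mrna <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end), genes$strand,
    type = "mRNA", ID = genes$transcript_id, Parent = genes$gene_id
  )
  gr_exon <- GenomicRanges::GRanges(
    models$contig, IRanges::IRanges(models$start, models$end),
    models$strand,
    type = "exon", ID = NA_character_, Parent = models$transcript_id
  )
  gr <- c(gr_gene, gr_mrna, gr_exon)
  gr <- gr[order(
    as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr),
    match(gr$type, c("gene", "mRNA", "exon"))
  )]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @return for the reader, an exon table in the [generate_annotation()]
#'   layout.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(empty_models())
  }
  ex <- gr[gr$type == "exon"]
  mrna <- gr[gr$type == "mRNA"]
  tx2gene <- setNames(
    vapply(mrna$Parent, function(p) p[1], character(1)),
    mrna$ID
  )
  tx <- vapply(ex$Parent, function(p) p[1], character(1))
  out <- tibble(
    gene_id = unname(tx2gene[tx]),
    transcript_id = tx,
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex)
  ) %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(
      exon = if (.data$strand[1] == "+") {
        row_number()
      } else {
        rev(row_number())
      }
    ) %>%
    ungroup() %>%
    select(
      "gene_id", "transcript_id", "contig", "strand", "exon",
      "start", "end"
    ) %>%
    arrange(.data$gene_id, .data$exon)
  out
}

#' Write contigs as FASTA
#' @param genome named `DNAStringSet`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
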