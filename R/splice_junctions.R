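#' Enumerate all annotated splice junctions
#'
#' For a gene whose exons in genomic order are `e1..en`, every ordered
#' pair `(ei, ej)`, `i < j`, defines a candidate junction — `n(n-1)/2`
#' per gene — whose donor side is the last base of the left exon and
#' whose acceptor side is the first base of the right exon.  Coordinates
#' are kept on the forward genomic axis (`donor_end < acceptor_start`);
#' the strand column carries the gene strand for 5'/3' labelling
#' downstream.
#'
#' @param models exon table.
#' @return junction tibble: `contig`, `donor_end`, `acceptor_start`,
#'   `strand`, `gene_id`, `origin` (`"annotated"`).
#' @export
enumerate_annotated_junctions <- function(models) {
  per_gene <- split(models, models$gene_id)
  rows <- lapply(per_gene, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2) {
      return(NULL)
    }
    idx <- utils::combn(n, 2)
    tibble(
      contig = ex$contig[1],
      donor_end = ex$end[idx[1, ]],
      acceptor_start = ex$start[idx[2, ]],
      strand = ex$strand[1],
      gene_id = ex$gene_id[1],
      origin = "annotated"
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(empty_junctions())
  }
  arrange(out, .data$contig, .data$donor_end, .data$acceptor_start)
}

empty_junctions <- function() {
  tibble(
    contig = character(), donor_end = integer(),
    acceptor_start = integer(), strand = character(),
    gene_id = character(), origin = character()
  )
}

junction_key <- function(j) {
  paste(j$contig, j$donor_end, j$acceptor_start, j$strand, sep = ":")
}

#' Read novel junctions from a plain TSV
#'
#' Expects columns `contig`, `donor_end`, `acceptor_start`, `strand`
#' (1-based inclusive coordinates of the flanking exonic bases).
#'
#' @param path file path.
#' @return junction tibble without gene attachment.
#' @export
read_junctions_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("contig", "donor_end", "acceptor_start", "strand")
  if (!all(need %in% names(x))) {
    stop("junction TSV must have columns ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(
    !is.finite(x$donor_end) | !is.finite(x$acceptor_start) |
      x$donor_end >= x$acceptor_start
  )
  if (length(bad)) {
    stop("malformed junction at line ", bad[1] + 1L,
      " of ", path,
      call. = FALSE
    )
  }
  tibble(
    contig = as.character(x$contig),
    donor_end = as.integer(x$donor_end),
    acceptor_start = as.integer(x$acceptor_start),
    strand = as.character(x$strand)
  )
}

#' Read junctions from a BED12 file (TopHat junctions.bed dialect)
#'
#' Each BED12 record encodes a junction as two (or more) anchor blocks;
#' consecutive block pairs give one junction each: the donor is the last
#' base of the left block, the acceptor the first base of the right
#' block.
#'
#' @param path BED12 file.
#' @return junction tibble without gene attachment.
#' @export
read_junctions_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  rows <- list()
  for (i in seq_along(gr)) {
    bl <- gr$blocks[[i]]
    if (is.null(bl) || length(bl) < 2) next
    # block ranges are relative to the record start in rtracklayer
    abs_start <- GenomicRanges::start(gr[i]) + IRanges::start(bl) - 1L
    abs_end <- GenomicRanges::start(gr[i]) + IRanges::end(bl) - 1L
    for (b in seq_len(length(bl) - 1L)) {
      rows[[length(rows) + 1L]] <- tibble(
        contig = as.character(GenomicRanges::seqnames(gr[i])),
        donor_end = abs_end[b],
        acceptor_start = abs_start[b + 1L],
        strand = as.character(GenomicRanges::strand(gr[i]))
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      contig = character(), donor_end = integer(),
      acceptor_start = integer(), strand = character()
    ))
  }
  bind_rows(rows)
}

#' Merge annotated and novel junction sets
#'
#' Junction identity is `(contig, donor_end, acceptor_start, strand)`;
#' on a collision the annotated origin wins.  Novel junctions are
#' attached to the gene whose span contains them (same contig); those
#' overlapping no gene are flagged `intergenic`.
#'
#' @param annotated [enumerate_annotated_junctions()] output.
#' @param novel junction tibble from [read_junctions_tsv()] or
#'   [read_junctions_bed12()] (gene attachment optional).
#' @return deduplicated junction tibble.
#' @export
merge_junctions <- function(annotated, novel) {
  if (nrow(novel) == 0) {
    return(annotated)
  }
  if (!"gene_id" %in% names(novel)) novel$gene_id <- NA_character_
  spans <- annotated %>%
    group_by(.data$gene_id, .data$contig) %>%
    summarise(
      lo = min(.data$donor_end), hi = max(.data$acceptor_start),
      .groups = "drop"
    )
  attach_gene <- function(contig, d, a) {
    hit <- spans$contig == contig & spans$lo <= a & spans$hi >= d
    if (any(hit)) spans$gene_id[which(hit)[1]] else NA_character_
  }
  novel <- novel %>%
    mutate(
      gene_id = ifelse(
        is.na(.data$gene_id),
        mapply(attach_gene, .data$contig, .data$donor_end,
          .data$acceptor_start
        ),
        .data$gene_id
      ),
      origin = ifelse(is.na(.data$gene_id), "intergenic", "novel")
    )
  combined <- bind_rows(annotated, novel)
  combined[!duplicated(junction_key(combined)), , drop = FALSE]
}

#' Extract junction flank sequences
#'
#' The flank is the last `min(w, available)` exonic bases ending at the
#' donor concatenated with the first `min(w, available)` bases starting
#' at the acceptor, in genomic orientation; availability is bounded by
#' the containing exon (or the contig where no exon of the junction's
#' gene contains the coordinate).  A read spanning the spliced boundary
#' aligns contiguously to this sequence.
#'
#' @param junctions junction tibble.
#' @param genome contig `DNAStringSet`.
#' @param models exon table (used for the exon-side truncation; may be
#'   empty).
#' @param w flank width per side (default 65).
#' @return `junctions` plus `flank_seq`, `donor_flank` (bases on the
#'   donor side) and `junction_id`.
#' @export
extract_flanks <- function(junctions, genome, models = NULL, w = 65L) {
  if (nrow(junctions) == 0) {
    junctions$flank_seq <- character(0)
    junctions$donor_flank <- integer(0)
    junctions$junction_id <- character(0)
    return(junctions)
  }
  contig_chr <- as.character(genome)
  bad <- !(junctions$contig %in% names(contig_chr))
  if (any(bad)) {
    stop("junction on unknown contig: ",
      junctions$contig[which(bad)[1]],
      call. = FALSE
    )
  }
  seqs <- character(nrow(junctions))
  dlen <- integer(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    ex <- if (!is.null(models) && !is.na(jx$gene_id)) {
      models[models$gene_id == jx$gene_id, , drop = FALSE]
    } else {
      NULL
    }
    fl <- junction_flank_chr(
      contig_chr[[jx$contig]], jx$donor_end, jx$acceptor_start, w, ex
    )
    seqs[i] <- fl$seq
    dlen[i] <- fl$d
  }
  junctions$flank_seq <- seqs
  junctions$donor_flank <- dlen
  junctions$junction_id <- junction_key(junctions)
  junctions
}
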