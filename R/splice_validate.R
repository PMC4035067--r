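#' Validate junctions by flank-spanning read support
#'
#' A read supports a junction when it aligns gaplessly to the junction's
#' flank sequence with at most `max_mismatch` mismatches (either strand)
#' and its alignment overlaps the internal boundary by at least
#' `min_anchor` bases on each side — without the anchor requirement any
#' read merely ending at the boundary would trivially "span" it.  A
#' junction is validated when at least `min_reads` distinct reads
#' support it.
#'
#' @param reads read set (see [match_reads()] for accepted types).
#' @param junctions flank-annotated junction tibble from
#'   [extract_flanks()].
#' @param max_mismatch mismatch cap per read (default 1).
#' @param min_anchor minimum bases on each side of the boundary.
#' @param min_reads support threshold for validation (default 2).
#' @return `junctions` plus `support` (distinct supporting reads) and
#'   `validated`.
#' @export
validate_junctions <- function(reads, junctions, max_mismatch = 1L,
                               min_anchor = 8L, min_reads = 2L) {
  if (!"flank_seq" %in% names(junctions)) {
    stop("junctions must carry flank sequences; run extract_flanks()",
      call. = FALSE
    )
  }
  reads <- as_named_dna(reads, "read")
  if (length(reads) && nrow(junctions)) {
    side_w <- pmax(
      junctions$donor_flank,
      nchar(junctions$flank_seq) - junctions$donor_flank
    )
    if (max(Biostrings::width(reads)) > 2L * max(side_w)) {
      stop("reads longer than twice the flank width cannot span a ",
        "junction; increase w",
        call. = FALSE
      )
    }
  }
  support <- junction_support(
    reads, junctions$flank_seq, junctions$junction_id,
    junctions$donor_flank, max_mismatch, min_anchor
  )
  junctions$support <- as.integer(unname(support[junctions$junction_id]))
  junctions$support[is.na(junctions$support)] <- 0L
  junctions$validated <- junctions$support >= min_reads
  junctions
}

# Distinct-read support per flank, applying the anchor rule.
junction_support <- function(reads, flank_seq, flank_id, donor_flank,
                             max_mismatch, min_anchor) {
  if (length(reads) == 0 || length(flank_seq) == 0) {
    return(setNames(integer(length(flank_id)), flank_id))
  }
  subjects <- Biostrings::DNAStringSet(setNames(flank_seq, flank_id))
  hits <- hamming_hit_table(reads, subjects, max_mismatch, TRUE)
  if (nrow(hits) == 0) {
    return(setNames(integer(length(flank_id)), flank_id))
  }
  rw <- setNames(Biostrings::width(reads), names(reads))
  d <- setNames(donor_flank, flank_id)
  w_read <- unname(rw[hits$read_id])
  dd <- unname(d[hits$subject_id])
  spans <- hits$start <= dd - min_anchor + 1L &
    hits$start + w_read - 1L >= dd + min_anchor
  hits <- hits[spans, , drop = FALSE]
  sup <- hits %>%
    distinct(.data$read_id, .data$subject_id) %>%
    count(.data$subject_id, name = "support")
  out <- setNames(integer(length(flank_id)), flank_id)
  out[sup$subject_id] <- sup$support
  out
}

#' Detect retained introns from boundary-spanning reads
#'
#' For every annotated intron two retention pseudo-junctions are formed:
#' the contiguous genomic sequence of `w` bases on each side of the
#' exon-end/intron-start boundary, and of the intron-end/exon-start
#' boundary.  A retained intron is called in a library when *both*
#' boundaries are spanned by at least `min_reads` reads under the same
#' alignment and anchor rules as junction validation — reads crossing
#' only one boundary (or exon-interior reads) do not qualify.
#'
#' @param reads read set.
#' @param models exon table.
#' @param genome contig `DNAStringSet`.
#' @param w flank width per side.
#' @param max_mismatch,min_anchor,min_reads as in
#'   [validate_junctions()].
#' @return tibble of intron candidates: `gene_id`, `contig`, `strand`,
#'   `intron_start`, `intron_end`, `support5`, `support3`, `called`.
#' @export
detect_retained_introns <- function(reads, models, genome, w = 65L,
                                    max_mismatch = 1L, min_anchor = 8L,
                                    min_reads = 2L) {
  introns <- enumerate_introns(models)
  if (nrow(introns) == 0) {
    return(introns %>% mutate(
      support5 = integer(0), support3 = integer(0), called = logical(0)
    ))
  }
  contig_chr <- as.character(genome)
  n <- nrow(introns)
  seqs <- character(2L * n)
  dlen <- integer(2L * n)
  ids <- character(2L * n)
  for (i in seq_len(n)) {
    ix <- introns[i, ]
    cs <- contig_chr[[ix$contig]]
    up <- junction_flank_chr(
      cs, ix$intron_start - 1L, ix$intron_start, w, NULL
    )
    dn <- junction_flank_chr(
      cs, ix$intron_end, ix$intron_end + 1L, w, NULL
    )
    seqs[2L * i - 1L] <- up$seq
    dlen[2L * i - 1L] <- up$d
    ids[2L * i - 1L] <- paste0("ri5:", i)
    seqs[2L * i] <- dn$seq
    dlen[2L * i] <- dn$d
    ids[2L * i] <- paste0("ri3:", i)
  }
  reads <- as_named_dna(reads, "read")
  sup <- junction_support(
    reads, seqs, ids, dlen, max_mismatch, min_anchor
  )
  introns$support5 <- as.integer(sup[paste0("ri5:", seq_len(n))])
  introns$support3 <- as.integer(sup[paste0("ri3:", seq_len(n))])
  introns$called <- introns$support5 >= min_reads &
    introns$support3 >= min_reads
  introns
}

# Introns between genomically consecutive exons of each gene.
enumerate_introns <- function(models) {
  per_gene <- split(models, models$gene_id)
  rows <- lapply(per_gene, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2) {
      return(NULL)
    }
    tibble(
      gene_id = ex$gene_id[1],
      contig = ex$contig[1],
      strand = ex$strand[1],
      intron_start = ex$end[-n] + 1L,
      intron_end = ex$start[-1L] - 1L
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      gene_id = character(), contig = character(), strand = character(),
      intron_start = integer(), intron_end = integer()
    ))
  }
  out[out$intron_end >= out$intron_start, , drop = FALSE]
}
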