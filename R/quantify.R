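#' Keep reads that map to a single gene
#'
#' Reads whose hits touch transcripts of two or more distinct genes are
#' discarded (multi-gene reads carry no usable signal under unique-tag
#' counting); reads hitting one gene are assigned once, to their
#' best-scoring transcript hit.
#'
#' @param hits hit table from [match_reads()].
#' @param tx2gene named character vector mapping `transcript_id` to
#'   `gene_id`; every hit transcript must be present.
#' @param read_ids optional character vector of all read names that
#'   entered matching, used to tally unaligned reads.
#' @return list with `assignments` (tibble `read_id`, `gene_id`,
#'   `transcript_id`) and `counts` (tibble `unique`, `multi_gene`,
#'   `unaligned`).
#' @export
filter_unique <- function(hits, tx2gene, read_ids = NULL) {
  missing <- setdiff(unique(hits$subject_id), names(tx2gene))
  if (length(missing)) {
    stop(
      "transcripts without a gene mapping: ",
      paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(hits)) {
    hits <- hits %>% mutate(gene_id = unname(tx2gene[.data$subject_id]))
    per_read <- hits %>%
      group_by(.data$read_id) %>%
      summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
    uni_ids <- per_read$read_id[per_read$n_genes == 1L]
    multi <- nrow(per_read) - length(uni_ids)
    assignments <- hits %>%
      filter(.data$read_id %in% uni_ids) %>%
      arrange(.data$read_id, .data$mismatches, .data$subject_id) %>%
      group_by(.data$read_id) %>%
      summarise(
        gene_id = first(.data$gene_id),
        transcript_id = first(.data$subject_id),
        .groups = "drop"
      )
  } else {
    multi <- 0L
    assignments <- tibble(
      read_id = character(), gene_id = character(),
      transcript_id = character()
    )
  }
  unaligned <- if (is.null(read_ids)) {
    NA_integer_
  } else {
    length(setdiff(read_ids, unique(hits$read_id)))
  }
  list(
    assignments = assignments,
    counts = tibble(
      unique = nrow(assignments),
      multi_gene = as.integer(multi),
      unaligned = unaligned
    )
  )
}

#' FPKM quantification of uniquely assigned reads
#'
#' FPKM is `C * 1e9 / (L * N)` with `C` the transcript's unique fragment
#' count, `L` its length in bp and `N` the library's total uniquely
#' mapped fragments, so the measure is invariant to rescaling all counts
#' and the library size together.
#'
#' @param assignments tibble from [filter_unique()].
#' @param lengths tibble (`transcript_id`, `length`) or named numeric
#'   vector of transcript lengths (bp, > 0); transcripts without
#'   assignments get `C = 0`.
#' @param library_id label stored in the output.
#' @return tibble (`transcript_id`, `library_id`, `C`, `L`, `N`, `FPKM`).
#' @export
quantify <- function(assignments, lengths, library_id = "lib") {
  if (is.numeric(lengths)) {
    lengths <- tibble(
      transcript_id = names(lengths), length = as.numeric(lengths)
    )
  }
  if (any(lengths$length <= 0)) {
    stop("transcript lengths must be > 0", call. = FALSE)
  }
  n_total <- nrow(assignments)
  counts <- assignments %>% count(.data$transcript_id, name = "C")
  out <- lengths %>%
    left_join(counts, by = "transcript_id") %>%
    mutate(
      C = ifelse(is.na(.data$C), 0L, .data$C),
      library_id = library_id,
      L = .data$length,
      N = n_total,
      FPKM = if (n_total == 0) 0 else .data$C * 1e9 / (.data$L * n_total)
    ) %>%
    select("transcript_id", "library_id", "C", "L", "N", "FPKM")
  if (n_total == 0) {
    warning("no uniquely mapped reads; FPKM undefined, emitting zeros",
      call. = FALSE
    )
    out <- out[0, ]
  }
  out
}

#' Expression filter over a library pair
#'
#' A transcript survives if its FPKM reaches `min_fpkm` in at least one
#' of the two libraries of a species (control/salt); transcripts below
#' the floor in both are removed as unexpressed.
#'
#' @param records long FPKM table ([quantify()] rows for two libraries).
#' @param min_fpkm survival threshold (default 1).
#' @return the surviving subset of `records`.
#' @export
expression_filter <- function(records, min_fpkm = 1) {
  libs <- unique(records$library_id)
  if (length(libs) != 2) {
    stop("expression_filter expects exactly two libraries, got ",
      length(libs),
      call. = FALSE
    )
  }
  keep <- records %>%
    group_by(.data$transcript_id) %>%
    summarise(ok = max(.data$FPKM) >= min_fpkm, .groups = "drop")
  records %>%
    filter(
      .data$transcript_id %in% keep$transcript_id[keep$ok]
    )
}

#' Mapped-gene overlaps between the four libraries
#'
#' @param sets named list of four character vectors (mapped gene sets).
#' @return list with `pairwise` (tibble of the 6 pairwise intersection
#'   sizes), `four_way` (size of the joint intersection) and
#'   `fraction_ge2` (fraction of distinct genes present in at least two
#'   libraries).
#' @export
library_overlap <- function(sets) {
  if (length(sets) != 4 || is.null(names(sets))) {
    stop("library_overlap expects a named list of four sets",
      call. = FALSE
    )
  }
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  pairwise <- tibble(
    lib1 = pairs[1, ], lib2 = pairs[2, ],
    intersection = apply(pairs, 2, function(p) {
      length(intersect(sets[[p[1]]], sets[[p[2]]]))
    })
  )
  four_way <- length(Reduce(intersect, sets))
  all_genes <- unique(unlist(sets))
  occ <- rowSums(vapply(
    sets, function(s) all_genes %in% s, logical(length(all_genes))
  ))
  fraction_ge2 <- if (length(all_genes)) {
    mean(occ >= 2)
  } else {
    0
  }
  list(
    pairwise = pairwise, four_way = four_way,
    fraction_ge2 = fraction_ge2
  )
}

#' Library-level mapping summary
#'
#' The tag-accounting row of a library: clean tags split into uniquely
#' aligned, non-uniquely aligned (multi-gene) and unaligned, plus the
#' matched-gene count against the annotated-gene universe.  Percentages
#' are count ratios times 100, rounded half-up to one decimal; the three
#' alignment categories always sum to the clean-tag total.
#'
#' @param total_clean_tags clean reads entering alignment.
#' @param unique_aligned uniquely assigned reads.
#' @param multi_gene reads discarded as multi-gene.
#' @param matched_genes distinct genes with at least one unique tag.
#' @param gene_universe annotated-gene denominator for the matched-gene
#'   percentage.
#' @param library_id label.
#' @return one-row tibble in the summary-table shape.
#' @export
summarize_library <- function(total_clean_tags, unique_aligned,
                              multi_gene, matched_genes, gene_universe,
                              library_id = "lib") {
  unaligned <- total_clean_tags - unique_aligned - multi_gene
  if (unaligned < 0) {
    stop("alignment categories exceed the clean-tag total", call. = FALSE)
  }
  if (total_clean_tags == 0 || gene_universe == 0) {
    warning("zero totals; percentages reported as 0", call. = FALSE)
  }
  tibble(
    library_id = library_id,
    matched_genes = matched_genes,
    matched_genes_pct = pct1(matched_genes, gene_universe),
    unique_aligned = unique_aligned,
    unique_pct = pct1(unique_aligned, total_clean_tags),
    non_unique = multi_gene,
    non_unique_pct = pct1(multi_gene, total_clean_tags),
    unaligned = unaligned,
    unaligned_pct = pct1(unaligned, total_clean_tags),
    total_clean_tags = total_clean_tags
  )
}
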