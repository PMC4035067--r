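#' Classify alternative-splicing events from validated junctions
#'
#' Geometric rules over one library's validated junctions, per gene:
#'
#' * **Pairs sharing an acceptor** (differing donors): if both donors lie
#'   in the same exon the pair is an alternative splice-site event at the
#'   genomic-left side (A5SS on plus-strand genes, A3SS on minus); if the
#'   donors lie in *different* exons and neither of those exons receives
#'   the acceptor of any validated junction of the gene — i.e. both look
#'   like first exons — the pair is an alternative-first/last-exon event
#'   (AFE on plus strand, ALE on minus).
#' * **Pairs sharing a donor** are classified symmetrically at the
#'   genomic-right side.
#' * **Skipped exon**: a validated junction not consumed by any pair
#'   event whose intron span fully contains one or more annotated exons
#'   is one SE event (with that skipped-exon set).  Pair events take
#'   precedence so one junction pair is never double-counted.
#' * **Retained introns** are passed through from
#'   [detect_retained_introns()].
#'
#' Junctions not attached to a gene are skipped with a warning.
#'
#' @param junctions validated-junction tibble ([validate_junctions()]
#'   output); only rows with `validated == TRUE` are used.
#' @param models exon table.
#' @param ri optional retained-intron table; rows with `called == TRUE`
#'   become RI events.
#' @param library_id label stored on the events.
#' @return tibble of events: `library_id`, `type`, `gene_id`, `contig`,
#'   `strand`, `event_id` (identity across libraries), `donor_1`,
#'   `acceptor_1`, `donor_2`, `acceptor_2`, `skipped_exons`.
#' @export
classify_events <- function(junctions, models, ri = NULL,
                            library_id = "lib") {
  vj <- junctions[junctions$validated %||% TRUE, , drop = FALSE]
  orphan <- is.na(vj$gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " validated junction(s) not attached to a ",
      "gene; skipped",
      call. = FALSE
    )
    vj <- vj[!orphan, , drop = FALSE]
  }
  rows <- list()
  for (g in unique(vj$gene_id)) {
    ex <- models[models$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    jg <- vj[vj$gene_id == g, , drop = FALSE]
    strand <- ex$strand[1]
    exon_of <- function(pos) {
      hit <- which(ex$start <= pos & ex$end >= pos)
      if (length(hit)) hit[1] else NA_integer_
    }
    acceptor_exons <- unique(stats::na.omit(
      vapply(jg$acceptor_start, exon_of, integer(1))
    ))
    donor_exons <- unique(stats::na.omit(
      vapply(jg$donor_end, exon_of, integer(1))
    ))
    consumed <- character(0)
    jid <- junction_key(jg)

    emit_pair <- function(type, j1, j2) {
      d <- sort(c(jg$donor_end[j1], jg$donor_end[j2]))
      a <- sort(c(jg$acceptor_start[j1], jg$acceptor_start[j2]))
      tibble(
        library_id = library_id, type = type, gene_id = g,
        contig = ex$contig[1], strand = strand,
        event_id = sprintf(
          "%s:%s:%s:%s", type, g,
          paste(d, collapse = ","), paste(a, collapse = ",")
        ),
        donor_1 = d[1], acceptor_1 = a[1],
        donor_2 = d[2], acceptor_2 = a[2],
        skipped_exons = NA_character_
      )
    }

    # shared-acceptor pairs: variation at the genomic-left (donor) side
    for (acc in unique(jg$acceptor_start[duplicated(jg$acceptor_start)])) {
      members <- which(jg$acceptor_start == acc)
      prs <- utils::combn(members, 2)
      for (k in seq_len(ncol(prs))) {
        j1 <- prs[1, k]
        j2 <- prs[2, k]
        e1 <- exon_of(jg$donor_end[j1])
        e2 <- exon_of(jg$donor_end[j2])
        if (is.na(e1) || is.na(e2)) next
        if (e1 == e2) {
          type <- if (strand == "+") "A5SS" else "A3SS"
        } else if (!(e1 %in% acceptor_exons) &&
          !(e2 %in% acceptor_exons)) {
          type <- if (strand == "+") "AFE" else "ALE"
        } else {
          next
        }
        rows[[length(rows) + 1L]] <- emit_pair(type, j1, j2)
        consumed <- c(consumed, jid[c(j1, j2)])
      }
    }
    # shared-donor pairs: variation at the genomic-right (acceptor) side
    for (don in unique(jg$donor_end[duplicated(jg$donor_end)])) {
      members <- which(jg$donor_end == don)
      prs <- utils::combn(members, 2)
      for (k in seq_len(ncol(prs))) {
        j1 <- prs[1, k]
        j2 <- prs[2, k]
        e1 <- exon_of(jg$acceptor_start[j1])
        e2 <- exon_of(jg$acceptor_start[j2])
        if (is.na(e1) || is.na(e2)) next
        if (e1 == e2) {
          type <- if (strand == "+") "A3SS" else "A5SS"
        } else if (!(e1 %in% donor_exons) && !(e2 %in% donor_exons)) {
          type <- if (strand == "+") "ALE" else "AFE"
        } else {
          next
        }
        rows[[length(rows) + 1L]] <- emit_pair(type, j1, j2)
        consumed <- c(consumed, jid[c(j1, j2)])
      }
    }
    # skipped exons from the remaining junctions
    for (j in seq_len(nrow(jg))) {
      if (jid[j] %in% consumed) next
      skipped <- which(
        ex$start > jg$donor_end[j] & ex$end < jg$acceptor_start[j]
      )
      if (length(skipped) == 0) next
      rows[[length(rows) + 1L]] <- tibble(
        library_id = library_id, type = "SE", gene_id = g,
        contig = ex$contig[1], strand = strand,
        event_id = sprintf(
          "SE:%s:%d:%d", g, jg$donor_end[j], jg$acceptor_start[j]
        ),
        donor_1 = jg$donor_end[j], acceptor_1 = jg$acceptor_start[j],
        donor_2 = NA_integer_, acceptor_2 = NA_integer_,
        skipped_exons = paste(ex$exon[skipped], collapse = ",")
      )
    }
  }
  if (!is.null(ri) && nrow(ri)) {
    called <- ri[ri$called, , drop = FALSE]
    if (nrow(called)) {
      rows[[length(rows) + 1L]] <- tibble(
        library_id = library_id, type = "RI", gene_id = called$gene_id,
        contig = called$contig, strand = called$strand,
        event_id = sprintf(
          "RI:%s:%d:%d", called$gene_id, called$intron_start,
          called$intron_end
        ),
        donor_1 = called$intron_start - 1L,
        acceptor_1 = called$intron_end + 1L,
        donor_2 = NA_integer_, acceptor_2 = NA_integer_,
        skipped_exons = NA_character_
      )
    }
  }
  if (length(rows) == 0) {
    return(empty_events())
  }
  bind_rows(rows) %>% distinct()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_events <- function() {
  tibble(
    library_id = character(), type = character(), gene_id = character(),
    contig = character(), strand = character(), event_id = character(),
    donor_1 = integer(), acceptor_1 = integer(), donor_2 = integer(),
    acceptor_2 = integer(), skipped_exons = character()
  )
}

#' Aggregate alternative-splicing events across libraries
#'
#' Per-library totals are column sums over the six event types; the
#' `Total` column counts distinct events across libraries (union by
#' event identity, i.e. type, gene and defining coordinates).  Locus
#' counts tally distinct genes with any event; when a species map is
#' given, cross-species and salt-specific locus overlaps are reported.
#'
#' @param events row-bound [classify_events()] tables.
#' @param libraries library order for the report columns.
#' @param species_map optional named vector `library -> species`.
#' @param condition_map optional named vector `library -> condition`
#'   (`"control"`/`"salt"`), used for salt-specific locus counts.
#' @return list: `by_type` (type x library counts plus the union
#'   `Total`), `total_events` (per library and union), `loci` (per
#'   library and union), and `locus_overlap` when maps are given.
#' @export
aggregate_as <- function(events, libraries = NULL, species_map = NULL,
                         condition_map = NULL) {
  types <- as_event_types()
  if (is.null(libraries)) {
    libraries <- sort(unique(events$library_id))
  }
  by_type <- tibble(type = types)
  for (lib in libraries) {
    cnt <- events %>%
      filter(.data$library_id == lib) %>%
      count(.data$type)
    by_type[[lib]] <- cnt$n[match(types, cnt$type)]
    by_type[[lib]][is.na(by_type[[lib]])] <- 0L
  }
  uni <- events %>% distinct(.data$type, .data$event_id)
  by_type$Total <- vapply(
    types, function(tp) sum(uni$type == tp), integer(1),
    USE.NAMES = FALSE
  )
  total_events <- c(
    setNames(
      vapply(libraries, function(l) {
        sum(events$library_id == l)
      }, integer(1)),
      libraries
    ),
    Total = nrow(uni)
  )
  locus_sets <- lapply(libraries, function(l) {
    unique(events$gene_id[events$library_id == l])
  })
  names(locus_sets) <- libraries
  loci <- c(
    setNames(lengths(locus_sets), libraries),
    Total = length(unique(events$gene_id))
  )
  out <- list(by_type = by_type, total_events = total_events, loci = loci)
  if (!is.null(species_map)) {
    sp <- unique(unname(species_map[libraries]))
    sp_sets <- lapply(sp, function(s) {
      unique(unlist(locus_sets[names(species_map)[species_map == s]]))
    })
    names(sp_sets) <- sp
    overlap <- list(
      species_loci = lengths(sp_sets),
      common = length(Reduce(intersect, sp_sets))
    )
    if (!is.null(condition_map)) {
      salt_only <- vapply(sp, function(s) {
        libs_s <- intersect(
          names(species_map)[species_map == s], libraries
        )
        salt <- unlist(locus_sets[
          libs_s[condition_map[libs_s] == "salt"]
        ])
        ctrl <- unlist(locus_sets[
          libs_s[condition_map[libs_s] == "control"]
        ])
        length(setdiff(salt, ctrl))
      }, integer(1))
      overlap$salt_only <- setNames(salt_only, sp)
    }
    out$locus_overlap <- overlap
  }
  out
}
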