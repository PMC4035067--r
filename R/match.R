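#' Gapless matching of reads to reference sequences
#'
#' Reports every gapless full-length alignment of each read to each
#' subject sequence with Hamming distance at most `max_mismatch`
#' (default 1, the DGE mapping policy).  Matching is strand-agnostic:
#' reverse-complement alignments are reported with `strand == "-"`.  An
#' unknown base (N) never matches a different letter, so it consumes one
#' mismatch.
#'
#' Internally the engine uses a pigeonhole split: each read is cut into
#' `max_mismatch + 1` pieces, at least one of which must match exactly;
#' exact piece hits are found with an Aho-Corasick dictionary scan
#' ([Biostrings::matchPDict()]) over the concatenated subjects and then
#' verified by direct Hamming count, so its results are exactly those of
#' a brute-force scan of every offset.
#'
#' @param reads named `DNAStringSet` (or `QualityScaledDNAStringSet`, or
#'   named character vector) of reads.
#' @param subjects named `DNAStringSet` (or character) of reference
#'   sequences, e.g. transcripts.
#' @param max_mismatch maximum Hamming distance of a hit.
#' @param both_strands also match the reverse complement?
#' @return tibble with one row per hit: `read_id`, `subject_id`, `start`
#'   (1-based position of the alignment on the subject's forward
#'   sequence), `strand`, `mismatches`.
#' @examples
#' match_reads(
#'   c(r1 = "ACGTACGT"),
#'   c(t1 = "TTTACGTACGTTT")
#' )
#' @export
match_reads <- function(reads, subjects, max_mismatch = 1L,
                        both_strands = TRUE) {
  reads <- as_named_dna(reads, "read")
  subjects <- as_named_dna(subjects, "subject")
  if (length(subjects) == 0) {
    stop("subjects must be non-empty", call. = FALSE)
  }
  hamming_hit_table(reads, subjects, max_mismatch, both_strands)
}

as_named_dna <- function(x, what) {
  if (is(x, "QualityScaledXStringSet")) {
    x <- Biostrings::DNAStringSet(as.character(x))
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  } else if (!is(x, "DNAStringSet")) {
    x <- as(x, "DNAStringSet")
  }
  if (is.null(names(x))) {
    names(x) <- sprintf("%s%d", what, seq_along(x))
  }
  if (anyDuplicated(names(x))) {
    stop(what, " names must be unique", call. = FALSE)
  }
  x
}

hamming_hit_table <- function(reads, subjects, max_mismatch = 1L,
                              both_strands = TRUE) {
  empty <- tibble(
    read_id = character(), subject_id = character(), start = integer(),
    strand = character(), mismatches = integer()
  )
  if (length(reads) == 0) {
    return(empty)
  }
  subj_chr <- as.character(subjects)
  subj_w <- nchar(subj_chr)
  sep <- strrep("N", max(Biostrings::width(reads)) + 5L)
  cat_chr <- paste(subj_chr, collapse = sep)
  # 1-based start of each subject inside the concatenation
  subj_off <- cumsum(c(0L, head(subj_w + nchar(sep), -1)))
  subj_start <- subj_off + 1L
  cat_dna <- Biostrings::DNAString(cat_chr)

  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    pats <- if (strand == "+") {
      reads
    } else {
      Biostrings::reverseComplement(reads)
    }
    pat_chr <- as.character(pats)
    for (w in unique(Biostrings::width(pats))) {
      in_grp <- which(Biostrings::width(pats) == w)
      grp_chr <- pat_chr[in_grp]
      clean <- !grepl("[^ACGT]", grp_chr)
      cand <- collect_candidates(
        pats[in_grp[clean]], w, max_mismatch, cat_dna
      )
      if (any(!clean)) {
        cand <- rbind(cand, brute_candidates(
          grp_chr[!clean], names(pats)[in_grp[!clean]],
          cat_chr, subj_start, subj_w, w
        ))
      }
      if (is.null(cand) || nrow(cand) == 0) next
      cand <- unique(cand)
      # restrict to alignments falling inside a single subject
      idx <- findInterval(cand$start, subj_start)
      ok <- idx >= 1 &
        cand$start + w - 1L <= subj_start[idx] + subj_w[idx] - 1L
      cand <- cand[ok, , drop = FALSE]
      idx <- idx[ok]
      if (nrow(cand) == 0) next
      mm <- mismatch_counts(
        substring(cat_chr, cand$start, cand$start + w - 1L),
        pat_chr[cand$read_id]
      )
      hit <- mm <= max_mismatch
      if (!any(hit)) next
      rows[[length(rows) + 1L]] <- tibble(
        read_id = cand$read_id[hit],
        subject_id = names(subjects)[idx[hit]],
        start = as.integer(cand$start[hit] - subj_off[idx[hit]]),
        strand = strand,
        mismatches = as.integer(mm[hit])
      )
    }
  }
  if (length(rows) == 0) {
    return(empty)
  }
  bind_rows(rows) %>%
    arrange(.data$read_id, .data$subject_id, .data$start, .data$strand)
}

# Candidate alignment starts (in concatenation coordinates) from exact
# matches of the pigeonhole pieces.
collect_candidates <- function(pats, w, max_mismatch, cat_dna) {
  if (length(pats) == 0) {
    return(NULL)
  }
  n_piece <- max_mismatch + 1L
  if (w < n_piece) {
    # shorter than the piece count: every in-bounds offset is a candidate
    starts <- seq_len(length(cat_dna) - w + 1L)
    return(data.frame(
      read_id = rep(names(pats), each = length(starts)),
      start = rep(starts, times = length(pats)),
      stringsAsFactors = FALSE
    ))
  }
  cuts <- floor(seq(0, w, length.out = n_piece + 1L))
  out <- vector("list", n_piece)
  for (p in seq_len(n_piece)) {
    p_start <- cuts[p] + 1L
    piece_chr <- substring(
      as.character(pats), p_start, cuts[p + 1L]
    )
    # duplicated pieces (overlapping reads) are collapsed before the
    # dictionary scan and expanded afterwards
    uniq <- which(!duplicated(piece_chr))
    grp <- match(piece_chr, piece_chr[uniq])
    ids_by_uniq <- split(names(pats), grp)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(piece_chr[uniq]))
    m <- Biostrings::matchPDict(pd, cat_dna)
    cnt <- S4Vectors::elementNROWS(m)
    if (sum(cnt) == 0) next
    starts <- IRanges::start(unlist(m)) - (p_start - 1L)
    rep_idx <- rep.int(seq_along(cnt), cnt)
    ids <- ids_by_uniq[rep_idx]
    n_each <- lengths(ids)
    out[[p]] <- data.frame(
      read_id = unlist(ids, use.names = FALSE),
      start = rep(starts, n_each),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(NULL)
  }
  res <- do.call(rbind, out)
  res[res$start >= 1L, , drop = FALSE]
}

# Fallback for reads containing non-ACGT letters: scan every subject
# offset directly.
brute_candidates <- function(grp_chr, ids, cat_chr, subj_start, subj_w,
                             w) {
  out <- list()
  for (i in seq_along(grp_chr)) {
    for (s in seq_along(subj_start)) {
      if (subj_w[s] < w) next
      starts <- subj_start[s] + seq_len(subj_w[s] - w + 1L) - 1L
      out[[length(out) + 1L]] <- data.frame(
        read_id = ids[i], start = starts, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(NULL)
  }
  do.call(rbind, out)
}

# Hamming distance between equal-length strings, byte-wise.
mismatch_counts <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
    USE.NAMES = FALSE
  )
}
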