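#' Read-cleaning parameters
#'
#' Thresholds of the four cleaning rules, applied in the order
#' duplicates, low-complexity, unknown-base count, base quality:
#'
#' * exact duplicates (identical sequence) are collapsed to their first
#'   occurrence;
#' * low-complexity reads, concretised as a single base making up at
#'   least `low_complexity_rule` of the read, are removed;
#' * reads with more than `max_unknown_bases` N calls are removed;
#' * reads with more than `max_lowq_fraction` of bases at Phred
#'   `<= quality_floor` are removed.
#'
#' @param max_unknown_bases maximum tolerated N calls (default 8; a read
#'   with 9 Ns is removed).
#' @param quality_floor Phred score at or below which a base counts as
#'   low quality.
#' @param max_lowq_fraction maximum tolerated fraction of low-quality
#'   bases.
#' @param drop_exact_duplicates collapse identical sequences?
#' @param low_complexity_rule single-base-run fraction at or above which
#'   a read is low complexity.
#' @return a `qc_params` list.
#' @export
qc_params <- function(max_unknown_bases = 8L, quality_floor = 5L,
                      max_lowq_fraction = 0.5,
                      drop_exact_duplicates = TRUE,
                      low_complexity_rule = 0.8) {
  stopifnot(
    max_unknown_bases >= 0, quality_floor >= 0,
    max_lowq_fraction >= 0, max_lowq_fraction <= 1,
    low_complexity_rule > 0, low_complexity_rule <= 1
  )
  structure(
    list(
      max_unknown_bases = as.integer(max_unknown_bases),
      quality_floor = as.integer(quality_floor),
      max_lowq_fraction = max_lowq_fraction,
      drop_exact_duplicates = isTRUE(drop_exact_duplicates),
      low_complexity_rule = low_complexity_rule
    ),
    class = "qc_params"
  )
}

#' Clean a read library
#'
#' Applies the [qc_params()] rules in order and reports the removal count
#' per rule.  Input plus removals always reconciles: `kept` equals the
#' input count minus the sum of the per-rule removals.
#'
#' @param reads a `QualityScaledDNAStringSet` (see [read_fastq()]).
#' @param params a [qc_params()].
#' @return list with `reads` (the kept subset) and `report`, a one-row
#'   tibble of counts (`input`, `removed_duplicate`,
#'   `removed_low_complexity`, `removed_n_rich`, `removed_low_quality`,
#'   `kept`).
#' @export
clean_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  n_in <- length(reads)
  keep <- reads

  n_dup <- 0L
  if (params$drop_exact_duplicates && length(keep)) {
    dup <- duplicated(as.character(keep))
    n_dup <- sum(dup)
    keep <- keep[!dup]
  }

  n_lc <- 0L
  if (length(keep)) {
    base_max <- apply(
      Biostrings::letterFrequency(keep, c("A", "C", "G", "T")), 1, max
    )
    lc <- base_max / Biostrings::width(keep) >= params$low_complexity_rule
    n_lc <- sum(lc)
    keep <- keep[!lc]
  }

  n_n <- 0L
  if (length(keep)) {
    nn <- as.vector(Biostrings::letterFrequency(keep, "N")) >
      params$max_unknown_bases
    n_n <- sum(nn)
    keep <- keep[!nn]
  }

  n_lq <- 0L
  if (length(keep)) {
    qint <- as(Biostrings::quality(keep), "IntegerList")
    frac_low <- sum(qint <= params$quality_floor) /
      Biostrings::width(keep)
    lq <- frac_low > params$max_lowq_fraction
    n_lq <- sum(lq)
    keep <- keep[!lq]
  }

  report <- tibble(
    input = n_in,
    removed_duplicate = n_dup,
    removed_low_complexity = n_lc,
    removed_n_rich = n_n,
    removed_low_quality = n_lq,
    kept = length(keep)
  )
  list(reads = keep, report = report)
}
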