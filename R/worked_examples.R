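#' Recompute the bundled worked examples
#'
#' A regression harness over reference tables bundled with the package
#' (a published two-species salt-stress DGE study whose printed inputs
#' double as test vectors).  Every quantity is recomputed from its
#' printed *inputs* and compared with the printed value:
#'
#' * log2 FPKM ratios per species for 19 co-up-regulated genes, from the
#'   four printed FPKM columns (zero FPKM is floored at `pseudo_fpkm`
#'   inside the ratio).  Because the printed FPKM inputs are themselves
#'   rounded to two decimals, each row's tolerance comes from interval
#'   arithmetic over the input rounding plus the printed rounding of the
#'   ratio.
#' * library-summary percentages from the printed tag counts, at
#'   one-decimal rounding (one unit in the last place).
#' * alternative-splicing totals as column sums of the printed per-type
#'   counts (exact).
#' * per-species DEG totals, common and union counts from the printed
#'   eight cluster sizes via [cluster_totals()] (exact).
#'
#' @param pseudo_fpkm floor used for zero FPKM inside ratios.
#' @return tibble with one row per check: `check`, `expected`,
#'   `computed`, `tol`, `pass`.
#' @export
verify_worked_examples <- function(pseudo_fpkm = 0.001) {
  ex_dir <- system.file("extdata", "worked_examples",
    package = "saltdge"
  )
  rows <- list()
  add <- function(check, expected, computed, tol) {
    rows[[length(rows) + 1L]] <<- tibble(
      check = check, expected = expected, computed = computed,
      tol = tol, pass = abs(computed - expected) <= tol + 1e-9
    )
  }

  # --- log2 FPKM ratios -------------------------------------------------
  fp <- readr::read_tsv(
    file.path(ex_dir, "fpkm_pairs.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  lfc <- function(salt, ctrl) {
    log2(pmax(salt, pseudo_fpkm) / pmax(ctrl, pseudo_fpkm))
  }
  # interval bound: each printed FPKM is within +-0.005 of the true value
  lfc_tol <- function(salt, ctrl) {
    hi <- lfc(salt + 0.005, pmax(ctrl - 0.005, 0))
    lo <- lfc(pmax(salt - 0.005, 0), ctrl + 0.005)
    (hi - lo) / 2 + 0.005
  }
  for (i in seq_len(nrow(fp))) {
    add(
      paste0("log2_ratio_a:", fp$transcript_id[i]),
      fp$log2_a[i],
      lfc(fp$fpkm_salt_a[i], fp$fpkm_ctrl_a[i]),
      lfc_tol(fp$fpkm_salt_a[i], fp$fpkm_ctrl_a[i])
    )
    add(
      paste0("log2_ratio_b:", fp$transcript_id[i]),
      fp$log2_b[i],
      lfc(fp$fpkm_salt_b[i], fp$fpkm_ctrl_b[i]),
      lfc_tol(fp$fpkm_salt_b[i], fp$fpkm_ctrl_b[i])
    )
  }

  # --- library-summary percentages -------------------------------------
  ls <- readr::read_tsv(
    file.path(ex_dir, "library_summary.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  tc <- readr::read_tsv(
    file.path(ex_dir, "transcript_counts.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  universe <- tc$value[tc$quantity == "annotated_genes"]
  for (i in seq_len(nrow(ls))) {
    lib <- ls$library_id[i]
    s <- summarize_library(
      total_clean_tags = ls$total_clean_tags[i],
      unique_aligned = ls$unique_aligned[i],
      multi_gene = ls$non_unique[i],
      matched_genes = ls$matched_genes[i],
      gene_universe = universe,
      library_id = lib
    )
    add(
      paste0("matched_genes_pct:", lib), ls$matched_genes_pct[i],
      s$matched_genes_pct, 0.1
    )
    add(
      paste0("unique_pct:", lib), ls$unique_pct[i], s$unique_pct, 0.1
    )
    add(
      paste0("non_unique_pct:", lib), ls$non_unique_pct[i],
      s$non_unique_pct, 0.1
    )
    add(
      paste0("unaligned_pct:", lib), ls$unaligned_pct[i],
      s$unaligned_pct, 0.1
    )
  }
  add(
    "transcripts_pct_of_annotated",
    tc$value[tc$quantity == "transcripts_pct_of_annotated"],
    pct1(
      tc$value[tc$quantity == "transcripts_identified"], universe
    ),
    0
  )

  # --- AS totals as column sums ----------------------------------------
  as_types <- readr::read_tsv(
    file.path(ex_dir, "as_event_counts.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  as_totals <- readr::read_tsv(
    file.path(ex_dir, "as_event_totals.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  printed_tot <- as_totals[
    as_totals$quantity == "total_as_events", , drop = FALSE
  ]
  for (col in setdiff(names(as_types), "type")) {
    add(
      paste0("total_as_events:", col),
      printed_tot[[col]],
      sum(as_types[[col]]),
      0
    )
  }

  # --- cluster arithmetic ----------------------------------------------
  cl <- readr::read_tsv(
    file.path(ex_dir, "deg_cluster_sizes.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  tot <- readr::read_tsv(
    file.path(ex_dir, "deg_totals.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  derived <- cluster_totals(cl$size, species = c("Peu", "Ppr"))
  for (i in seq_len(nrow(tot))) {
    add(
      paste0("deg_total:", tot$quantity[i]),
      tot$value[i],
      unname(derived[tot$quantity[i]]),
      0
    )
  }

  bind_rows(rows)
}
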