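#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates every stage over a simulated four-library experiment:
#' generate genome/annotation and plant truth; simulate and QC the four
#' read libraries; match, filter to unique-gene reads and quantify FPKM;
#' call the multi-metric DEG consensus per species and classify the
#' eight cross-species clusters; tabulate categories; cross-validate
#' against simulated qPCR; run PAGE and SEA enrichment (skipped, and
#' noted in the manifest, when `go_map` is `NULL` and
#' `simulate_go = FALSE`); build the junction database and call the six
#' alternative-splicing event types per library; and score recovery
#' against the planted truth.  Identical configurations produce
#' identical bundles.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, report tables (library
#'   summary, DEG table, cluster counts, category counts, enrichment,
#'   AS tables) and a JSON manifest are written there.
#' @param qc [qc_params()] used for read cleaning.
#' @param go_map optional gene-set table (see [page()]); default is the
#'   synthetic map from [simulate_go_map()].
#' @param simulate_go set `FALSE` (with `go_map = NULL`) to skip the
#'   enrichment stage.
#' @param metrics metric list for [call_degs()].
#' @param splice_w flank width for the splice-junction stage.
#' @param min_reads junction-validation read threshold.
#' @param max_mismatch mismatch cap for matching and validation.
#' @param min_anchor junction anchor requirement (bp).
#' @return a `salt_pipeline` list; see the manifest element for the
#'   counts every stage reports.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         qc = qc_params(), go_map = NULL,
                         simulate_go = TRUE,
                         metrics = list(
                           poisson = metric_poisson_ratio,
                           fisher = metric_fisher
                         ),
                         splice_w = 65L, min_reads = 2L,
                         max_mismatch = 1L, min_anchor = 8L) {
  validate_sim_config(config)
  libs <- config$libraries
  species <- config$species

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  # --- synthesize -------------------------------------------------------
  ann <- stage("simulate", generate_annotation(config))
  truth <- stage("simulate", plant_truth(ann$models, config))
  reads <- stage("simulate", lapply(
    setNames(libs, libs),
    function(l) simulate_reads(ann$genome, ann$models, truth, l, config)
  ))

  # --- QC ---------------------------------------------------------------
  qc_out <- stage("qc", lapply(reads, clean_reads, params = qc))
  qc_report <- bind_rows(
    lapply(qc_out, function(x) x$report),
    .id = "library_id"
  )

  # --- match + quantify -------------------------------------------------
  txs <- transcript_seqs(ann$genome, ann$models)
  tl <- transcript_lengths(ann$models)
  t2g <- setNames(tl$gene_id, tl$transcript_id)
  lens <- setNames(tl$length, tl$transcript_id)
  quant <- list()
  summaries <- list()
  gene_sets <- list()
  for (l in libs) {
    kept <- qc_out[[l]]$reads
    hits <- stage("quantify", match_reads(kept, txs, max_mismatch))
    fu <- stage("quantify", filter_unique(hits, t2g, names(kept)))
    quant[[l]] <- quantify(fu$assignments, lens, l)
    gene_sets[[l]] <- unique(fu$assignments$gene_id)
    summaries[[l]] <- summarize_library(
      total_clean_tags = length(kept),
      unique_aligned = fu$counts$unique,
      multi_gene = fu$counts$multi_gene,
      matched_genes = length(gene_sets[[l]]),
      gene_universe = config$n_genes,
      library_id = l
    )
  }
  summaries <- bind_rows(summaries)
  overlap <- library_overlap(gene_sets)

  # --- DEG consensus per species ---------------------------------------
  expr <- list()
  calls <- list()
  for (s in seq_along(species)) {
    ctrl <- libs[2 * s - 1]
    salt <- libs[2 * s]
    pair <- bind_rows(quant[[ctrl]], quant[[salt]])
    pair <- expression_filter(pair)
    wide <- full_join(
      quant[[ctrl]] %>%
        select("transcript_id",
          C_ctrl = "C", N_ctrl = "N", FPKM_ctrl = "FPKM"
        ),
      quant[[salt]] %>%
        select("transcript_id",
          C_salt = "C", N_salt = "N", FPKM_salt = "FPKM"
        ),
      by = "transcript_id"
    ) %>%
      filter(.data$transcript_id %in% unique(pair$transcript_id))
    expr[[species[s]]] <- wide
    calls[[species[s]]] <- stage("deg", call_degs(
      wide,
      metrics = metrics, species = species[s]
    ))
  }
  clusters <- stage("deg", classify_clusters(
    calls[[species[1]]], calls[[species[2]]], species
  ))
  category_map <- simulate_category_map(truth)
  categories <- categorize_degs(calls, category_map)

  # --- qPCR cross-validation -------------------------------------------
  qpcr <- stage("qpcr", {
    ct <- simulate_qpcr(truth)
    val <- list(ct = ct)
    pairs <- list()
    for (s in seq_along(species)) {
      ctrl <- libs[2 * s - 1]
      salt <- libs[2 * s]
      rel <- ddct(
        ct[ct$sample %in% c(ctrl, salt), , drop = FALSE],
        "actin", ctrl
      )
      rel <- rel[rel$sample == salt, , drop = FALSE]
      seq_lfc <- calls[[species[s]]] %>%
        select("transcript_id", "log2_ratio")
      merged <- rel %>%
        inner_join(seq_lfc, by = c(gene = "transcript_id"))
      pairs[[species[s]]] <- merged
    }
    merged_all <- bind_rows(pairs, .id = "species")
    val$fold_changes <- merged_all
    val$pearson_r <- validate_correlation(
      log2(merged_all$rel_expr), merged_all$log2_ratio
    )
    val
  })

  # --- enrichment -------------------------------------------------------
  if (is.null(go_map) && simulate_go) {
    go_map <- simulate_go_map(truth)
  }
  enrichment <- NULL
  if (!is.null(go_map)) {
    enrichment <- stage("enrich", {
      out <- list()
      for (s in species) {
        ratios <- setNames(
          calls[[s]]$log2_ratio, calls[[s]]$transcript_id
        )
        out[[paste0("page_", s)]] <- page(go_map, ratios)
        degs <- calls[[s]]$transcript_id[calls[[s]]$status != "ns"]
        out[[paste0("sea_", s)]] <- sea(
          go_map, degs, calls[[s]]$transcript_id
        )
      }
      out$report <- enrichment_report(
        out[[paste0("page_", species[1])]],
        out[[paste0("page_", species[2])]],
        species
      )
      out
    })
  }

  # --- alternative splicing --------------------------------------------
  splicing <- stage("splice", {
    annotated <- enumerate_annotated_junctions(ann$models)
    merged <- merge_junctions(annotated, truth$novel_junctions)
    flanked <- extract_flanks(merged, ann$genome, ann$models, splice_w)
    events <- list()
    validated <- list()
    for (l in libs) {
      vj <- validate_junctions(
        qc_out[[l]]$reads, flanked, max_mismatch, min_anchor, min_reads
      )
      ri <- detect_retained_introns(
        qc_out[[l]]$reads, ann$models, ann$genome, splice_w,
        max_mismatch, min_anchor, min_reads
      )
      validated[[l]] <- vj
      events[[l]] <- classify_events(
        vj[vj$validated, , drop = FALSE], ann$models, ri, l
      )
    }
    all_events <- bind_rows(events)
    species_map <- setNames(rep(species, each = 2), libs)
    condition_map <- setNames(
      rep(c("control", "salt"), times = 2), libs
    )
    agg <- aggregate_as(all_events, libs, species_map, condition_map)
    list(
      junctions = flanked, validated = validated,
      events = all_events, aggregate = agg
    )
  })

  # --- recovery scoring and manifest -----------------------------------
  recovery <- evaluate_recovery(truth, calls, splicing$events, species)
  manifest <- list(
    config = list(
      n_genes = config$n_genes, library_size = config$library_size,
      seed = config$seed, libraries = libs
    ),
    qc = qc_report,
    library_summaries = summaries,
    mapped_gene_overlap = list(
      four_way = overlap$four_way, fraction_ge2 = overlap$fraction_ge2
    ),
    deg = list(
      cluster_sizes = as.list(clusters$sizes),
      totals = as.list(clusters$totals)
    ),
    qpcr_pearson_r = qpcr$pearson_r,
    enrichment = if (is.null(enrichment)) {
      list(skipped = TRUE)
    } else {
      list(
        skipped = FALSE,
        n_terms_tested = nrow(enrichment[[paste0("page_", species[1])]])
      )
    },
    as_counts = list(
      by_type = splicing$aggregate$by_type,
      total_events = as.list(splicing$aggregate$total_events),
      loci = as.list(splicing$aggregate$loci)
    ),
    recovery = recovery
  )

  result <- list(
    config = config, annotation = ann, truth = truth,
    qc = qc_out, qc_report = qc_report,
    expression = quant, expression_pairs = expr,
    summaries = summaries, overlap = overlap,
    calls = calls, clusters = clusters, categories = categories,
    qpcr = qpcr, enrichment = enrichment, splicing = splicing,
    recovery = recovery, manifest = manifest
  )
  class(result) <- "salt_pipeline"

  if (!is.null(out_dir)) {
    write_pipeline_bundle(result, out_dir)
  }
  result
}

#' Score pipeline calls against the planted truth
#'
#' DEG sensitivity is the fraction of planted (gene, species) regulation
#' events called with the planted direction; the false-call rate is the
#' fraction of unplanted (gene, species) pairs called either direction.
#' Splicing sensitivity (per event type) is the fraction of planted
#' (event, library) pairs recovered by an event with the same identity
#' (type, gene, defining coordinates).
#'
#' @param truth a `sim_truth`.
#' @param calls named list of per-species [call_degs()] tables.
#' @param events combined [classify_events()] table.
#' @param species the two species labels.
#' @return list of recovery metrics.
#' @export
evaluate_recovery <- function(truth, calls, events, species) {
  g <- truth$genes
  expected <- list()
  up_a <- c("a_up_only", "co_up", "a_up_b_down")
  dn_a <- c("a_down_only", "co_down", "a_down_b_up")
  up_b <- c("b_up_only", "co_up", "a_down_b_up")
  dn_b <- c("b_down_only", "co_down", "a_up_b_down")
  exp_status <- function(cls, up, dn) {
    dplyr::case_when(
      cls %in% up ~ "up", cls %in% dn ~ "down", TRUE ~ "ns"
    )
  }
  truth_status <- tibble(
    transcript_id = rep(g$transcript_id, 2),
    species = rep(species, each = nrow(g)),
    expected = c(
      exp_status(g$de_class, up_a, dn_a),
      exp_status(g$de_class, up_b, dn_b)
    )
  )
  called <- bind_rows(calls) %>%
    select("transcript_id", "species", called = "status")
  cmp <- truth_status %>%
    left_join(called, by = c("transcript_id", "species")) %>%
    mutate(called = ifelse(is.na(.data$called), "ns", .data$called))
  planted <- cmp %>% filter(.data$expected != "ns")
  nulls <- cmp %>% filter(.data$expected == "ns")
  deg_sensitivity <- if (nrow(planted)) {
    mean(planted$called == planted$expected)
  } else {
    NA_real_
  }
  deg_false_call_rate <- if (nrow(nulls)) {
    mean(nulls$called != "ns")
  } else {
    NA_real_
  }

  # splicing: expected event identity per planted (event, library)
  tr_ev <- truth$as_events
  as_sens <- list()
  if (nrow(tr_ev)) {
    expected_rows <- list()
    for (i in seq_len(nrow(tr_ev))) {
      e <- tr_ev[i, ]
      eid <- if (e$type == "RI") {
        sprintf("RI:%s:%d:%d", e$gene_id, e$intron_start, e$intron_end)
      } else if (e$type == "SE") {
        sprintf("SE:%s:%d:%d", e$gene_id, e$j1_donor, e$j1_acceptor)
      } else {
        d <- sort(c(e$j1_donor, e$j2_donor))
        a <- sort(c(e$j1_acceptor, e$j2_acceptor))
        sprintf(
          "%s:%s:%s:%s", e$type, e$gene_id,
          paste(d, collapse = ","), paste(a, collapse = ",")
        )
      }
      expected_rows[[i]] <- tibble(
        type = e$type, event_id = eid,
        library_id = strsplit(e$libraries, ";")[[1]]
      )
    }
    expected_ev <- bind_rows(expected_rows)
    found <- events %>% distinct(.data$library_id, .data$event_id)
    expected_ev$hit <- paste(
      expected_ev$library_id, expected_ev$event_id
    ) %in% paste(found$library_id, found$event_id)
    for (tp in as_event_types()) {
      sub <- expected_ev[expected_ev$type == tp, , drop = FALSE]
      as_sens[[tp]] <- if (nrow(sub)) mean(sub$hit) else NA_real_
    }
    planted_ids <- unique(expected_ev$event_id)
    spurious <- events %>%
      distinct(.data$type, .data$event_id) %>%
      filter(!.data$event_id %in% planted_ids) %>%
      count(.data$type)
    as_spurious <- setNames(
      as.list(spurious$n), spurious$type
    )
  } else {
    as_sens <- setNames(
      rep(list(NA_real_), length(as_event_types())), as_event_types()
    )
    as_spurious <- list()
  }
  list(
    deg_sensitivity = deg_sensitivity,
    deg_false_call_rate = deg_false_call_rate,
    n_planted_deg = nrow(planted),
    as_sensitivity = as_sens,
    as_spurious_events = as_spurious
  )
}

#' Write the report bundle of a pipeline run
#'
#' Emits the library-summary, DEG, cluster-count, category-count,
#' enrichment and AS tables as TSV plus a machine-readable JSON manifest
#' of every count, and the log2-FPKM matrix (genes x libraries) for
#' external clustering tools.
#'
#' @param result a `salt_pipeline`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(
    result$summaries, file.path(out_dir, "library_summary.tsv")
  )
  deg_table <- bind_rows(result$calls) %>%
    left_join(result$clusters$assignments, by = "transcript_id")
  write_tsv_file(deg_table, file.path(out_dir, "deg_calls.tsv"))
  write_tsv_file(
    tibble(
      cluster = names(result$clusters$sizes),
      n = as.integer(result$clusters$sizes)
    ),
    file.path(out_dir, "deg_clusters.tsv")
  )
  write_tsv_file(
    result$categories, file.path(out_dir, "deg_categories.tsv")
  )
  if (!is.null(result$enrichment)) {
    write_tsv_file(
      result$enrichment$report, file.path(out_dir, "enrichment.tsv")
    )
  }
  write_tsv_file(
    result$splicing$aggregate$by_type,
    file.path(out_dir, "as_events_by_type.tsv")
  )
  write_tsv_file(
    result$splicing$events, file.path(out_dir, "as_events.tsv")
  )
  ov <- result$splicing$aggregate$locus_overlap
  if (!is.null(ov)) {
    write_tsv_file(
      tibble(
        quantity = c(
          paste0("loci_", names(ov$species_loci)), "loci_common",
          paste0("loci_salt_only_", names(ov$salt_only))
        ),
        value = as.integer(c(
          ov$species_loci, ov$common, ov$salt_only
        ))
      ),
      file.path(out_dir, "as_locus_overlap.tsv")
    )
  }
  # log2 FPKM matrix for external clustering (pseudo-floor for zeros)
  fpkm <- bind_rows(result$expression_pairs, .id = "species")
  log_mat <- fpkm %>%
    select("species", "transcript_id", "FPKM_ctrl", "FPKM_salt") %>%
    tidyr::pivot_longer(
      c("FPKM_ctrl", "FPKM_salt"),
      names_to = "condition", values_to = "FPKM"
    ) %>%
    mutate(log2_fpkm = log2(pmax(.data$FPKM, 0.001)))
  write_tsv_file(log_mat, file.path(out_dir, "log2_fpkm_long.tsv"))
  jsonlite::write_json(
    result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(out_dir)
}
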