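#' Plant ground truth: differential expression and splicing events
#'
#' Assigns each gene an expected fragment count per library, a
#' cross-species differential-expression class (or none), and at most one
#' alternative-splicing event.  Expected counts are
#' `library_size * a_g L_g m_gl / sum(a L)` where `a_g` is a log-normal
#' relative abundance, `L_g` the mature transcript length and `m_gl` the
#' planted fold-change multiplier, so a planted gene's expected log2
#' salt/control ratio equals its planted effect exactly (realised library
#' sizes may drift by the planted mass, as in a real sequencing run).
#'
#' Splicing events are planted only in genes with no DE label so the two
#' ground truths stay orthogonal.  For alternative first/last exon events
#' the gene's mature message drops the alternative exon; all other genes
#' express their full annotated transcript.  Every defining junction of a
#' planted event receives planted spanning reads in the event's libraries
#' (see [simulate_reads()]), so planted events are validatable at the
#' 2-read threshold.
#'
#' @param models exon table from [generate_annotation()].
#' @param config the [sim_config()] used to generate `models`.
#' @return an object of class `sim_truth`: a list with
#'   * `genes`: per-gene tibble with expected counts (`mu_<library>`),
#'     `de_class`, `log2_effect`, expected per-species log2 ratios and the
#'     mature `isoform` (comma-joined transcription-order exon ranks);
#'   * `as_events`: planted events with type, defining junction
#'     coordinates and target libraries;
#'   * `novel_junctions`: planted junctions absent from the annotated
#'     exon-pair database (alternative 5'/3' sites), in the layout the
#'     junction reader consumes.
#' @export
plant_truth <- function(models, config) {
  validate_sim_config(config)
  if (nrow(models) == 0) {
    if (sum(config$de_fraction_per_class) > 0 ||
      sum(config$as_plant_rates) > 0) {
      stop("cannot plant truth into an empty gene model set",
        call. = FALSE
      )
    }
  }
  libs <- config$libraries
  with_seed(derive_seed(config$seed, 1L), {
    gene_info <- models %>%
      group_by(
        .data$gene_id, .data$transcript_id, .data$contig, .data$strand
      ) %>%
      summarise(
        n_exons = dplyr::n(),
        length = sum(.data$end - .data$start + 1L),
        .groups = "drop"
      )
    n <- nrow(gene_info)

    # --- DE classes: one multinomial draw per gene ------------------------
    fr <- config$de_fraction_per_class[de_class_keys()]
    cls <- if (n > 0) {
      sample(
        c(de_class_keys(), "none"), n,
        replace = TRUE, prob = c(fr, 1 - sum(fr))
      )
    } else {
      character(0)
    }
    eff <- ifelse(
      cls == "none", 0,
      config$de_log2_effect + runif(n, 0, 0.5)
    )

    # --- AS events: at most one per gene, never in a DE gene -------------
    rates <- config$as_plant_rates[as_event_types()]
    drawn <- if (n > 0) {
      sample(
        c(as_event_types(), "none"), n,
        replace = TRUE, prob = c(rates, 1 - sum(rates))
      )
    } else {
      character(0)
    }
    drawn[cls != "none"] <- "none"
    plan <- plant_as_events(models, gene_info, drawn, config)

    # --- expected fragment counts ----------------------------------------
    ab <- rlnorm(
      n, config$base_expression[["log_mean"]],
      config$base_expression[["log_sd"]]
    )
    iso_len <- gene_info$length - plan$dropped_len
    mult <- de_multipliers(cls, eff, config$species, libs)
    if (n > 0) {
      # raise planted genes so their control-library expectation clears
      # the configured floor (iterated: raising mass shrinks the rest)
      for (i in seq_len(100)) {
        w <- ab * iso_len
        mu_ctrl <- config$library_size * w / sum(w)
        low <- cls != "none" & mu_ctrl < config$de_min_expected
        if (!any(low)) break
        ab[low] <- ab[low] * 1.001 *
          config$de_min_expected / mu_ctrl[low]
      }
      w <- ab * iso_len
      mu <- config$library_size * outer(w / sum(w), rep(1, 4)) * mult
    } else {
      mu <- matrix(numeric(0), 0, 4)
    }
    colnames(mu) <- paste0("mu_", libs)

    genes <- gene_info %>%
      mutate(
        base_abund = ab,
        de_class = ifelse(cls == "none", NA_character_, cls),
        log2_effect = eff,
        isoform = plan$isoform
      ) %>%
      bind_cols(as_tibble(mu)) %>%
      mutate(
        expected_log2_a = log2(
          .data[[paste0("mu_", libs[2])]] /
            .data[[paste0("mu_", libs[1])]]
        ),
        expected_log2_b = log2(
          .data[[paste0("mu_", libs[4])]] /
            .data[[paste0("mu_", libs[3])]]
        )
      )

    out <- list(
      genes = genes,
      as_events = plan$events,
      support_junctions = plan$support,
      novel_junctions = plan$novel,
      config = config
    )
    class(out) <- "sim_truth"
    out
  })
}

# Fold-change multiplier matrix (genes x 4 libraries, order aC aS bC bS).
de_multipliers <- function(cls, eff, species, libs) {
  n <- length(cls)
  m <- matrix(1, n, 4, dimnames = list(NULL, libs))
  up <- 2^eff
  dn <- 2^-eff
  a_salt <- 2L
  b_salt <- 4L
  m[cls %in% c("a_up_only", "co_up", "a_up_b_down"), a_salt] <-
    up[cls %in% c("a_up_only", "co_up", "a_up_b_down")]
  m[cls %in% c("a_down_only", "co_down", "a_down_b_up"), a_salt] <-
    dn[cls %in% c("a_down_only", "co_down", "a_down_b_up")]
  m[cls %in% c("b_up_only", "co_up", "a_down_b_up"), b_salt] <-
    up[cls %in% c("b_up_only", "co_up", "a_down_b_up")]
  m[cls %in% c("b_down_only", "co_down", "a_up_b_down"), b_salt] <-
    dn[cls %in% c("b_down_only", "co_down", "a_up_b_down")]
  m
}

# Geometry of planted AS events.  Works in genomic exon order; the event
# label is chosen so that, given the gene's strand, the genomic shape is
# read out as the requested type by the caller.
plant_as_events <- function(models, gene_info, drawn, config) {
  n <- nrow(gene_info)
  isoform <- character(n)
  dropped_len <- integer(n)
  events <- list()
  novel <- list()
  support <- list()
  shift <- config$as_site_shift
  pick <- function(v) v[sample.int(length(v), 1L)] # safe for length 1
  for (i in seq_len(n)) {
    gi <- gene_info[i, ]
    ex <- models[models$gene_id == gi$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE] # genomic order
    ne <- nrow(ex)
    isoform[i] <- paste(sort(ex$exon), collapse = ",")
    type <- drawn[i]
    if (type == "none") next
    need <- if (type %in% c("SE", "AFE", "ALE")) 3L else 2L
    if (ne < need) {
      warning(
        "skipping planted ", type, " event in ", gi$gene_id,
        " (needs >= ", need, " exons, has ", ne, ")",
        call. = FALSE
      )
      next
    }
    minus <- gi$strand == "-"
    # genomic shape implementing `type` on this strand
    shape <- switch(type,
      SE = "skip",
      RI = "retain",
      A5SS = if (minus) "alt_right_site" else "alt_left_site",
      A3SS = if (minus) "alt_left_site" else "alt_right_site",
      AFE = if (minus) "alt_right_exon" else "alt_left_exon",
      ALE = if (minus) "alt_left_exon" else "alt_right_exon"
    )
    ev <- tibble(
      event_id = sprintf("ev_%s_%s", type, gi$gene_id),
      type = type, gene_id = gi$gene_id, contig = gi$contig,
      strand = gi$strand,
      libraries = paste(config$libraries, collapse = ";"),
      j1_donor = NA_integer_, j1_acceptor = NA_integer_,
      j2_donor = NA_integer_, j2_acceptor = NA_integer_,
      intron_start = NA_integer_, intron_end = NA_integer_,
      skipped_exon = NA_integer_
    )
    if (shape == "skip") {
      # both isoforms are present: the skip junction defines the event,
      # and the two inclusion junctions get support reads too so the
      # exon reads as skipped rather than as an alternative terminal exon
      k <- pick(2:(ne - 1L))
      ev$j1_donor <- ex$end[k - 1L]
      ev$j1_acceptor <- ex$start[k + 1L]
      ev$skipped_exon <- ex$exon[k]
      support[[length(support) + 1L]] <- tibble(
        event_id = ev$event_id, gene_id = gi$gene_id,
        contig = gi$contig,
        donor = c(ex$end[k - 1L], ex$end[k]),
        acceptor = c(ex$start[k], ex$start[k + 1L]),
        libraries = ev$libraries
      )
    } else if (shape == "retain") {
      k <- pick(seq_len(ne - 1L))
      ev$intron_start <- ex$end[k] + 1L
      ev$intron_end <- ex$start[k + 1L] - 1L
    } else if (shape == "alt_left_site") {
      k <- pick(seq_len(ne - 1L))
      ev$j1_donor <- ex$end[k]
      ev$j1_acceptor <- ex$start[k + 1L]
      ev$j2_donor <- ex$end[k] - shift
      ev$j2_acceptor <- ex$start[k + 1L]
      novel[[length(novel) + 1L]] <- tibble(
        contig = gi$contig, donor_end = ev$j2_donor,
        acceptor_start = ev$j2_acceptor, strand = gi$strand
      )
    } else if (shape == "alt_right_site") {
      k <- pick(seq_len(ne - 1L))
      ev$j1_donor <- ex$end[k]
      ev$j1_acceptor <- ex$start[k + 1L]
      ev$j2_donor <- ex$end[k]
      ev$j2_acceptor <- ex$start[k + 1L] + shift
      novel[[length(novel) + 1L]] <- tibble(
        contig = gi$contig, donor_end = ev$j2_donor,
        acceptor_start = ev$j2_acceptor, strand = gi$strand
      )
    } else if (shape == "alt_left_exon") {
      # two candidate first (genomic-left) exons 1 and 2 joining exon 3;
      # the mature message skips exon 2 so the 1-2 junction is unsupported
      ev$j1_donor <- ex$end[1L]
      ev$j1_acceptor <- ex$start[3L]
      ev$j2_donor <- ex$end[2L]
      ev$j2_acceptor <- ex$start[3L]
      keep <- ex$exon[-2L]
      isoform[i] <- paste(sort(keep), collapse = ",")
      dropped_len[i] <- ex$end[2L] - ex$start[2L] + 1L
    } else if (shape == "alt_right_exon") {
      ev$j1_donor <- ex$end[ne - 2L]
      ev$j1_acceptor <- ex$start[ne]
      ev$j2_donor <- ex$end[ne - 2L]
      ev$j2_acceptor <- ex$start[ne - 1L]
      keep <- ex$exon[-(ne - 1L)]
      isoform[i] <- paste(sort(keep), collapse = ",")
      dropped_len[i] <- ex$end[ne - 1L] - ex$start[ne - 1L] + 1L
    }
    # every defining junction of the event gets planted support reads
    if (ev$type != "RI") {
      jd <- c(ev$j1_donor, ev$j2_donor)
      ja <- c(ev$j1_acceptor, ev$j2_acceptor)
      keep_j <- !is.na(jd)
      support[[length(support) + 1L]] <- tibble(
        event_id = ev$event_id, gene_id = gi$gene_id,
        contig = gi$contig,
        donor = jd[keep_j], acceptor = ja[keep_j],
        libraries = ev$libraries
      )
    }
    events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) bind_rows(events) else empty_as_truth()
  novel <- if (length(novel)) {
    distinct(bind_rows(novel))
  } else {
    tibble(
      contig = character(), donor_end = integer(),
      acceptor_start = integer(), strand = character()
    )
  }
  support <- if (length(support)) {
    distinct(bind_rows(support))
  } else {
    tibble(
      event_id = character(), gene_id = character(),
      contig = character(), donor = integer(), acceptor = integer(),
      libraries = character()
    )
  }
  list(
    events = events, novel = novel, support = support,
    isoform = isoform, dropped_len = dropped_len
  )
}

empty_as_truth <- function() {
  tibble(
    event_id = character(), type = character(), gene_id = character(),
    contig = character(), strand = character(), libraries = character(),
    j1_donor = integer(), j1_acceptor = integer(),
    j2_donor = integer(), j2_acceptor = integer(),
    intron_start = integer(), intron_end = integer(),
    skipped_exon = integer()
  )
}

#' Write a truth table to disk
#'
#' Emits `truth_genes.tsv`, `truth_as_events.tsv` and a combined
#' `truth.json`.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_file(truth$as_events, file.path(dir, "truth_as_events.tsv"))
  jsonlite::write_json(
    list(
      genes = truth$genes, as_events = truth$as_events,
      novel_junctions = truth$novel_junctions
    ),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' Synthetic gene-to-GO mapping
#'
#' Builds a term collection over the simulated genes.  A handful of terms
#' are enriched by sampling preferentially from genes planted as
#' up-regulated in one species, so parametric enrichment has signal to
#' find; the remaining terms are uniform draws.
#'
#' @param truth a `sim_truth`.
#' @param n_terms number of terms.
#' @param term_size integer range of member counts per term.
#' @param n_enriched number of terms biased toward planted up-regulated
#'   genes (half per species).
#' @param enrich_weight sampling weight multiplier for the biased genes.
#' @return tibble (`term_id`, `ontology`, `description`,
#'   `transcript_id`), the layout consumed by [page()] and [sea()].
#' @export
simulate_go_map <- function(truth, n_terms = 40L, term_size = c(10L, 60L),
                            n_enriched = 8L, enrich_weight = 12) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  with_seed(derive_seed(truth$config$seed, 21L), {
    onts <- sample(c("P", "F", "C"), n_terms, replace = TRUE)
    up_a <- !is.na(g$de_class) &
      g$de_class %in% c("a_up_only", "co_up", "a_up_b_down")
    up_b <- !is.na(g$de_class) &
      g$de_class %in% c("b_up_only", "co_up", "a_down_b_up")
    rows <- lapply(seq_len(n_terms), function(i) {
      m <- min(sample_range(term_size, 1L), nrow(g))
      wts <- rep(1, nrow(g))
      if (i <= n_enriched %/% 2) {
        wts[up_a] <- enrich_weight
      } else if (i <= n_enriched) {
        wts[up_b] <- enrich_weight
      }
      tibble(
        term_id = sprintf("TERM:%04d", i),
        ontology = onts[i],
        description = sprintf("synthetic gene set %d", i),
        transcript_id = sample(g$transcript_id, m, prob = wts)
      )
    })
    bind_rows(rows)
  })
}

#' Synthetic functional category map
#'
#' Labels a random subset of genes with transcription-factor-family or
#' transporter categories, for the category tabulation step.
#'
#' @param truth a `sim_truth`.
#' @param categories category labels to draw from.
#' @param n_labelled number of genes to label (each gets one category).
#' @return tibble (`transcript_id`, `category`).
#' @export
simulate_category_map <- function(truth,
                                  categories = c(
                                    "AP2/ERF", "bZIP", "MYB", "WRKY",
                                    "NAC", "transporter"
                                  ),
                                  n_labelled = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  if (is.null(n_labelled)) n_labelled <- max(1L, nrow(g) %/% 5L)
  n_labelled <- min(n_labelled, nrow(g))
  with_seed(derive_seed(truth$config$seed, 22L), {
    tibble(
      transcript_id = sample(g$transcript_id, n_labelled),
      category = sample(categories, n_labelled, replace = TRUE)
    )
  })
}

#' Synthetic qPCR Ct table
#'
#' Emulates a relative-quantification experiment over selected planted
#' genes: target Ct values drop by the planted log2 fold change under
#' salt (one PCR cycle per doubling), with replicate noise, and a
#' reference gene is measured in every sample.
#'
#' @param truth a `sim_truth`.
#' @param n_genes number of target genes (planted DE genes are preferred;
#'   a few stable genes are always included).
#' @param reps technical/biological replicates per gene and sample.
#' @param ref_gene reference (internal control) gene name.
#' @param noise_sd replicate Ct standard deviation (cycles).
#' @return tibble (`gene`, `sample`, `replicate`, `ct`); samples are the
#'   four library names.
#' @export
simulate_qpcr <- function(truth, n_genes = 12L, reps = 3L,
                          ref_gene = "actin", noise_sd = 0.2) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  libs <- truth$config$libraries
  with_seed(derive_seed(truth$config$seed, 23L), {
    de <- g$transcript_id[!is.na(g$de_class)]
    stable <- g$transcript_id[is.na(g$de_class)]
    pick <- c(
      sample(de, min(length(de), max(0L, n_genes - 3L))),
      sample(stable, min(length(stable), 3L))
    )
    gx <- g[match(pick, g$transcript_id), , drop = FALSE]
    base_ct <- runif(nrow(gx), 20, 27)
    rows <- lapply(seq_len(nrow(gx)), function(i) {
      lfc <- c(
        0, gx$expected_log2_a[i], 0, gx$expected_log2_b[i]
      )
      expand <- expand.grid(
        sample = libs, replicate = seq_len(reps),
        stringsAsFactors = FALSE
      )
      tibble(
        gene = gx$transcript_id[i],
        sample = expand$sample,
        replicate = expand$replicate,
        ct = base_ct[i] - lfc[match(expand$sample, libs)] +
          rnorm(nrow(expand), 0, noise_sd)
      )
    })
    ref <- tibble(
      gene = ref_gene,
      sample = rep(libs, each = reps),
      replicate = rep(seq_len(reps), times = length(libs)),
      ct = 15 + rnorm(length(libs) * reps, 0, noise_sd / 2)
    )
    bind_rows(bind_rows(rows), ref)
  })
}
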