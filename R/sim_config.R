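#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults
#' describe the study conditions the downstream recovery checks assume:
#' 500 genes, a planted minimum absolute log2 effect of 2, and at least 50
#' expected fragments per planted differentially expressed gene in its
#' control library.
#'
#' @param n_genes number of genes to simulate.
#' @param exons_per_gene integer range (length 2) of exons per gene.
#' @param exon_len integer range of exon lengths (bp).
#' @param intron_len integer range of intron lengths (bp).
#' @param base_expression log-normal parameters (`log_mean`, `log_sd`) of
#'   the per-gene relative abundance.
#' @param de_fraction_per_class named proportions for the eight
#'   cross-species differential-expression classes (`a_`/`b_` refer to the
#'   first and second species); must sum to at most 1.
#' @param de_log2_effect minimum planted absolute log2 fold change
#'   (must exceed 1, the calling threshold).
#' @param de_min_expected minimum expected fragment count, in the control
#'   library, for a planted DE gene (its abundance is raised if needed).
#' @param count_noise negative-binomial dispersion of fragment counts
#'   (0 gives Poisson counts).
#' @param library_size expected fragments per library.
#' @param as_plant_rates named per-event-type planting probabilities for
#'   the six alternative-splicing event types (`SE`, `RI`, `A5SS`, `A3SS`,
#'   `AFE`, `ALE`); at most one event is planted per gene.
#' @param as_support_reads junction-spanning reads planted per defining
#'   junction per library (>= 2 so planted events are validatable).
#' @param as_site_shift bp offset used for alternative 5'/3' splice sites.
#' @param read_len read length in bp.
#' @param qc_contamination rates of planted contaminant reads: `duplicate`
#'   (exact copies), `n_rich` (more than 8 unknown bases) and
#'   `low_quality` (more than half the bases at Phred <= 5).
#' @param flank_width junction flank width used when planting spanning
#'   reads; mirrors the splice-caller default.
#' @param min_anchor minimum bases a planted spanning read keeps on each
#'   side of a junction boundary; `read_len` must be at least twice this.
#' @param species two labels naming the emulated species; libraries are
#'   named `<species>C` (control) and `<species>S` (salt).
#' @param seed integer seed; every generator stage derives its own stream
#'   from it, so identical configurations give byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 20, library_size = 2000, seed = 7)
#' cfg$libraries
#' @export
sim_config <- function(n_genes = 500L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(120L, 300L),
                       intron_len = c(80L, 200L),
                       base_expression = c(log_mean = log(20), log_sd = 1),
                       de_fraction_per_class = c(
                         a_up_only = 0.03, b_up_only = 0.03,
                         a_down_only = 0.03, b_down_only = 0.03,
                         co_up = 0.02, co_down = 0.02,
                         a_up_b_down = 0.005, a_down_b_up = 0.005
                       ),
                       de_log2_effect = 2,
                       de_min_expected = 50,
                       count_noise = 0.02,
                       library_size = 40000L,
                       as_plant_rates = c(
                         SE = 0.05, RI = 0.05, A5SS = 0.04,
                         A3SS = 0.04, AFE = 0.04, ALE = 0.04
                       ),
                       as_support_reads = 4L,
                       as_site_shift = 12L,
                       read_len = 75L,
                       qc_contamination = c(
                         duplicate = 0.01, n_rich = 0.005, low_quality = 0.005
                       ),
                       flank_width = 65L,
                       min_anchor = 8L,
                       species = c("Peu", "Ppr"),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len),
    base_expression = base_expression,
    de_fraction_per_class = de_fraction_per_class,
    de_log2_effect = de_log2_effect,
    de_min_expected = de_min_expected,
    count_noise = count_noise,
    library_size = as.integer(library_size),
    as_plant_rates = as_plant_rates,
    as_support_reads = as.integer(as_support_reads),
    as_site_shift = as.integer(as_site_shift),
    read_len = as.integer(read_len),
    qc_contamination = qc_contamination,
    flank_width = as.integer(flank_width),
    min_anchor = as.integer(min_anchor),
    species = as.character(species),
    seed = as.integer(seed)
  )
  cfg$libraries <- as.character(
    t(outer(cfg$species, c("C", "S"), paste0))
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

de_class_keys <- function() {
  c(
    "a_up_only", "b_up_only", "a_down_only", "b_down_only",
    "co_up", "co_down", "a_up_b_down", "a_down_b_up"
  )
}

as_event_types <- function() c("SE", "RI", "A5SS", "A3SS", "AFE", "ALE")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  for (fld in c("exons_per_gene", "exon_len", "intron_len")) {
    rng <- cfg[[fld]]
    if (length(rng) != 2 || any(rng < 1) || rng[1] > rng[2]) {
      stop(fld, " must be a non-degenerate integer range", call. = FALSE)
    }
  }
  fr <- cfg$de_fraction_per_class
  if (!setequal(names(fr), de_class_keys())) {
    stop("de_fraction_per_class must name the eight DE classes",
      call. = FALSE
    )
  }
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("DE class proportions must lie in [0,1] and sum to <= 1",
      call. = FALSE
    )
  }
  if (cfg$de_log2_effect <= 1) {
    stop("de_log2_effect must exceed 1", call. = FALSE)
  }
  rates <- cfg$as_plant_rates
  if (!setequal(names(rates), as_event_types())) {
    stop("as_plant_rates must name the six AS event types", call. = FALSE)
  }
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("AS planting rates must lie in [0,1] and sum to <= 1",
      call. = FALSE
    )
  }
  qc <- cfg$qc_contamination
  if (!setequal(names(qc), c("duplicate", "n_rich", "low_quality")) ||
    any(qc < 0) || any(qc > 1)) {
    stop("qc_contamination must give rates in [0,1] for duplicate, ",
      "n_rich and low_quality reads",
      call. = FALSE
    )
  }
  if (cfg$read_len < 2 * cfg$min_anchor) {
    stop("read_len must be at least twice min_anchor", call. = FALSE)
  }
  if (length(cfg$species) != 2 || anyDuplicated(cfg$species)) {
    stop("species must be two distinct labels", call. = FALSE)
  }
  if (cfg$as_support_reads < 2) {
    stop("as_support_reads must be >= 2 (the validation threshold)",
      call. = FALSE
    )
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(
    " ", x$n_genes, "genes;", x$library_size, "fragments/library;",
    "read length", x$read_len, "bp\n"
  )
  cat(
    "  libraries:", paste(x$libraries, collapse = ", "),
    " seed:", x$seed, "\n"
  )
  invisible(x)
}
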