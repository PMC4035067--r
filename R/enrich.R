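#' Parametric analysis of gene set enrichment (PAGE)
#'
#' For a gene set of size `m` with mean log2 ratio `Sm`, against a
#' background of all scored genes with mean `mu` and standard deviation
#' `delta`, the enrichment Z-score is `Z = (Sm - mu) * sqrt(m) / delta`;
#' under random sets Z is approximately standard normal, so `p` is the
#' two-sided normal tail and `q` its BH adjustment.  The background is
#' every gene with a defined ratio (typically all transcripts passing the
#' expression filter), not only the DEGs: PAGE is a whole-distribution
#' method and reports sub-threshold shifts.
#'
#' @param gene_sets long tibble (`term_id`, `ontology`, `description`,
#'   `transcript_id`).
#' @param ratios named numeric vector of per-gene log2 ratios (the
#'   background).
#' @param min_set_size sets with fewer scored members are skipped.
#' @return tibble: `term_id`, `ontology`, `description`, `m`, `Sm`,
#'   `mu`, `delta`, `Z`, `p`, `q`, ordered by `p`.
#' @export
page <- function(gene_sets, ratios, min_set_size = 10L) {
  stopifnot_named_numeric(ratios, "ratios")
  mu <- mean(ratios)
  delta <- sd(ratios)
  if (!is.finite(delta) || delta == 0) {
    stop("degenerate background: ratio standard deviation is zero",
      call. = FALSE
    )
  }
  scored <- gene_sets %>%
    filter(.data$transcript_id %in% names(ratios)) %>%
    mutate(ratio = unname(ratios[.data$transcript_id]))
  out <- scored %>%
    group_by(.data$term_id, .data$ontology, .data$description) %>%
    summarise(
      m = dplyr::n(), Sm = mean(.data$ratio), .groups = "drop"
    ) %>%
    filter(.data$m >= min_set_size) %>%
    mutate(
      mu = mu, delta = delta,
      Z = (.data$Sm - mu) * sqrt(.data$m) / delta,
      p = 2 * pnorm(-abs(.data$Z))
    )
  out$q <- adjust_fdr(out$p)
  out %>% arrange(.data$p)
}

#' Singular enrichment analysis (SEA)
#'
#' Hypergeometric over-representation of each term among the DEGs: with
#' `N` background genes of which `K` carry the term, and `n` DEGs of
#' which `k` carry it, `p = P(X >= k)`; Bonferroni correction multiplies
#' by the number of tested terms.  Significance is `p_bonf < alpha`.
#'
#' @param gene_sets long term table as in [page()].
#' @param degs character vector of DEG ids (must lie in `background`).
#' @param background character vector of all testable gene ids.
#' @param alpha significance level for the corrected p-value.
#' @return tibble: `term_id`, `ontology`, `description`, `K`, `k`, `N`,
#'   `n`, `p`, `p_bonf`, `significant`, ordered by `p`.
#' @export
sea <- function(gene_sets, degs, background, alpha = 0.05) {
  extra <- setdiff(degs, background)
  if (length(extra)) {
    stop(
      "DEGs absent from the background: ",
      paste(head(extra, 5), collapse = ", "),
      call. = FALSE
    )
  }
  nn <- length(unique(degs))
  nb <- length(unique(background))
  sets <- gene_sets %>%
    filter(.data$transcript_id %in% background) %>%
    group_by(.data$term_id, .data$ontology, .data$description) %>%
    summarise(
      K = dplyr::n_distinct(.data$transcript_id),
      k = dplyr::n_distinct(intersect(.data$transcript_id, degs)),
      .groups = "drop"
    )
  n_terms <- nrow(sets)
  sets %>%
    mutate(
      N = nb, n = nn,
      p = phyper(.data$k - 1, .data$K, nb - .data$K, nn,
        lower.tail = FALSE
      ),
      p_bonf = pmin(1, .data$p * n_terms),
      significant = .data$p_bonf < alpha
    ) %>%
    arrange(.data$p)
}

#' Side-by-side enrichment report for two species
#'
#' One row per term with the set size and each species' Z, mean and FDR;
#' terms absent from one species keep blanks there.  Rows are ordered by
#' ontology (P, F, C) and then by the first species' Z descending.
#'
#' @param page_a,page_b [page()] tables computed on the same gene-set
#'   collection (the scored set size `m` is taken from the first species,
#'   falling back to the second where a term was only scored there).
#' @param species labels used as column suffixes.
#' @return wide tibble in the comparison-table shape.
#' @export
enrichment_report <- function(page_a, page_b, species = c("A", "B")) {
  sel <- function(x, suff) {
    x %>%
      select(
        "term_id", "ontology", "description",
        !!paste0("m_", suff) := "m",
        !!paste0("Z_", suff) := "Z",
        !!paste0("mean_", suff) := "Sm",
        !!paste0("fdr_", suff) := "q"
      )
  }
  out <- full_join(
    sel(page_a, species[1]), sel(page_b, species[2]),
    by = c("term_id", "ontology", "description")
  )
  ma <- out[[paste0("m_", species[1])]]
  mb <- out[[paste0("m_", species[2])]]
  za <- out[[paste0("Z_", species[1])]]
  out$m <- ifelse(is.na(ma), mb, ma)
  out[[paste0("m_", species[1])]] <- NULL
  out[[paste0("m_", species[2])]] <- NULL
  out %>%
    mutate(
      .okey = match(.data$ontology, c("P", "F", "C")),
      .zkey = ifelse(is.na(za), -Inf, za)
    ) %>%
    arrange(.data$.okey, desc(.data$.zkey)) %>%
    select(
      "term_id", "ontology", "description", "m", dplyr::everything(),
      -".okey", -".zkey"
    )
}
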