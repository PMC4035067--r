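#' Consensus differential-expression calls for one species
#'
#' A transcript is called up-regulated when all three criteria hold under
#' *every* configured metric (consensus by intersection):
#' 1. FPKM at least `min_fpkm` in either library;
#' 2. `log2(FPKM_salt / FPKM_control)` above `lfc` (below `-lfc` for
#'    down);
#' 3. every metric's BH-adjusted p-value below `alpha`.
#'
#' Zero FPKM inside the ratio is floored at `pseudo_fpkm` (the floor is
#' used only there, never in criterion 1).  Adding a metric can only
#' shrink the called set.
#'
#' @param expr tibble with one row per transcript: `transcript_id`,
#'   `C_ctrl`, `C_salt` (unique fragment counts), `N_ctrl`, `N_salt`
#'   (library totals), `FPKM_ctrl`, `FPKM_salt`.
#' @param metrics named list of metric functions with signature
#'   `f(x, y, N1, N2)` returning p-values (control first); defaults to
#'   the built-in Poisson-ratio and Fisher tests.
#' @param lfc log2 fold-change threshold (criterion 2).
#' @param alpha FDR threshold (criterion 3).
#' @param min_fpkm expression threshold (criterion 1).
#' @param pseudo_fpkm floor applied to zero FPKM inside the ratio.
#' @param species label stored in the output.
#' @return tibble: `transcript_id`, `species`, `log2_ratio`, one
#'   `p_<metric>` and `q_<metric>` column per metric, `status`
#'   (`up`/`down`/`ns`).
#' @export
call_degs <- function(expr,
                      metrics = list(
                        poisson = metric_poisson_ratio,
                        fisher = metric_fisher
                      ),
                      lfc = 1, alpha = 0.05, min_fpkm = 1,
                      pseudo_fpkm = 0.001, species = "sp") {
  need <- c(
    "transcript_id", "C_ctrl", "C_salt", "N_ctrl", "N_salt",
    "FPKM_ctrl", "FPKM_salt"
  )
  if (!all(need %in% names(expr))) {
    stop(
      "expr is missing columns: ",
      paste(setdiff(need, names(expr)), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(metrics) < 1 || is.null(names(metrics))) {
    stop("metrics must be a non-empty named list", call. = FALSE)
  }
  out <- expr %>%
    mutate(
      species = species,
      log2_ratio = log2(
        pmax(.data$FPKM_salt, pseudo_fpkm) /
          pmax(.data$FPKM_ctrl, pseudo_fpkm)
      )
    )
  sig_all <- rep(TRUE, nrow(out))
  for (mn in names(metrics)) {
    p <- metrics[[mn]](expr$C_ctrl, expr$C_salt, expr$N_ctrl, expr$N_salt)
    q <- adjust_fdr(p)
    out[[paste0("p_", mn)]] <- p
    out[[paste0("q_", mn)]] <- q
    sig_all <- sig_all & q < alpha
  }
  expressed <- out$FPKM_ctrl >= min_fpkm | out$FPKM_salt >= min_fpkm
  out$status <- dplyr::case_when(
    expressed & sig_all & out$log2_ratio > lfc ~ "up",
    expressed & sig_all & out$log2_ratio < -lfc ~ "down",
    TRUE ~ "ns"
  )
  out %>%
    select(
      "transcript_id", "species", "log2_ratio",
      dplyr::starts_with("p_"), dplyr::starts_with("q_"), "status"
    )
}

#' Eight-cluster cross-species classification of DEGs
#'
#' Transcripts differentially expressed in at least one species are
#' partitioned into eight clusters by their joint pattern: exclusive
#' up/down per species, co-up, co-down, and the two opposing patterns.
#'
#' @param calls_a,calls_b [call_degs()] tables for the two species over a
#'   shared transcript universe.
#' @param species the two species labels used in cluster names.
#' @return list with `assignments` (tibble `transcript_id`, `cluster`),
#'   `sizes` (named cluster sizes in canonical order) and `totals` (see
#'   [cluster_totals()]).
#' @export
classify_clusters <- function(calls_a, calls_b,
                              species = c("A", "B")) {
  joined <- full_join(
    calls_a %>% select("transcript_id", status_a = "status"),
    calls_b %>% select("transcript_id", status_b = "status"),
    by = "transcript_id"
  ) %>%
    mutate(
      status_a = ifelse(is.na(.data$status_a), "ns", .data$status_a),
      status_b = ifelse(is.na(.data$status_b), "ns", .data$status_b)
    )
  lab <- cluster_labels(species)
  assignments <- joined %>%
    filter(.data$status_a != "ns" | .data$status_b != "ns") %>%
    mutate(cluster = dplyr::case_when(
      .data$status_a == "up" & .data$status_b == "ns" ~ lab[1],
      .data$status_a == "ns" & .data$status_b == "up" ~ lab[2],
      .data$status_a == "down" & .data$status_b == "ns" ~ lab[3],
      .data$status_a == "ns" & .data$status_b == "down" ~ lab[4],
      .data$status_a == "up" & .data$status_b == "up" ~ lab[5],
      .data$status_a == "down" & .data$status_b == "down" ~ lab[6],
      .data$status_a == "up" & .data$status_b == "down" ~ lab[7],
      .data$status_a == "down" & .data$status_b == "up" ~ lab[8]
    )) %>%
    select("transcript_id", "cluster")
  sizes <- setNames(
    as.numeric(table(factor(assignments$cluster, levels = lab))), lab
  )
  list(
    assignments = assignments,
    sizes = sizes,
    totals = cluster_totals(sizes, species)
  )
}

cluster_labels <- function(species = c("A", "B")) {
  a <- species[1]
  b <- species[2]
  c(
    paste0(a, "-up-only"), paste0(b, "-up-only"),
    paste0(a, "-down-only"), paste0(b, "-down-only"),
    "co-up", "co-down",
    paste0(a, "-up/", b, "-down"), paste0(a, "-down/", b, "-up")
  )
}

#' Per-species DEG totals from the eight cluster sizes
#'
#' The eight clusters partition the DEG union, so every headline count
#' reconstructs from them: a species' up total is its exclusive-up
#' cluster plus co-up plus its up-in-opposing cluster, the common-DEG
#' count is the four shared clusters, and the union is the sum of all
#' eight.
#'
#' @param sizes numeric vector of the eight cluster sizes in the
#'   canonical order (A-up-only, B-up-only, A-down-only, B-down-only,
#'   co-up, co-down, A-up/B-down, A-down/B-up).
#' @param species the two species labels.
#' @return named numeric vector: `<A>_up`, `<A>_down`, `<A>_total`,
#'   `<B>_up`, `<B>_down`, `<B>_total`, `common`, `union`.
#' @examples
#' cluster_totals(c(272, 394, 298, 152, 198, 114, 1, 1))
#' @export
cluster_totals <- function(sizes, species = c("A", "B")) {
  if (length(sizes) != 8) {
    stop("sizes must give the eight cluster sizes", call. = FALSE)
  }
  s <- unname(as.numeric(sizes))
  a <- species[1]
  b <- species[2]
  setNames(
    c(
      s[1] + s[5] + s[7], # A up
      s[3] + s[6] + s[8], # A down
      s[1] + s[3] + s[5] + s[6] + s[7] + s[8],
      s[2] + s[5] + s[8], # B up
      s[4] + s[6] + s[7], # B down
      s[2] + s[4] + s[5] + s[6] + s[7] + s[8],
      s[5] + s[6] + s[7] + s[8], # DEG in both species
      sum(s)
    ),
    c(
      paste0(a, "_up"), paste0(a, "_down"), paste0(a, "_total"),
      paste0(b, "_up"), paste0(b, "_down"), paste0(b, "_total"),
      "common", "union"
    )
  )
}

#' Tabulate DEGs by functional category
#'
#' Counts each DEG once per category it belongs to (a gene with two
#' annotations appears in both rows); DEGs absent from the map fall into
#' `Other`.
#'
#' @param calls named list of [call_degs()] tables (one per species).
#' @param category_map tibble (`transcript_id`, `category`).
#' @return tibble `category`, `species`, `direction`, `n`.
#' @export
categorize_degs <- function(calls, category_map) {
  rows <- lapply(names(calls), function(sp) {
    degs <- calls[[sp]] %>% filter(.data$status != "ns")
    if (nrow(degs) == 0) {
      return(NULL)
    }
    cats <- category_map[
      category_map$transcript_id %in% degs$transcript_id, ,
      drop = FALSE
    ]
    degs %>%
      left_join(cats, by = "transcript_id",
        relationship = "many-to-many"
      ) %>%
      mutate(
        category = ifelse(is.na(.data$category), "Other", .data$category)
      ) %>%
      count(.data$category, .data$status, name = "n") %>%
      rename(direction = "status") %>%
      mutate(species = sp)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      category = character(), species = character(),
      direction = character(), n = integer()
    ))
  }
  out %>% select("category", "species", "direction", "n")
}
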