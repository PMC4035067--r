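#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference` within the same sample
#' and replicate; `ddCt = mean dCt_sample - mean dCt_calibrator`;
#' relative expression is `2^-ddCt` (1 in the calibrator by
#' construction).
#'
#' @param ct tibble (`gene`, `sample`, `replicate`, `ct`); the reference
#'   gene must be measured in every sample.
#' @param reference_gene internal-control gene name (e.g. actin).
#' @param calibrator sample against which expression is expressed.
#' @return tibble (`gene`, `sample`, `ddct`, `rel_expr`).
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("g1", "actin"), each = 4),
#'   sample = rep(c("ctrl", "ctrl", "salt", "salt"), 2),
#'   replicate = rep(1:2, 4),
#'   ct = c(25, 25, 22, 22, 15, 15, 15, 15)
#' )
#' ddct(ct, "actin", "ctrl") # g1 in salt: ddCt = -3, fold change 8
#' @export
ddct <- function(ct, reference_gene, calibrator) {
  ref <- ct %>%
    filter(.data$gene == reference_gene) %>%
    select("sample", "replicate", ref_ct = "ct")
  if (!all(unique(ct$sample) %in% ref$sample)) {
    stop("reference gene must be measured in every sample",
      call. = FALSE
    )
  }
  if (!calibrator %in% ct$sample) {
    stop("calibrator sample not present", call. = FALSE)
  }
  dct <- ct %>%
    filter(.data$gene != reference_gene) %>%
    inner_join(ref, by = c("sample", "replicate")) %>%
    mutate(dct = .data$ct - .data$ref_ct) %>%
    group_by(.data$gene, .data$sample) %>%
    summarise(mean_dct = mean(.data$dct), .groups = "drop")
  cal <- dct %>%
    filter(.data$sample == calibrator) %>%
    select("gene", cal_dct = "mean_dct")
  dct %>%
    inner_join(cal, by = "gene") %>%
    mutate(
      ddct = .data$mean_dct - .data$cal_dct,
      rel_expr = 2^-.data$ddct
    ) %>%
    select("gene", "sample", "ddct", "rel_expr")
}

#' Pearson correlation between qPCR and RNA-seq fold changes
#'
#' @param log2_qpcr,log2_rnaseq paired log2 fold changes (n >= 3).
#' @return Pearson's r; `NA` with a warning when either vector has zero
#'   variance.
#' @export
validate_correlation <- function(log2_qpcr, log2_rnaseq) {
  if (length(log2_qpcr) != length(log2_rnaseq) ||
    length(log2_qpcr) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (sd(log2_qpcr) == 0 || sd(log2_rnaseq) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(log2_qpcr, log2_rnaseq, method = "pearson")
}
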