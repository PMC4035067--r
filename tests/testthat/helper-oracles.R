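# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (full scans, direct summation, exhaustive
# enumeration) so they share no code path with the implementation.

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(s, ""), function(x) paste(rev(x), collapse = ""), ""
  ))
}

# all gapless alignments of each read (both strands) at every offset of
# every subject, with Hamming distance <= mm
brute_hamming <- function(reads, subjects, mm = 1) {
  out <- list()
  for (rn in names(reads)) {
    for (sn in names(subjects)) {
      r <- reads[[rn]]
      s <- subjects[[sn]]
      w <- nchar(r)
      L <- nchar(s)
      if (w > L) next
      for (st in 1:(L - w + 1)) {
        seg <- substring(s, st, st + w - 1)
        for (strand in c("+", "-")) {
          q <- if (strand == "+") r else revcomp_chr(r)
          d <- sum(charToRaw(seg) != charToRaw(q))
          if (d <= mm) {
            out[[length(out) + 1]] <- data.frame(
              read_id = rn, subject_id = sn, start = as.integer(st),
              strand = strand, mismatches = as.integer(d),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      read_id = character(), subject_id = character(),
      start = integer(), strand = character(), mismatches = integer(),
      stringsAsFactors = FALSE
    ))
  }
  b <- do.call(rbind, out)
  b <- b[order(b$read_id, b$subject_id, b$start, b$strand), ]
  rownames(b) <- NULL
  b
}

# direct log-space summation of the conditional tag-count distribution
brute_poisson_ratio_p <- function(x, y, N1, N2, ymax = 5e5) {
  r <- N2 / N1
  lp <- function(yy) {
    yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
      lgamma(yy + 1) - (x + yy + 1) * log(1 + r)
  }
  ys <- 0:ymax
  pm <- exp(lp(ys))
  lo <- sum(pm[ys <= y])
  hi <- sum(pm[ys >= y])
  min(1, 2 * min(lo, hi))
}

# exhaustive enumeration of 2x2 tables with fixed margins; two-sided
# Fisher p sums probabilities <= that of the observed table
brute_fisher_p <- function(x, y, N1, N2) {
  n_col1 <- x + y
  lprob <- function(a) {
    lchoose(N1, a) + lchoose(N2, n_col1 - a) - lchoose(N1 + N2, n_col1)
  }
  a_all <- max(0, n_col1 - N2):min(N1, n_col1)
  p_all <- exp(lprob(a_all))
  p_obs <- exp(lprob(x))
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by enumeration over achievable k
brute_hyper_p <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  pm <- exp(
    lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  )
  sum(pm[ks >= k])
}

# hand Benjamini-Hochberg step-up
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# small deterministic annotation fixture: 3 genes on one contig
tiny_models <- function() {
  tibble::tibble(
    gene_id = rep(c("gA", "gB", "gC"), times = c(3, 2, 1)),
    transcript_id = rep(c("gA.1", "gB.1", "gC.1"), times = c(3, 2, 1)),
    contig = "ctg01",
    strand = c("+", "+", "+", "-", "-", "+"),
    exon = c(1L, 2L, 3L, 2L, 1L, 1L),
    start = c(11L, 61L, 121L, 201L, 261L, 331L),
    end = c(40L, 90L, 160L, 230L, 300L, 380L)
  )
}

tiny_genome <- function(seed = 42, len = 500) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(
    ctg01 = paste(sample(c("A", "C", "G", "T"), len, TRUE),
      collapse = ""
    )
  ))
}

# reads as a QualityScaledDNAStringSet with uniform quality
qreads <- function(seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- strrep("I", nchar(seqs))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals)
  )
  if (is.null(names(seqs))) {
    names(x) <- sprintf("r%03d", seq_along(x))
  } else {
    names(x) <- names(seqs)
  }
  x
}
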