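#' Simulate a sequencing library
#'
#' Draws per-gene fragment counts (negative binomial around the planted
#' expectations), samples read start positions uniformly along each
#' gene's mature transcript, adds junction-spanning reads for every
#' planted alternative-splicing event targeted at this library, and
#' injects the three QC-relevant contaminant classes (exact duplicates,
#' N-rich reads, low-quality reads) at the configured rates.  Reads are
#' single-end `read_len`-mers with Sanger Phred+33 qualities; paired-end
#' sequencing is emulated at the fragment-count level only.
#'
#' A zero `library_size` yields an empty read set.
#'
#' @param genome named contig `DNAStringSet`.
#' @param models exon table.
#' @param truth a [plant_truth()] result.
#' @param library_id one of `config$libraries`.
#' @param config the generating [sim_config()].
#' @return a [Biostrings::QualityScaledDNAStringSet] with unique read
#'   names.
#' @export
simulate_reads <- function(genome, models, truth, library_id, config) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "sim_truth"))
  lib_idx <- match(library_id, config$libraries)
  if (is.na(lib_idx)) {
    stop(
      "library_id must be one of: ",
      paste(config$libraries, collapse = ", "),
      call. = FALSE
    )
  }
  rl <- config$read_len
  if (config$library_size == 0L) {
    return(empty_reads())
  }
  with_seed(derive_seed(config$seed, 10L + lib_idx), {
    g <- truth$genes
    mu <- g[[paste0("mu_", library_id)]]
    disp <- config$count_noise
    counts <- if (disp > 0) {
      rnbinom(nrow(g), mu = mu, size = 1 / disp)
    } else {
      rpois(nrow(g), mu)
    }

    iso <- lapply(strsplit(g$isoform, ","), as.integer)
    names(iso) <- g$gene_id
    txs <- transcript_seqs(genome, models, iso)
    tx_chr <- as.character(txs)[g$transcript_id]

    seqs <- character(0)
    for (i in seq_len(nrow(g))) {
      if (counts[i] == 0L) next
      L <- nchar(tx_chr[i])
      if (L < rl) next
      pos <- sample.int(L - rl + 1L, counts[i], replace = TRUE)
      seqs <- c(seqs, substring(tx_chr[i], pos, pos + rl - 1L))
    }

    seqs <- c(seqs, planted_junction_reads(
      genome, models, truth, library_id, config
    ))

    quals <- rep(strrep("I", rl), length(seqs))

    # contaminants ---------------------------------------------------------
    n_base <- length(seqs)
    rates <- config$qc_contamination
    nd <- rbinom(1L, n_base, rates[["duplicate"]])
    if (nd > 0) {
      idx <- sample.int(n_base, nd, replace = TRUE)
      seqs <- c(seqs, seqs[idx])
      quals <- c(quals, quals[idx])
    }
    nn <- rbinom(1L, n_base, rates[["n_rich"]])
    if (nn > 0) {
      nr <- vapply(seq_len(nn), function(i) {
        s <- sample(c("A", "C", "G", "T"), rl, replace = TRUE)
        k <- sample(9:min(20L, rl), 1L)
        s[sample.int(rl, k)] <- "N"
        paste(s, collapse = "")
      }, character(1))
      seqs <- c(seqs, nr)
      quals <- c(quals, rep(strrep("I", rl), nn))
    }
    nl <- rbinom(1L, n_base, rates[["low_quality"]])
    if (nl > 0) {
      lq <- vapply(seq_len(nl), function(i) {
        paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
          collapse = ""
        )
      }, character(1))
      lq_qual <- vapply(seq_len(nl), function(i) {
        q <- rep("I", rl)
        k <- ceiling(rl * runif(1, 0.55, 0.9))
        q[sample.int(rl, k)] <- "#"
        paste(q, collapse = "")
      }, character(1))
      seqs <- c(seqs, lq)
      quals <- c(quals, lq_qual)
    }

    if (length(seqs) == 0L) {
      return(empty_reads())
    }
    ord <- sample.int(length(seqs))
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs[ord]),
      Biostrings::PhredQuality(quals[ord])
    )
    names(out) <- sprintf("%s_r%06d", library_id, seq_along(out))
    out
  })
}

empty_reads <- function() {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(character(0)),
    Biostrings::PhredQuality(character(0))
  )
}

# Junction-spanning and intron-boundary reads for planted events targeted
# at `library_id`.  Read start offsets are sampled without replacement so
# planted support survives exact-duplicate removal.
planted_junction_reads <- function(genome, models, truth, library_id,
                                   config) {
  in_lib <- function(libstr) {
    vapply(
      strsplit(libstr, ";"),
      function(ls) library_id %in% ls, logical(1)
    )
  }
  contig_chr <- as.character(genome)
  rl <- config$read_len
  anchor <- config$min_anchor
  w <- config$flank_width
  k <- config$as_support_reads
  out <- character(0)

  # spliced-junction support reads (skip, inclusion, alternative-site
  # and alternative-exon junctions alike)
  sup <- truth$support_junctions
  if (!is.null(sup) && nrow(sup)) {
    sup <- sup[in_lib(sup$libraries), , drop = FALSE]
    for (i in seq_len(nrow(sup))) {
      ex <- models[models$gene_id == sup$gene_id[i], , drop = FALSE]
      fl <- junction_flank_chr(
        contig_chr[[sup$contig[i]]], sup$donor[i], sup$acceptor[i], w, ex
      )
      out <- c(out, spanning_reads_chr(
        fl$seq, fl$d, rl, anchor, k,
        lo_bound = 1L, hi_bound = nchar(fl$seq)
      ))
    }
  }

  # intron-retention boundary reads (contiguous genomic sequence)
  ev <- truth$as_events
  if (nrow(ev)) {
    ri <- ev[ev$type == "RI" & in_lib(ev$libraries), , drop = FALSE]
    for (i in seq_len(nrow(ri))) {
      cs <- contig_chr[[ri$contig[i]]]
      for (p in c(ri$intron_start[i] - 1L, ri$intron_end[i])) {
        out <- c(out, spanning_reads_chr(
          cs, p, rl, anchor, k,
          lo_bound = 1L, hi_bound = nchar(cs)
        ))
      }
    }
  }
  out
}

# Reads of length rl spanning the boundary after position `p` of `seq`,
# keeping >= `anchor` bases on each side; distinct start offsets.
spanning_reads_chr <- function(seq, p, rl, anchor, k, lo_bound, hi_bound) {
  s_min <- max(lo_bound, p + anchor - rl + 1L)
  s_max <- min(p - anchor + 1L, hi_bound - rl + 1L)
  if (s_max < s_min) {
    warning("cannot place spanning reads (window too small); skipping",
      call. = FALSE
    )
    return(character(0))
  }
  cand <- seq.int(s_min, s_max)
  starts <- cand[sample.int(length(cand), min(k, length(cand)))]
  substring(seq, starts, starts + rl - 1L)
}

# Flank sequence around a junction: up to `w` bases ending at the donor
# and starting at the acceptor, truncated to the containing exon (or to
# the contig where no exon contains the coordinate).  Returns the
# concatenated sequence and the donor-side length `d`.
junction_flank_chr <- function(contig_chr, donor_end, acceptor_start, w,
                               exons = NULL) {
  len <- nchar(contig_chr)
  if (donor_end < 1 || acceptor_start > len || donor_end >= acceptor_start) {
    stop("junction coordinates off contig", call. = FALSE)
  }
  d_lo <- 1L
  a_hi <- len
  if (!is.null(exons) && nrow(exons)) {
    dx <- exons$start <= donor_end & exons$end >= donor_end
    if (any(dx)) d_lo <- max(exons$start[dx])
    ax <- exons$start <= acceptor_start & exons$end >= acceptor_start
    if (any(ax)) a_hi <- min(exons$end[ax])
  }
  ds <- max(d_lo, donor_end - w + 1L)
  ae <- min(a_hi, acceptor_start + w - 1L)
  list(
    seq = paste0(
      substr(contig_chr, ds, donor_end),
      substr(contig_chr, acceptor_start, ae)
    ),
    d = donor_end - ds + 1L
  )
}

#' Write and read FASTQ (Sanger Phred+33)
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(
      path,
      quality.scoring = "phred"
    ),
    # Biostrings notes that it drops its own internal quality mcols
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
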