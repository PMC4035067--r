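# Shared small helpers.

#' Round half away from zero
#'
#' Fixed-point rounding used for report percentages, so that e.g. 74.45
#' prints as 74.5 regardless of the IEC 60559 banker's rounding that
#' `round()` applies to ties.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of `num` over `den`, rounded half-up to one decimal; 0 when
# the denominator is zero (callers decide whether that deserves a warning).
pct1 <- function(num, den) {
  out <- ifelse(den == 0, 0, 100 * num / den)
  round_half_up(out, 1)
}

# Deterministic sub-seed derivation: each stochastic stage draws from its
# own stream so that stages are individually reproducible.  Kept < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

stopifnot_named_numeric <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named numeric vector", call. = FALSE)
  }
  invisible(x)
}
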