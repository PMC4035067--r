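test_that("Poisson-ratio test matches direct summation of its distribution", {
  cases <- list(
    c(0, 20, 1e6, 1e6), c(5, 9, 1e6, 2e6), c(50, 12, 1e6, 1.1e6),
    c(3, 3, 5e5, 5e5), c(0, 0, 1e6, 1e6), c(100, 180, 2e6, 2e6)
  )
  for (cs in cases) {
    got <- metric_poisson_ratio(cs[1], cs[2], cs[3], cs[4])
    want <- brute_poisson_ratio_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Poisson-ratio test is symmetric where symmetry is exact", {
  # equal counts in equal libraries: p = 1 after capping
  expect_equal(metric_poisson_ratio(5, 5, 1e6, 1e6), 1)
  expect_equal(metric_poisson_ratio(0, 0, 3e6, 3e6), 1)
  # the conditional construction is only near-symmetric under
  # exchanging the libraries; check agreement on the log scale
  p1 <- metric_poisson_ratio(3, 10, 1e6, 2e6)
  p2 <- metric_poisson_ratio(10, 3, 2e6, 1e6)
  expect_lt(abs(log10(p1) - log10(p2)), log10(2) + 1e-9)
  expect_error(metric_poisson_ratio(-1, 2, 1e6, 1e6), "non-negative")
})

test_that("Fisher metric agrees with exhaustive table enumeration", {
  expect_equal(metric_fisher(5, 5, 10, 10), 1)
  cases <- list(
    c(10, 0, 10, 10), c(3, 7, 12, 12), c(0, 6, 8, 20), c(2, 2, 4, 4)
  )
  for (cs in cases) {
    got <- metric_fisher(cs[1], cs[2], cs[3], cs[4])
    want <- brute_fisher_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
  # monotone: a more extreme imbalance at fixed margins never raises p
  p_seq <- vapply(0:5, function(x) {
    metric_fisher(5 + x, 5 - x, 20, 20)
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("BH adjustment reproduces the hand example and its bounds", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  set.seed(1)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_equal(q, brute_bh(p))
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG consensus applies all three criteria under every metric", {
  expr <- tibble::tibble(
    transcript_id = c("up", "weak_fc", "weak_p", "unexpressed", "down"),
    C_ctrl = c(10, 100, 50, 0, 200),
    C_salt = c(100, 190, 60, 4, 40),
    N_ctrl = 1e5, N_salt = 1e5,
    FPKM_ctrl = c(5, 50, 25, 0.0, 100),
    FPKM_salt = c(50, 93, 30, 0.9, 20)
  )
  calls <- call_degs(expr, species = "Peu")
  st <- setNames(calls$status, calls$transcript_id)
  expect_equal(unname(st["up"]), "up")
  expect_equal(unname(st["weak_fc"]), "ns") # |log2 0.9| < 1 despite tiny p
  expect_equal(unname(st["weak_p"]), "ns")
  expect_equal(unname(st["unexpressed"]), "ns") # FPKM < 1 both sides
  expect_equal(unname(st["down"]), "down")
  # published worked examples of the ratio criterion
  expect_equal(
    round(log2(430.78 / 17.64), 2), 4.61
  )
  expect_equal(
    round(log2(190.54 / 48.70), 2), 1.97
  )
  # a zero denominator is floored inside the ratio only
  r <- call_degs(
    tibble::tibble(
      transcript_id = "z", C_ctrl = 0, C_salt = 50,
      N_ctrl = 1e5, N_salt = 1e5, FPKM_ctrl = 0, FPKM_salt = 15.30
    ),
    species = "x"
  )
  expect_equal(r$log2_ratio, log2(15.30 / 0.001), tolerance = 1e-12)
  expect_equal(round(r$log2_ratio, 2), 13.90)
})

test_that("adding a metric never enlarges the DEG set", {
  set.seed(42)
  n <- 150
  expr <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:n),
    C_ctrl = rpois(n, 60),
    C_salt = rpois(n, 60 * sample(c(1, 4), n, TRUE, c(0.8, 0.2))),
    N_ctrl = 2e5, N_salt = 2e5
  ) |>
    dplyr::mutate(
      FPKM_ctrl = C_ctrl * 1e9 / (1000 * N_ctrl),
      FPKM_salt = C_salt * 1e9 / (1000 * N_salt)
    )
  one <- call_degs(expr,
    metrics = list(poisson = metric_poisson_ratio), species = "s"
  )
  two <- call_degs(expr, species = "s")
  deg1 <- one$transcript_id[one$status != "ns"]
  deg2 <- two$transcript_id[two$status != "ns"]
  expect_true(all(deg2 %in% deg1))
})

test_that("eight clusters partition the DEG union and rebuild totals", {
  mk <- function(ids, status, sp) {
    tibble::tibble(
      transcript_id = ids, species = sp, log2_ratio = 0,
      status = status
    )
  }
  a <- mk(
    c("t1", "t2", "t3", "t4", "t5", "t6"),
    c("up", "up", "down", "ns", "up", "down"), "A"
  )
  b <- mk(
    c("t1", "t2", "t3", "t4", "t5", "t6"),
    c("up", "ns", "down", "down", "down", "ns"), "B"
  )
  cl <- classify_clusters(a, b, species = c("A", "B"))
  expect_equal(sum(cl$sizes), 6) # t1..t6 minus none: all but t4? t4 is B-down
  got <- setNames(
    cl$assignments$cluster, cl$assignments$transcript_id
  )
  expect_equal(unname(got["t1"]), "co-up")
  expect_equal(unname(got["t2"]), "A-up-only")
  expect_equal(unname(got["t3"]), "co-down")
  expect_equal(unname(got["t4"]), "B-down-only")
  expect_equal(unname(got["t5"]), "A-up/B-down")
  expect_equal(unname(got["t6"]), "A-down-only")
  expect_equal(unname(cl$totals["A_up"]), 3)
  expect_equal(unname(cl$totals["union"]), 6)
  # all-ns: every cluster empty
  empty <- classify_clusters(
    mk("t1", "ns", "A"), mk("t1", "ns", "B")
  )
  expect_true(all(empty$sizes == 0))
})

test_that("category tabulation counts DEGs once per category", {
  calls <- list(
    A = tibble::tibble(
      transcript_id = c("t1", "t2", "t3"), species = "A",
      log2_ratio = 2, status = c("up", "up", "down")
    )
  )
  cmap <- tibble::tibble(
    transcript_id = c("t1", "t2", "t1"),
    category = c("WRKY", "WRKY", "transporter")
  )
  out <- categorize_degs(calls, cmap)
  expect_equal(
    out$n[out$category == "WRKY" & out$direction == "up"], 2
  )
  # a DEG with two categories is counted in both
  expect_equal(
    out$n[out$category == "transporter" & out$direction == "up"], 1
  )
  # uncategorized DEGs land in Other
  expect_equal(
    out$n[out$category == "Other" & out$direction == "down"], 1
  )
  none <- categorize_degs(calls, cmap[0, ])
  expect_true(all(none$category == "Other"))
})

test_that("2^-ddCt reproduces its closed-form examples", {
  grid <- expand.grid(
    sample = c("ctrl", "salt"), replicate = 1:3,
    stringsAsFactors = FALSE
  )
  # target identical to reference everywhere: relative expression 1
  ct <- dplyr::bind_rows(
    tibble::tibble(
      gene = "g1", sample = grid$sample, replicate = grid$replicate,
      ct = 20
    ),
    tibble::tibble(
      gene = "actin", sample = grid$sample, replicate = grid$replicate,
      ct = 20
    )
  )
  r <- ddct(ct, "actin", "ctrl")
  expect_true(all(r$rel_expr == 1))
  # ddCt = -3 (target drops 3 cycles under salt): fold change 8
  ct2 <- ct
  ct2$ct[ct2$gene == "g1" & ct2$sample == "salt"] <- 17
  r2 <- ddct(ct2, "actin", "ctrl")
  expect_equal(r2$rel_expr[r2$sample == "salt"], 8)
  # ddCt = +1: fold change 0.5
  ct3 <- ct
  ct3$ct[ct3$gene == "g1" & ct3$sample == "salt"] <- 21
  r3 <- ddct(ct3, "actin", "ctrl")
  expect_equal(r3$rel_expr[r3$sample == "salt"], 0.5)
  expect_error(
    ddct(ct[ct$gene != "actin", ], "actin", "ctrl"), "reference"
  )
})

test_that("validation correlation matches the textbook formula", {
  expect_equal(validate_correlation(1:5, 1:5), 1)
  expect_equal(validate_correlation(1:5, -(1:5)), -1)
  x <- c(1, 2, 3)
  y <- c(2, 4, 7)
  n <- 3
  r_direct <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(validate_correlation(x, y), r_direct, tolerance = 1e-10)
  expect_warning(
    r0 <- validate_correlation(c(1, 1, 1), c(1, 2, 3)),
    "zero variance"
  )
  expect_true(is.na(r0))
})
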