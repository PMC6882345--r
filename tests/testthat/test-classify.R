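test_that("cells classify to the standard eight-rule scheme", {
  expect_equal(classify_cell(1, FALSE, FALSE), 1L)
  expect_equal(classify_cell(1, FALSE, TRUE), 2L)
  expect_equal(classify_cell(1, TRUE, FALSE), 3L)
  expect_equal(classify_cell(1, TRUE, TRUE), 4L)
  expect_equal(classify_cell(2, FALSE, FALSE), 5L)
  expect_equal(classify_cell(7, TRUE, TRUE), 8L)
})

test_that("default rules are exhaustive over counts and flag combinations", {
  grid <- expand.grid(count = 1:5, maf = c(FALSE, TRUE),
                      conseq = c(FALSE, TRUE))
  got <- classify_cell(grid$count, grid$maf, grid$conseq)
  want <- ifelse(grid$count == 1, 1L, 5L) +
    2L * grid$maf + 1L * grid$conseq
  expect_equal(got, want)
  expect_true(all(got %in% 1:8))
})

test_that("rule matching generalises to more count tiers", {
  rules <- expand.grid(min_count = c(1L, 2L, 10L), maf = c(FALSE, TRUE),
                       conseq = c(FALSE, TRUE))
  rules$idx <- seq_len(nrow(rules))
  rules$colour <- "black"; rules$report <- FALSE
  expect_equal(classify_cell(9, FALSE, FALSE, rules),
               rules$idx[rules$min_count == 2 & !rules$maf & !rules$conseq])
  expect_equal(classify_cell(10, FALSE, FALSE, rules),
               rules$idx[rules$min_count == 10 & !rules$maf & !rules$conseq])
})

test_that("Benjamini-Hochberg boundary follows the step-up rule", {
  b <- fdr_threshold(c(0.001, 0.01, 0.02, 0.8), q = 0.05)
  expect_equal(b$p_star, 0.02)
  expect_equal(b$nlp_star, -log10(0.02), tolerance = 1e-12)
  expect_equal(b$boundary_col, ceiling(-log10(0.02) / 0.125))

  none <- fdr_threshold(c(1, 1, 1), q = 0.05)
  expect_true(is.na(none$p_star))
  expect_identical(none$boundary_col, Inf)

  single <- fdr_threshold(0.04, q = 0.05)
  expect_equal(single$p_star, 0.04)

  expect_error(fdr_threshold(numeric(0), q = 0.05),
               class = "gg_input_error")
})

test_that("a fixed -log10 p threshold can replace the FDR boundary", {
  opts <- gg_options(threshold_nlp = "genomewide")
  b <- fdr_threshold(runif(10), options = opts)
  expect_equal(b$p_star, 5e-8, tolerance = 1e-12)
  expect_equal(b$boundary_col, ceiling(-log10(5e-8) / 0.125))
})

test_that("BH boundary agrees with the p.adjust oracle on random p-sets", {
  set.seed(23)
  for (i in 1:200) {
    m <- sample.int(500, 1)
    p <- 10^(-runif(m, 0, 8 * runif(1)))
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- fdr_threshold(p, q)$p_star
    want <- bh_oracle(p, q)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("bubbles appear only on significant cells with reporting rules", {
  lay <- build_layout(c("1" = 9e6), 3e6)
  opts <- gg_options()
  # cell A: idx 8 (2 variants, low MAF + high impact) at nlp ~ 10
  # cell B: idx 5 (2 plain variants) at nlp ~ 10; cell C: idx 8, ns
  rec <- data.frame(
    name = paste0("v", 1:6),
    chrom = "1",
    pos = c(100, 200, 3.5e6, 3.6e6, 6.5e6, 6.6e6),
    pvalue = c(1e-10, 1e-10, 1e-10, 1e-10, 0.5, 0.5),
    maf = c(0.01, 0.3, 0.3, 0.3, 0.01, 0.3),
    consequence = c("intron_variant", "stop_gained", "intron_variant",
                    "intron_variant", "intron_variant", "stop_gained"),
    stringsAsFactors = FALSE
  )
  m <- accumulate(rec, lay, opts)
  b <- fdr_threshold(m$pvalues, 0.05, opts)
  cells <- classify_matrix(m, boundary = b)
  sig8 <- cells[cells$idx == 8 & cells$significant, ]
  expect_equal(nrow(sig8), 1L)
  expect_true(sig8$bubble)
  sig5 <- cells[cells$idx == 5, ]
  expect_true(sig5$significant)
  expect_false(sig5$bubble)
  ns8 <- cells[cells$idx == 8 & !cells$significant, ]
  expect_equal(nrow(ns8), 1L)
  expect_false(ns8$bubble)
})

test_that("bubble soundness and cell ordering hold on random matrices", {
  opts <- gg_options()
  for (seed in c(3, 41)) {
    set.seed(seed)
    rec <- random_records(3000)
    lay <- build_layout(rec, opts$chunk_bp)
    m <- accumulate(rec, lay, opts)
    b <- fdr_threshold(m$pvalues, 0.05, opts)
    cells <- classify_matrix(m, boundary = b)
    expect_equal(nrow(cells), sum(m$count > 0))
    expect_equal(sum(cells$count), m$total_variants)
    expect_true(all(cells$significant[cells$bubble]))
    ord <- order(cells$row, cells$col)
    expect_equal(ord, seq_len(nrow(cells)))  # row-major deterministic order
  }
})

test_that("key counts tally every non-empty cell and the max cell count", {
  cells <- data.frame(row = 0:4, col = 0L, count = c(1L, 1L, 1L, 2L, 9L),
                      idx = c(1L, 1L, 1L, 5L, 5L),
                      significant = FALSE, bubble = FALSE)
  mat <- list(count = matrix(c(1L, 1L, 1L, 2L, 9L, 0L), ncol = 1))
  k <- key_counts(cells, mat)
  expect_equal(unname(k$counts[c("1", "5")]), c(3L, 2L))
  expect_equal(sum(k$counts), nrow(cells))
  expect_equal(k$max_cell_count, 9L)

  empty <- key_counts(cells[0, ], list(count = matrix(0L, 2, 2)))
  expect_true(all(empty$counts == 0L))
  expect_equal(empty$max_cell_count, 0L)
})

test_that("key counts equal a brute-force tally on a random matrix", {
  set.seed(7)
  rec <- random_records(4000)
  lay <- build_layout(rec, 3e6)
  m <- accumulate(rec, lay)
  b <- fdr_threshold(m$pvalues, 0.05)
  cells <- classify_matrix(m, boundary = b)
  k <- key_counts(cells, m)
  # full enumeration over the matrix, independent of classify_matrix
  tally <- integer(8)
  for (cell in which(m$count > 0)) {
    idx <- classify_cell(m$count[cell], m$maf_any[cell], m$conseq_any[cell])
    tally[idx] <- tally[idx] + 1L
  }
  expect_equal(unname(k$counts), tally)
  expect_equal(sum(k$counts), sum(m$count > 0))
})
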