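test_that("genome layout bins chromosomes with ceiling division", {
  expect_equal(build_layout(c("1" = 9e6), 3e6)$n_rows, 3L)
  expect_equal(build_layout(c("1" = 9e6 + 1), 3e6)$n_rows, 4L)
  lay <- build_layout(c("1" = 7e6, "2" = 2e6), 3e6)
  expect_equal(lay$n_rows, 4L)
  expect_equal(unname(lay$row_offset), c(0L, 3L))
  expect_error(build_layout(numeric(0)), class = "gg_input_error")
})

test_that("chromosomes order 1..22, X, Y, MT, then others", {
  labs <- c("GL000192.1", "MT", "10", "2", "X", "1", "Y", "22")
  expect_equal(labs[order_chromosomes(labs)],
               c("1", "2", "10", "22", "X", "Y", "MT", "GL000192.1"))
})

test_that("positions map to rows with half-open 1-based bins", {
  lay <- build_layout(c("1" = 7e6, "2" = 2e6), 3e6)
  expect_equal(position_to_row("1", 1, lay), 0L)
  expect_equal(position_to_row("1", 3e6, lay), 0L)
  expect_equal(position_to_row("1", 3e6 + 1, lay), 1L)
  expect_equal(position_to_row("2", 1, lay), 3L)
  expect_error(position_to_row("1", 8e6, lay), class = "gg_validation_error")
  expect_error(position_to_row("9", 1, lay), class = "gg_input_error")
})

test_that("every position maps to exactly one row, 1..chunk_bp per row", {
  lay <- build_layout(c("1" = 35, "2" = 10), chunk_bp = 10)
  rows <- c(position_to_row(rep("1", 35), 1:35, lay),
            position_to_row(rep("2", 10), 1:10, lay))
  expect_equal(sort(unique(rows)), 0:(lay$n_rows - 1))
  expect_true(all(table(rows) >= 1 & table(rows) <= 10))
  expect_equal(unname(table(rows)[as.character(3)]), 5L)  # 35 %% 10
})

test_that("p-values land in half-open -log10 bins with capping", {
  expect_equal(pvalue_to_col(1), 0L)
  expect_equal(pvalue_to_col(1e-21), 159L)
  expect_equal(pvalue_to_col(1e-20), 159L)
  expect_equal(pvalue_to_col(0.05), 10L)
  expect_equal(pvalue_to_col(0), 159L)  # underflow policy: capped bin
  expect_error(pvalue_to_col(1.5), class = "gg_validation_error")
  # monotonicity: decreasing p never decreases the column
  set.seed(11)
  p <- sort(10^(-runif(500, 0, 30)), decreasing = TRUE)
  cols <- pvalue_to_col(p)
  expect_true(all(diff(cols) >= 0))
  expect_true(all(pvalue_to_col(10^(-runif(50, 20, 300))) == 159L))
})

test_that("high-impact consequence test is a case-insensitive set lookup", {
  expect_true(is_high_impact("stop_gained"))
  expect_true(is_high_impact("STOP_GAINED"))
  expect_false(is_high_impact("synonymous_variant"))
  expect_equal(is_high_impact(c("stop_lost", "intron_variant"), "stop_lost"),
               c(TRUE, FALSE))
})

test_that("accumulate counts every accepted record and sets cell flags", {
  lay <- build_layout(c("1" = 7e6, "2" = 2e6), 3e6)
  rec <- data.frame(
    name = paste0("v", 1:5), chrom = c("1", "1", "1", "2", "2"),
    pos = c(100, 200, 5e6, 1, 2e6),
    pvalue = c(0.5, 0.5, 1e-30, 0.01, 0.3),
    maf = c(0.01, 0.3, 0.3, 0.3, 0.3),
    consequence = c("intron_variant", "stop_gained", "intron_variant",
                    "intron_variant", "intron_variant"),
    stringsAsFactors = FALSE
  )
  m <- accumulate(rec, lay)
  expect_equal(sum(m$count), 5L)
  expect_equal(m$total_variants, 5L)
  # capped variant increments the last column
  expect_equal(m$count[5e6 %/% 3e6 + 1, 160], 1L)
  # two variants in one cell: count 2, one low-MAF + one high-impact
  cell <- which(m$count == 2L)
  expect_length(cell, 1L)
  expect_true(m$maf_any[cell])
  expect_true(m$conseq_any[cell])
  # flags only ever appear on occupied cells
  expect_true(all(m$count[m$maf_any] >= 1))
  expect_true(all(m$count[m$conseq_any] >= 1))
})

test_that("records on unknown chromosomes are skipped with a warning", {
  lay <- build_layout(c("1" = 7e6), 3e6)
  rec <- tiny_summary()  # includes chrom 2
  expect_warning(m <- accumulate(rec, lay), "skipped")
  expect_equal(m$total_variants, 2L)
  expect_equal(sum(m$count), 2L)
})

test_that("accumulate matches a naive per-record binner on random streams", {
  opts <- gg_options()
  for (seed in c(5, 17, 91)) {
    set.seed(seed)
    rec <- random_records(2000)
    lay <- build_layout(rec, opts$chunk_bp)
    fast <- accumulate(rec, lay, opts)
    slow <- naive_binner(rec, lay, opts)
    expect_identical(fast$count, slow$count)
    expect_identical(fast$maf_any, slow$maf_any)
    expect_identical(fast$conseq_any, slow$conseq_any)
  }
})
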