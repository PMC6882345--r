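fit_fixture <- function(n = 5000, n_loci = 6, seed = 42) {
  sim <- simulate_gwas(n, n_loci, seed = seed)
  gwasgrid(sim$summary_path, loci = sim$loci_path)
}

test_that("cell style: grey parity below the boundary, rule colours above", {
  lay <- build_layout(c("1" = 3e6, "2" = 3e6), 3e6)
  cells <- data.frame(row = c(0L, 1L, 0L), col = c(1L, 1L, 100L),
                      count = c(1L, 1L, 2L), idx = c(1L, 1L, 8L),
                      significant = c(FALSE, FALSE, TRUE),
                      bubble = c(FALSE, FALSE, TRUE))
  st <- resolve_cell_style(cells, layout = lay)
  expect_equal(st$fill[1], "grey35")  # odd chromosome, dark grey
  expect_equal(st$fill[2], "grey72")  # even chromosome, light grey
  expect_equal(st$fill[3], "cyan")
  expect_equal(st$glyph, c(NA, NA, "8"))
})

test_that("key ranges span each tier and end at the data-driven maximum", {
  key <- structure(list(counts = stats::setNames(c(3L, 0L, 1L, 0L, 2L, 0L,
                                                   0L, 1L), 1:8),
                        max_cell_count = 400L), class = "gg_key")
  k <- render_key(key)
  expect_equal(k$data$range[1:4], rep("1", 4))
  expect_equal(k$data$range[5:8], rep("2-400", 4))
  expect_equal(k$data$counter[2], 0L)  # unused rules still shown
  expect_s3_class(k$plot, "ggplot")
})

test_that("key counters always equal the classified-cell tally", {
  fit <- fit_fixture()
  k <- render_key(fit$key, fit$rules)
  tally <- as.integer(table(factor(fit$cells$idx, levels = 1:8)))
  expect_equal(k$data$counter, tally)
  expect_equal(k$data$range[5], paste0("2-", max(fit$matrix$count)))
})

test_that("single labels stay at their anchors", {
  lab <- data.frame(text = "GENE1", x = 5, y = 10, w = 2, h = 1)
  out <- layout_labels(lab, seed = 1)
  expect_equal(out$px, 5)
  expect_equal(out$py, 10)
  expect_false(out$leader)
})

test_that("coincident labels separate without overlap, deterministically", {
  lab <- data.frame(text = c("A", "B"), x = c(5, 5), y = c(10, 10),
                    w = 2, h = 1)
  a <- layout_labels(lab, seed = 9)
  b <- layout_labels(lab, seed = 9)
  expect_identical(a, b)
  expect_false(gwasgrid:::boxes_overlap(a$px, a$py, a$w, a$h))
  expect_true(all(a$displacement <= 2))
  c2 <- layout_labels(lab, seed = 10)
  expect_false(gwasgrid:::boxes_overlap(c2$px, c2$py, c2$w, c2$h))
})

test_that("label layout removes all overlaps for 200 random labels", {
  set.seed(81)
  lab <- data.frame(text = paste0("G", 1:200),
                    x = runif(200, 0, 20), y = runif(200, 0, 900),
                    w = runif(200, 1, 3), h = runif(200, 5, 12))
  out <- layout_labels(lab, seed = 4)
  expect_false(gwasgrid:::boxes_overlap(out$px, out$py, out$w, out$h))
  out2 <- layout_labels(lab, seed = 4)
  expect_identical(out$py, out2$py)
})

test_that("figures render with empty, tabular and labelled annotations", {
  fit <- fit_fixture()
  fit$loci <- NULL
  f0 <- tempfile(fileext = ".pdf")
  render_figure(fit, f0)               # no loci: empty right panel
  expect_gt(file.info(f0)$size, 1000)

  fit <- fit_fixture()
  f1 <- tempfile(fileext = ".pdf")
  render_figure(fit, f1, mode = "table")
  f2 <- tempfile(fileext = ".pdf")
  render_figure(fit, f2, mode = "labels", seed = 2)
  expect_true(all(file.info(c(f1, f2))$size > 1000))

  ftif <- tempfile(fileext = ".tiff")
  render_figure(fit, ftif)             # format inferred from extension
  expect_gt(file.info(ftif)$size, 1000)
})

test_that("table mode enforces the loci capacity, label mode does not", {
  fit <- fit_fixture()
  many <- fit$loci[rep(1, 131), ]
  many$name <- paste0("rs", 1:131); many$gene <- paste0("G", 1:131)
  fit$loci <- many
  expect_error(render_figure(fit, tempfile(fileext = ".pdf"),
                             mode = "table"),
               "labels", class = "gg_capacity_error")
  expect_warning(render_figure(fit, tempfile(fileext = ".pdf"),
                               mode = "table", auto_mode = TRUE),
                 "label mode")
  fit$loci <- many[1:130, ]
  f <- tempfile(fileext = ".pdf")
  render_figure(fit, f, mode = "table")
  expect_gt(file.info(f)$size, 1000)
})

test_that("PDF output is reproducible modulo embedded timestamps", {
  fit <- fit_fixture(2000, 4)
  f1 <- tempfile(fileext = ".pdf"); f2 <- tempfile(fileext = ".pdf")
  render_figure(fit, f1, seed = 5)
  render_figure(fit, f2, seed = 5)
  strip <- function(f) {
    x <- readLines(f, warn = FALSE, skipNul = TRUE)
    x[!grepl("CreationDate|ModDate", x, useBytes = TRUE)]
  }
  expect_identical(strip(f1), strip(f2))
})
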