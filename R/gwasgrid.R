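#' Bin and classify GWAS summary statistics for a transposed Manhattan plot
#'
#' The main entry point: reads (or accepts) genome-wide summary statistics,
#' splits the genome into fixed-width chunks and \eqn{-\log_{10} p} into
#' fixed-width chunks, counts variants per cell, flags cells containing
#' low-MAF or high-impact variants, computes the Benjamini-Hochberg
#' false-discovery-rate significance boundary, and classifies every
#' non-empty cell against the rule table. The returned object is plotted
#' with [plot()] or written to file with [render_figure()].
#'
#' @param summary Path to a summary-statistics file (TSV/CSV, optionally
#'   gzipped) or a data frame with columns `name`, `chrom`, `pos`,
#'   `pvalue`, `maf`, `consequence`.
#' @param loci Optional loci-of-interest table: a path or a data frame (see
#'   [read_loci_table()]).
#' @param config Configuration: a path, `"default"`, or a list with
#'   elements `rules` and `options` as returned by [read_config()].
#' @param column_map Optional canonical-field to header mapping for the
#'   summary file.
#' @param lengths Optional chromosome lengths: a named vector, a data frame
#'   (`chrom`, `length`), or a path to a two-column file. By default lengths
#'   are inferred as the maximum observed position per chromosome.
#' @param strict If `TRUE`, malformed summary rows are fatal instead of
#'   skipped.
#' @param ... Overrides for individual [gg_options()] fields, e.g.
#'   `chunk_bp = 1e6` or `fdr_q = 0.01`.
#'
#' @return An object of class `gwasgrid`: a list with components `layout`
#'   (genome bin layout), `matrix` (the `gg_matrix` count matrix),
#'   `boundary` (significance boundary), `cells` (classified non-empty
#'   cells), `key` (key summary), `rules`, `options`, `loci`, `n_read`,
#'   `n_skipped` and `call`.
#' @export
#' @examples
#' sim <- simulate_gwas(2000, 4, seed = 42)
#' fit <- gwasgrid(sim$summary_path, loci = sim$loci_path)
#' fit
#' summary(fit)
gwasgrid <- function(summary, loci = NULL, config = "default",
                     column_map = NULL, lengths = NULL, strict = FALSE,
                     ...) {
  cfg <- if (is.list(config) && !is.null(config$rules)) config
         else read_config(config)
  rules <- validate_rules(cfg$rules)
  opts <- cfg$options
  dots <- list(...)
  if (length(dots)) {
    o <- utils::modifyList(unclass(opts), dots)
    opts <- do.call(gg_options, o[names(o) %in% names(formals(gg_options))])
  }

  if (is.character(summary)) {
    records <- read_summary_stats(summary, column_map, strict)
  } else if (is.data.frame(summary)) {
    need <- c("name", "chrom", "pos", "pvalue", "maf", "consequence")
    miss <- setdiff(need, names(summary))
    if (length(miss))
      gg_config_error(paste0("summary data frame missing column(s): ",
                             paste(miss, collapse = ", ")))
    records <- summary
    attr(records, "n_rows") <- nrow(summary)
    attr(records, "n_skipped") <- 0L
  } else {
    gg_input_error("summary must be a file path or a data frame")
  }
  if (nrow(records) == 0L)
    gg_input_error("no usable variant records in the summary statistics")

  if (is.null(lengths)) {
    layout <- build_layout(records, chunk_bp = opts$chunk_bp)
  } else {
    if (is.character(lengths)) {
      lf <- data.table::fread(lengths, header = FALSE, data.table = FALSE)
      lengths <- stats::setNames(as.numeric(lf[[2]]),
                                 sub("^chr", "", as.character(lf[[1]]),
                                     ignore.case = TRUE))
    }
    layout <- build_layout(lengths, chunk_bp = opts$chunk_bp)
  }

  if (is.character(loci)) loci <- read_loci_table(loci)
  if (!is.null(loci) && nrow(loci)) {
    ok <- loci$chrom %in% layout$chrom_order &
      loci$pos <= layout$chrom_length[match(loci$chrom,
                                            layout$chrom_order)]
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      warning(sum(!ok), " locus/loci outside the genome layout dropped",
              call. = FALSE)
      loci <- loci[ok, , drop = FALSE]
    }
  }

  mat <- accumulate(records, layout, opts)
  boundary <- fdr_threshold(mat$pvalues, opts$fdr_q, opts)
  cells <- classify_matrix(mat, rules, boundary)
  key <- key_counts(cells, mat, rules)

  structure(list(
    layout = layout, matrix = mat, boundary = boundary, cells = cells,
    key = key, rules = rules, options = opts, loci = loci,
    n_read = attr(records, "n_rows"),
    n_skipped = attr(records, "n_skipped"),
    call = match.call()
  ), class = "gwasgrid")
}

#' @export
print.gwasgrid <- function(x, ...) {
  cat("Binned transposed Manhattan plot object\n")
  cat(sprintf("  %s variants in %s non-empty cells (%d x %d matrix)\n",
              format(x$matrix$total_variants, big.mark = ","),
              format(nrow(x$cells), big.mark = ","),
              x$matrix$n_rows, x$matrix$n_cols))
  cat(sprintf("  %d chromosomes, %s bp chunks, %.3g -log10(p) chunks capped at %g\n",
              length(x$layout$chrom_order),
              format(x$layout$chunk_bp, big.mark = ","),
              x$options$pbin, x$options$cap_nlp))
  print(x$boundary)
  cat(sprintf("  significant cells: %d (%d with bubbles); loci annotated: %d\n",
              sum(x$cells$significant), sum(x$cells$bubble),
              if (is.null(x$loci)) 0L else nrow(x$loci)))
  invisible(x)
}

#' @export
summary.gwasgrid <- function(object, ...) {
  key <- render_key(object$key, object$rules)$data
  structure(list(object = object, key = key), class = "summary.gwasgrid")
}

#' @export
print.summary.gwasgrid <- function(x, ...) {
  print(x$object)
  cat("\nKey (cells per classification rule):\n")
  print(x$key, row.names = FALSE)
  invisible(x)
}

#' Plot a gwasgrid object
#'
#' Draws the composed two-panel figure on the current device. Arguments in
#' `...` are passed to [render_figure()] (`mode`, `seed`, `auto_mode`, ...).
#'
#' @param x A `gwasgrid` object.
#' @param ... Passed to [render_figure()].
#' @return The composed plot, invisibly.
#' @export
plot.gwasgrid <- function(x, ...) {
  fig <- render_figure(x, out_path = NULL, ...)
  print(fig)
  invisible(fig)
}
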