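#' Map p-values to significance columns
#'
#' Significance bins are half-open on the \eqn{-\log_{10} p} scale:
#' column j covers `[j*pbin, (j+1)*pbin)`. P-values are capped: anything at
#' or below `10^-cap_nlp` (including p = 0, which arises from numeric
#' underflow in source files) is assigned to the last column, so the bin
#' count is still incremented and only the exact significance is lost.
#'
#' @param pvalue Numeric vector of p-values in `[0, 1]`.
#' @param pbin \eqn{-\log_{10} p} bin width.
#' @param cap_nlp \eqn{-\log_{10} p} ceiling.
#' @return 0-based column index (vectorised); the number of columns is
#'   `ceiling(cap_nlp / pbin)`.
#' @export
#' @examples
#' pvalue_to_col(1)       # 0
#' pvalue_to_col(1e-21)   # 159: capped into the last bin
#' pvalue_to_col(0.05)    # 10
pvalue_to_col <- function(pvalue, pbin = 0.125, cap_nlp = 20) {
  pvalue <- as.numeric(pvalue)
  if (any(!is.na(pvalue) & (pvalue < 0 | pvalue > 1)))
    gg_validation_error("p-values must lie in [0, 1]")
  n_cols <- as.integer(ceiling(cap_nlp / pbin))
  nlp <- -log10(pvalue)          # p = 0 gives Inf, capped below
  nlp <- pmin(nlp, cap_nlp)
  as.integer(pmin(floor(nlp / pbin), n_cols - 1L))
}

#' Test consequence terms for high impact
#'
#' Case-insensitive membership in the high-impact term set (by default the
#' Ensembl VEP HIGH-impact consequence terms shipped with the package).
#'
#' @param consequence Character vector of consequence terms.
#' @param terms High-impact term set.
#' @return Logical vector.
#' @export
#' @examples
#' is_high_impact(c("stop_gained", "synonymous_variant"))
is_high_impact <- function(consequence, terms = default_high_impact_terms()) {
  tolower(trimws(consequence)) %in% tolower(terms)
}

#' Accumulate variants into the genome-by-significance count matrix
#'
#' Bins each variant record into its (genome chunk, \eqn{-\log_{10} p}
#' chunk) cell and increments the cell counter, additionally flagging cells
#' that contain at least one low-MAF variant (`maf < maf_threshold`) and
#' cells that contain at least one high-impact variant. Records on
#' chromosomes absent from the layout are skipped with a warning. The
#' accepted p-values are retained for the false-discovery-rate boundary.
#'
#' @param records Variant record data frame (from [read_summary_stats()] or
#'   [simulate_gwas()]): columns `chrom`, `pos`, `pvalue`, `maf`,
#'   `consequence`.
#' @param layout A [build_layout()] genome layout.
#' @param options A [gg_options()] object.
#' @return An object of class `gg_matrix`: a list with integer matrix
#'   `count` (`n_rows` x `n_cols`), logical matrices `maf_any` and
#'   `conseq_any`, `total_variants`, numeric vector `pvalues`, plus the
#'   `layout` and `options` used. Matrix element `[r+1, c+1]` corresponds to
#'   0-based cell `(r, c)`.
#' @export
accumulate <- function(records, layout, options = gg_options()) {
  n_cols <- n_sig_cols(options)
  n_rows <- layout$n_rows
  known <- records$chrom %in% layout$chrom_order
  if (any(!known)) {
    warning(sum(!known), " record(s) on chromosome(s) not in the layout ",
            "were skipped: ",
            paste(unique(records$chrom[!known]), collapse = ", "),
            call. = FALSE)
    records <- records[known, , drop = FALSE]
  }
  count <- matrix(0L, n_rows, n_cols)
  maf_any <- matrix(FALSE, n_rows, n_cols)
  conseq_any <- matrix(FALSE, n_rows, n_cols)
  if (nrow(records)) {
    row <- position_to_row(records$chrom, records$pos, layout)
    col <- pvalue_to_col(records$pvalue, options$pbin, options$cap_nlp)
    cell <- row + as.numeric(col) * n_rows + 1  # 1-based linear index
    tab <- tabulate(cell, nbins = n_rows * n_cols)
    count[] <- as.integer(tab)
    low <- records$maf < options$maf_threshold
    maf_any[unique(cell[low])] <- TRUE
    hi <- is_high_impact(records$consequence, options$high_impact_terms)
    conseq_any[unique(cell[hi])] <- TRUE
  }
  structure(list(
    count = count,
    maf_any = maf_any,
    conseq_any = conseq_any,
    n_rows = n_rows,
    n_cols = n_cols,
    total_variants = nrow(records),
    pvalues = records$pvalue,
    layout = layout,
    options = options
  ), class = "gg_matrix")
}

#' @export
print.gg_matrix <- function(x, ...) {
  cat("Binned GWAS count matrix:", x$n_rows, "genome bins x", x$n_cols,
      "significance bins;", x$total_variants, "variants in",
      sum(x$count > 0), "non-empty cells\n")
  invisible(x)
}
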