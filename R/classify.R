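#' Benjamini-Hochberg significance boundary
#'
#' Applies the Benjamini-Hochberg step-up procedure to the accepted
#' p-values: with sorted \eqn{p_{(1)} \le \dots \le p_{(m)}}, the largest
#' rejected p-value is \eqn{p^* = p_{(k)}} for
#' \eqn{k = \max\{i : p_{(i)} \le i q / m\}}. A cell is counted significant
#' when the lower edge of its significance column is at or beyond
#' \eqn{-\log_{10} p^*}, so a bin straddling the threshold is never split.
#' If `options$threshold_nlp` is set, that fixed \eqn{-\log_{10} p} cut is
#' used instead of FDR.
#'
#' @param pvalues Numeric vector of p-values (the full accepted multiset).
#' @param q FDR level (default from `options$fdr_q`).
#' @param options A [gg_options()] object (bin width, cap, fixed threshold).
#' @return An object of class `gg_boundary`: list with `q`, `p_star`
#'   (largest rejected p-value, `NA` if nothing is rejected), `nlp_star`,
#'   and `boundary_col` (first 0-based significant column; `Inf` when no
#'   cell is significant).
#' @export
#' @examples
#' b <- fdr_threshold(c(0.001, 0.01, 0.02, 0.8), q = 0.05)
#' b$p_star      # 0.02
fdr_threshold <- function(pvalues, q = options$fdr_q, options = gg_options()) {
  n_cols <- n_sig_cols(options)
  if (!is.na(options$threshold_nlp)) {
    nlp_star <- options$threshold_nlp
    p_star <- 10^(-nlp_star)
  } else {
    pvalues <- pvalues[is.finite(pvalues)]
    m <- length(pvalues)
    if (m == 0L) gg_input_error("no p-values supplied to fdr_threshold")
    ps <- sort(pvalues)
    ok <- which(ps <= seq_len(m) * q / m)
    if (length(ok) == 0L) {
      return(structure(list(q = q, p_star = NA_real_, nlp_star = NA_real_,
                            boundary_col = Inf), class = "gg_boundary"))
    }
    p_star <- ps[max(ok)]
    nlp_star <- -log10(p_star)
  }
  # first column whose lower edge j*pbin reaches nlp_star (ties significant)
  boundary_col <- ceiling(nlp_star / options$pbin - 1e-9)
  if (boundary_col > n_cols - 1L) boundary_col <- Inf
  structure(list(q = q, p_star = p_star, nlp_star = nlp_star,
                 boundary_col = boundary_col), class = "gg_boundary")
}

#' @export
print.gg_boundary <- function(x, ...) {
  if (is.na(x$p_star))
    cat("Significance boundary: no p-value rejected at q =", x$q, "\n")
  else
    cat(sprintf(
      "Significance boundary: p* = %.3g (-log10 = %.3f), first column %s\n",
      x$p_star, x$nlp_star, format(x$boundary_col)))
  invisible(x)
}

#' Classify one cell against the rule table
#'
#' Returns the unique rule whose count tier applies (largest `min_count`
#' less than or equal to the cell count) and whose MAF and consequence flags
#' equal the cell's flags. With the default eight-rule scheme this
#' reproduces the standard classification: e.g. a single plain variant is
#' idx 1 (black); two or more variants with both a low-MAF and a high-impact
#' variant is idx 8 (cyan).
#'
#' @param count Cell variant count (`>= 1`), vectorised.
#' @param maf_any Does the cell contain a low-MAF variant? (vectorised)
#' @param conseq_any Does the cell contain a high-impact variant?
#'   (vectorised)
#' @param rules Validated rule table (see [read_config()]).
#' @return Integer vector of rule `idx` values.
#' @export
#' @examples
#' classify_cell(1, TRUE, TRUE)    # 4
#' classify_cell(7, TRUE, TRUE)    # 8
classify_cell <- function(count, maf_any, conseq_any,
                          rules = default_rules()) {
  tiers <- sort(unique(rules$min_count))
  if (any(count < 1)) gg_validation_error("cell count must be >= 1")
  iv <- findInterval(count, tiers)
  iv[iv == 0L] <- NA_integer_  # count below every tier: no rule can match
  tier <- tiers[iv]
  key <- paste(tier, as.logical(maf_any), as.logical(conseq_any))
  rkey <- paste(rules$min_count, rules$maf, rules$conseq)
  hit <- match(key, rkey)
  if (anyNA(hit)) {
    # counts below the smallest tier: only reachable with an invalid config
    gg_stop(paste0("no rule matches cell (count=", count[is.na(hit)][1],
                   ", maf=", maf_any[is.na(hit)][1],
                   ", conseq=", conseq_any[is.na(hit)][1], ")"),
            "gg_classification_error")
  }
  as.integer(rules$idx[hit])
}

#' Classify every non-empty cell of a count matrix
#'
#' Produces one classified record per non-empty cell, in row-major order
#' (by genome row, then significance column). A cell is `significant` when
#' its column is at or beyond the boundary column; `bubble` is `TRUE` only
#' for significant cells whose rule has `report = TRUE`.
#'
#' @param mat A `gg_matrix` from [accumulate()].
#' @param rules Validated rule table.
#' @param boundary A `gg_boundary` from [fdr_threshold()].
#' @return Data frame with columns `row`, `col` (0-based), `count`, `idx`,
#'   `significant`, `bubble`.
#' @export
classify_matrix <- function(mat, rules = default_rules(), boundary) {
  nz <- which(mat$count > 0L)
  if (length(nz) == 0L)
    return(data.frame(row = integer(), col = integer(), count = integer(),
                      idx = integer(), significant = logical(),
                      bubble = logical()))
  row <- as.integer((nz - 1L) %% mat$n_rows)
  col <- as.integer((nz - 1L) %/% mat$n_rows)
  ord <- order(row, col)
  row <- row[ord]; col <- col[ord]; nz <- nz[ord]
  cells <- data.frame(
    row = row, col = col,
    count = mat$count[nz],
    idx = classify_cell(mat$count[nz], mat$maf_any[nz], mat$conseq_any[nz],
                        rules),
    stringsAsFactors = FALSE
  )
  cells$significant <- cells$col >= boundary$boundary_col
  cells$bubble <- cells$significant &
    rules$report[match(cells$idx, rules$idx)]
  cells
}

#' Summarise classified cells for the plot key
#'
#' Counts, for every rule index, how many cells in the plot carry it (zero
#' for unused indices) and records the maximum cell count over the whole
#' matrix, which sets the upper end of the count ranges displayed in the
#' key.
#'
#' @param cells Classified cells from [classify_matrix()].
#' @param mat The `gg_matrix` the cells came from.
#' @param rules Rule table (defines the set of indices reported).
#' @return A list of class `gg_key`: `counts` (named integer vector, one
#'   entry per rule idx) and `max_cell_count`.
#' @export
key_counts <- function(cells, mat, rules = default_rules()) {
  counts <- stats::setNames(integer(nrow(rules)), rules$idx)
  if (nrow(cells)) {
    tab <- table(factor(cells$idx, levels = rules$idx))
    counts[] <- as.integer(tab)
  }
  structure(list(
    counts = counts,
    max_cell_count = if (any(mat$count > 0L)) max(mat$count) else 0L
  ), class = "gg_key")
}
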