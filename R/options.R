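#' Global plotting and binning options
#'
#' Container for the tunable parameters of the binned Manhattan pipeline.
#' Defaults follow the shipped configuration: 3 Mbp genome chunks, 0.125
#' \eqn{-\log_{10} p} chunks capped at 20 (p-values below 1e-20 are assigned
#' to the cap), a 5\% minor-allele-frequency threshold and a 5\% false
#' discovery rate.
#'
#' @param chunk_bp Genome bin width in base pairs (default 3,000,000).
#' @param pbin \eqn{-\log_{10} p} bin width (default 0.125).
#' @param cap_nlp \eqn{-\log_{10} p} ceiling; smaller p-values land in the
#'   last significance bin (default 20, i.e. p = 1e-20).
#' @param maf_threshold Low-frequency cutoff on minor allele frequency
#'   (default 0.05).
#' @param fdr_q False-discovery-rate level for the significance boundary
#'   (default 0.05).
#' @param threshold_nlp Optional fixed \eqn{-\log_{10} p} significance cut
#'   used instead of the FDR boundary; the string `"genomewide"` is a preset
#'   for p = 5e-8. `NA` (default) selects Benjamini-Hochberg FDR.
#' @param high_impact_terms Character vector of consequence terms treated as
#'   high impact (case-insensitive). Defaults to the Ensembl VEP HIGH-impact
#'   term list shipped with the package.
#' @param annotation_mode `"table"` or `"labels"`: how loci of interest are
#'   displayed.
#' @param table_capacity Maximum number of loci the tabular annotation panel
#'   accepts (default 130).
#' @param output_format `"pdf"` or `"tiff"`.
#' @param tiff_dpi Resolution for TIFF output (default 300).
#' @param max_label_displacement Maximum label displacement in the label
#'   layout, as a fraction of the canvas diagonal (default 0.5).
#'
#' @return An object of class `gg_options` (a validated named list).
#' @export
#' @examples
#' opts <- gg_options()
#' opts$chunk_bp
gg_options <- function(chunk_bp = 3e6,
                       pbin = 0.125,
                       cap_nlp = 20,
                       maf_threshold = 0.05,
                       fdr_q = 0.05,
                       threshold_nlp = NA_real_,
                       high_impact_terms = NULL,
                       annotation_mode = c("table", "labels"),
                       table_capacity = 130,
                       output_format = c("pdf", "tiff"),
                       tiff_dpi = 300,
                       max_label_displacement = 0.5) {
  if (is.null(high_impact_terms))
    high_impact_terms <- default_high_impact_terms()
  if (identical(threshold_nlp, "genomewide"))
    threshold_nlp <- -log10(5e-8)
  opts <- list(
    chunk_bp = as.numeric(chunk_bp),
    pbin = as.numeric(pbin),
    cap_nlp = as.numeric(cap_nlp),
    maf_threshold = as.numeric(maf_threshold),
    fdr_q = as.numeric(fdr_q),
    threshold_nlp = as.numeric(threshold_nlp),
    high_impact_terms = as.character(high_impact_terms),
    annotation_mode = match.arg(annotation_mode),
    table_capacity = as.integer(table_capacity),
    output_format = match.arg(output_format),
    tiff_dpi = as.numeric(tiff_dpi),
    max_label_displacement = as.numeric(max_label_displacement)
  )
  validate_options(opts)
  structure(opts, class = "gg_options")
}

validate_options <- function(o) {
  chk <- function(ok, msg) if (!isTRUE(ok)) gg_validation_error(msg)
  chk(o$chunk_bp >= 1, "chunk_bp must be >= 1")
  chk(o$pbin > 0, "pbin must be > 0")
  chk(o$cap_nlp > 0, "cap_nlp must be > 0")
  chk(o$maf_threshold > 0 && o$maf_threshold < 0.5,
      "maf_threshold must be in (0, 0.5)")
  chk(o$fdr_q > 0 && o$fdr_q < 1, "fdr_q must be in (0, 1)")
  chk(is.na(o$threshold_nlp) || o$threshold_nlp > 0,
      "threshold_nlp must be positive when set")
  chk(o$table_capacity >= 1, "table_capacity must be >= 1")
  invisible(o)
}

#' Default high-impact consequence terms
#'
#' Reads the Ensembl VEP HIGH-impact consequence term list shipped with the
#' package (release 110).
#'
#' @return Character vector of consequence terms.
#' @export
default_high_impact_terms <- function() {
  path <- system.file("extdata", "vep_high_impact_terms.txt",
                      package = "gwasgrid", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# number of significance columns implied by the options
n_sig_cols <- function(options) as.integer(ceiling(options$cap_nlp / options$pbin))
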