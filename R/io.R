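# Reading the three input files: summary statistics, loci of interest, and
# the rule/option configuration. All delimited-text readers accept tab or
# comma (auto-detected from the header; tab wins a tie) and transparently
# read gzip-compressed files.

default_synonyms <- list(
  name        = c("name", "snp", "rsid", "variant", "variant_id", "id",
                  "marker", "markername"),
  chrom       = c("chrom", "chr", "chromosome", "#chrom", "#chr"),
  pos         = c("pos", "bp", "position", "base_pair_location", "pos_b37",
                  "pos_b38", "bp_hg19", "bp_hg38"),
  pvalue      = c("pvalue", "p", "pval", "p_value", "p.value", "p-value"),
  maf         = c("maf", "minor_allele_frequency", "freq", "af", "eaf",
                  "effect_allele_frequency", "a1freq"),
  consequence = c("consequence", "conseq", "csq", "most_severe_consequence",
                  "annotation")
)

loci_synonyms <- list(
  name       = c("name", "snp", "rsid", "variant", "variant_id", "sentinel",
                 "marker", "markername"),
  chrom      = c("chrom", "chr", "chromosome"),
  pos        = c("pos", "bp", "position"),
  eaf        = c("eaf", "effect_allele_frequency", "freq", "af"),
  odds_ratio = c("odds_ratio", "or", "oddsratio"),
  pvalue     = c("pvalue", "p", "pval", "p_value", "p.value"),
  novelty    = c("novelty", "novel", "novel_known", "status"),
  gene       = c("gene", "gene_name", "genename", "locus", "nearest_gene")
)

# read all lines through gzfile(), which handles both plain and gzip input
read_text_lines <- function(path) {
  if (!file.exists(path)) gg_input_error(paste0("file not found: ", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) gg_input_error(paste0("empty file: ", path))
  lines
}

detect_delim <- function(header_line) {
  n_tab <- lengths(regmatches(header_line, gregexpr("\t", header_line)))
  n_com <- lengths(regmatches(header_line, gregexpr(",", header_line)))
  if (n_com > n_tab) "," else "\t"  # tab preferred on tie
}

# map file headers onto canonical field names; explicit column_map entries
# (canonical -> actual header) override the synonym table. Case-insensitive.
resolve_columns <- function(headers, fields, synonyms, column_map = NULL) {
  lw <- tolower(trimws(headers))
  out <- stats::setNames(rep(NA_integer_, length(fields)), fields)
  for (f in fields) {
    if (!is.null(column_map) && !is.null(column_map[[f]])) {
      i <- match(tolower(column_map[[f]]), lw)
      if (is.na(i))
        gg_config_error(paste0("column_map names header '", column_map[[f]],
                               "' for '", f, "' but it is not in the file"))
    } else {
      i <- match(synonyms[[f]], lw)
      i <- i[!is.na(i)][1]
    }
    out[f] <- if (length(i) && !is.na(i)) i else NA_integer_
  }
  missing <- names(out)[is.na(out)]
  if (length(missing))
    gg_config_error(paste0("required column(s) not found: ",
                           paste(missing, collapse = ", "),
                           " (use column_map to name them explicitly)"))
  out
}

parse_delim <- function(lines, delim) {
  dt <- data.table::fread(text = lines, sep = delim, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          strip.white = TRUE, blank.lines.skip = TRUE)
  dt
}

#' Read genome-wide summary statistics
#'
#' Reads a delimited text file (tab or comma; optionally gzip-compressed) of
#' per-variant association results. Column headers are matched
#' case-insensitively against a synonym list (e.g. `P`, `PVAL`, `P_VALUE` all
#' map to `pvalue`); non-standard headers can be named explicitly via
#' `column_map`. Rows with unparsable numeric fields are skipped with a
#' warning (or become fatal under `strict = TRUE`). Minor allele frequencies
#' above 0.5 are folded to `1 - maf` with a warning, and p-values of exactly
#' 0 are retained (they are later assigned to the capped significance bin).
#'
#' @param path Path to the summary-statistics file (`.tsv`, `.csv`, or either
#'   gzip-compressed).
#' @param column_map Optional named list/character vector mapping canonical
#'   field names (`name`, `chrom`, `pos`, `pvalue`, `maf`, `consequence`) to
#'   the actual file headers.
#' @param strict If `TRUE`, the first malformed row raises an error instead
#'   of being skipped.
#'
#' @return A data frame with columns `name`, `chrom`, `pos`, `pvalue`, `maf`,
#'   `consequence`, one row per accepted variant in file order, with
#'   attributes `n_rows` (data rows in the file) and `n_skipped` (rows
#'   rejected by the row-error policy).
#' @export
read_summary_stats <- function(path, column_map = NULL, strict = FALSE) {
  lines <- read_text_lines(path)
  delim <- detect_delim(lines[1])
  df <- parse_delim(lines, delim)
  idx <- resolve_columns(names(df), names(default_synonyms),
                         default_synonyms, column_map)
  out <- data.frame(
    name        = df[[idx["name"]]],
    chrom       = sub("^chr", "", df[[idx["chrom"]]], ignore.case = TRUE),
    pos         = suppressWarnings(as.numeric(df[[idx["pos"]]])),
    pvalue      = suppressWarnings(as.numeric(df[[idx["pvalue"]]])),
    maf         = suppressWarnings(as.numeric(df[[idx["maf"]]])),
    consequence = df[[idx["consequence"]]],
    stringsAsFactors = FALSE
  )
  n_rows <- nrow(out)
  bad <- !is.finite(out$pos) | out$pos < 1 |
    !is.finite(out$pvalue) | out$pvalue < 0 | out$pvalue > 1 |
    !is.finite(out$maf) | out$maf < 0 | out$maf > 1
  if (any(bad)) {
    if (strict)
      gg_validation_error(paste0("malformed row ", which(bad)[1],
                                 " in ", path, " (strict mode)"))
    warning(sum(bad), " malformed row(s) skipped in ", path, call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  fold <- out$maf > 0.5
  if (any(fold)) {
    warning(sum(fold), " allele frequencies > 0.5 folded to 1 - value ",
            "(interpreted as non-minor allele frequency)", call. = FALSE)
    out$maf[fold] <- 1 - out$maf[fold]
  }
  if (any(out$pvalue == 0))
    warning(sum(out$pvalue == 0),
            " p-value(s) of exactly 0 will be assigned to the capped bin",
            call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rows") <- n_rows
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read the loci-of-interest table
#'
#' Reads the annotation table of lead (sentinel) variants: one row per locus
#' with the sentinel name, chromosome, position, effect-allele frequency,
#' odds ratio, p-value, novel/known status, and gene name. Order is
#' preserved.
#'
#' @param path Path to the loci table (tab- or comma-separated, optionally
#'   gzipped).
#' @param column_map Optional canonical-field to header mapping, as in
#'   [read_summary_stats()].
#' @return A data frame with columns `name`, `chrom`, `pos`, `eaf`,
#'   `odds_ratio`, `pvalue`, `novelty`, `gene` in file order (possibly zero
#'   rows).
#' @export
read_loci_table <- function(path, column_map = NULL) {
  lines <- read_text_lines(path)
  delim <- detect_delim(lines[1])
  df <- parse_delim(lines, delim)
  idx <- resolve_columns(names(df), names(loci_synonyms), loci_synonyms,
                         column_map)
  out <- data.frame(
    name       = df[[idx["name"]]],
    chrom      = sub("^chr", "", df[[idx["chrom"]]], ignore.case = TRUE),
    pos        = suppressWarnings(as.numeric(df[[idx["pos"]]])),
    eaf        = suppressWarnings(as.numeric(df[[idx["eaf"]]])),
    odds_ratio = suppressWarnings(as.numeric(df[[idx["odds_ratio"]]])),
    pvalue     = suppressWarnings(as.numeric(df[[idx["pvalue"]]])),
    novelty    = tolower(trimws(df[[idx["novelty"]]])),
    gene       = df[[idx["gene"]]],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) return(out)
  check_row <- function(ok, what) {
    if (any(!ok))
      gg_validation_error(paste0("loci table row ", which(!ok)[1], ": ", what))
  }
  check_row(is.finite(out$pos) & out$pos >= 1, "position must be >= 1")
  check_row(is.finite(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1,
            "p-value must be in (0, 1]")
  check_row(is.finite(out$odds_ratio) & out$odds_ratio > 0,
            "odds_ratio must be > 0")
  check_row(is.finite(out$eaf) & out$eaf > 0 & out$eaf < 1,
            "effect allele frequency must be in (0, 1)")
  check_row(out$novelty %in% c("novel", "known"),
            "novelty must be 'novel' or 'known'")
  out
}

# the eight-rule default classification scheme
default_rules <- function() {
  data.frame(
    idx       = 1:8,
    min_count = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    maf       = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    conseq    = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    colour    = c("black", "light pink", "green", "dark magenta",
                  "blue", "pink", "red", "cyan"),
    report    = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# colour names in the rule table may contain spaces ("dark magenta"); R
# colour names do not
resolve_colour <- function(x) gsub(" ", "", tolower(x))

validate_rules <- function(rules) {
  req <- c("idx", "min_count", "maf", "conseq", "colour", "report")
  missing <- setdiff(req, names(rules))
  if (length(missing))
    gg_config_error(paste0("config rule table missing column(s): ",
                           paste(missing, collapse = ", ")))
  if (anyDuplicated(rules$idx))
    gg_validation_error(paste0("duplicate rule idx: ",
      paste(unique(rules$idx[duplicated(rules$idx)]), collapse = ", ")))
  if (any(rules$min_count < 1))
    gg_validation_error("rule min_count must be >= 1")
  bad_col <- vapply(rules$colour, function(cc)
    inherits(try(grDevices::col2rgb(resolve_colour(cc)), silent = TRUE),
             "try-error"), logical(1))
  if (any(bad_col))
    gg_config_error(paste0("unresolvable colour(s): ",
                           paste(rules$colour[bad_col], collapse = ", ")))
  # coverage: every (count tier, maf, conseq) combination exactly once
  tiers <- sort(unique(rules$min_count))
  combos <- expand.grid(min_count = tiers, maf = c(FALSE, TRUE),
                        conseq = c(FALSE, TRUE))
  have <- paste(rules$min_count, rules$maf, rules$conseq)
  want <- paste(combos$min_count, combos$maf, combos$conseq)
  fmt <- function(k) {
    p <- strsplit(k, " ")[[1]]
    paste0("(min_count=", p[1], ", maf=", p[2], ", conseq=", p[3], ")")
  }
  if (anyDuplicated(have))
    gg_validation_error(paste0("overlapping rule combination: ",
      fmt(have[duplicated(have)][1])))
  gap <- setdiff(want, have)
  if (length(gap))
    gg_validation_error(paste0("rule table does not cover combination ",
                               fmt(gap[1])))
  rules
}

#' Read a configuration file
#'
#' The configuration is a delimited rule table (columns `idx`, `min.count`,
#' `maf`, `conseq`, `col`, `report`) followed by an `[options]` section of
#' `key=value` pairs for the global parameters. The special path
#' `"default"` loads the configuration shipped with the package, whose eight
#' rules classify cells by variant count (1 vs 2+), low-MAF content and
#' high-impact content.
#'
#' @param path Path to a configuration file, or `"default"`.
#' @return A list with elements `rules` (validated rule data frame, columns
#'   `idx`, `min_count`, `maf`, `conseq`, `colour`, `report`) and `options`
#'   (a [gg_options()] object).
#' @export
#' @examples
#' cfg <- read_config("default")
#' cfg$rules
read_config <- function(path) {
  if (identical(path, "default"))
    path <- system.file("extdata", "default_config.txt",
                        package = "gwasgrid", mustWork = TRUE)
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  opt_at <- which(trimws(lines) == "[options]")
  rule_lines <- if (length(opt_at)) lines[seq_len(opt_at[1] - 1L)] else lines
  opt_lines <- if (length(opt_at)) lines[-seq_len(opt_at[1])] else character()
  if (length(rule_lines) < 2L)
    gg_config_error("configuration has no rule table")
  delim <- detect_delim(rule_lines[1])
  df <- parse_delim(rule_lines, delim)
  names(df) <- tolower(trimws(names(df)))
  names(df)[names(df) == "min.count"] <- "min_count"
  rules <- data.frame(
    idx       = as.integer(df$idx),
    min_count = as.integer(df$min_count),
    maf       = as.logical(toupper(df$maf)),
    conseq    = as.logical(toupper(df$conseq)),
    colour    = df$col %||% df$colour,
    report    = as.logical(toupper(df$report)),
    stringsAsFactors = FALSE
  )
  validate_rules(rules)
  kv <- list()
  for (ln in opt_lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      gg_config_error(paste0("malformed option line: ", ln))
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num <- function(key, default) {
    v <- kv[[key]]
    if (is.null(v)) default else suppressWarnings(as.numeric(v))
  }
  terms <- if (!is.null(kv[["high.impact.terms"]]))
    strsplit(kv[["high.impact.terms"]], ",", fixed = TRUE)[[1]] else NULL
  thr <- kv[["threshold.nlp"]]
  thr <- if (is.null(thr)) NA_real_
         else if (identical(thr, "genomewide")) "genomewide"
         else suppressWarnings(as.numeric(thr))
  options <- gg_options(
    chunk_bp = num("chunk.bp", 3e6),
    pbin = num("pbin", 0.125),
    cap_nlp = num("cap.nlp", 20),
    maf_threshold = num("maf.threshold", 0.05),
    fdr_q = num("fdr.q", 0.05),
    threshold_nlp = thr,
    high_impact_terms = terms,
    annotation_mode = kv[["annotation.mode"]] %||% "table",
    table_capacity = num("table.capacity", 130),
    output_format = kv[["output.format"]] %||% "pdf",
    tiff_dpi = num("tiff.dpi", 300)
  )
  list(rules = rules, options = options)
}

#' Write the default configuration file
#'
#' Serialises the shipped eight-rule classification scheme and the default
#' global options to a tab-separated configuration file that [read_config()]
#' reads back identically. Output is deterministic: two writes produce
#' byte-identical files.
#'
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  rules <- default_rules()
  hdr <- "idx\tmin.count\tmaf\tconseq\tcol\treport"
  body <- sprintf("%d\t%d\t%s\t%s\t%s\t%s", rules$idx, rules$min_count,
                  rules$maf, rules$conseq, rules$colour, rules$report)
  opts <- c(
    "[options]",
    "chunk.bp=3000000",
    "pbin=0.125",
    "cap.nlp=20",
    "maf.threshold=0.05",
    "fdr.q=0.05",
    "annotation.mode=table",
    "table.capacity=130",
    "output.format=pdf",
    "tiff.dpi=300"
  )
  txt <- c("# gwasgrid configuration: cell classification rules + options",
           hdr, body, "", opts)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) gg_io_error(paste0("cannot write configuration to ", path))
  invisible(path)
}
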