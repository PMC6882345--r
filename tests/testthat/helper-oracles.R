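# Independent oracles and tiny-fixture builders shared across the suite.
# These deliberately avoid the package's own vectorised code paths: the
# binner oracle is a plain per-record loop, the FDR oracle goes through
# stats::p.adjust.

write_tsv <- function(df, path = tempfile(fileext = ".tsv"), gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

tiny_summary <- function() {
  data.frame(
    name = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(100, 4e6, 200),
    pvalue = c(0.5, 1e-9, 0.01),
    maf = c(0.3, 0.02, 0.4),
    consequence = c("intron_variant", "stop_gained", "missense_variant"),
    stringsAsFactors = FALSE
  )
}

tiny_loci <- function() {
  data.frame(
    name = c("rs2", "rs9"), chrom = c("1", "2"), pos = c(4e6, 200),
    eaf = c(0.12, 0.45), odds_ratio = c(1.21, 0.88),
    pvalue = c(1e-9, 1e-6), novelty = c("novel", "known"),
    gene = c("GENEA", "GENEB"), stringsAsFactors = FALSE
  )
}

# brute-force two-pass binner: one record at a time, no shared code with
# accumulate()
naive_binner <- function(records, layout, options = gg_options()) {
  n_cols <- as.integer(ceiling(options$cap_nlp / options$pbin))
  count <- matrix(0L, layout$n_rows, n_cols)
  maf_any <- matrix(FALSE, layout$n_rows, n_cols)
  conseq_any <- matrix(FALSE, layout$n_rows, n_cols)
  hi <- tolower(options$high_impact_terms)
  for (i in seq_len(nrow(records))) {
    ch <- records$chrom[i]
    if (!ch %in% layout$chrom_order) next
    r <- layout$row_offset[[ch]] +
      floor((records$pos[i] - 1) / layout$chunk_bp)
    nlp <- min(-log10(records$pvalue[i]), options$cap_nlp)
    cc <- min(floor(nlp / options$pbin), n_cols - 1)
    count[r + 1, cc + 1] <- count[r + 1, cc + 1] + 1L
    if (records$maf[i] < options$maf_threshold)
      maf_any[r + 1, cc + 1] <- TRUE
    if (tolower(records$consequence[i]) %in% hi)
      conseq_any[r + 1, cc + 1] <- TRUE
  }
  list(count = count, maf_any = maf_any, conseq_any = conseq_any)
}

# BH largest rejected p-value via stats::p.adjust
bh_oracle <- function(p, q) {
  rej <- p[stats::p.adjust(p, "BH") <= q]
  if (length(rej)) max(rej) else NA_real_
}

# random variant records over a small two-chromosome genome
random_records <- function(n, lens = c("1" = 50e6, "2" = 30e6)) {
  ch <- sample(names(lens), n, replace = TRUE)
  data.frame(
    name = paste0("v", seq_len(n)),
    chrom = ch,
    pos = floor(runif(n, 1, lens[ch])),
    pvalue = 10^(-runif(n, 0, 25)),
    maf = runif(n, 0.001, 0.5),
    consequence = sample(c("intron_variant", "stop_gained",
                           "missense_variant", "frameshift_variant"),
                         n, replace = TRUE, prob = c(.6, .05, .3, .05)),
    stringsAsFactors = FALSE
  )
}
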