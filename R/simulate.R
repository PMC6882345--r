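# Seeded synthetic GWAS generator. Produces the three pipeline inputs
# (summary statistics, loci table, configuration) plus a ground-truth record
# so expected per-cell counts can be recomputed independently in tests.

# 22 autosomes with lengths following the human karyotype shape (Mbp scale,
# longest ~249 Mbp); a fixed constant so no reference genome is ever needed.
synthetic_karyotype <- function() {
  mbp <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
           135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  stats::setNames(mbp * 1e6, as.character(1:22))
}

benign_terms <- c("intron_variant", "intergenic_variant",
                  "synonymous_variant", "missense_variant",
                  "3_prime_UTR_variant", "5_prime_UTR_variant",
                  "upstream_gene_variant", "downstream_gene_variant",
                  "regulatory_region_variant", "non_coding_transcript_variant")

#' Simulate a GWAS summary-statistics dataset with known truth
#'
#' Generates `n_variants` variants over 22 synthetic autosomes: a null
#' background with p-values uniform on (0, 1), MAF uniform on
#' (0.001, 0.5) and ~1\% high-impact consequences, plus `n_loci` spiked
#' association loci. Each spiked locus is a cluster of variants whose
#' \eqn{-\log_{10} p} decays log-linearly away from the sentinel; sentinel
#' significance cycles through \eqn{-\log_{10} p} of 30, 12, 18 and 25, so
#' some loci exceed the significance cap (p = 1e-30 exercises the capped
#' bin). Loci cycle through the four annotation combinations (plain,
#' low-MAF, high-impact, both) so every default rule index can be realised.
#' The loci table lists one sentinel per spiked locus. Output is
#' deterministic: the same seed reproduces byte-identical files.
#'
#' @param n_variants Total number of variants (`>= n_loci`).
#' @param n_loci Number of spiked association loci (0 for a pure-null
#'   simulation).
#' @param seed Integer RNG seed.
#' @param options A [gg_options()] object (MAF threshold, cap).
#' @param dir Output directory (created if needed).
#' @param compress If `TRUE`, the summary file is written gzip-compressed.
#' @return List with `summary_path`, `loci_path`, `config_path` and `truth`
#'   (class `gg_truth`): the seed, the spiked-locus table (`chrom`, `centre`,
#'   `min_p`, `n_variants`, `low_maf`, `high_impact`), the full simulated
#'   variant data frame, and the chromosome lengths used.
#' @export
simulate_gwas <- function(n_variants, n_loci, seed = 1L,
                          options = gg_options(), dir = tempfile("ggsim"),
                          compress = FALSE) {
  n_variants <- as.integer(n_variants); n_loci <- as.integer(n_loci)
  if (is.na(n_variants) || is.na(n_loci) || n_loci < 0 ||
      n_variants < n_loci)
    gg_input_error("need n_variants >= n_loci >= 0")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  lens <- synthetic_karyotype()
  chroms <- names(lens)

  n_per <- if (n_loci > 0)
    max(1L, min(30L, n_variants %/% max(1L, 2L * n_loci))) else 0L
  n_spike <- n_per * n_loci
  n_null <- n_variants - n_spike

  # spiked loci: deterministic cluster shapes, seeded placement
  spike <- NULL; loci_truth <- NULL; loci_tab <- NULL
  if (n_loci > 0) {
    nlp_cycle <- c(30, 12, 18, 25)
    k <- seq_len(n_loci)
    l_chrom <- chroms[((k - 1L) %% length(chroms)) + 1L]
    centre <- floor(stats::runif(n_loci, 5e6, lens[l_chrom] - 5e6))
    nlp_max <- nlp_cycle[((k - 1L) %% length(nlp_cycle)) + 1L]
    combo <- (k - 1L) %% 4L
    low_maf <- combo %in% c(1L, 3L)
    high_imp <- combo %in% c(2L, 3L)
    rows <- vector("list", n_loci)
    for (i in k) {
      off <- if (n_per == 1L) 0 else round(seq(-1.5e6, 1.5e6,
                                               length.out = n_per))
      nlp <- nlp_max[i] * (1 - abs(off) / 2.5e6)
      nlp <- pmax(nlp, 0.1)
      maf <- stats::runif(n_per, options$maf_threshold + 0.01, 0.5)
      if (low_maf[i]) {
        j <- seq_len(max(1L, n_per %/% 2L))
        maf[j] <- stats::runif(length(j), 0.005,
                               options$maf_threshold - 0.001)
      }
      cons <- sample(benign_terms, n_per, replace = TRUE)
      if (high_imp[i]) {
        j <- unique(c(which.max(nlp), 1L))
        cons[j] <- sample(options$high_impact_terms, length(j),
                          replace = TRUE)
      }
      rows[[i]] <- data.frame(
        name = sprintf("locus%d_v%d", i, seq_len(n_per)),
        chrom = l_chrom[i],
        pos = pmin(pmax(centre[i] + off, 1), lens[l_chrom[i]]),
        pvalue = 10^(-nlp),
        maf = maf,
        consequence = cons,
        stringsAsFactors = FALSE
      )
    }
    spike <- do.call(rbind, rows)
    loci_truth <- data.frame(
      name = sprintf("locus%d_v%d", k, vapply(rows, function(r)
        which.min(r$pvalue), integer(1))),
      chrom = l_chrom, centre = centre,
      min_p = 10^(-nlp_max), n_variants = n_per,
      low_maf = low_maf, high_impact = high_imp,
      stringsAsFactors = FALSE
    )
    loci_tab <- data.frame(
      name = loci_truth$name,
      chrom = l_chrom,
      pos = vapply(seq_len(n_loci), function(i)
        rows[[i]]$pos[which.min(rows[[i]]$pvalue)], numeric(1)),
      eaf = round(stats::runif(n_loci, 0.05, 0.95), 3),
      odds_ratio = round(exp(abs(stats::rnorm(n_loci, 0, 0.15))) , 3),
      pvalue = loci_truth$min_p,
      novelty = ifelse(k %% 2L == 1L, "novel", "known"),
      gene = sprintf("GENE%d", k),
      stringsAsFactors = FALSE
    )
  }

  null <- NULL
  if (n_null > 0) {
    nc <- sample.int(length(chroms), n_null, replace = TRUE,
                     prob = lens / sum(lens))
    null <- data.frame(
      name = sprintf("null_v%d", seq_len(n_null)),
      chrom = chroms[nc],
      pos = floor(stats::runif(n_null, 1, lens[nc])) + 0,
      pvalue = stats::runif(n_null),
      maf = stats::runif(n_null, 0.001, 0.5),
      consequence = ifelse(stats::runif(n_null) < 0.01,
                           sample(options$high_impact_terms, n_null,
                                  replace = TRUE),
                           sample(benign_terms, n_null, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  }
  variants <- rbind(null, spike)
  variants <- variants[order(match(variants$chrom, chroms), variants$pos,
                             variants$name), , drop = FALSE]
  rownames(variants) <- NULL

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir,
                            if (compress) "summary.tsv.gz" else "summary.tsv")
  con <- if (compress) gzfile(summary_path, "wt") else file(summary_path, "wt")
  utils::write.table(variants, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  loci_path <- file.path(dir, "loci.tsv")
  empty_loci <- data.frame(name = character(), chrom = character(),
                           pos = numeric(), eaf = numeric(),
                           odds_ratio = numeric(), pvalue = numeric(),
                           novelty = character(), gene = character())
  utils::write.table(loci_tab %||% empty_loci, loci_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  config_path <- write_default_config(file.path(dir, "config.txt"))
  truth <- structure(list(seed = seed, n_variants = n_variants,
                          loci = loci_truth, variants = variants,
                          chrom_lengths = lens), class = "gg_truth")
  list(summary_path = summary_path, loci_path = loci_path,
       config_path = config_path, truth = truth)
}

#' Minimal fixture realising every default rule index
#'
#' Constructs, deterministically, a small variant set on one chromosome in
#' which exactly one cell realises each of the eight default classification
#' indices, together with the expected per-cell classification. Because the
#' fixture is built constructively, the expectation is known at generation
#' time without running the classifier.
#'
#' @param seed Unused placeholder for interface symmetry (the construction
#'   is deterministic).
#' @return List with `variants` (record data frame), `expected` (data frame
#'   `row`, `col`, `count`, `idx`), and `lengths` (named chromosome length
#'   vector for [build_layout()]).
#' @export
make_index_coverage_fixture <- function(seed = 1L) {
  opts <- gg_options()
  mk <- function(i, n, mafs, cons) {
    col <- 80L + i                      # distinct significance bins
    p <- 10^(-(col + 0.5) * opts$pbin)  # mid-bin
    pos <- (i - 1) * opts$chunk_bp + 1.5e6 + seq_len(n) * 1000
    data.frame(name = sprintf("fx%d_%d", i, seq_len(n)), chrom = "1",
               pos = pos, pvalue = p, maf = mafs, consequence = cons,
               stringsAsFactors = FALSE)
  }
  lo <- 0.01; hi <- 0.3
  v <- rbind(
    mk(1, 1, hi, "intron_variant"),
    mk(2, 1, hi, "stop_gained"),
    mk(3, 1, lo, "intron_variant"),
    mk(4, 1, lo, "stop_gained"),
    mk(5, 2, c(hi, hi), c("intron_variant", "missense_variant")),
    mk(6, 2, c(hi, hi), c("stop_gained", "intron_variant")),
    mk(7, 2, c(lo, hi), c("intron_variant", "intron_variant")),
    mk(8, 2, c(lo, hi), c("intron_variant", "stop_gained"))
  )
  expected <- data.frame(row = 0:7, col = 80L + 1:8,
                         count = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
                         idx = 1:8)
  list(variants = v, expected = expected,
       lengths = c("1" = 8 * opts$chunk_bp))
}
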