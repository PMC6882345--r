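#' Genome bin layout
#'
#' Splits an ordered set of chromosomes into fixed-width bins and records, for
#' each chromosome, the matrix row at which its bins start. Rows are 0-based:
#' the first bin of the first chromosome is row 0. Chromosomes are ordered
#' numerically 1..22, then X, Y, MT, then any other labels lexicographically.
#'
#' @param lengths Either a named numeric vector of chromosome lengths in bp,
#'   or a data frame with columns `chrom` and `length`, or a variant record
#'   data frame (columns `chrom`, `pos`) from which lengths are inferred as
#'   the maximum observed position per chromosome.
#' @param chunk_bp Bin width in base pairs.
#'
#' @return An object of class `gg_layout`: a list with `chrom_order`,
#'   `chrom_length` (named, bp), `chunk_bp`, `row_offset` (named, 0-based),
#'   `n_bins` (bins per chromosome) and `n_rows` (total genome bins).
#' @export
#' @examples
#' build_layout(c(chr1 = 7e6, chr2 = 2e6), chunk_bp = 3e6)
build_layout <- function(lengths, chunk_bp = 3e6) {
  if (is.data.frame(lengths)) {
    if (all(c("chrom", "length") %in% names(lengths))) {
      len <- stats::setNames(as.numeric(lengths$length),
                             as.character(lengths$chrom))
    } else if (all(c("chrom", "pos") %in% names(lengths))) {
      len <- tapply(as.numeric(lengths$pos), as.character(lengths$chrom), max)
      len <- stats::setNames(as.numeric(len), names(len))
    } else {
      gg_input_error("lengths data frame needs columns chrom+length or chrom+pos")
    }
  } else {
    if (is.null(names(lengths)))
      gg_input_error("chromosome length vector must be named")
    len <- stats::setNames(as.numeric(lengths), names(lengths))
  }
  if (length(len) == 0L) gg_input_error("no chromosomes supplied")
  if (any(!is.finite(len) | len < 1))
    gg_validation_error("all chromosome lengths must be >= 1")
  ord <- order_chromosomes(names(len))
  len <- len[ord]
  n_bins <- as.integer(ceiling(len / chunk_bp))
  row_offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(row_offset) <- names(len)
  structure(list(
    chrom_order = names(len),
    chrom_length = len,
    chunk_bp = as.numeric(chunk_bp),
    row_offset = row_offset,
    n_bins = stats::setNames(n_bins, names(len)),
    n_rows = sum(n_bins)
  ), class = "gg_layout")
}

#' Canonical chromosome ordering
#'
#' Orders labels numerically (1..22, after stripping an optional "chr"
#' prefix), then X, Y, MT/M, then remaining labels lexicographically.
#'
#' @param labels Character vector of chromosome labels.
#' @return Integer permutation ordering `labels`.
#' @export
order_chromosomes <- function(labels) {
  core <- sub("^chr", "", labels, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(core))
  up <- toupper(core)
  special <- match(up, c("X", "Y", "MT", "M"))
  special[special == 4L] <- 3L  # M == MT
  grp <- ifelse(!is.na(num), 1L, ifelse(!is.na(special), 2L, 3L))
  order(grp, num, special, core)
}

#' Map a genomic position to its matrix row
#'
#' Genome bins are half-open in 1-based coordinates: bin k of a chromosome
#' covers positions `k*chunk_bp + 1 .. (k+1)*chunk_bp`.
#'
#' @param chrom Chromosome label(s) present in the layout.
#' @param pos 1-based base-pair position(s).
#' @param layout A `gg_layout`.
#' @return 0-based row index (vectorised).
#' @export
#' @examples
#' lay <- build_layout(c(chr1 = 7e6, chr2 = 2e6), 3e6)
#' position_to_row("chr2", 1, lay)  # 3
position_to_row <- function(chrom, pos, layout) {
  chrom <- as.character(chrom)
  i <- match(chrom, layout$chrom_order)
  if (anyNA(i))
    gg_input_error(paste0("chromosome not in layout: ",
                          paste(unique(chrom[is.na(i)]), collapse = ", ")))
  pos <- as.numeric(pos)
  bad <- pos < 1 | pos > layout$chrom_length[i]
  if (any(bad))
    gg_validation_error(paste0(sum(bad),
      " position(s) outside the chromosome length range"))
  as.integer(layout$row_offset[i] + floor((pos - 1) / layout$chunk_bp))
}

# which chromosome each 0-based row belongs to; returns integer index into
# layout$chrom_order
row_to_chrom_index <- function(rows, layout) {
  findInterval(rows, layout$row_offset)
}

#' @export
print.gg_layout <- function(x, ...) {
  cat("Genome bin layout:", length(x$chrom_order), "chromosomes,",
      x$n_rows, "bins of", format(x$chunk_bp, big.mark = ","), "bp\n")
  invisible(x)
}
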