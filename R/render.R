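# Figure assembly: transposed binned Manhattan heatmap (left), locus
# annotation panel (right, table or repelled labels), and the
# auto-generated key (bottom). Built with ggplot2 and composed with
# patchwork.

#' Resolve the display style of classified cells
#'
#' Non-significant cells are drawn as the grey chromosome banding: dark grey
#' on odd chromosomes, light grey on even chromosomes (position in the
#' layout's chromosome order). Significant cells take their matched rule's
#' colour, and cells flagged for reporting additionally carry the rule index
#' as a bubble glyph.
#'
#' @param cells Classified cells from [classify_matrix()].
#' @param rules Rule table with a `colour` column.
#' @param layout The `gg_layout` (defines chromosome parity).
#' @return `cells` with added columns `chrom`, `parity`, `fill` (R colour)
#'   and `glyph` (`NA` or the rule index as text for bubble cells).
#' @export
resolve_cell_style <- function(cells, rules = default_rules(), layout) {
  ci <- row_to_chrom_index(cells$row, layout)
  cells$chrom <- layout$chrom_order[ci]
  cells$parity <- ifelse(ci %% 2L == 1L, "odd", "even")
  rule_col <- resolve_colour(rules$colour[match(cells$idx, rules$idx)])
  grey <- ifelse(cells$parity == "odd", "grey35", "grey72")
  cells$fill <- ifelse(cells$significant, rule_col, grey)
  cells$glyph <- ifelse(cells$bubble, as.character(cells$idx), NA_character_)
  cells
}

key_range_labels <- function(rules, max_cell_count) {
  tiers <- sort(unique(rules$min_count))
  vapply(rules$min_count, function(mc) {
    nxt <- tiers[tiers > mc]
    upper <- if (length(nxt)) nxt[1] - 1L else max(max_cell_count, mc)
    if (upper <= mc) as.character(mc) else paste0(mc, "-", upper)
  }, character(1))
}

flag_description <- function(maf, conseq) {
  ifelse(maf & conseq, "low MAF + high impact",
         ifelse(maf, "low MAF",
                ifelse(conseq, "high impact", "none")))
}

#' Build the plot key
#'
#' One key row per rule: colour swatch, rule index, the count range the rule
#' covers (the top tier runs to the data-driven maximum cell count),
#' the annotation flags it encodes, and a counter of how many cells in the
#' plot carry the rule.
#'
#' @param key A `gg_key` from [key_counts()].
#' @param rules Rule table.
#' @return List with `data` (the key rows as a data frame: `idx`, `range`,
#'   `annotation`, `counter`, `colour`) and `plot` (a ggplot panel).
#' @export
render_key <- function(key, rules = default_rules()) {
  df <- data.frame(
    idx = rules$idx,
    range = key_range_labels(rules, key$max_cell_count),
    annotation = flag_description(rules$maf, rules$conseq),
    counter = as.integer(key$counts[as.character(rules$idx)]),
    colour = resolve_colour(rules$colour),
    stringsAsFactors = FALSE
  )
  df$y <- rev(seq_len(nrow(df)))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_tile(ggplot2::aes(x = 0, y = .data$y), fill = df$colour,
                       width = 0.6, height = 0.7, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(x = 1, y = .data$y,
                                    label = .data$idx), hjust = 0, size = 2.8) +
    ggplot2::geom_text(ggplot2::aes(x = 2.2, y = .data$y,
                                    label = .data$range), hjust = 0, size = 2.8) +
    ggplot2::geom_text(ggplot2::aes(x = 4.6, y = .data$y,
                                    label = .data$annotation),
                       hjust = 0, size = 2.8) +
    ggplot2::geom_text(ggplot2::aes(x = 10, y = .data$y,
                                    label = paste0(.data$counter, " cells")),
                       hjust = 0, size = 2.8) +
    ggplot2::annotate("text", x = c(1, 2.2, 4.6, 10), y = nrow(df) + 1,
                      label = c("idx", "count", "annotation", "in plot"),
                      hjust = 0, size = 2.8, fontface = "bold") +
    ggplot2::xlim(-0.5, 13) +
    ggplot2::ylim(0, nrow(df) + 1.6) +
    ggplot2::labs(title = "Key") +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 9,
                                                      face = "bold"))
  list(data = df[, c("idx", "range", "annotation", "counter", "colour")],
       plot = p)
}

heatmap_panel <- function(styled, layout, boundary, options) {
  pbin <- options$pbin
  mids <- layout$row_offset + layout$n_bins / 2
  p <- ggplot2::ggplot(styled,
                       ggplot2::aes(x = (.data$col + 0.5) * pbin,
                                    y = .data$row + 0.5)) +
    ggplot2::geom_tile(fill = styled$fill, width = pbin, height = 1) +
    ggplot2::scale_y_reverse(breaks = mids, labels = layout$chrom_order,
                             limits = c(layout$n_rows, 0), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, options$cap_nlp),
                                expand = c(0.01, 0)) +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
  if (is.finite(boundary$boundary_col))
    p <- p + ggplot2::geom_vline(xintercept = boundary$boundary_col * pbin,
                                 linetype = "dashed", colour = "grey40",
                                 linewidth = 0.3)
  bub <- styled[styled$bubble, , drop = FALSE]
  if (nrow(bub)) {
    p <- p +
      ggplot2::geom_point(data = bub, shape = 21, size = 3.6, stroke = 0.4,
                          colour = "black", fill = NA) +
      ggplot2::geom_text(data = bub, ggplot2::aes(label = .data$glyph),
                         size = 1.9)
  }
  p
}

table_panel <- function(loci, options) {
  n <- nrow(loci)
  cols_x <- c(variant = 0, gene = 2.1, or = 3.6, eaf = 4.5, p = 5.4,
              novelty = 6.8)
  base <- ggplot2::ggplot() +
    ggplot2::xlim(-0.1, 7.8) +
    ggplot2::theme_void()
  if (n == 0L) return(base + ggplot2::ylim(0, 1))
  size <- max(0.9, min(2.6, 260 / (n + 2)))
  df <- data.frame(
    y = rev(seq_len(n)),
    variant = loci$name,
    gene = loci$gene,
    or = sprintf("%.2f", loci$odds_ratio),
    eaf = sprintf("%.2f", loci$eaf),
    p = formatC(loci$pvalue, format = "e", digits = 1),
    novelty = loci$novelty,
    stringsAsFactors = FALSE
  )
  p <- base + ggplot2::ylim(0, n + 2)
  for (f in names(cols_x)) {
    p <- p + ggplot2::geom_text(
      data = df, ggplot2::aes(y = .data$y, label = .data[[f]]),
      x = cols_x[[f]], hjust = 0, size = size)
  }
  hdr <- c("variant", "gene", "OR", "EAF", "p", "status")
  p + ggplot2::annotate("text", x = unname(cols_x), y = n + 1.2, label = hdr,
                        hjust = 0, size = max(size, 1.8), fontface = "bold")
}

labelled_heatmap <- function(p, loci, layout, options, seed) {
  txt <- ifelse(is.na(loci$gene) | !nzchar(loci$gene), loci$name, loci$gene)
  anch_row <- position_to_row(loci$chrom, loci$pos, layout) + 0.5
  anch_x <- (pvalue_to_col(loci$pvalue, options$pbin, options$cap_nlp) + 0.5) *
    options$pbin
  n <- length(txt)
  scale <- 55 / max(55, 1.3 * n)  # shrink boxes when many labels compete
  lab <- data.frame(text = txt, x = anch_x, y = anch_row,
                    w = 0.30 * (nchar(txt) + 2) * max(scale, 0.5),
                    h = layout$n_rows / 55 * scale,
                    stringsAsFactors = FALSE)
  placed <- layout_labels(
    lab, seed = seed,
    max_displacement = options$max_label_displacement *
      sqrt(options$cap_nlp^2 + layout$n_rows^2),
    canvas = c(0, options$cap_nlp, 0, layout$n_rows))
  lead <- placed[placed$leader, , drop = FALSE]
  if (nrow(lead))
    p <- p + ggplot2::geom_segment(
      data = lead, ggplot2::aes(x = .data$x, y = .data$y,
                                xend = .data$px, yend = .data$py),
      linewidth = 0.2, colour = "grey50", inherit.aes = FALSE)
  p + ggplot2::geom_label(
    data = placed, ggplot2::aes(x = .data$px, y = .data$py,
                                label = .data$text),
    size = max(1.1, 1.9 * sqrt(scale)),
    label.padding = ggplot2::unit(0.08, "lines"),
    inherit.aes = FALSE)
}

#' Render the two-panel binned Manhattan figure
#'
#' Draws the transposed heatmap (genome on the vertical axis, chromosome 1
#' at the top; \eqn{-\log_{10} p} on the horizontal axis) with alternating
#' grey chromosome banding below the significance boundary, rule-coloured
#' cells beyond it and numbered bubbles on reported cells; the loci of
#' interest as either an annotation table (up to `table_capacity` rows,
#' default 130) or repelled name labels; and the auto-generated key. Saves
#' to PDF (vector) or TIFF.
#'
#' @param x A fitted [gwasgrid()] object.
#' @param out_path Output file path; `NULL` returns the composed plot
#'   without writing.
#' @param format `"pdf"` or `"tiff"`; defaults to the configured
#'   `output_format` (or is inferred from `out_path`'s extension).
#' @param mode `"table"` or `"labels"`; defaults to the configured
#'   `annotation_mode`.
#' @param auto_mode If `TRUE`, a loci table too long for table mode falls
#'   back to label mode with a warning instead of an error.
#' @param seed Seed for the label layout.
#' @param width,height Page size in inches (default portrait A4).
#' @return The composed plot (patchwork), invisibly; with `out_path` set,
#'   the file is written first.
#' @export
render_figure <- function(x, out_path = NULL, format = NULL, mode = NULL,
                          auto_mode = FALSE, seed = 1L,
                          width = 8.27, height = 11.69) {
  stopifnot(inherits(x, "gwasgrid"))
  options <- x$options
  mode <- mode %||% options$annotation_mode
  mode <- match.arg(mode, c("table", "labels"))
  loci <- x$loci %||% data.frame()
  n_loci <- nrow(loci)
  if (mode == "table" && n_loci > options$table_capacity) {
    if (auto_mode) {
      warning(n_loci, " loci exceed the table capacity of ",
              options$table_capacity, "; switching to label mode",
              call. = FALSE)
      mode <- "labels"
    } else {
      gg_capacity_error(paste0(
        n_loci, " loci exceed the annotation table capacity of ",
        options$table_capacity,
        "; use annotation mode 'labels' (gene-name labels) instead"))
    }
  }
  styled <- resolve_cell_style(x$cells, x$rules, x$layout)
  heat <- heatmap_panel(styled, x$layout, x$boundary, options)
  key <- render_key(x$key, x$rules)
  if (mode == "labels" && n_loci > 0) {
    heat <- labelled_heatmap(heat, loci, x$layout, options, seed)
    fig <- patchwork::wrap_plots(heat, key$plot, ncol = 1,
                                 heights = c(5, 1))
  } else {
    tab <- table_panel(loci, options)
    top <- patchwork::wrap_plots(heat, tab, nrow = 1,
                                 widths = c(1.6, 1))
    fig <- patchwork::wrap_plots(top, key$plot, ncol = 1,
                                 heights = c(5, 1))
  }
  if (!is.null(out_path)) {
    if (is.null(format)) {
      ext <- tolower(tools::file_ext(out_path))
      format <- if (ext %in% c("pdf", "tiff", "tif"))
        sub("^tif$", "tiff", ext) else options$output_format
    }
    format <- match.arg(format, c("pdf", "tiff"))
    dir <- dirname(out_path)
    if (!dir.exists(dir) || file.access(dir, 2) != 0)
      gg_io_error(paste0("cannot write figure to ", out_path))
    if (format == "pdf") {
      grDevices::pdf(out_path, width = width, height = height,
                     useDingbats = FALSE)
    } else {
      grDevices::tiff(out_path, width = width, height = height,
                      units = "in", res = options$tiff_dpi,
                      compression = "lzw")
    }
    on.exit(grDevices::dev.off())
    print(fig)
  }
  invisible(fig)
}
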