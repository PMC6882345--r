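# Deterministic force-directed label placement. Labels are axis-aligned
# boxes anchored at data coordinates; overlapping boxes repel each other
# while a weak spring pulls each label back to its anchor. A final sweep
# pass guarantees zero pairwise overlaps (the force phase alone only makes
# the layout compact). All randomness (tie-breaking jitter) comes from the
# seed, so layouts are reproducible.

#' Lay out text labels without overlaps
#'
#' Places label boxes near their anchors so that no two boxes overlap.
#' Ties (e.g. identical anchors) are broken with seeded jitter, making the
#' layout deterministic for a fixed seed. When the packing is infeasible on
#' the given canvas the function warns and returns its best effort rather
#' than failing.
#'
#' @param labels Data frame with columns `text`, `x`, `y` (anchor, data
#'   coordinates), `w`, `h` (box extent in the same coordinates).
#' @param seed Integer seed for tie-breaking jitter.
#' @param max_displacement Maximum intended displacement from the anchor (in
#'   data coordinates); exceeding it triggers a warning, not an error.
#' @param canvas Optional numeric `c(xmin, xmax, ymin, ymax)`; placed boxes
#'   are kept inside where possible.
#' @param pad Minimum gap between boxes, as a fraction of the mean box size.
#' @return The input data frame with added columns `px`, `py` (placed box
#'   centre), `displacement` and `leader` (`TRUE` when the displacement
#'   exceeds the box size and a leader line should be drawn).
#' @export
layout_labels <- function(labels, seed = 1L, max_displacement = Inf,
                          canvas = NULL, pad = 0.05) {
  n <- nrow(labels)
  out <- labels
  out$px <- out$x; out$py <- out$y
  out$displacement <- 0; out$leader <- FALSE
  if (n == 0L) return(out)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  w <- out$w; h <- out$h
  gx <- pad * mean(w); gy <- pad * mean(h)
  px <- out$x + stats::runif(n, -1e-6, 1e-6) * max(w)
  py <- out$y + stats::runif(n, -1e-6, 1e-6) * max(h)

  if (n > 1L) {
    # force phase: vectorised pairwise repulsion + spring to anchor
    half_w <- outer(w, w, "+") / 2 + gx
    half_h <- outer(h, h, "+") / 2 + gy
    for (it in seq_len(150L)) {
      dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
      ox <- half_w - abs(dx); oy <- half_h - abs(dy)
      olap <- ox > 0 & oy > 0
      diag(olap) <- FALSE
      if (!any(olap)) {
        # converged: relax toward anchors while staying overlap-free
        px <- px + 0.1 * (out$x - px)
        py <- py + 0.1 * (out$y - py)
        next
      }
      # push along y mostly (labels usually stack vertically), x a little
      sy <- ifelse(dy >= 0, 1, -1) * oy * olap
      sx <- ifelse(dx >= 0, 1, -1) * ox * olap
      py <- py + 0.30 * rowSums(sy)
      px <- px + 0.05 * rowSums(sx)
      px <- px + 0.02 * (out$x - px)
      py <- py + 0.02 * (out$y - py)
    }
    # guarantee pass: deterministic sweep, move along y to the nearest free
    # slot; terminates because y is unbounded
    ordp <- order(py, px, out$text)
    placed <- integer(0)
    step <- pmax(h, 1e-9) / 4
    for (i in ordp) {
      k <- 0L
      repeat {
        cand <- py[i] + ((-1)^k) * ceiling(k / 2) * 2 * step[i]
        ok <- TRUE
        for (j in placed) {
          if (abs(px[i] - px[j]) < (w[i] + w[j]) / 2 + gx &&
              abs(cand - py[j]) < (h[i] + h[j]) / 2 + gy) { ok <- FALSE; break }
        }
        if (ok) { py[i] <- cand; break }
        k <- k + 1L
        if (k > 4000L) { warning("label packing did not converge; ",
                                 "layout is best-effort", call. = FALSE)
                         py[i] <- cand; break }
      }
      placed <- c(placed, i)
    }
  }
  if (!is.null(canvas)) {
    px2 <- pmin(pmax(px, canvas[1] + w / 2), canvas[2] - w / 2)
    py2 <- pmin(pmax(py, canvas[3] + h / 2), canvas[4] - h / 2)
    if (!boxes_overlap(px2, py2, w + 2 * gx, h + 2 * gy)) {
      px <- px2; py <- py2  # clamping into the canvas kept boxes disjoint
    } else {
      outside <- px - w / 2 < canvas[1] | px + w / 2 > canvas[2] |
                 py - h / 2 < canvas[3] | py + h / 2 > canvas[4]
      if (any(outside))
        warning(sum(outside), " label(s) fall outside the canvas; ",
                "layout is best-effort", call. = FALSE)
      px <- px2
    }
  }
  # labels the layout never needed to move snap back to their anchor
  snap <- abs(px - out$x) < 1e-4 * pmax(w, 1e-12) &
          abs(py - out$y) < 1e-4 * pmax(h, 1e-12)
  px[snap] <- out$x[snap]; py[snap] <- out$y[snap]
  out$px <- px; out$py <- py
  out$displacement <- sqrt((px - out$x)^2 + (py - out$y)^2)
  if (any(out$displacement > max_displacement))
    warning(sum(out$displacement > max_displacement),
            " label(s) displaced beyond the configured maximum", call. = FALSE)
  out$leader <- out$displacement > pmax(out$w, out$h)
  out
}

# TRUE if any two boxes (centres cx,cy, extents w,h) overlap; used by tests
boxes_overlap <- function(cx, cy, w, h) {
  n <- length(cx)
  if (n < 2L) return(FALSE)
  dx <- abs(outer(cx, cx, "-")); dy <- abs(outer(cy, cy, "-"))
  ox <- outer(w, w, "+") / 2 - dx
  oy <- outer(h, h, "+") / 2 - dy
  olap <- ox > 1e-12 & oy > 1e-12
  diag(olap) <- FALSE
  any(olap)
}
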