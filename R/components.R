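#' Label connected components of a binary mask
#'
#' Run-based connected-component labelling with union-find, supporting both
#' 4- and 8-connectivity.  Components are numbered deterministically by the
#' raster position of their first pixel (top-most row, then left-most
#' column), so labels are stable across platforms.
#'
#' @param mask Logical `H x W` matrix; `TRUE` pixels are foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   default).
#' @return Integer `H x W` matrix: 0 for background, `1..K` component labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.", class = "fpquant_config_error")
  }
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  if (!any(mask)) return(labels)

  # horizontal runs, generated in raster order (row, then start column)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (r in seq_len(H)) {
    x <- mask[r, ]
    d <- diff(c(FALSE, x, FALSE))
    s <- which(d == 1L)
    if (length(s)) {
      e <- which(d == -1L) - 1L
      run_row <- c(run_row, rep.int(r, length(s)))
      run_s <- c(run_s, s); run_e <- c(run_e, e)
    }
  }
  nr <- length(run_s)
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # 8-connectivity lets runs touch diagonally, i.e. column reach extends by 1
  reach <- if (connectivity == 8L) 1L else 0L
  row_first <- match(seq_len(H), run_row)

  for (r in 2L:H) {
    ia <- row_first[r]; ib <- row_first[r - 1L]
    if (is.na(ia) || is.na(ib)) next
    while (ia <= nr && run_row[ia] == r && ib <= nr && run_row[ib] == r - 1L) {
      if (run_s[ia] - reach <= run_e[ib] && run_e[ia] + reach >= run_s[ib]) {
        ra <- find(ia); rb <- find(ib)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      # advance the run ending first; same-row runs are >= 2 apart, so no
      # cross-pair can be missed even with diagonal reach
      if (run_e[ia] < run_e[ib]) ia <- ia + 1L else ib <- ib + 1L
    }
  }

  roots <- vapply(seq_len(nr), find, integer(1))
  # the root is always the minimal run index of its component, and runs are
  # in raster order, so sorting roots yields top-most/left-most numbering
  comp <- match(roots, sort(unique(roots)))

  lens <- run_e - run_s + 1L
  rows_rep <- rep.int(run_row, lens)
  cols_rep <- sequence(lens) - 1L + rep.int(run_s, lens)
  labels[cbind(rows_rep, cols_rep)] <- rep.int(comp, lens)
  labels
}

# Ordered outer contours of a labelled image, via EBImage border tracing.
# Returns a list (indexed by label) of matrices with columns x, y (1-based).
component_contours <- function(labels) {
  oc <- EBImage::ocontour(EBImage::Image(t(labels)))
  lapply(oc, function(m) cbind(x = m[, 1L] + 1L, y = m[, 2L] + 1L))
}
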