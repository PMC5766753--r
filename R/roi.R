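#' Regions of interest for colour learning
#'
#' A marker for each tissue class is learned from one or more training
#' regions of interest (ROIs) drawn on the image.  Three kinds of region are
#' supported: axis-aligned rectangles, polygons, and arbitrary pixel masks.
#' Several ROIs may share a class label; their pixels are pooled when the
#' class marker is learned.
#'
#' Pixel coordinates are 1-based with `x` = column and `y` = row, origin at
#' the top-left corner of the image.
#'
#' @param class_label One of `"fungiform"`, `"filiform"`, `"base"`,
#'   `"background"`.
#' @param xmin,xmax,ymin,ymax Integer rectangle bounds, inclusive.
#' @param x,y Numeric vertex coordinates of a polygon (closed implicitly).
#' @param mask Logical matrix of the full image size; `TRUE` pixels belong
#'   to the ROI.
#' @return An object of class `fp_roi`.
#' @name roi
NULL

new_roi <- function(class_label, kind, ...) {
  class_label <- match.arg(tolower(class_label), FP_CLASS_ORDER)
  structure(list(class_label = class_label, kind = kind, ...),
            class = "fp_roi")
}

#' @rdname roi
#' @export
roi_rect <- function(class_label, xmin, xmax, ymin, ymax) {
  if (xmax < xmin || ymax < ymin) {
    abort("Rectangle ROI has no interior pixels.", class = "fpquant_roi_error")
  }
  new_roi(class_label, "rect",
          xmin = as.integer(xmin), xmax = as.integer(xmax),
          ymin = as.integer(ymin), ymax = as.integer(ymax))
}

#' @rdname roi
#' @export
roi_polygon <- function(class_label, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  new_roi(class_label, "polygon", x = as.numeric(x), y = as.numeric(y))
}

#' @rdname roi
#' @export
roi_mask <- function(class_label, mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) {
    abort("Mask ROI has no interior pixels.", class = "fpquant_roi_error")
  }
  new_roi(class_label, "mask", mask = mask)
}

#' @export
print.fp_roi <- function(x, ...) {
  cat(sprintf("<fp_roi> class '%s', %s\n", x$class_label, x$kind))
  invisible(x)
}

# Even-odd rule point-in-polygon, vectorised over points.  Points exactly on
# an edge may fall either side; training ROIs are not drawn that tightly.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Linear pixel indices (column-major, i.e. usable on an H x W matrix) covered
# by an ROI, clipped against the image; errors if the ROI leaves the image.
roi_pixel_index <- function(roi, dim_hw) {
  H <- dim_hw[1L]; W <- dim_hw[2L]
  idx <- switch(
    roi$kind,
    rect = {
      if (roi$xmin < 1L || roi$ymin < 1L || roi$xmax > W || roi$ymax > H) {
        abort("Rectangle ROI lies outside the image.",
              class = "fpquant_bounds_error")
      }
      rows <- roi$ymin:roi$ymax
      cols <- roi$xmin:roi$xmax
      as.vector(outer(rows, (cols - 1L) * H, "+"))
    },
    polygon = {
      if (min(roi$x) < 0.5 || min(roi$y) < 0.5 ||
          max(roi$x) > W + 0.5 || max(roi$y) > H + 0.5) {
        abort("Polygon ROI lies outside the image.",
              class = "fpquant_bounds_error")
      }
      rows <- max(1L, floor(min(roi$y))):min(H, ceiling(max(roi$y)))
      cols <- max(1L, floor(min(roi$x))):min(W, ceiling(max(roi$x)))
      px <- rep(cols, each = length(rows))
      py <- rep(rows, times = length(cols))
      keep <- points_in_polygon(px, py, roi$x, roi$y)
      (px[keep] - 1L) * H + py[keep]
    },
    mask = {
      if (!identical(dim(roi$mask), as.integer(dim_hw))) {
        abort("Mask ROI does not match the image dimensions.",
              class = "fpquant_bounds_error")
      }
      which(roi$mask)
    }
  )
  if (length(idx) == 0L) {
    abort("ROI covers no interior pixel.", class = "fpquant_roi_error")
  }
  idx
}
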