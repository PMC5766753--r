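#' Learn mean-colour markers from training ROIs
#'
#' For each tissue class, the marker is the unweighted arithmetic mean CIELAB
#' colour over all pixels of all ROIs carrying that class label.  The three
#' tongue classes (`fungiform`, `filiform`, `base`) must each be covered; a
#' `background` ROI is optional and enables background rejection during
#' classification.
#'
#' @param lab An `H x W x 3` CIELAB image from [rgb_to_lab()].
#' @param rois A list of [roi_rect()] / [roi_polygon()] / [roi_mask()]
#'   specifications.
#' @param require A character vector of class labels that must be present
#'   (default: the three tongue classes).
#' @return A tibble with one row per class: `class`, `L`, `a`, `b`,
#'   `n_pixels`, ordered fungiform, filiform, base, background.
#' @export
learn_markers <- function(lab, rois,
                          require = FP_TONGUE_CLASSES) {
  stopifnot(is.array(lab), length(dim(lab)) == 3L)
  if (inherits(rois, "fp_roi")) rois <- list(rois)
  labels <- vapply(rois, function(r) r$class_label, character(1))
  missing <- setdiff(require, labels)
  if (length(missing) > 0L) {
    abort(paste0("No training ROI for class(es): ",
                 paste(missing, collapse = ", "), "."),
          class = "fpquant_missing_class_error")
  }
  H <- dim(lab)[1L]; W <- dim(lab)[2L]
  npx <- H * W
  chan <- function(k) lab[(k - 1L) * npx + seq_len(npx)]

  out <- lapply(intersect(FP_CLASS_ORDER, unique(labels)), function(cl) {
    idx <- unique(unlist(lapply(rois[labels == cl], roi_pixel_index,
                                dim_hw = c(H, W))))
    tibble(
      class = cl,
      L = mean(lab[idx]),
      a = mean(lab[npx + idx]),
      b = mean(lab[2L * npx + idx]),
      n_pixels = length(idx)
    )
  })
  dplyr::bind_rows(out)
}

check_markers <- function(markers, n_min = 2L) {
  stopifnot(is.data.frame(markers),
            all(c("class", "L", "a", "b") %in% names(markers)))
  if (anyDuplicated(markers$class)) {
    abort("Duplicate class labels among markers.",
          class = "fpquant_config_error")
  }
  if (!all(markers$class %in% FP_CLASS_ORDER)) {
    abort("Unknown marker class label.", class = "fpquant_config_error")
  }
  if (nrow(markers) < n_min) {
    abort("At least two markers with distinct classes are required.",
          class = "fpquant_config_error")
  }
  # canonical tie-break order
  markers[order(match(markers$class, FP_CLASS_ORDER)), , drop = FALSE]
}

#' Segment an image by nearest colour marker
#'
#' Every pixel is assigned the class of the marker minimising the Euclidean
#' distance in CIELAB.  Ties are broken deterministically in the fixed order
#' fungiform, filiform, base, background.  With `channels = "ab"` the
#' lightness channel is ignored, trading some discriminability for stronger
#' illumination invariance (off by default).
#'
#' @param lab CIELAB image array (`H x W x 3`).
#' @param markers Marker tibble from [learn_markers()] (or hand-built with
#'   columns `class`, `L`, `a`, `b`).
#' @param analysis_mask Optional logical `H x W` matrix; only `TRUE` pixels
#'   are classified, the rest are labelled background.
#' @param channels `"Lab"` (default, full 3-D distance) or `"ab"`.
#' @return An `fp_classmap`: an integer `H x W` matrix with values
#'   0 = background, 1 = fungiform, 2 = filiform, 3 = base.
#' @export
classify_pixels <- function(lab, markers, analysis_mask = NULL,
                            channels = c("Lab", "ab")) {
  stopifnot(is.array(lab), length(dim(lab)) == 3L, dim(lab)[3L] == 3L)
  channels <- match.arg(channels)
  markers <- check_markers(markers)
  H <- dim(lab)[1L]; W <- dim(lab)[2L]
  npx <- H * W

  Lv <- lab[seq_len(npx)]
  av <- lab[npx + seq_len(npx)]
  bv <- lab[2L * npx + seq_len(npx)]

  k <- nrow(markers)
  d2 <- matrix(0, nrow = npx, ncol = k)
  wL <- if (channels == "Lab") 1 else 0
  for (j in seq_len(k)) {
    d2[, j] <- wL * (Lv - markers$L[j])^2 +
      (av - markers$a[j])^2 + (bv - markers$b[j])^2
  }
  best <- max.col(-d2, ties.method = "first")
  codes <- class_code(markers$class)
  labels <- codes[best]

  if (!is.null(analysis_mask)) {
    stopifnot(is.logical(analysis_mask),
              identical(dim(analysis_mask), c(H, W)))
    labels[!as.vector(analysis_mask)] <- FP_CLASSES[["background"]]
  }
  new_classmap(matrix(labels, nrow = H, ncol = W))
}

new_classmap <- function(m) {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "integer"
  structure(m, class = c("fp_classmap", "matrix", "array"))
}

#' @export
print.fp_classmap <- function(x, ...) {
  tab <- tabulate(as.vector(x) + 1L, nbins = 4L)
  cat(sprintf(
    "<fp_classmap> %d x %d px: %d fungiform, %d filiform, %d base, %d background\n",
    nrow(x), ncol(x), tab[2L], tab[3L], tab[4L], tab[1L]))
  invisible(x)
}

#' Re-analyse a rectangular region with locally learned markers
#'
#' Papilla colour shade varies across the tongue, so a single global marker
#' set can leave papillae in some areas unresolved.  A rectangular region can
#' be re-interrogated with markers learned from ROIs local to that region;
#' the regional result is merged with the original classification of the
#' pixels outside the rectangle.  Pixels labelled background in `base_map`
#' keep that label, so the analysis support is unchanged.
#'
#' If the local ROIs miss one of the tongue classes, the global marker for
#' that class is used as a fall-back (a message reports this).
#'
#' @param lab CIELAB image the `base_map` was computed from.
#' @param base_map `fp_classmap` from [classify_pixels()].
#' @param rect Rectangle `c(xmin, xmax, ymin, ymax)` in pixel coordinates
#'   (inclusive), or a list with those names.
#' @param local_rois ROIs lying inside the rectangle, used to learn the local
#'   markers.  Alternatively supply ready-made `local_markers`.
#' @param local_markers Optional marker tibble overriding `local_rois`.
#' @param global_markers The markers used to produce `base_map`; required for
#'   missing-class fall-back.
#' @inheritParams classify_pixels
#' @return A complete `fp_classmap`.
#' @export
reanalyze_region <- function(lab, base_map, rect, local_rois = NULL,
                             local_markers = NULL, global_markers = NULL,
                             channels = c("Lab", "ab")) {
  channels <- match.arg(channels)
  H <- dim(lab)[1L]; W <- dim(lab)[2L]
  stopifnot(identical(dim(base_map), c(H, W)))
  if (is.list(rect) && !is.null(rect$xmin)) {
    rect <- c(rect$xmin, rect$xmax, rect$ymin, rect$ymax)
  }
  rect <- as.integer(rect)
  if (rect[2L] < rect[1L] || rect[4L] < rect[3L]) {
    return(base_map)  # zero-area rectangle: nothing to re-analyse
  }
  if (rect[1L] < 1L || rect[3L] < 1L || rect[2L] > W || rect[4L] > H) {
    abort("Re-analysis rectangle lies outside the image.",
          class = "fpquant_bounds_error")
  }

  if (is.null(local_markers)) {
    if (is.null(local_rois)) {
      abort("Supply `local_rois` or `local_markers`.",
            class = "fpquant_config_error")
    }
    local_markers <- learn_markers(lab, local_rois, require = "fungiform")
  }
  missing <- setdiff(FP_TONGUE_CLASSES, local_markers$class)
  if (length(missing) > 0L) {
    if (is.null(global_markers)) {
      abort(paste0("Local markers miss class(es) ",
                   paste(missing, collapse = ", "),
                   " and no `global_markers` were given for fall-back."),
            class = "fpquant_missing_class_error")
    }
    inform(paste0("Falling back to global marker(s) for: ",
                  paste(missing, collapse = ", "), "."))
    local_markers <- dplyr::bind_rows(
      local_markers, global_markers[global_markers$class %in% missing, ])
  }

  rows <- rect[3L]:rect[4L]
  cols <- rect[1L]:rect[2L]
  sub_lab <- lab[rows, cols, , drop = FALSE]
  sub_tongue <- matrix(base_map[rows, cols] != FP_CLASSES[["background"]],
                       nrow = length(rows))
  sub_map <- classify_pixels(sub_lab, local_markers,
                             analysis_mask = sub_tongue, channels = channels)
  out <- base_map
  out[rows, cols] <- sub_map
  new_classmap(unclass(out))
}
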