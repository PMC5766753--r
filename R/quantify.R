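#' Circular-equivalent diameter of a papilla
#'
#' Papillae are assumed circular, so the reported diameter is that of the
#' circle with the same area: `2 * sqrt(area / pi)`.
#'
#' @param area_mm2 Positive area(s) in mm^2.
#' @return Diameter(s) in mm.
#' @examples
#' equivalent_diameter(pi)  # 2 mm
#' @export
equivalent_diameter <- function(area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    abort("`area_mm2` must be positive.", class = "fpquant_domain_error")
  }
  2 * sqrt(area_mm2 / pi)
}

#' Extract individual papillae from a class map
#'
#' Connected components of the fungiform class are extracted and measured:
#' pixel area, physical area, centroid (unweighted mean of pixel
#' coordinates), ordered outer boundary, and circular-equivalent diameter.
#' Components smaller than `min_area_mm2` are discarded as colour noise.
#' Papillae are ordered by their top-most, then left-most pixel.
#'
#' @param map An `fp_classmap` from [classify_pixels()].
#' @param mm_per_px Spatial calibration, millimetres per pixel (> 0).
#' @param min_area_mm2 Minimum retained component area in mm^2 (default
#'   0.01, i.e. an equivalent diameter of about 0.11 mm).
#' @param connectivity Component connectivity, 4 or 8 (default 8: blob edges
#'   fragment less under 8-connectivity).
#' @param boundary If `TRUE` (default) attach the ordered outer contour of
#'   each papilla as a list-column of `x, y` matrices.
#' @return A tibble with one row per papilla: `id`, `x_px`, `y_px`,
#'   `area_px`, `area_mm2`, `equiv_diameter_mm`, `boundary` (optional
#'   list-column), and empty `side`/`band`/`grid` columns filled in by
#'   [assign_papillae()].
#' @export
extract_papillae <- function(map, mm_per_px, min_area_mm2 = 0.01,
                             connectivity = 8L, boundary = TRUE) {
  stopifnot(inherits(map, "fp_classmap") || is.matrix(map))
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) {
    abort("`mm_per_px` must be > 0.", class = "fpquant_domain_error")
  }
  if (min_area_mm2 < 0) {
    abort("`min_area_mm2` must be >= 0.", class = "fpquant_domain_error")
  }
  fg <- unclass(map) == FP_CLASSES[["fungiform"]]
  labels <- label_components(fg, connectivity = connectivity)
  K <- max(labels)
  empty <- tibble(
    id = integer(0), x_px = numeric(0), y_px = numeric(0),
    area_px = integer(0), area_mm2 = numeric(0),
    equiv_diameter_mm = numeric(0),
    side = character(0), band = integer(0), grid = character(0)
  )
  if (K == 0L) return(empty)

  idx <- which(labels > 0L)
  lab_v <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L

  area_px <- tabulate(lab_v, nbins = K)
  cx <- unname(rowsum(as.numeric(cols), lab_v)[, 1L]) / area_px
  cy <- unname(rowsum(as.numeric(rows), lab_v)[, 1L]) / area_px

  min_area_px <- min_area_mm2 / mm_per_px^2
  keep <- which(area_px >= min_area_px)
  if (length(keep) == 0L) return(empty)

  area_keep <- area_px[keep]
  out <- tibble(
    id = seq_along(keep),
    x_px = cx[keep],
    y_px = cy[keep],
    area_px = area_keep,
    area_mm2 = area_keep * mm_per_px^2,
    equiv_diameter_mm = equivalent_diameter(area_keep * mm_per_px^2),
    side = NA_character_,
    band = NA_integer_,
    grid = NA_character_
  )
  if (boundary) {
    # relabel so contours are computed only for retained components
    filt <- labels
    filt[!(labels %in% keep)] <- 0L
    filt[filt > 0L] <- match(filt[filt > 0L], keep)
    out$boundary <- component_contours(filt)[as.character(out$id)]
  }
  out
}

#' Fungiform papilla density over the tongue
#'
#' Density is the total area of retained papillae divided by the whole
#' tongue area, where the tongue is the union of the three tissue classes
#' (fungiform + filiform + base); background pixels are excluded.  The
#' numerator uses the papillae retained after the minimum-area filter, so
#' density and count describe the same set of structures.
#'
#' @param papillae Papilla tibble from [extract_papillae()].
#' @param map The `fp_classmap` the papillae were extracted from.
#' @return A fraction in `[0, 1]`.
#' @export
compute_density <- function(papillae, map) {
  tongue_px <- sum(unclass(map) != FP_CLASSES[["background"]])
  if (tongue_px == 0L) {
    abort("Class map contains no tongue pixels.",
          class = "fpquant_degenerate_error")
  }
  sum(papillae$area_px) / tongue_px
}

#' Count papillae inside a circular region
#'
#' Membership is decided by the papilla centroid (boundary-inclusive), which
#' matches the manual practice of counting papillae "in" a ring and keeps
#' counts additive across regions.
#'
#' @param papillae Papilla tibble.
#' @param centre_px Circle centre `c(x, y)` in pixel coordinates.
#' @param diameter_mm Circle diameter in mm (default 6, the conventional
#'   counting template near the tongue tip).
#' @param mm_per_px Spatial calibration.
#' @return Integer count.
#' @export
count_in_circle <- function(papillae, centre_px, diameter_mm = 6,
                            mm_per_px) {
  stopifnot(diameter_mm > 0, mm_per_px > 0)
  if (nrow(papillae) == 0L) return(0L)
  r_px <- (diameter_mm / 2) / mm_per_px
  d <- sqrt((papillae$x_px - centre_px[1L])^2 +
              (papillae$y_px - centre_px[2L])^2)
  sum(d <= r_px)
}
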