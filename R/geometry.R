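#' Derive the tongue analysis geometry
#'
#' From the tongue mask and spatial calibration, derives the geometry used
#' for spatial mapping of papillae over the anterior 2 cm:
#'
#' * the tip row (the most protruded tongue pixel; by default the tongue tip
#'   points to the image bottom),
#' * the midline splitting left and right sides (the vertical line through
#'   the tongue-mask centroid column, kept as a continuous coordinate),
#' * two 1-cm horizontal bands measured from the tip along image rows
#'   (Band 1 = `[0, 10)` mm, Band 2 = `[10, 20)` mm, half-open),
#' * per (side, band), 4 equal-width vertical strips between the midline and
#'   that band's lateral mask extreme, numbered from the midline outward:
#'   strips 1-4 in Band 1 and 5-8 in Band 2 give grids L1-L8 / R1-R8,
#' * the 6-mm counting circle, by default placed wholly inside the tongue on
#'   the left side with its right edge tangent to the midline, as close to
#'   the tip as possible.
#'
#' Note that image `LEFT` (small x) is used for the "L" labels, matching the
#' on-screen orientation of the analysed photographs.
#'
#' @param tongue_mask Logical `H x W` matrix of tongue pixels.
#' @param mm_per_px Spatial calibration (> 0).
#' @param tip `"bottom"` (default) or `"top"`: the direction of protrusion.
#' @param midline_col Optional override of the midline column (numeric).
#' @param circle_centre Optional override `c(x, y)` of the counting-circle
#'   centre; `NA` to skip circle placement.
#' @param circle_diameter_mm Counting-circle diameter (default 6 mm).
#' @param band_mm Band edges in mm from the tip (fixed default `c(0, 10, 20)`).
#' @return An `fp_geometry` list: `mm_per_px`, `tongue_mask`, `tip`,
#'   `tip_row`, `midline_col`, `band_mm`, `extents` (tibble: side, band,
#'   extent_px), `circle_centre_px`, `circle_diameter_mm`.
#' @export
derive_geometry <- function(tongue_mask, mm_per_px,
                            tip = c("bottom", "top"),
                            midline_col = NULL,
                            circle_centre = NULL,
                            circle_diameter_mm = 6,
                            band_mm = c(0, 10, 20)) {
  stopifnot(is.matrix(tongue_mask), is.logical(tongue_mask))
  tip <- match.arg(tip)
  if (!any(tongue_mask)) {
    abort("Tongue mask is empty.", class = "fpquant_degenerate_error")
  }
  if (mm_per_px <= 0) {
    abort("`mm_per_px` must be > 0.", class = "fpquant_domain_error")
  }
  H <- nrow(tongue_mask); W <- ncol(tongue_mask)
  idx <- which(tongue_mask)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L

  tip_row <- if (tip == "bottom") max(rows) else min(rows)
  d_mm <- row_dist_mm(rows, tip_row, tip, mm_per_px)
  if (max(d_mm) < band_mm[3L]) {
    warn(sprintf(
      "Tongue mask spans only %.1f mm from the tip; the %g-mm analysis depth is truncated.",
      max(d_mm), band_mm[3L]))
  }
  if (is.null(midline_col)) midline_col <- mean(cols)

  extents <- do.call(rbind, lapply(1:2, function(b) {
    in_band <- d_mm >= band_mm[b] & d_mm < band_mm[b + 1L]
    cb <- cols[in_band]
    left <- cb[cb <= midline_col]
    right <- cb[cb > midline_col]
    data.frame(
      band = b,
      side = c("L", "R"),
      extent_px = c(
        if (length(left)) max(midline_col - left) else NA_real_,
        if (length(right)) max(right - midline_col) else NA_real_
      )
    )
  }))
  extents <- as_tibble(extents)

  geom <- structure(
    list(
      mm_per_px = mm_per_px,
      tongue_mask = tongue_mask,
      tip = tip,
      tip_row = tip_row,
      midline_col = midline_col,
      band_mm = band_mm,
      extents = extents,
      circle_centre_px = NULL,
      circle_diameter_mm = circle_diameter_mm
    ),
    class = "fp_geometry"
  )
  if (is.null(circle_centre)) {
    geom$circle_centre_px <- place_circle(geom)
  } else if (!anyNA(circle_centre)) {
    geom$circle_centre_px <- as.numeric(circle_centre)
  }
  geom
}

row_dist_mm <- function(y, tip_row, tip, mm_per_px) {
  if (tip == "bottom") (tip_row - y) * mm_per_px else (y - tip_row) * mm_per_px
}

# Default placement of the counting circle: wholly inside the tongue mask,
# on the left side with the right edge tangent to the midline, as close to
# the tip as possible.  Returns c(x, y) or NULL when it cannot fit.
place_circle <- function(geom) {
  r_px <- (geom$circle_diameter_mm / 2) / geom$mm_per_px
  cx <- geom$midline_col - r_px
  H <- nrow(geom$tongue_mask); W <- ncol(geom$tongue_mask)
  ri <- ceiling(r_px)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, ]
  cxi <- round(cx)
  if (cxi - ri < 1L || cxi + ri > W) return(NULL)
  ys <- if (geom$tip == "bottom") {
    seq(geom$tip_row - ri, ri + 1L)
  } else {
    seq(geom$tip_row + ri, H - ri)
  }
  for (y in ys) {
    px <- cbind(y + off$dy, cxi + off$dx)
    if (all(geom$tongue_mask[px])) return(c(x = cx, y = y))
  }
  NULL
}

#' @export
print.fp_geometry <- function(x, ...) {
  cat(sprintf(
    "<fp_geometry> %d x %d px at %.4g mm/px; tip %s (row %d), midline x = %.1f\n",
    nrow(x$tongue_mask), ncol(x$tongue_mask), x$mm_per_px, x$tip, x$tip_row,
    x$midline_col))
  if (!is.null(x$circle_centre_px)) {
    cat(sprintf("  %g-mm circle at (%.1f, %.1f)\n", x$circle_diameter_mm,
                x$circle_centre_px[1L], x$circle_centre_px[2L]))
  }
  invisible(x)
}

#' Assign papillae to tongue side, band, and grid
#'
#' Assignment is by centroid: side by the centroid column against the
#' midline (exactly on the midline counts as left), band by the centroid's
#' row distance from the tip with half-open 1-cm intervals, and grid by
#' which of the 4 equal-width strips between midline and the band's lateral
#' extreme contains the centroid.  Papillae whose centroid lies beyond the
#' 2-cm analysis depth are flagged (`band = NA`) and excluded from counts.
#'
#' @param papillae Papilla tibble from [extract_papillae()].
#' @param geometry `fp_geometry` from [derive_geometry()].
#' @return The papilla tibble with `side`, `band`, `grid` filled in.
#' @export
assign_papillae <- function(papillae, geometry) {
  stopifnot(inherits(geometry, "fp_geometry"))
  if (nrow(papillae) == 0L) return(papillae)
  d <- row_dist_mm(papillae$y_px, geometry$tip_row, geometry$tip,
                   geometry$mm_per_px)
  band <- ifelse(d < geometry$band_mm[2L], 1L,
                 ifelse(d < geometry$band_mm[3L], 2L, NA_integer_))
  side <- ifelse(papillae$x_px <= geometry$midline_col, "L", "R")

  ext <- geometry$extents
  key <- paste(side, band)
  extent <- ext$extent_px[match(key, paste(ext$side, ext$band))]
  off <- abs(papillae$x_px - geometry$midline_col)
  strip <- pmin(floor(4 * off / extent), 3)
  grid_num <- strip + 1L + (band - 1L) * 4L
  grid <- ifelse(is.na(band), NA_character_, paste0(side, grid_num))

  papillae$side <- ifelse(is.na(band), NA_character_, side)
  papillae$band <- as.integer(band)
  papillae$grid <- grid
  papillae
}

#' Summarise papilla counts, density and spatial distribution
#'
#' Assembles the whole-tongue summary: total count, per-band and per-side
#' counts, the 16 grid counts L1-L8 / R1-R8, the count inside the 6-mm
#' circle, the papilla density (fungiform area over whole tongue area) and
#' the mean circular-equivalent diameter.  Conservation invariants (side,
#' band and grid counts each sum to the total) are asserted on every call.
#'
#' @param papillae Assigned papilla tibble from [assign_papillae()].
#' @param geometry `fp_geometry`.
#' @param map Optional `fp_classmap` for the density denominator; without it
#'   density is `NA`.
#' @return A one-row tibble: `total`, `band1`, `band2`, `left`, `right`,
#'   `L1..L8`, `R1..R8`, `circle_count`, `density`, `mean_equiv_diameter_mm`,
#'   `n_excluded` (papillae beyond the analysis depth).
#' @export
fp_summarize <- function(papillae, geometry, map = NULL) {
  stopifnot(inherits(geometry, "fp_geometry"))
  grids <- c(paste0("L", 1:8), paste0("R", 1:8))
  inb <- papillae[!is.na(papillae$band), , drop = FALSE]
  total <- nrow(inb)

  grid_counts <- setNames(integer(16L), grids)
  tab <- table(factor(inb$grid, levels = grids))
  grid_counts[names(tab)] <- as.integer(tab)

  out <- tibble(
    total = total,
    band1 = sum(inb$band == 1L),
    band2 = sum(inb$band == 2L),
    left = sum(inb$side == "L"),
    right = sum(inb$side == "R"),
    !!!as.list(grid_counts),
    circle_count = if (is.null(geometry$circle_centre_px)) NA_integer_ else {
      count_in_circle(inb, geometry$circle_centre_px,
                      geometry$circle_diameter_mm, geometry$mm_per_px)
    },
    density = if (is.null(map)) NA_real_ else compute_density(inb, map),
    mean_equiv_diameter_mm = if (total > 0L) mean(inb$equiv_diameter_mm)
      else NA_real_,
    n_excluded = nrow(papillae) - total
  )
  stopifnot(
    out$band1 + out$band2 == out$total,
    out$left + out$right == out$total,
    sum(grid_counts) == out$total
  )
  out
}
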