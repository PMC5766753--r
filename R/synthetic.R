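#' Parameters for the synthetic tongue generator
#'
#' Defaults describe a realistic anterior-tongue crop: a 48-mm-wide
#' protruded tongue imaged at 0.05 mm/px with the tip at the image bottom,
#' 204 papillae (the population mean automated count, 148 in the first
#' centimetre + 56 in the second, i.e. a Band-1 fraction of about 0.7),
#' papilla radii uniform in 0.2-0.5 mm, whitish filiform texture covering
#' about 30% of the tongue, a +/-8% linear illumination drift across the
#' image, and additive Gaussian sensor noise in 8-bit RGB units.
#'
#' Class colours are well separated in CIELAB (pairwise distances around 25
#' units or more) so that at zero noise every rendered pixel classifies to
#' its true class under the default illumination drift.
#'
#' @param width_px,height_px Image size in pixels.
#' @param mm_per_px Spatial calibration (default 0.05 mm/px).
#' @param tongue_half_width_mm,tongue_length_mm Superellipse half-axes of
#'   the tongue outline (the crop shows only the anterior part).
#' @param shape_exponent Superellipse exponent; 3 gives a blunt,
#'   tongue-like tip.
#' @param tip_margin_px Rows between the tongue tip and the image bottom.
#' @param base_colour,filiform_colour,papilla_colour,background_colour sRGB
#'   triples in 0-255.
#' @param n_papillae Number of papillae to plant.
#' @param band1_fraction Fraction planted within the first centimetre from
#'   the tip.
#' @param papilla_radius_mm Range `c(min, max)` of papilla radii in mm.
#' @param filiform_coverage Fraction of tongue pixels given filiform
#'   texture.
#' @param filiform_scale_px Spatial scale of the filiform texture blobs.
#' @param illumination_amplitude Relative amplitude of the multiplicative
#'   linear illumination gradient across the image width.
#' @param noise_sigma Additive Gaussian noise SD in RGB units.
#' @param boundary_margin_px Minimum distance of planted centres from any
#'   band/grid/midline boundary, so that detected centroids and planted
#'   centres bin identically.
#' @param min_gap_px Minimum free gap between planted disks (keeps
#'   components separate under 8-connectivity).
#' @param antialias If `TRUE`, blend papilla edge pixels by sub-pixel
#'   coverage.  The default `FALSE` renders hard-edged disks so that the
#'   ground-truth class map describes the noiseless image exactly.
#' @param max_attempts Placement attempts per papilla before a capacity
#'   error is raised.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `fp_synth_params`.
#' @export
synth_params <- function(width_px = 1000L, height_px = 480L,
                         mm_per_px = 0.05,
                         tongue_half_width_mm = 24,
                         tongue_length_mm = 26,
                         shape_exponent = 3,
                         tip_margin_px = 10L,
                         base_colour = c(228, 150, 150),
                         filiform_colour = c(238, 222, 212),
                         papilla_colour = c(190, 85, 105),
                         background_colour = c(40, 40, 45),
                         n_papillae = 204L,
                         band1_fraction = 0.7,
                         papilla_radius_mm = c(0.2, 0.5),
                         filiform_coverage = 0.30,
                         filiform_scale_px = 3L,
                         illumination_amplitude = 0.08,
                         noise_sigma = 0,
                         boundary_margin_px = 2,
                         min_gap_px = 3,
                         antialias = FALSE,
                         max_attempts = 400L,
                         seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$width_px >= 1, p$height_px >= 1, p$mm_per_px > 0,
    p$n_papillae >= 0, p$band1_fraction >= 0, p$band1_fraction <= 1,
    length(p$papilla_radius_mm) == 2L,
    p$papilla_radius_mm[1L] <= p$papilla_radius_mm[2L],
    p$noise_sigma >= 0
  )
  for (nm in c("base_colour", "filiform_colour", "papilla_colour",
               "background_colour")) {
    if (length(p[[nm]]) != 3L || any(p[[nm]] < 0) || any(p[[nm]] > 255)) {
      abort(sprintf("`%s` must be an sRGB triple in [0, 255].", nm),
            class = "fpquant_config_error")
    }
  }
  structure(p, class = "fp_synth_params")
}

# Box blur via a summed-area table (used to give the filiform speckle a
# blob-like spatial scale).
box_blur <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  S <- apply(m, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  S0 <- matrix(0, H + 1L, W + 1L)
  S0[-1L, -1L] <- S
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  r1 <- pmax(i - r, 1L); r2 <- pmin(i + r, H)
  c1 <- pmax(j - r, 1L); c2 <- pmin(j + r, W)
  s <- S0[cbind(r2 + 1L, c2 + 1L)] - S0[cbind(r1, c2 + 1L)] -
    S0[cbind(r2 + 1L, c1)] + S0[cbind(r1, c1)]
  matrix(s / ((r2 - r1 + 1) * (c2 - c1 + 1)), H, W)
}

#' Generate a synthetic tongue image with exact ground truth
#'
#' Renders a superelliptical tongue filled with base tissue, overlays
#' filiform texture, plants non-overlapping fungiform papilla disks with a
#' Band-1/Band-2 gradient, applies a multiplicative linear illumination
#' gradient and additive Gaussian noise, and returns the image together
#' with its exact ground truth (true class map, planted centres and radii,
#' per-grid true counts).
#'
#' Placement is rejection sampling (Poisson-disk style): a candidate centre
#' is accepted only if the whole disk lies inside the tongue with a margin,
#' the centre keeps `boundary_margin_px` clear of every band/grid/midline
#' boundary, and the disk keeps `min_gap_px` clear of every accepted disk.
#' If a papilla cannot be placed within `max_attempts` candidates, a
#' capacity error reports how many were placed.
#'
#' @param params An [synth_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A list of class `fp_synthetic` with elements `image` (H x W x 3
#'   integer sRGB array) and `truth` (class `fp_truth`: `class_map`,
#'   `papillae` tibble with `centre_x`, `centre_y`, `radius_px`,
#'   `radius_mm`, `side`, `band`, `grid`, plus `tongue_mask`, `geometry`,
#'   `params`).
#' @export
generate_tongue <- function(params = synth_params(), seed = NULL) {
  stopifnot(inherits(params, "fp_synth_params"))
  if (is.null(seed)) seed <- params$seed
  withr::with_seed(as.integer(seed), generate_tongue_impl(params))
}

generate_tongue_impl <- function(p) {
  H <- as.integer(p$height_px); W <- as.integer(p$width_px)
  mmpp <- p$mm_per_px
  cx <- (W + 1) / 2
  tip_row <- H - as.integer(p$tip_margin_px)
  a_px <- p$tongue_half_width_mm / mmpp
  b_px <- p$tongue_length_mm / mmpp
  y0 <- tip_row - b_px
  pe <- p$shape_exponent

  ty <- abs((seq_len(H) - y0) / b_px)^pe
  rad <- ifelse(ty <= 1, a_px * (1 - ty)^(1 / pe), -1)
  distx <- abs(seq_len(W) - cx)
  mask <- outer(rad, distx, ">=")

  truth <- matrix(FP_CLASSES[["background"]], H, W)
  truth[mask] <- FP_CLASSES[["base"]]

  # filiform texture: thresholded box-blurred uniform noise
  if (p$filiform_coverage > 0) {
    blur <- box_blur(matrix(runif(H * W), H, W), as.integer(p$filiform_scale_px))
    thr <- quantile(blur[mask], 1 - p$filiform_coverage, names = FALSE)
    truth[mask & blur > thr] <- FP_CLASSES[["filiform"]]
  }

  geometry <- derive_geometry(mask, mmpp, tip = "bottom")
  placed <- place_papillae(p, mask, geometry, tip_row)

  # paint papilla disks (hard edges: pixel centre within radius)
  n <- nrow(placed)
  cov <- vector("list", n)
  for (i in seq_len(n)) {
    px <- disk_pixels(placed$centre_x[i], placed$centre_y[i],
                      placed$radius_px[i], H, W,
                      antialias = isTRUE(p$antialias))
    truth[px$idx[px$alpha >= 0.5]] <- FP_CLASSES[["fungiform"]]
    cov[[i]] <- px
  }

  img <- array(0, dim = c(H, W, 3L))
  npx <- H * W
  for (ch in 1:3) {
    plane <- matrix(p$background_colour[ch], H, W)
    plane[truth == FP_CLASSES[["base"]]] <- p$base_colour[ch]
    plane[truth == FP_CLASSES[["filiform"]]] <- p$filiform_colour[ch]
    plane[truth == FP_CLASSES[["fungiform"]]] <- p$papilla_colour[ch]
    if (isTRUE(p$antialias)) {
      for (i in seq_len(n)) {
        px <- cov[[i]]
        edge <- px$alpha > 0 & px$alpha < 1
        plane[px$idx[edge]] <- px$alpha[edge] * p$papilla_colour[ch] +
          (1 - px$alpha[edge]) * plane[px$idx[edge]]
      }
    }
    img[, , ch] <- plane
  }

  # multiplicative linear illumination gradient across the image width
  if (p$illumination_amplitude != 0) {
    g <- 1 + p$illumination_amplitude * (seq_len(W) - cx) / a_px
    img <- sweep(img, 2L, g, "*")
  }
  if (p$noise_sigma > 0) {
    img <- img + rnorm(length(img), sd = p$noise_sigma)
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  papillae <- assign_papillae(
    tibble(
      id = seq_len(n),
      x_px = placed$centre_x, y_px = placed$centre_y,
      area_px = NA_integer_, area_mm2 = pi * placed$radius_mm^2,
      equiv_diameter_mm = 2 * placed$radius_mm,
      side = NA_character_, band = NA_integer_, grid = NA_character_
    ),
    geometry
  )
  truth_tbl <- tibble(
    centre_x = placed$centre_x, centre_y = placed$centre_y,
    radius_px = placed$radius_px, radius_mm = placed$radius_mm,
    side = papillae$side, band = papillae$band, grid = papillae$grid
  )

  structure(
    list(
      image = img,
      truth = structure(
        list(
          class_map = new_classmap(truth),
          papillae = truth_tbl,
          tongue_mask = mask,
          geometry = geometry,
          params = p
        ),
        class = "fp_truth"
      )
    ),
    class = "fp_synthetic"
  )
}

# pixels of a disk; alpha is 0/1 for hard edges or sub-pixel coverage (4x4
# supersampling) when antialias = TRUE
disk_pixels <- function(x, y, r_px, H, W, antialias = FALSE) {
  rows <- max(1L, floor(y - r_px - 1)):min(H, ceiling(y + r_px + 1))
  cols <- max(1L, floor(x - r_px - 1)):min(W, ceiling(x + r_px + 1))
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  d2 <- (px - x)^2 + (py - y)^2
  if (antialias) {
    sub <- (seq_len(4L) - 2.5) / 4
    alpha <- numeric(length(px))
    for (dy in sub) for (dx in sub) {
      alpha <- alpha + ((px + dx - x)^2 + (py + dy - y)^2 <= r_px^2) / 16
    }
  } else {
    alpha <- as.numeric(d2 <= r_px^2)
  }
  keep <- alpha > 0
  list(idx = (px[keep] - 1L) * H + py[keep], alpha = alpha[keep])
}

place_papillae <- function(p, mask, geometry, tip_row) {
  n <- as.integer(p$n_papillae)
  out <- data.frame(centre_x = numeric(0), centre_y = numeric(0),
                    radius_px = numeric(0), radius_mm = numeric(0))
  if (n == 0L) return(out)
  mmpp <- p$mm_per_px
  H <- nrow(mask); W <- ncol(mask)
  n1 <- round(p$band1_fraction * n)
  bands <- c(rep(1L, n1), rep(2L, n - n1))
  m_px <- p$boundary_margin_px
  m_mm <- m_px * mmpp
  mid <- geometry$midline_col
  ext <- geometry$extents

  xs <- numeric(n); ys <- numeric(n); rs <- numeric(n)
  k <- 0L
  theta <- seq(0, 2 * pi, length.out = 17L)[-17L]
  for (i in seq_len(n)) {
    lo <- geometry$band_mm[bands[i]]
    hi <- geometry$band_mm[bands[i] + 1L]
    ok <- FALSE
    for (att in seq_len(p$max_attempts)) {
      r_mm <- runif(1L, p$papilla_radius_mm[1L], p$papilla_radius_mm[2L])
      r_px <- r_mm / mmpp
      d <- runif(1L, lo + m_mm, hi - m_mm)
      if (min(abs(d - geometry$band_mm)) < m_mm) next
      y <- tip_row - d / mmpp
      row <- round(y)
      if (row - r_px - 2 < 1 || row + r_px + 2 > H) next
      half <- max(0, sum(mask[row, ]) / 2 - r_px - 2)
      if (half <= 0) next
      x <- runif(1L, mid - half, mid + half)
      # keep the centre clear of midline and strip boundaries
      side <- if (x <= mid) "L" else "R"
      extent <- ext$extent_px[ext$side == side & ext$band == bands[i]]
      if (is.na(extent) || extent <= 0) next
      off <- abs(x - mid)
      edges <- extent * (0:4) / 4
      if (min(abs(off - edges)) < m_px) next
      # whole disk inside the mask with a 1-px clearance
      bx <- round(x + (r_px + 1.5) * cos(theta))
      by <- round(y + (r_px + 1.5) * sin(theta))
      if (any(bx < 1L | bx > W | by < 1L | by > H)) next
      if (!all(mask[cbind(by, bx)])) next
      # no overlap with accepted disks
      if (k > 0L) {
        d2 <- (xs[1:k] - x)^2 + (ys[1:k] - y)^2
        if (any(d2 < (rs[1:k] + r_px + p$min_gap_px)^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(
        "Could not place papilla %d of %d within %d attempts (%d placed).",
        i, n, p$max_attempts, k),
        class = "fpquant_capacity_error")
    }
    k <- k + 1L
    xs[k] <- x; ys[k] <- y; rs[k] <- r_px
  }
  data.frame(centre_x = xs, centre_y = ys, radius_px = rs,
             radius_mm = rs * mmpp)
}

#' @export
print.fp_synthetic <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fp_synthetic> %d x %d px, %d planted papillae (seed %s)\n",
              d[1L], d[2L], nrow(x$truth$papillae),
              format(x$truth$params$seed)))
  invisible(x)
}

#' Reference counts from planted ground truth
#'
#' Bins the planted papilla centres into side/band/grid exactly as
#' [assign_papillae()] bins detected centroids, and assembles the same
#' summary row.  This plays the role of the manual-count reference arm when
#' validating the automated pipeline: the truth counts are exact by
#' construction.
#'
#' @param truth The `truth` element of [generate_tongue()] output.
#' @param geometry Optional `fp_geometry`; defaults to the geometry the
#'   generator derived from its own mask.
#' @return A one-row summary tibble as from [fp_summarize()]; `density` is
#'   the planted fungiform pixel fraction of the tongue.
#' @export
truth_counts <- function(truth, geometry = NULL) {
  stopifnot(inherits(truth, "fp_truth"))
  if (is.null(geometry)) geometry <- truth$geometry
  tp <- truth$papillae
  papillae <- assign_papillae(
    tibble(
      id = seq_len(nrow(tp)),
      x_px = tp$centre_x, y_px = tp$centre_y,
      area_px = NA_integer_, area_mm2 = pi * tp$radius_mm^2,
      equiv_diameter_mm = 2 * tp$radius_mm,
      side = NA_character_, band = NA_integer_, grid = NA_character_
    ),
    geometry
  )
  out <- fp_summarize(papillae, geometry, map = NULL)
  cm <- unclass(truth$class_map)
  out$density <- sum(cm == FP_CLASSES[["fungiform"]]) /
    sum(cm != FP_CLASSES[["background"]])
  out
}

#' Learn class markers from ground-truth patches
#'
#' Uses the true class map of a synthetic tongue as mask ROIs and learns
#' the mean CIELAB marker of every class present, including background.
#' This is the idealised stand-in for manual ROI selection when validating
#' the pipeline end to end.
#'
#' @param image An RGB image array (typically `x$image` of
#'   [generate_tongue()] output).
#' @param truth The matching `fp_truth`.
#' @return A marker tibble as from [learn_markers()].
#' @export
markers_from_truth <- function(image, truth) {
  stopifnot(inherits(truth, "fp_truth"))
  lab <- rgb_to_lab(image)
  cm <- unclass(truth$class_map)
  present <- FP_CLASS_ORDER[class_code(FP_CLASS_ORDER) %in% unique(as.vector(cm))]
  rois <- lapply(present, function(cl) roi_mask(cl, cm == class_code(cl)))
  learn_markers(lab, rois, require = intersect(FP_TONGUE_CLASSES, present))
}
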