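#' Quantify fungiform papillae on a tongue image
#'
#' Runs the full analysis pipeline: sRGB to CIELAB conversion, marker
#' learning from training ROIs (unless markers are supplied), nearest-marker
#' segmentation, optional rectangular re-analysis with local markers,
#' papilla extraction and measurement, geometry derivation, side/band/grid
#' assignment and the whole-tongue summary.  The run is deterministic given
#' its inputs.
#'
#' @param image RGB array (`H x W x 3`, 0-255) or a path readable by
#'   [read_tongue_image()].
#' @param mm_per_px Spatial calibration, mm per pixel.
#' @param rois List of training ROIs ([roi_rect()], [roi_polygon()],
#'   [roi_mask()]) covering at least the three tongue classes; a
#'   `background` ROI enables background rejection.  Ignored when `markers`
#'   is given.
#' @param markers Optional ready-made marker tibble (columns `class`, `L`,
#'   `a`, `b`).
#' @param analysis_mask Optional logical matrix restricting the analysis;
#'   pixels outside are background.
#' @param reanalysis Optional list of re-analysis specs, each a list with
#'   `rect = c(xmin, xmax, ymin, ymax)` and `rois` (or `markers`) local to
#'   that rectangle.
#' @param min_area_mm2 Minimum papilla area retained (default 0.01).
#' @param connectivity 4 or 8 (default 8).
#' @param channels `"Lab"` or `"ab"` colour distance (default full 3-D).
#' @param tip,midline_col,circle_centre,circle_diameter_mm Geometry
#'   options, see [derive_geometry()].
#' @param boundary Attach papilla boundary contours (default `TRUE`).
#' @return An `fp_quant` object: `markers`, `class_map`, `papillae`
#'   (assigned tibble), `geometry`, `summary` (one-row tibble),
#'   `mm_per_px`, `options`.
#' @examples
#' syn <- generate_tongue(synth_params(n_papillae = 40, seed = 7))
#' q <- fp_quantify(syn$image, mm_per_px = 0.05,
#'                  markers = markers_from_truth(syn$image, syn$truth))
#' q$summary$total
#' @export
fp_quantify <- function(image, mm_per_px, rois = NULL, markers = NULL,
                        analysis_mask = NULL, reanalysis = NULL,
                        min_area_mm2 = 0.01, connectivity = 8L,
                        channels = c("Lab", "ab"),
                        tip = c("bottom", "top"), midline_col = NULL,
                        circle_centre = NULL, circle_diameter_mm = 6,
                        boundary = TRUE) {
  channels <- match.arg(channels)
  tip <- match.arg(tip)
  if (is.character(image)) image <- read_tongue_image(image)
  stopifnot(is.array(image), length(dim(image)) == 3L)

  lab <- rgb_to_lab(image)
  if (is.null(markers)) {
    if (is.null(rois)) {
      abort("Supply `rois` or `markers`.", class = "fpquant_config_error")
    }
    markers <- learn_markers(lab, rois)
  } else {
    markers <- check_markers(markers)
  }

  map <- classify_pixels(lab, markers, analysis_mask = analysis_mask,
                         channels = channels)
  if (!is.null(reanalysis)) {
    for (spec in reanalysis) {
      map <- reanalyze_region(lab, map, rect = spec$rect,
                              local_rois = spec$rois,
                              local_markers = spec$markers,
                              global_markers = markers,
                              channels = channels)
    }
  }

  tongue_mask <- unclass(map) != FP_CLASSES[["background"]]
  geometry <- derive_geometry(tongue_mask, mm_per_px, tip = tip,
                              midline_col = midline_col,
                              circle_centre = circle_centre,
                              circle_diameter_mm = circle_diameter_mm)
  papillae <- extract_papillae(map, mm_per_px, min_area_mm2 = min_area_mm2,
                               connectivity = connectivity,
                               boundary = boundary)
  papillae <- assign_papillae(papillae, geometry)
  summary <- fp_summarize(papillae, geometry, map = map)

  structure(
    list(markers = markers, class_map = map, papillae = papillae,
         geometry = geometry, summary = summary, mm_per_px = mm_per_px,
         options = list(min_area_mm2 = min_area_mm2,
                        connectivity = connectivity, channels = channels)),
    class = "fp_quant"
  )
}

#' @export
print.fp_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<fp_quant> %d papillae on %.1f x %.1f mm of tongue\n",
           "  Band 1: %d   Band 2: %d   Left: %d   Right: %d\n",
           "  density %.4f, mean equivalent diameter %.3f mm, circle count %s\n"),
    s$total, nrow(x$class_map) * x$mm_per_px, ncol(x$class_map) * x$mm_per_px,
    s$band1, s$band2, s$left, s$right, s$density, s$mean_equiv_diameter_mm,
    format(s$circle_count)))
  invisible(x)
}

#' @export
tidy.fp_quant <- function(x, ...) {
  dplyr::select(x$papillae, -dplyr::any_of("boundary"))
}

#' @export
glance.fp_quant <- function(x, ...) {
  x$summary
}

#' Run the pipeline from a configuration and write artifacts
#'
#' Executes [fp_quantify()] as described by a validated configuration and
#' writes the standard artifact set to the output directory: the label
#' mask (`label_mask.png`), a QC overlay (`overlay.png`), the per-papilla
#' table (`papillae.csv`), the summary (`summary.json`), the geometry echo
#' (`geometry.json`), the configuration echo (`config_echo.json`) and a
#' run log (`run.log`).  Re-running with an identical configuration
#' reproduces identical CSV/JSON outputs.
#'
#' @param cfg An `fp_config` from [read_config()] / [validate_config()], or
#'   a path to a config file.
#' @param output_dir Overrides `cfg$output_dir`.
#' @return The `fp_quant` object, invisibly; artifacts on disk.
#' @export
run_quantify <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "fp_config"))
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("No `output_dir` given.", class = "fpquant_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log("ERROR in stage '%s': %s", stage, conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "fpquant_stage_error", parent = e)
    })
  }

  image <- run_stage("read_image", read_tongue_image(cfg$image))
  log("read image %s (%d x %d)", cfg$image, dim(image)[1L], dim(image)[2L])

  rois <- NULL
  markers <- NULL
  if (!is.null(cfg$markers)) {
    markers <- dplyr::bind_rows(lapply(cfg$markers, as_tibble))
  } else {
    rois <- run_stage("rois",
                      config_rois(cfg$rois, dim(image)[1:2], cfg$config_dir))
  }
  analysis_mask <- if (!is.null(cfg$background_mask)) {
    run_stage("background_mask", read_mask_png(cfg$background_mask))
  }
  reanalysis <- if (!is.null(cfg$reanalysis)) {
    lapply(cfg$reanalysis, function(sp) {
      list(rect = unlist(sp$rect),
           rois = if (!is.null(sp$rois)) {
             config_rois(sp$rois, dim(image)[1:2], cfg$config_dir)
           },
           markers = if (!is.null(sp$markers)) {
             dplyr::bind_rows(lapply(sp$markers, as_tibble))
           })
    })
  }

  q <- run_stage("quantify", fp_quantify(
    image, mm_per_px = cfg$mm_per_px, rois = rois, markers = markers,
    analysis_mask = analysis_mask, reanalysis = reanalysis,
    min_area_mm2 = cfg$min_area_mm2,
    connectivity = cfg$connectivity,
    tip = cfg$tip,
    midline_col = cfg$midline_col,
    circle_centre = unlist(cfg$circle_centre),
    circle_diameter_mm = cfg$circle_diameter_mm
  ))
  log("quantified: %d papillae, density %.5f", q$summary$total,
      q$summary$density)

  run_stage("write_outputs", {
    write_class_map(q$class_map, file.path(out_dir, "label_mask.png"))
    write_overlay_png(image, q$class_map, file.path(out_dir, "overlay.png"),
                      geometry = q$geometry)
    readr::write_csv(tidy(q), file.path(out_dir, "papillae.csv"))
    jsonlite::write_json(as.list(q$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(geometry_echo(q$geometry),
                         file.path(out_dir, "geometry.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_echo <- cfg
    cfg_echo$config_dir <- NULL
    jsonlite::write_json(unclass(cfg_echo),
                         file.path(out_dir, "config_echo.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  log("artifacts written to %s", out_dir)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(q)
}

geometry_echo <- function(g) {
  list(
    mm_per_px = g$mm_per_px,
    tip = g$tip,
    tip_row = g$tip_row,
    midline_col = g$midline_col,
    band_mm = g$band_mm,
    extents = g$extents,
    circle_centre_px = g$circle_centre_px,
    circle_diameter_mm = g$circle_diameter_mm
  )
}

#' Method-agreement report for paired count tables
#'
#' Given a tidy table with one row per subject and one column per
#' measurement arm (methods, assessors, or repeated images), computes
#' Bland-Altman agreement and Spearman correlation for every requested
#' column pair, and the two-way random absolute-agreement ICC across all
#' arms.
#'
#' @param data Data frame, one row per subject.
#' @param columns Character vector of arm columns (default: all numeric
#'   columns).
#' @param pairs Optional list of `c(x, y)` column pairs (default: all
#'   unordered pairs of `columns`).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @return An `fp_validation` object: `icc` (class `fp_icc`), `pairs`
#'   tibble (per pair: mean_diff, sd_diff, loa_low, loa_high, spearman_r,
#'   spearman_p), `n`.
#' @export
fp_validate <- function(data, columns = NULL, pairs = NULL,
                        loa_multiplier = 1.96) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(columns) < 2L) {
    abort("Need at least two measurement columns.",
          class = "fpquant_config_error")
  }
  if (nrow(data) < 3L) {
    abort("At least 3 subjects are required.",
          class = "fpquant_insufficient_data_error")
  }
  if (is.null(pairs)) {
    pairs <- utils::combn(columns, 2L, simplify = FALSE)
  }
  icc <- icc_twoway_random(as.matrix(data[columns]))
  rows <- lapply(pairs, function(pr) {
    ba <- bland_altman(data, pr[1L], pr[2L], loa_multiplier = loa_multiplier)
    sp <- spearman_cor(data, pr[1L], pr[2L])
    tibble(x = pr[1L], y = pr[2L],
           mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
           loa_low = ba$loa_low, loa_high = ba$loa_high,
           ba_p = ba$p_value,
           spearman_r = sp$estimate, spearman_p = sp$p_value)
  })
  structure(
    list(icc = icc, pairs = dplyr::bind_rows(rows), n = nrow(data)),
    class = "fp_validation"
  )
}

#' @export
print.fp_validation <- function(x, ...) {
  cat(sprintf("<fp_validation> %d subjects, ICC single %.3f / average %.3f\n",
              x$n, x$icc$icc_single, x$icc$icc_average))
  print(as.data.frame(x$pairs), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.fp_validation <- function(x, ...) {
  x$pairs
}

#' @export
glance.fp_validation <- function(x, ...) {
  tibble(icc_single = x$icc$icc_single, icc_average = x$icc$icc_average,
         n_pairs = nrow(x$pairs), nobs = x$n)
}
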