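#' Read a tongue photograph
#'
#' Reads an 8-bit RGB image from PNG or TIFF into an `H x W x 3` integer
#' array with values in 0-255.  Grayscale images are replicated to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer `H x W x 3` array.
#' @export
read_tongue_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path),
          class = "fpquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = abort("JPEG input is not supported; convert to PNG or TIFF.",
                 class = "fpquant_io_error"),
    abort(sprintf("Unsupported image format '.%s'.", ext),
          class = "fpquant_io_error")
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3L] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    abort("Image must have 1, 3 or 4 channels.", class = "fpquant_io_error")
  }
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an RGB image array to PNG
#'
#' @param img `H x W x 3` array with values in 0-255.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}

#' Write / read a class map as an indexed PNG
#'
#' The label image is stored as an 8-bit grayscale PNG with pixel values
#' 0 = background, 1 = fungiform, 2 = filiform, 3 = base (visually near
#' black; intended for programmatic use, see [write_overlay_png()] for QC).
#'
#' @param map `fp_classmap`.
#' @param path PNG path.
#' @export
write_class_map <- function(map, path) {
  png::writePNG(unclass(map) / 255, target = path)
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  new_classmap(matrix(as.integer(round(m * 255)), nrow = nrow(m)))
}

#' Read a tongue mask from a single-channel PNG
#'
#' Pixels with value 0 are background; 255 (or anything above half range)
#' is tongue.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Write a colour QC overlay
#'
#' Blends the original image with the class colours (fungiform red,
#' filiform white, base green tint) and draws the analysis geometry
#' (midline, band edges, counting circle) when a geometry is supplied.
#'
#' @param image RGB array the classes were computed from.
#' @param map `fp_classmap`.
#' @param path Output PNG path.
#' @param geometry Optional `fp_geometry` to draw.
#' @param alpha Blend weight of the class colour (default 0.45).
#' @export
write_overlay_png <- function(image, map, path, geometry = NULL,
                              alpha = 0.45) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  overlay_cols <- list(fungiform = c(255, 40, 40),
                       filiform = c(250, 250, 250),
                       base = c(80, 200, 120))
  out <- array(as.numeric(image), dim = dim(image))
  m <- unclass(map)
  for (cl in names(overlay_cols)) {
    sel <- m == class_code(cl)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * overlay_cols[[cl]][ch]
      out[, , ch] <- plane
    }
  }
  if (!is.null(geometry)) {
    draw <- function(rows, cols, col_rgb) {
      rows <- rows[rows >= 1 & rows <= H]
      cols <- cols[cols >= 1 & cols <= W]
      for (ch in 1:3) out[rows, cols, ch] <<- col_rgb[ch]
    }
    draw(seq_len(H), round(geometry$midline_col), c(30, 30, 220))
    for (bm in geometry$band_mm) {
      r <- if (geometry$tip == "bottom") {
        geometry$tip_row - round(bm / geometry$mm_per_px)
      } else {
        geometry$tip_row + round(bm / geometry$mm_per_px)
      }
      draw(r, seq_len(W), c(30, 30, 220))
    }
    if (!is.null(geometry$circle_centre_px)) {
      th <- seq(0, 2 * pi, length.out = 360L)
      r_px <- geometry$circle_diameter_mm / 2 / geometry$mm_per_px
      cxp <- round(geometry$circle_centre_px[1L] + r_px * cos(th))
      cyp <- round(geometry$circle_centre_px[2L] + r_px * sin(th))
      ok <- cxp >= 1 & cxp <= W & cyp >= 1 & cyp <= H
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[cbind(cyp[ok], cxp[ok])] <- c(255, 220, 0)[ch]
        out[, , ch] <- plane
      }
    }
  }
  write_image_png(out, path)
}

#' Read and validate an analysis configuration
#'
#' Configurations are YAML or JSON.  Required fields: `image` (path),
#' `mm_per_px` (> 0), and `rois` (a list of entries with `class` and either
#' `rect: [xmin, xmax, ymin, ymax]`, `polygon: {x: [...], y: [...]}` or
#' `mask: path.png`) unless ready-made `markers` (list of `{class, L, a,
#' b}`) are given.  Optional: `background_mask` (PNG path),
#' `reanalysis` (list of `{rect, rois}`), `min_area_mm2`, `connectivity`,
#' `tip`, `midline_col`, `circle_centre`, `circle_diameter_mm`,
#' `output_dir`, `seed`.  The schema is validated before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration.
#' @return A validated config list of class `fp_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "fpquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("Config must be YAML or JSON.", class = "fpquant_io_error")
  )
  cfg$config_dir <- dirname(normalizePath(path))
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A configuration list (as from [read_config()]).
#' @export
validate_config <- function(cfg) {
  req <- function(cond, msg) {
    if (!isTRUE(cond)) abort(msg, class = "fpquant_config_error")
  }
  req(!is.null(cfg$image), "Config field `image` is required.")
  pth <- resolve_path(cfg$image, cfg$config_dir)
  req(file.exists(pth), sprintf("Image file not found: %s", pth))
  cfg$image <- pth
  req(is.numeric(cfg$mm_per_px) && cfg$mm_per_px > 0,
      "Config field `mm_per_px` must be a positive number.")
  req(!is.null(cfg$rois) || !is.null(cfg$markers),
      "Config must define `rois` or `markers`.")
  if (!is.null(cfg$rois)) {
    classes <- vapply(cfg$rois, function(r) tolower(r$class %||% ""),
                      character(1))
    missing <- setdiff(FP_TONGUE_CLASSES, classes)
    req(length(missing) == 0L,
        paste0("Config `rois` miss tongue class(es): ",
               paste(missing, collapse = ", "), "."))
  }
  if (!is.null(cfg$background_mask)) {
    cfg$background_mask <- resolve_path(cfg$background_mask, cfg$config_dir)
    req(file.exists(cfg$background_mask),
        sprintf("Mask file not found: %s", cfg$background_mask))
  }
  cfg$min_area_mm2 <- cfg$min_area_mm2 %||% 0.01
  cfg$connectivity <- cfg$connectivity %||% 8L
  cfg$tip <- cfg$tip %||% "bottom"
  cfg$circle_diameter_mm <- cfg$circle_diameter_mm %||% 6
  structure(cfg, class = c("fp_config", "list"))
}

resolve_path <- function(p, base) {
  if (is.null(base) || file.exists(p) || grepl("^(/|~)", p)) return(p)
  file.path(base, p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_rois <- function(roi_specs, dim_hw, base_dir = NULL) {
  lapply(roi_specs, function(r) {
    if (!is.null(r$rect)) {
      roi_rect(r$class, r$rect[[1L]], r$rect[[2L]], r$rect[[3L]], r$rect[[4L]])
    } else if (!is.null(r$polygon)) {
      roi_polygon(r$class, unlist(r$polygon$x), unlist(r$polygon$y))
    } else if (!is.null(r$mask)) {
      roi_mask(r$class, read_mask_png(resolve_path(r$mask, base_dir)))
    } else {
      abort("Each ROI needs `rect`, `polygon` or `mask`.",
            class = "fpquant_config_error")
    }
  })
}

#' Convert rectangle annotations from an external tool to ROI specs
#'
#' Takes a data frame with columns `class`, `xmin`, `xmax`, `ymin`, `ymax`
#' (as exported from any annotation tool's CSV) and returns the
#' corresponding list of rectangle ROIs.
#'
#' @param df Data frame of rectangle annotations.
#' @return List of `fp_roi` objects.
#' @export
rois_from_table <- function(df) {
  stopifnot(all(c("class", "xmin", "xmax", "ymin", "ymax") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    roi_rect(df$class[i], df$xmin[i], df$xmax[i], df$ymin[i], df$ymax[i])
  })
}
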