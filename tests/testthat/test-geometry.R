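test_that("bands convert mm to rows from the tip", {
  mask <- matrix(TRUE, 200, 50)
  suppressWarnings(  # mask is exactly 20 mm deep, a borderline truncation
    g <- derive_geometry(mask, mm_per_px = 0.1, circle_centre = NA))
  expect_equal(g$tip_row, 200L)
  d <- fpquant:::row_dist_mm(1:200, g$tip_row, g$tip, g$mm_per_px)
  # Band 1 = [0, 10) mm: the bottom 100 rows; Band 2 the 100 above
  expect_equal(which(d >= 0 & d < 10), 101:200)
  expect_equal(which(d >= 10 & d < 20), 1:100)
})

test_that("a symmetric mask puts the midline at the central column", {
  mask <- matrix(FALSE, 60, 81)
  mask[10:60, 11:71] <- TRUE
  g <- derive_geometry(mask, mm_per_px = 0.5, circle_centre = NA)
  expect_equal(g$midline_col, 41)
})

test_that("degenerate inputs are rejected", {
  expect_error(derive_geometry(matrix(FALSE, 5, 5), 0.1),
               class = "fpquant_degenerate_error")
  expect_error(derive_geometry(matrix(TRUE, 5, 5), -1),
               class = "fpquant_domain_error")
  expect_warning(derive_geometry(matrix(TRUE, 50, 50), 0.1,
                                 circle_centre = NA),
                 "truncated")
})

test_that("assignment follows the centroid rules", {
  mask <- matrix(TRUE, 400, 200)   # 20 mm x 10 mm at 0.05 mm/px
  suppressWarnings(
    g <- derive_geometry(mask, mm_per_px = 0.05, circle_centre = NA))
  pap <- tibble::tibble(
    id = 1:4,
    x_px = c(60, 60, 100.5, 150),
    y_px = c(400 - 3 / 0.05,   # 3 mm from tip, left, innermost quarter?
             400 - 10 / 0.05,  # exactly on the 10-mm edge
             400 - 25 / 0.05,  # beyond the 20-mm analysis depth
             400 - 1 / 0.05),
    area_px = 10L, area_mm2 = 10 * 0.05^2,
    equiv_diameter_mm = 1, side = NA_character_, band = NA_integer_,
    grid = NA_character_)
  out <- assign_papillae(pap, g)
  # x = 60 is 40.5 px left of the midline (100.5); left extent is 99.5 px,
  # so 40.5/99.5 falls in the second quarter -> L2
  expect_equal(out$side[1], "L")
  expect_equal(out$band[1], 1L)
  expect_equal(out$grid[1], "L2")
  # half-open band intervals: exactly 10 mm -> Band 2 (grid offset +4)
  expect_equal(out$band[2], 2L)
  expect_equal(out$grid[2], "L6")
  # beyond 20 mm: flagged out of range
  expect_true(is.na(out$band[3]))
  expect_true(is.na(out$grid[3]))
  # exactly on the midline counts as left
  on_mid <- assign_papillae(dplyr::mutate(pap[4, ], x_px = 100.5), g)
  expect_equal(on_mid$side, "L")
  expect_equal(out$side[4], "R")
})

test_that("an innermost-strip centroid near the tip lands in L1", {
  mask <- matrix(TRUE, 400, 200)
  suppressWarnings(
    g <- derive_geometry(mask, mm_per_px = 0.05, circle_centre = NA))
  pap <- tibble::tibble(id = 1L, x_px = 95, y_px = 400 - 3 / 0.05,
                        area_px = 10L, area_mm2 = 0.025,
                        equiv_diameter_mm = 1, side = NA_character_,
                        band = NA_integer_, grid = NA_character_)
  expect_equal(assign_papillae(pap, g)$grid, "L1")
})

test_that("grid assignment equals a brute-force point-in-region test", {
  syn <- generate_tongue(small_params(seed = 71, n_papillae = 35L))
  g <- syn$truth$geometry
  pap <- assign_papillae(
    tibble::tibble(id = seq_len(35), x_px = syn$truth$papillae$centre_x,
                   y_px = syn$truth$papillae$centre_y, area_px = 1L,
                   area_mm2 = 1, equiv_diameter_mm = 1,
                   side = NA_character_, band = NA_integer_,
                   grid = NA_character_), g)
  for (i in seq_len(nrow(pap))) {
    x <- pap$x_px[i]; y <- pap$y_px[i]
    d <- fpquant:::row_dist_mm(y, g$tip_row, g$tip, g$mm_per_px)
    band <- if (d < 10) 1L else if (d < 20) 2L else NA_integer_
    side <- if (x <= g$midline_col) "L" else "R"
    ext <- g$extents$extent_px[g$extents$side == side &
                                 g$extents$band == band]
    strip <- min(floor(4 * abs(x - g$midline_col) / ext), 3)
    expect_equal(pap$grid[i], paste0(side, strip + 1L + (band - 1L) * 4L))
  }
})

test_that("every tongue pixel within 2 cm belongs to exactly one grid cell", {
  syn <- generate_tongue(small_params(seed = 72, n_papillae = 0L))
  g <- syn$truth$geometry
  mask <- syn$truth$tongue_mask
  idx <- which(mask)
  y <- ((idx - 1L) %% nrow(mask)) + 1L
  x <- ((idx - 1L) %/% nrow(mask)) + 1L
  d <- fpquant:::row_dist_mm(y, g$tip_row, g$tip, g$mm_per_px)
  in_depth <- d >= 0 & d < 20
  pix <- tibble::tibble(id = seq_along(idx), x_px = as.numeric(x),
                        y_px = as.numeric(y), area_px = 1L, area_mm2 = 1,
                        equiv_diameter_mm = 1, side = NA_character_,
                        band = NA_integer_, grid = NA_character_)
  out <- assign_papillae(pix, g)
  expect_true(all(!is.na(out$grid[in_depth])))
  expect_true(all(out$grid[in_depth] %in% grid_cols))
  expect_true(all(is.na(out$grid[!in_depth])))
})

test_that("summary counts conserve and a one-per-grid layout is exact", {
  mask <- matrix(TRUE, 400, 200)
  suppressWarnings(
    g <- derive_geometry(mask, mm_per_px = 0.05, circle_centre = NA))
  # one papilla per grid: strip centres at offsets (k+0.5)/4 * extent
  mid <- g$midline_col
  rows <- c(400 - 5 / 0.05, 400 - 15 / 0.05)  # band centres
  pap <- list()
  for (band in 1:2) for (side in c("L", "R")) for (k in 0:3) {
    ext <- g$extents$extent_px[g$extents$side == side &
                                 g$extents$band == band]
    off <- (k + 0.5) / 4 * ext
    pap[[length(pap) + 1L]] <- tibble::tibble(
      x_px = if (side == "L") mid - off else mid + off,
      y_px = rows[band])
  }
  pap <- dplyr::bind_rows(pap)
  pap <- dplyr::mutate(pap, id = dplyr::row_number(), area_px = 4L,
                       area_mm2 = 0.01, equiv_diameter_mm = 0.1,
                       side = NA_character_, band = NA_integer_,
                       grid = NA_character_)
  s <- fp_summarize(assign_papillae(pap, g), g)
  expect_equal(s$total, 16L)
  expect_equal(unname(unlist(s[grid_cols])), rep(1L, 16))
  expect_equal(c(s$band1, s$band2, s$left, s$right), c(8L, 8L, 8L, 8L))

  # zero papillae: all-zero summary
  empty <- fp_summarize(pap[0, ], g)
  expect_equal(empty$total, 0L)
  expect_equal(sum(unlist(empty[grid_cols])), 0L)
})

test_that("the counting circle sits inside the tongue, tangent to the midline, near the tip", {
  syn <- generate_tongue(small_params(seed = 73, n_papillae = 0L))
  g <- syn$truth$geometry
  expect_false(is.null(g$circle_centre_px))
  r_px <- g$circle_diameter_mm / 2 / g$mm_per_px
  expect_equal(g$circle_centre_px[["x"]], g$midline_col - r_px)
  # wholly inside the mask
  th <- seq(0, 2 * pi, length.out = 90)
  bx <- round(g$circle_centre_px[["x"]] + (r_px - 1) * cos(th))
  by <- round(g$circle_centre_px[["y"]] + (r_px - 1) * sin(th))
  expect_true(all(syn$truth$tongue_mask[cbind(by, bx)]))
  # close to the tip: moving the circle 3 px tipward must not fit
  shift <- 3
  by2 <- round(g$circle_centre_px[["y"]] + shift + r_px * sin(th))
  expect_false(all(syn$truth$tongue_mask[cbind(pmin(by2, nrow(syn$truth$tongue_mask)), bx)]))
})

test_that("mirroring the image swaps left/right grid counts exactly", {
  syn <- generate_tongue(small_params(seed = 74, n_papillae = 30L))
  mk <- markers_from_truth(syn$image, syn$truth)
  q <- fp_quantify(syn$image, 0.05, markers = mk, boundary = FALSE)
  mirrored <- syn$image[, dim(syn$image)[2L]:1L, , drop = FALSE]
  qm <- fp_quantify(mirrored, 0.05, markers = mk, boundary = FALSE)
  s <- q$summary; sm <- qm$summary
  expect_equal(sm$total, s$total)
  expect_equal(sm$left, s$right)
  expect_equal(sm$right, s$left)
  for (k in 1:8) {
    expect_equal(sm[[paste0("L", k)]], s[[paste0("R", k)]])
    expect_equal(sm[[paste0("R", k)]], s[[paste0("L", k)]])
  }
  expect_equal(c(sm$band1, sm$band2), c(s$band1, s$band2))
})
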