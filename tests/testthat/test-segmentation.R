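lab_img <- function(m) {
  # helper: build an H x W x 3 Lab array from an H x W x 3 list of planes
  array(m, dim = dim(m))
}

uniform_lab <- function(H, W, colour) {
  array(rep(colour, each = H * W), dim = c(H, W, 3))
}

test_that("markers are ROI colour means, pooled across ROIs of a class", {
  img <- uniform_lab(6, 6, c(60, 25, 15))
  mk <- learn_markers(img, list(roi_rect("fungiform", 1, 3, 1, 3),
                                roi_rect("filiform", 4, 6, 1, 3),
                                roi_rect("base", 1, 3, 4, 6)))
  expect_equal(mk$class, c("fungiform", "filiform", "base"))
  expect_equal(mk$L, rep(60, 3))
  expect_equal(mk$n_pixels, rep(9L, 3))

  # two-pixel ROI: arithmetic mean
  img2 <- uniform_lab(1, 2, c(0, 0, 0))
  img2[1, 1, ] <- c(50, 10, 10)
  img2[1, 2, ] <- c(60, 20, 30)
  mk2 <- learn_markers(img2, list(roi_rect("fungiform", 1, 2, 1, 1)),
                       require = "fungiform")
  expect_equal(unlist(mk2[1, c("L", "a", "b")], use.names = FALSE),
               c(55, 15, 20))

  # pooling two ROIs equals the mean over the union of their pixels
  img3 <- uniform_lab(2, 2, c(0, 0, 0))
  img3[1, 1, 1] <- 10; img3[2, 2, 1] <- 30
  mk3 <- learn_markers(img3, list(roi_rect("base", 1, 1, 1, 1),
                                  roi_rect("base", 2, 2, 2, 2)),
                       require = "base")
  expect_equal(mk3$L, 20)
  expect_equal(mk3$n_pixels, 2L)
})

test_that("a class without ROI pixels raises a missing-class error", {
  img <- uniform_lab(4, 4, c(50, 0, 0))
  expect_error(
    learn_markers(img, list(roi_rect("fungiform", 1, 2, 1, 2))),
    class = "fpquant_missing_class_error")
})

test_that("markers learned on a noiseless synthetic base patch hit the true colour", {
  syn <- generate_tongue(small_params(n_papillae = 0L, filiform_coverage = 0,
                                      seed = 21))
  lab <- rgb_to_lab(syn$image)
  # a patch near the image centre column, where the illumination gradient
  # crosses 1, inside the tongue
  W <- ncol(syn$truth$tongue_mask)
  patch <- roi_rect("base", round(W / 2) - 5, round(W / 2) + 5, 300, 320)
  mk <- learn_markers(lab, list(patch), require = "base")
  true_lab <- rgb_to_lab(matrix(syn$truth$params$base_colour, ncol = 3))
  expect_lt(sqrt(sum((unlist(mk[1, c("L", "a", "b")]) - true_lab)^2)), 1)
})

test_that("classification assigns zero-distance pixels and breaks ties by class order", {
  img <- uniform_lab(1, 2, c(0, 0, 0))
  img[1, 1, ] <- c(40, 10, 10)   # exactly the fungiform marker
  img[1, 2, ] <- c(50, 10, 10)   # equidistant between the two markers
  mk <- tibble::tibble(class = c("base", "fungiform"),
                       L = c(60, 40), a = c(10, 10), b = c(10, 10))
  map <- classify_pixels(img, mk)
  expect_identical(map[1, 1], 1L)
  expect_identical(map[1, 2], 1L)  # tie goes to fungiform < base
})

test_that("classification equals brute-force nearest-marker search", {
  set.seed(31)
  for (rep in 1:10) {
    lab <- array(runif(32 * 32 * 3, -20, 90), dim = c(32, 32, 3))
    mk <- tibble::tibble(
      class = sample(c("fungiform", "filiform", "base")),
      L = runif(3, 0, 100), a = runif(3, -40, 60), b = runif(3, -40, 60))
    expect_identical(unclass(classify_pixels(lab, mk)),
                     brute_force_classify(lab, mk))
  }
})

test_that("marker order does not change the label map", {
  set.seed(32)
  lab <- array(runif(20 * 20 * 3, 0, 100), dim = c(20, 20, 3))
  mk <- tibble::tibble(class = c("fungiform", "filiform", "base", "background"),
                       L = runif(4, 0, 100), a = runif(4, -30, 50),
                       b = runif(4, -30, 50))
  base_map <- classify_pixels(lab, mk)
  for (rep in 1:5) {
    expect_identical(classify_pixels(lab, mk[sample(4), ]), base_map)
  }
})

test_that("analysis mask forces background; duplicate markers rejected", {
  lab <- uniform_lab(4, 4, c(50, 20, 10))
  mk <- tibble::tibble(class = c("fungiform", "base"),
                       L = c(50, 80), a = c(20, 0), b = c(10, 0))
  msk <- matrix(FALSE, 4, 4); msk[1:2, ] <- TRUE
  map <- classify_pixels(lab, mk, analysis_mask = msk)
  expect_true(all(map[1:2, ] == 1L))
  expect_true(all(map[3:4, ] == 0L))
  expect_error(
    classify_pixels(lab, dplyr::bind_rows(mk, mk[1, ])),
    class = "fpquant_config_error")
})

test_that("pixel classes partition the image", {
  set.seed(33)
  lab <- array(runif(30 * 30 * 3, 0, 100), dim = c(30, 30, 3))
  mk <- tibble::tibble(class = c("fungiform", "filiform", "base"),
                       L = runif(3, 0, 100), a = runif(3, -30, 50),
                       b = runif(3, -30, 50))
  map <- classify_pixels(lab, mk)
  counts <- table(factor(as.vector(map), levels = 0:3))
  expect_equal(sum(counts), 900)
  expect_equal(unname(counts[["0"]]), 0)  # no background marker, no mask
})

test_that("re-analysis with the global markers over the whole image is idempotent", {
  set.seed(41)
  lab <- array(runif(16 * 16 * 3, 0, 100), dim = c(16, 16, 3))
  mk <- tibble::tibble(class = c("fungiform", "filiform", "base"),
                       L = c(20, 50, 80), a = c(30, 0, -10), b = c(5, 10, 0))
  map <- classify_pixels(lab, mk)
  again <- reanalyze_region(lab, map, rect = c(1, 16, 1, 16),
                            local_markers = mk, global_markers = mk)
  expect_identical(unclass(again), unclass(map))
  # zero-area rectangle leaves the map untouched
  expect_identical(
    unclass(reanalyze_region(lab, map, rect = c(8, 7, 8, 7),
                             local_markers = mk)),
    unclass(map))
})

test_that("re-analysis never touches pixels outside its rectangle", {
  set.seed(42)
  lab <- array(runif(24 * 24 * 3, 0, 100), dim = c(24, 24, 3))
  mk <- tibble::tibble(class = c("fungiform", "filiform", "base"),
                       L = c(20, 50, 80), a = c(30, 0, -10), b = c(5, 10, 0))
  shifted <- dplyr::mutate(mk, L = L + 15)
  map <- classify_pixels(lab, mk)
  out <- reanalyze_region(lab, map, rect = c(5, 12, 7, 20),
                          local_markers = shifted, global_markers = mk)
  untouched <- unclass(out)
  untouched[7:20, 5:12] <- unclass(map)[7:20, 5:12]
  expect_identical(untouched, unclass(map))
})

test_that("local re-analysis recovers a colour-shifted region exactly", {
  # composite image: right half rendered with shifted class colours
  syn <- generate_tongue(small_params(seed = 43, n_papillae = 25L))
  truth_map <- unclass(syn$truth$class_map)
  img <- syn$image
  W <- ncol(truth_map)
  right <- (floor(W / 2) + 1L):W
  # hue-shift the right half's tongue pixels towards pink: base tissue there
  # starts to resemble the global fungiform marker
  shift <- c(1, 0.6, 0.7)
  for (ch in 1:3) {
    plane <- img[, , ch]
    sel <- truth_map[, right] != 0L
    sub <- plane[, right]
    sub[sel] <- round(sub[sel] * shift[ch])
    plane[, right] <- sub
    img[, , ch] <- plane
  }
  lab <- rgb_to_lab(img)
  mask_left <- syn$truth$tongue_mask
  mask_left[, right] <- FALSE
  global_rois <- lapply(c("fungiform", "filiform", "base"), function(cl) {
    roi_mask(cl, truth_map == fpquant:::class_code(cl) & mask_left)
  })
  global_mk <- learn_markers(lab, global_rois)
  base_map <- classify_pixels(lab, global_mk,
                              analysis_mask = syn$truth$tongue_mask)
  # global markers misclassify on the right half
  err_before <- mean((unclass(base_map) != truth_map)[, right][
    syn$truth$tongue_mask[, right]])
  expect_gt(err_before, 0)

  mask_right <- syn$truth$tongue_mask & !mask_left
  local_rois <- lapply(c("fungiform", "filiform", "base"), function(cl) {
    roi_mask(cl, truth_map == fpquant:::class_code(cl) & mask_right)
  })
  out <- reanalyze_region(lab, base_map, rect = c(min(right), W, 1, nrow(img)),
                          local_rois = local_rois, global_markers = global_mk)
  err_after <- mean((unclass(out) != truth_map)[, right][
    syn$truth$tongue_mask[, right]])
  expect_equal(err_after, 0)
  # left half bit-identical to the original analysis
  expect_identical(unclass(out)[, seq_len(min(right) - 1L)],
                   unclass(base_map)[, seq_len(min(right) - 1L)])
})

test_that("missing local tongue class falls back to the global marker", {
  set.seed(44)
  lab <- array(runif(10 * 10 * 3, 0, 100), dim = c(10, 10, 3))
  mk <- tibble::tibble(class = c("fungiform", "filiform", "base"),
                       L = c(20, 50, 80), a = c(30, 0, -10), b = c(5, 10, 0))
  map <- classify_pixels(lab, mk)
  expect_message(
    out <- reanalyze_region(lab, map, rect = c(1, 10, 1, 10),
                            local_markers = mk[1, ], global_markers = mk),
    "Falling back")
  expect_identical(unclass(out), unclass(map))
  # out-of-image rectangle errors
  expect_error(reanalyze_region(lab, map, rect = c(1, 11, 1, 10),
                                local_markers = mk),
               class = "fpquant_bounds_error")
})
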