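# A small, fast synthetic tongue: ~11 mm of anterior tongue at the default
# calibration, enough for both bands to be exercised while keeping unit
# tests quick.  Acceptance tests use the full default conditions instead.
small_params <- function(..., n_papillae = 40L) {
  synth_params(width_px = 420L, height_px = 460L,
               tongue_half_width_mm = 9, tongue_length_mm = 23,
               n_papillae = n_papillae, ...)
}

grid_cols <- c(paste0("L", 1:8), paste0("R", 1:8))

quantify_synthetic <- function(syn, ...) {
  fp_quantify(syn$image, mm_per_px = syn$truth$params$mm_per_px,
              markers = markers_from_truth(syn$image, syn$truth),
              boundary = FALSE, ...)
}
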