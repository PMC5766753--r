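#' Convert an sRGB tongue image to CIELAB
#'
#' Pixel colours are converted from 8-bit companded sRGB to CIELAB under the
#' D65 reference white.  CIELAB is close to perceptually uniform, so the
#' Euclidean distance used by [classify_pixels()] approximates perceived
#' colour difference and is less sensitive to illumination changes than a
#' distance taken directly in RGB.
#'
#' The conversion is the standard closed-form chain: undo the sRGB transfer
#' function (linear segment below 0.04045, gamma 2.4 above), apply the
#' sRGB-to-XYZ (D65) matrix, then the CIELAB cube-root compression with the
#' CIE linear segment near black.
#'
#' @param img An `H x W x 3` array of sRGB values in `[0, 255]` (numeric or
#'   integer), or an `n x 3` matrix of colours.
#' @return An array (or matrix) of the same shape: channel 1 is `L*` in
#'   `[0, 100]`, channels 2-3 are `a*` and `b*`.
#' @examples
#' rgb_to_lab(array(c(255, 0, 0), dim = c(1, 1, 3)))  # pure red
#' @export
rgb_to_lab <- function(img) {
  was_array <- is.array(img) && length(dim(img)) == 3L
  if (was_array) {
    if (dim(img)[3] != 3L) {
      abort("`img` must have 3 colour channels (H x W x 3).",
            class = "fpquant_format_error")
    }
    d <- dim(img)
    m <- matrix(img, ncol = 3L)
  } else if (is.matrix(img) && ncol(img) == 3L) {
    m <- img
  } else {
    abort("`img` must be an H x W x 3 array or an n x 3 matrix.",
          class = "fpquant_format_error")
  }
  if (anyNA(m) || min(m) < 0 || max(m) > 255) {
    abort("sRGB values must lie in [0, 255] with no missing values.",
          class = "fpquant_format_error")
  }

  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)

  # sRGB (IEC 61966-2-1) linear RGB -> XYZ, D65 white
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3L, byrow = TRUE)
  xyz <- lin %*% t(M)

  # normalise by the D65 reference white
  wn <- c(0.95047, 1.00000, 1.08883)
  xyz <- sweep(xyz, 2L, wn, "/")

  f <- function(t) {
    delta3 <- (6 / 29)^3
    ifelse(t > delta3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(xyz[, 1L]); fy <- f(xyz[, 2L]); fz <- f(xyz[, 3L])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))

  if (was_array) {
    out <- array(lab, dim = d)
    dimnames(out) <- NULL
    out
  } else {
    lab
  }
}
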