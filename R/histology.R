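#' Area fractions from stained cross-sections
#'
#' Stained radial-circumferential paraffin sections (Verhoeff-Van Gieson
#' for elastin, Masson's trichrome for cytoplasm, Movat pentachrome for
#' ground substance and fibrin) are quantified as area fractions: the
#' number of stain-positive pixels divided by the number of tissue pixels,
#' after background subtraction and pixel-based thresholding.  Because
#' trichrome can overstain collagen, the collagen fraction is computed by
#' the complement rule rather than thresholded directly.
#'
#' @name histology
NULL

# built-in stain rules: hue window (degrees on the HSV circle), minimum
# saturation, and value window; calibrated on the synthetic stain panel
default_stain_rules <- function() {
  list(
    elastin_vvg   = list(hue = c(240, 330), s_min = 0.29, v = c(0.05, 0.75)),
    cytoplasm_mtc = list(hue = c(306, 25),  s_min = 0.42, v = c(0.2, 1)),
    ground_movat  = list(hue = c(140, 215), s_min = 0.26, v = c(0.46, 1)),
    fibrin_movat  = list(hue = c(22, 70),   s_min = 0.44, v = c(0.52, 1))
  )
}

rgb_to_hsv_arr <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(r = as.numeric(img[, , 1]),
                            g = as.numeric(img[, , 2]),
                            b = as.numeric(img[, , 3]), maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

in_hue_window <- function(h, win) {
  if (win[1] <= win[2]) h >= win[1] & h <= win[2]
  else h >= win[1] | h <= win[2]     # window wrapping 360 -> 0
}

# rolling-ball style background correction: the slowly varying brightness
# field (large-radius morphological closing of the value channel) is
# divided out so thresholds are insensitive to uneven illumination
subtract_background <- function(v, radius_px = 25) {
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  bg <- EBImage::imageData(EBImage::closing(EBImage::Image(v), brush))
  bg <- pmax(bg, 1e-3)
  pmin(v / bg, 1)
}

#' Stain-positive area fraction of a section
#'
#' Tissue pixels are those that are not near-white background (after
#' illumination correction); stain-positive pixels are tissue pixels whose
#' hue/saturation/value fall inside the stain rule's windows.
#'
#' @param img RGB array (rows x cols x 3), values in [0, 1].
#' @param rule a stain rule name from \code{names(default_stain_rules())}
#'   or a list with \code{hue} (two-element window, degrees, possibly
#'   wrapping), \code{s_min} and \code{v} (value window).
#' @param background_radius_px radius of the illumination-correction
#'   structuring element; set to 0 to skip correction.
#' @param white_v,white_s value/saturation cutoffs defining background.
#' @param erode_px erosion radius applied to the tissue mask; pixels this
#'   close to the section edge are excluded from both numerator and
#'   denominator (edge pixels mix with the slide background and carry no
#'   reliable stain identity).
#' @return list with \code{fraction}, \code{n_positive}, \code{n_tissue},
#'   and logical masks \code{tissue}, \code{positive}.
#' @export
area_fraction <- function(img, rule, background_radius_px = 25,
                          white_v = 0.92, white_s = 0.08, erode_px = 3) {
  if (is.character(rule)) {
    rules <- default_stain_rules()
    if (!rule %in% names(rules)) stop("unknown stain rule: ", rule)
    rule <- rules[[rule]]
  }
  hsv <- rgb_to_hsv_arr(img)
  v <- if (background_radius_px > 0)
    subtract_background(hsv$v, background_radius_px) else hsv$v
  tissue <- !(v >= white_v & hsv$s <= white_s)
  if (erode_px > 0 && any(tissue)) {
    brush <- EBImage::makeBrush(2 * erode_px + 1, shape = "disc")
    tissue <- EBImage::imageData(
      EBImage::erode(EBImage::Image(tissue * 1), brush)) > 0.5
  }
  if (!any(tissue)) stop("empty tissue mask: image is all background")
  positive <- tissue & in_hue_window(hsv$h, rule$hue) &
    hsv$s >= rule$s_min & v >= rule$v[1] & v <= rule$v[2]
  list(fraction = sum(positive) / sum(tissue),
       n_positive = sum(positive), n_tissue = sum(tissue),
       tissue = tissue, positive = positive)
}

#' Collagen area fraction by the complement rule
#'
#' Trichrome overstains collagen, so the collagen fraction is computed as
#' the complement of the measured constituents:
#' \eqn{\phi_{col} = 1 - (\phi_{ela} + \phi_{cyt} + \phi_{gnd} + \phi_{fib})}
#' (four-term variant, the default — with it the printed group means sum
#' to 100\%), or \eqn{1 - (\phi_{ela} + \phi_{cyt})} (two-term variant),
#' with glycosaminoglycan content assumed negligible.
#'
#' @param elastin,cytoplasm area fractions in [0, 1].
#' @param ground,fibrin area fractions; ignored by the two-term variant.
#' @param terms \code{"four"} (default) or \code{"two"}.
#' @return collagen area fraction in [0, 1].
#' @examples
#' collagen_complement(0.37, 0.12, 0.07, 0.02)  # 0.42
#' @export
collagen_complement <- function(elastin, cytoplasm, ground = 0, fibrin = 0,
                                terms = c("four", "two")) {
  terms <- match.arg(terms)
  f <- c(elastin, cytoplasm, ground, fibrin)
  stopifnot(all(f >= 0), all(f <= 1))
  s <- if (terms == "four") elastin + cytoplasm + ground + fibrin
       else elastin + cytoplasm
  if (s > 1)
    stop(sprintf("inconsistent fractions: sum exceeds 1 by %.4g", s - 1))
  1 - s
}

#' Quantify a full stain panel
#'
#' Applies the per-stain rules to a panel of section images and closes the
#' composition with the collagen complement.
#'
#' @param vvg,mtc,movat RGB arrays for the three stains.
#' @param rules stain rules, defaults \code{\link{default_stain_rules}}.
#' @param terms complement variant, see \code{\link{collagen_complement}}.
#' @param ... further arguments passed to \code{\link{area_fraction}}
#'   (e.g. \code{erode_px}).
#' @return data.frame of constituents and fractions (summing to 1 with
#'   collagen included).
#' @export
quantify_stain_panel <- function(vvg, mtc, movat,
                                 rules = default_stain_rules(),
                                 terms = "four", ...) {
  ela <- area_fraction(vvg, rules$elastin_vvg, ...)$fraction
  cyt <- area_fraction(mtc, rules$cytoplasm_mtc, ...)$fraction
  gnd <- area_fraction(movat, rules$ground_movat, ...)$fraction
  fib <- area_fraction(movat, rules$fibrin_movat, ...)$fraction
  col <- collagen_complement(ela, cyt, gnd, fib, terms = terms)
  data.frame(
    constituent = c("elastin", "cytoplasm", "ground_substance", "fibrin",
                    "collagen"),
    fraction = c(ela, cyt, gnd, fib, col))
}
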