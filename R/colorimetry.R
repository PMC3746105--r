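#' Construct an iris image object
#'
#' Bundles decoded 8-bit RGB pixels with a boolean iris-region mask. The mask
#' is typically drawn by hand around the iris; everything outside it (sclera,
#' skin, background) is ignored by the colour summaries but may be used as the
#' neutral reference for white balancing.
#'
#' @param pixels Integer array of dimension `c(h, w, 3)` with channel values
#'   in `[0, 255]` (R, G, B).
#' @param mask Logical matrix of dimension `c(h, w)`; `TRUE` marks iris
#'   pixels. At least one pixel must be `TRUE`.
#' @param image_id Identifier carried into downstream summaries.
#' @param encoding_tag Free-text provenance tag (e.g. `"RAW-derived"`,
#'   `"JPEG"`) so parallel analyses of differently encoded photographs can be
#'   kept apart.
#' @return An object of class `iris_image`.
#' @export
iris_image <- function(pixels, mask, image_id = "img", encoding_tag = "unknown") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an h x w x 3 array")
  if (!is.matrix(mask) || !identical(dim(mask), dim(pixels)[1:2]))
    stop("mask shape must equal pixel-grid shape")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must be integers in [0, 255]")
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask must select at least one pixel")
  structure(list(pixels = pixels, mask = mask, image_id = image_id,
                 encoding_tag = encoding_tag),
            class = "iris_image")
}

#' @export
print.iris_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<iris_image '%s'> %dx%d px, %d in mask, encoding: %s\n",
              x$image_id, d[1], d[2], sum(x$mask), x$encoding_tag))
  invisible(x)
}

#' Gray-world white balance
#'
#' Scales each channel so that the channel means over the neutral reference
#' region are equal (the "gray world" assumption). The reference region is the
#' complement of the iris mask when the mask leaves any background pixels,
#' otherwise the whole image; the resulting gains are applied to every pixel.
#' This is a documented, deterministic stand-in for the interactive automatic
#' white-balance adjustment used when the photographs were originally
#' processed.
#'
#' @param image An [iris_image()].
#' @param enabled Set `FALSE` to pass the image through unchanged.
#' @return An `iris_image` of identical shape with balanced channels
#'   (rounded back to 8-bit and clipped to `[0, 255]`).
#' @export
white_balance <- function(image, enabled = TRUE) {
  stopifnot(inherits(image, "iris_image"))
  if (!enabled) return(image)
  px <- image$pixels
  ref <- if (any(!image$mask)) !image$mask else image$mask | TRUE
  ch_means <- vapply(1:3, function(k) mean(px[, , k][ref]), numeric(1))
  if (any(ch_means == 0)) stop("degenerate image")
  target <- mean(ch_means)
  out <- px
  for (k in 1:3) {
    scaled <- round(px[, , k] * (target / ch_means[k]))
    out[, , k] <- pmin(pmax(scaled, 0L), 255L)
  }
  storage.mode(out) <- "integer"
  image$pixels <- out
  image
}

#' Drop highlight and shadow pixels from the iris region
#'
#' Returns the mask-true pixels after removing specular reflections and
#' shadows cast by the eyelids and eyelashes. Because both excluded classes
#' are achromatic, a pixel is excluded only when *all three* channels exceed
#' `high` (white reflection) or *all three* fall below `low` (shadow); the
#' `channel_rule = "any"` alternative excludes on any single extreme channel,
#' at the cost of discarding saturated blue iris pixels.
#'
#' @param image An [iris_image()].
#' @param low,high Channel thresholds; defaults 10 and 250.
#' @param channel_rule `"all"` (default) or `"any"`; see Details.
#' @return Integer matrix with one row per retained pixel and columns
#'   `R`, `G`, `B`.
#' @export
filter_pixels <- function(image, low = 10, high = 250,
                          channel_rule = c("all", "any")) {
  stopifnot(inherits(image, "iris_image"))
  channel_rule <- match.arg(channel_rule)
  px <- matrix(image$pixels, ncol = 3L,
               dimnames = list(NULL, c("R", "G", "B")))[as.vector(image$mask), ,
                                                        drop = FALSE]
  if (channel_rule == "all") {
    hi <- rowSums(px > high) == 3L
    lo <- rowSums(px < low) == 3L
  } else {
    hi <- rowSums(px > high) > 0L
    lo <- rowSums(px < low) > 0L
  }
  kept <- px[!(hi | lo), , drop = FALSE]
  if (nrow(kept) == 0L) stop("no usable iris pixels")
  kept
}

# sRGB (IEC 61966-2-1) -> XYZ (D65, 2 degree observer) linear transform
.srgb_to_xyz_m <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
# reference white implied by the matrix (D65): using the row sums keeps the
# gray axis exactly achromatic (R = G = B gives a* = b* = 0 to machine precision)
.d65_white <- c(X = 0.95047, Y = 1.0000001, Z = 1.08883)

#' Convert 8-bit sRGB colours to CIE L*a*b*
#'
#' Applies the standard pipeline: inverse sRGB companding (piecewise gamma),
#' the sRGB\eqn{\to}XYZ linear transform for the D65 white point and the 2
#' degree observer, then the piecewise cube-root CIELAB formulas. `L*` is
#' lightness (0--100 for in-gamut inputs), `a*` the green(-)/magenta(+) axis
#' and `b*` the blue(-)/yellow(+) axis.
#'
#' @param rgb Length-3 vector or n x 3 matrix of channel values in `[0, 255]`.
#' @return An n x 3 numeric matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L, byrow = TRUE)
  if (ncol(rgb) != 3L) stop("rgb must have three channels")
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) stop("channel out of range [0, 255]")
  cs <- rgb / 255
  lin <- ifelse(cs <= 0.04045, cs / 12.92, ((cs + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz_m)
  xyz_n <- sweep(xyz, 2, .d65_white, "/")
  delta <- 6 / 29
  f <- ifelse(xyz_n > delta^3, xyz_n^(1 / 3), xyz_n / (3 * delta^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  out
}

#' Convert CIE L*a*b* colours to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]. Used by the synthetic image generator, which
#' specifies base iris colours in Lab.
#'
#' @param lab Length-3 vector or n x 3 matrix `(L, a, b)`.
#' @param check_gamut Error when the colour falls outside the sRGB gamut
#'   (default); otherwise clip.
#' @return An n x 3 integer matrix with columns `R`, `G`, `B`.
#' @export
lab_to_srgb <- function(lab, check_gamut = TRUE) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3L, byrow = TRUE)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  delta <- 6 / 29
  finv <- function(t) ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .d65_white, "*")
  lin <- xyz %*% t(solve(.srgb_to_xyz_m))
  if (check_gamut && (min(lin) < -1e-9 || max(lin) > 1 + 1e-9))
    stop("colour outside sRGB gamut")
  lin <- pmin(pmax(lin, 0), 1)
  cs <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- round(cs * 255)
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  out
}

#' Summarize an iris photograph as median chromaticity
#'
#' Filters the masked pixels with [filter_pixels()], converts the survivors to
#' CIE L*a*b* and reports the median a* and b*. L* is computed along the way
#' but deliberately never summarized because it depends on lighting rather
#' than pigmentation. Medians of even-length samples use the mean of the two
#' middle order statistics.
#'
#' @inheritParams filter_pixels
#' @return One-row data frame: `individual_id`, `median_a`, `median_b`,
#'   `n_pixels_total` (mask size), `n_pixels_kept`, `encoding_tag`.
#' @export
summarize_iris <- function(image, low = 10, high = 250,
                           channel_rule = c("all", "any")) {
  channel_rule <- match.arg(channel_rule)
  kept <- filter_pixels(image, low = low, high = high, channel_rule = channel_rule)
  lab <- srgb_to_lab(kept)
  data.frame(individual_id = image$image_id,
             median_a = stats::median(lab[, "a"]),
             median_b = stats::median(lab[, "b"]),
             n_pixels_total = sum(image$mask),
             n_pixels_kept = nrow(kept),
             encoding_tag = image$encoding_tag,
             stringsAsFactors = FALSE)
}
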