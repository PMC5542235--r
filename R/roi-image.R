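#' Construct a tumor region-of-interest image
#'
#' Bundles a 2-D grayscale image with an aligned binary tumor mask. This is
#' the unit every feature extractor consumes. Pixels are in arbitrary
#' scanner units until [normalize_intensity()] maps them onto the 0--255
#' gray-level range.
#'
#' The coordinate convention is matrix-style: element `[r, c]` is row `r`
#' (top to bottom) and column `c` (left to right). Co-occurrence offsets in
#' the texture module are defined against this convention.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param mask logical (or coercible) matrix of the same dimensions; any
#'   value `> 0` is treated as tumor.
#' @param case_id character scalar identifying the case.
#' @param normalized logical flag: `TRUE` once pixels are 0--255 integers.
#' @return An object of class `roi_image` with fields `case_id`, `pixels`,
#'   `mask` (logical) and `normalized`.
#' @examples
#' img <- roi_image(matrix(runif(64, 0, 500), 8), matrix(TRUE, 8, 8), "case01")
#' img <- normalize_intensity(img)
#' range(img$pixels)
#' @export
roi_image <- function(pixels, mask, case_id = "case", normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (!is.matrix(mask))
    stop("'mask' must be a matrix", call. = FALSE)
  if (!identical(dim(pixels), dim(mask)))
    stop(sprintf("geometry error: pixels are %dx%d but mask is %dx%d",
                 nrow(pixels), ncol(pixels), nrow(mask), ncol(mask)),
         call. = FALSE)
  mask <- mask > 0
  if (anyNA(pixels) || anyNA(mask))
    stop("pixels and mask must not contain missing values", call. = FALSE)
  if (any(pixels < 0))
    stop("pixel intensities must be non-negative", call. = FALSE)
  if (!any(mask))
    stop(sprintf("validation error: mask of case '%s' is empty", case_id),
         call. = FALSE)
  structure(
    list(case_id = as.character(case_id), pixels = pixels, mask = mask,
         normalized = isTRUE(normalized)),
    class = "roi_image"
  )
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> case '%s': %d x %d pixels, %d in mask, %s\n",
              x$case_id, nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              if (x$normalized) "normalized (0-255)" else "unnormalized"))
  invisible(x)
}

#' Stretch image intensities onto the full 0--255 range
#'
#' Linearly rescales the whole image (not just the ROI) so that the minimum
#' pixel maps to 0 and the maximum to 255, then rounds to integer gray
#' levels. This mirrors the preprocessing applied to each MR image before
#' contour delineation, so the normalization domain is the full field of
#' view.
#'
#' Rounding is half-away-from-zero so that discrete gray levels feeding the
#' co-occurrence matrix are reproducible across platforms.
#'
#' @param img a [roi_image()] with `normalized = FALSE`.
#' @return The same `roi_image` with integer pixels in `[0, 255]`, an exact
#'   0 minimum and 255 maximum, and `normalized = TRUE`. The mask is
#'   untouched.
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "roi_image"))
  if (img$normalized)
    stop("image is already normalized", call. = FALSE)
  p <- img$pixels
  lo <- min(p)
  hi <- max(p)
  if (hi == lo)
    stop(sprintf("degenerate input: case '%s' has constant intensity (no contrast)",
                 img$case_id), call. = FALSE)
  v <- 255 * (p - lo) / (hi - lo)
  img$pixels <- matrix(round_half_up(v), nrow(p), ncol(p))
  img$normalized <- TRUE
  img
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) {
  floor(x + 0.5)
}
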