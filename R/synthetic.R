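#' Specification of a synthetic two-class tumor cohort
#'
#' Describes a cohort of 2-D grayscale tumor images with irregular
#' star-convex masks whose interior texture differs between classes. The
#' IDH-mutant class is configured more heterogeneous by default -- a
#' shorter spatial correlation length of the interior Gaussian random
#' field -- which lowers its co-occurrence homogeneity (inverse difference
#' moment), while shape and first-order intensity statistics are drawn
#' from the same distributions in both classes so that only texture
#' carries the label. The default class sizes mirror a 32 wild-type : 7
#' mutant cohort.
#'
#' @param n_wt,n_mut class sizes (defaults 32 and 7).
#' @param image_size image side length in pixels (default 128).
#' @param base_radius mean tumor radius in pixels (default 30).
#' @param shape_irregularity total relative amplitude of the radial
#'   boundary perturbation, in `[0, 1)` (default 0.15, both classes).
#' @param texture_corr_len_wt,texture_corr_len_mut Gaussian-kernel
#'   correlation lengths of the interior texture, pixels (defaults 4 and
#'   1.5; the shorter mutant length is the heterogeneity mechanism).
#' @param texture_amp_wt,texture_amp_mut gray-level standard deviation of
#'   the interior texture (default 40 for both).
#' @param base_intensity mean tumor gray level before normalization
#'   (default 150).
#' @param background_intensity mean background gray level (default 60).
#' @param background_noise_sd background white-noise SD (default 10).
#' @param seed integer master seed; each case derives its own stream from
#'   it, so cohorts are reproducible case by case.
#' @return Object of class `cohort_spec` (a validated list of the above).
#' @export
cohort_spec <- function(n_wt = 32L, n_mut = 7L, image_size = 128L,
                        base_radius = 30, shape_irregularity = 0.15,
                        texture_corr_len_wt = 4, texture_corr_len_mut = 1.5,
                        texture_amp_wt = 40, texture_amp_mut = 40,
                        base_intensity = 150, background_intensity = 60,
                        background_noise_sd = 10, seed = 1L) {
  spec <- list(n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
               image_size = as.integer(image_size),
               base_radius = base_radius,
               shape_irregularity = shape_irregularity,
               texture_corr_len_wt = texture_corr_len_wt,
               texture_corr_len_mut = texture_corr_len_mut,
               texture_amp_wt = texture_amp_wt,
               texture_amp_mut = texture_amp_mut,
               base_intensity = base_intensity,
               background_intensity = background_intensity,
               background_noise_sd = background_noise_sd,
               seed = as.integer(seed))
  if (spec$n_wt < 1 || spec$n_mut < 1)
    stop("parameter error: class counts must be at least 1", call. = FALSE)
  if (spec$texture_corr_len_wt <= 0 || spec$texture_corr_len_mut <= 0)
    stop("parameter error: correlation lengths must be positive", call. = FALSE)
  if (spec$texture_amp_wt < 0 || spec$texture_amp_mut < 0 ||
      spec$background_noise_sd < 0)
    stop("parameter error: amplitudes must be non-negative", call. = FALSE)
  if (spec$shape_irregularity < 0 || spec$shape_irregularity >= 1)
    stop("parameter error: shape_irregularity must be in [0, 1) or the boundary radius can vanish",
         call. = FALSE)
  if (spec$base_radius * (1 + spec$shape_irregularity) >= spec$image_size / 2 - 1)
    stop("parameter error: base_radius (plus irregularity) does not fit in the image",
         call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d WT + %d mutant, %dx%d px, radius %g (irregularity %g)\n",
              x$n_wt, x$n_mut, x$image_size, x$image_size, x$base_radius,
              x$shape_irregularity))
  cat(sprintf("  texture corr len WT %g / mut %g px, amplitude WT %g / mut %g, seed %d\n",
              x$texture_corr_len_wt, x$texture_corr_len_mut,
              x$texture_amp_wt, x$texture_amp_mut, x$seed))
  invisible(x)
}

#' Generate one irregular star-convex tumor mask
#'
#' The boundary radius is `base_radius * (1 + sum_k a_k cos(k phi + phi_k))`
#' over harmonics k = 2..6, with non-negative amplitudes `a_k` drawn to
#' total `shape_irregularity` and uniform random phases. A pixel belongs
#' to the mask when its center lies within that radius of the image
#' center, so masks are filled, connected and non-empty.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer; when given, the RNG is seeded so the mask
#'   is a pure function of `(spec, seed)`.
#' @return Logical `image_size` x `image_size` matrix.
#' @export
generate_tumor_mask <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  ks <- 2:6
  w <- stats::runif(length(ks))
  a <- if (sum(w) > 0) spec$shape_irregularity * w / sum(w) else w * 0
  ph <- stats::runif(length(ks), 0, 2 * pi)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n) - ctr
  col <- t(row)
  phi <- atan2(row, col)
  rad <- sqrt(row^2 + col^2)
  rb <- spec$base_radius *
    (1 + Reduce(`+`, Map(function(ak, k, pk) ak * cos(k * phi + pk), a, ks, ph)))
  if (any(rb <= 0))
    stop("parameter error: irregularity drove the boundary radius non-positive",
         call. = FALSE)
  rad <= rb
}

#' Generate one class-conditional interior texture field
#'
#' Gaussian white noise smoothed with a Gaussian kernel whose width is the
#' class's correlation length, rescaled to unit variance, multiplied by
#' the class amplitude and shifted to the tumor base intensity; clipped to
#' `[0, 255]`. A shorter correlation length gives a grainier
#' (more heterogeneous) texture at the same marginal variance, which is
#' what depresses the inverse difference moment of the mutant class.
#'
#' @param spec a [cohort_spec()].
#' @param class_label 1 for IDH-mutant, 0 for wild-type.
#' @param seed optional integer, as in [generate_tumor_mask()].
#' @return Numeric `image_size` x `image_size` matrix in `[0, 255]`.
#' @export
generate_texture_field <- function(spec, class_label, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), class_label %in% c(0, 1))
  if (!is.null(seed)) set.seed(seed)
  corr <- if (class_label == 1) spec$texture_corr_len_mut else spec$texture_corr_len_wt
  amp <- if (class_label == 1) spec$texture_amp_mut else spec$texture_amp_wt
  n <- spec$image_size
  z <- matrix(stats::rnorm(n * n), n, n)
  sm <- EBImage::gblur(z, sigma = corr)
  s <- stats::sd(as.numeric(sm))
  if (s > 0) sm <- sm / s
  pmin(pmax(spec$base_intensity + amp * sm, 0), 255)
}

case_seed <- function(master, idx) {
  as.integer((as.numeric(master) + 7919 * idx) %% 2147483647)
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_wt + n_mut` grayscale image/mask PNG pairs, a
#' `manifest.csv` (columns `case_id,image,mask,label`) and a `spec.json`
#' into `out_dir`. Each case draws from its own RNG stream derived from
#' `(seed, case index)`, so regeneration with the same spec is
#' byte-identical. Images are tumor texture inside the mask over a noisy
#' darker background, so whole-image intensity normalization is exercised
#' realistically.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, created if needed.
#' @return The loaded [load_cohort()] manifest, invisibly.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep(0L, spec$n_wt), rep(1L, spec$n_mut))
  ids <- c(sprintf("wt_%02d", seq_len(spec$n_wt)),
           sprintf("mut_%02d", seq_len(spec$n_mut)))
  rows <- vector("list", length(ids))
  for (idx in seq_along(ids)) {
    sd_i <- case_seed(spec$seed, idx)
    mask <- generate_tumor_mask(spec, seed = sd_i)
    field <- generate_texture_field(spec, labels[idx], seed = sd_i + 1L)
    set.seed(sd_i + 2L)
    bg <- spec$background_intensity +
      spec$background_noise_sd * matrix(stats::rnorm(spec$image_size^2),
                                        spec$image_size)
    img <- ifelse(mask, field, pmin(pmax(bg, 0), 255))
    img_path <- file.path(out_dir, paste0(ids[idx], "_img.png"))
    mask_path <- file.path(out_dir, paste0(ids[idx], "_mask.png"))
    write_gray_png(img, img_path)
    write_gray_png(ifelse(mask, 255, 0), mask_path)
    rows[[idx]] <- data.frame(case_id = ids[idx],
                              image = basename(img_path),
                              mask = basename(mask_path),
                              label = labels[idx], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(load_cohort(manifest_path))
}
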