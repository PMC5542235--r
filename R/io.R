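#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with header `case_id,image,mask,label` listing one
#' image/mask pair per case. Labels are strictly binary with 1 = IDH-mutant
#' and 0 = IDH wild-type. Relative image/mask paths are resolved against the
#' manifest's own directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A data frame of class `cohort_manifest` with columns `case_id`,
#'   `image`, `mask` (absolute-ized paths) and integer `label`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("I/O error: manifest '%s' does not exist", manifest_path),
         call. = FALSE)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("case_id", "image", "mask", "label")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(m) == 0)
    stop("manifest contains no cases", call. = FALSE)
  m$case_id <- as.character(m$case_id)
  dup <- m$case_id[duplicated(m$case_id)]
  if (length(dup))
    stop(sprintf("validation error: duplicated case_id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  bad_lab <- !(m$label %in% c(0L, 1L))
  if (any(bad_lab))
    stop(sprintf("validation error: non-binary label for case(s): %s",
                 paste(m$case_id[bad_lab], collapse = ", ")), call. = FALSE)
  m$label <- as.integer(m$label)
  root <- dirname(normalizePath(manifest_path))
  resolve <- function(p) ifelse(is_absolute_path(p), p, file.path(root, p))
  m$image <- resolve(m$image)
  m$mask <- resolve(m$mask)
  for (i in seq_len(nrow(m))) {
    for (col in c("image", "mask")) {
      if (!file.exists(m[[col]][i]))
        stop(sprintf("I/O error: %s file '%s' of case '%s' does not exist",
                     col, m[[col]][i], m$case_id[i]), call. = FALSE)
    }
  }
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

is_absolute_path <- function(p) {
  grepl("^(/|[A-Za-z]:[/\\\\]|~)", p)
}

#' Load one image/mask pair as a ROI image
#'
#' Supports grayscale PNG and TIFF, and NIfTI (`.nii`/`.nii.gz`; a trailing
#' singleton third dimension is dropped, otherwise the first slice of a 3-D
#' volume is taken). PNG/TIFF intensities read as fractions of full scale
#' are expanded to 0--255; the image is still considered unnormalized until
#' [normalize_intensity()] runs, since the original acquisition need not
#' span the full range. Mask pixels with any value `> 0` are tumor.
#'
#' @param image_path path to the grayscale image.
#' @param mask_path path to the binary mask, same geometry.
#' @param case_id identifier attached to the result.
#' @return A [roi_image()], `normalized = FALSE`.
#' @export
load_roi_image <- function(image_path, mask_path, case_id = basename(image_path)) {
  pixels <- read_gray_image(image_path)
  mask <- read_gray_image(mask_path)
  if (!identical(dim(pixels), dim(mask)))
    stop(sprintf("geometry error: case '%s' image is %dx%d but mask is %dx%d",
                 case_id, nrow(pixels), ncol(pixels), nrow(mask), ncol(mask)),
         call. = FALSE)
  roi_image(pixels, mask > 0, case_id = case_id, normalized = FALSE)
}

# Read a 2-D single-channel image as a numeric matrix in row/col convention.
read_gray_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: image file '%s' does not exist", path),
         call. = FALSE)
  ext <- tolower(sub("^.*\\.", "", sub("\\.gz$", "", path)))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = as.array(RNifti::readNifti(path)),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE)
  )
  if (length(dim(a)) == 3) {
    if (dim(a)[3] == 1) {
      a <- a[, , 1]
    } else if (ext %in% c("png", "tif", "tiff")) {
      stop(sprintf("'%s' has %d channels; single-channel grayscale required",
                   path, dim(a)[3]), call. = FALSE)
    } else {
      a <- a[, , 1]  # first slice of a NIfTI volume
    }
  }
  if (length(dim(a)) != 2)
    stop(sprintf("'%s' is not a 2-D image", path), call. = FALSE)
  a <- unclass(a)
  # png/tiff readers scale integer samples to [0,1]; restore 8-bit units
  if (ext %in% c("png", "tif", "tiff")) a <- a * 255
  storage.mode(a) <- "double"
  a
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' Values are clipped to `[0, 255]` and rounded; companion writer for the
#' synthetic-cohort generator and for exporting normalized images.
#'
#' @param x numeric matrix.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(x, path) {
  v <- pmin(pmax(x, 0), 255)
  png::writePNG(round_half_up(v) / 255, target = path)
  invisible(path)
}
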