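#' Quantize a normalized image to G gray levels
#'
#' Maps gray value `v` in 0--255 to level `floor(v * G / 256)`, clipped to
#' `G - 1`, so each level covers an equal-width slice of the 8-bit range.
#' Reducing the level count keeps the co-occurrence matrix small and its
#' cells well populated at ROI sample sizes.
#'
#' @param img a normalized [roi_image()].
#' @param G number of gray levels, at least 2 (default 32).
#' @return The `roi_image` with pixels in `{0, ..., G-1}`; the number of
#'   levels is recorded in attribute `"G"`.
#' @export
quantize_gray_levels <- function(img, G = 32L) {
  stopifnot(inherits(img, "roi_image"))
  if (!img$normalized)
    stop("precondition error: quantization needs a normalized 0-255 image",
         call. = FALSE)
  if (G < 2)
    stop("parameter error: G must be at least 2", call. = FALSE)
  G <- as.integer(G)
  lev <- pmin(floor(img$pixels * G / 256), G - 1L)
  img$pixels <- matrix(as.integer(lev), nrow(lev), ncol(lev))
  attr(img, "G") <- G
  img
}

glcm_offset <- function(theta, d) {
  # (row, col) displacement; row 1 is the top of the image
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135 (degrees)", call. = FALSE))
}

#' Gray-level co-occurrence matrix of a masked ROI
#'
#' Counts ordered gray-level pairs `(pixel, pixel + offset)` together with
#' their reverses (symmetric accumulation), for pairs whose two pixels BOTH
#' lie inside the mask, then normalizes to probabilities. Directions follow
#' the usual image convention with row 1 at the top: 0 degrees is
#' rightwards along a row, 90 degrees upwards along a column, 45/135 the
#' two diagonals.
#'
#' @param img a quantized [roi_image()] (see [quantize_gray_levels()]).
#' @param d pixel distance (default 1).
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @return Object of class `glcm`: list with `p` (G x G probability matrix,
#'   `p[i + 1, j + 1]` for levels i, j), `G`, `d`, `theta`, `n_pairs`
#'   (ordered pairs counted, including reverses).
#' @export
compute_glcm <- function(img, d = 1L, theta = 0) {
  stopifnot(inherits(img, "roi_image"))
  G <- attr(img, "G")
  if (is.null(G))
    stop("precondition error: image must be quantized first", call. = FALSE)
  off <- glcm_offset(theta, as.integer(d))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  rs <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  cs <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(rs) < 1 || length(cs) < 1 || rs[1] > rs[length(rs)] ||
      cs[1] > cs[length(cs)])
    stop(sprintf("degenerate input: no %g-degree pairs at distance %d", theta, d),
         call. = FALSE)
  a <- img$pixels[rs, cs, drop = FALSE]
  b <- img$pixels[rs + off[1], cs + off[2], drop = FALSE]
  ok <- img$mask[rs, cs, drop = FALSE] & img$mask[rs + off[1], cs + off[2], drop = FALSE]
  if (!any(ok))
    stop(sprintf("degenerate input: mask admits no %g-degree pairs at distance %d",
                 theta, d), call. = FALSE)
  i <- a[ok]; j <- b[ok]
  # symmetric: count (i,j) and (j,i)
  counts <- tabulate(c(i * G + j, j * G + i) + 1L, nbins = G * G)
  n_pairs <- sum(counts)
  structure(list(p = matrix(counts / n_pairs, G, G, byrow = TRUE),
                 G = G, d = as.integer(d), theta = theta, n_pairs = n_pairs),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> G = %d levels, d = %d, theta = %g deg, %d pairs\n",
              x$G, x$d, x$theta, x$n_pairs))
  invisible(x)
}

#' Marginal statistics of a co-occurrence matrix
#'
#' Computes the row/column marginal distributions and their means and
#' standard deviations, the distributions of `i + j` and `|i - j|`, and the
#' entropies used by the information measure of correlation. Natural
#' logarithms throughout, with `0 * log 0 = 0`.
#'
#' @param g a [compute_glcm()] result.
#' @return Object of class `glcm_marginals`: `px`, `py` (marginals over
#'   levels 0..G-1), `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `p_plus`
#'   (distribution of i + j over 0..2(G-1)), `p_minus` (distribution of
#'   |i - j| over 0..G-1), `HX`, `HY`, `HXY`, `HXY1`.
#' @export
compute_marginals <- function(g) {
  stopifnot(inherits(g, "glcm"))
  G <- g$G
  lev <- 0:(G - 1)
  p <- g$p
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sigma_x <- sqrt(sum((lev - mu_x)^2 * px))
  sigma_y <- sqrt(sum((lev - mu_y)^2 * py))
  ij_sum <- outer(lev, lev, `+`)
  ij_dif <- abs(outer(lev, lev, `-`))
  p_plus <- rep(0, 2 * G - 1)                      # index s = 0..2(G-1)
  aggs <- tapply(p, ij_sum, sum)
  p_plus[as.integer(names(aggs)) + 1L] <- as.numeric(aggs)
  p_minus <- rep(0, G)                             # index k = 0..G-1
  aggd <- tapply(p, ij_dif, sum)
  p_minus[as.integer(names(aggd)) + 1L] <- as.numeric(aggd)
  pxy_prod <- outer(px, py)
  structure(list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 p_plus = p_plus, p_minus = p_minus,
                 HX = neg_plogp(px), HY = neg_plogp(py),
                 HXY = neg_plogp(p), HXY1 = xlogy_sum(p, pxy_prod)),
            class = "glcm_marginals")
}

neg_plogp <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# -sum p * log(q) over cells where p > 0
xlogy_sum <- function(p, q) {
  keep <- p > 0
  -sum(p[keep] * log(q[keep]))
}

#' The fourteen GLCM texture features
#'
#' Haralick-style texture descriptors of a co-occurrence matrix, over gray
#' levels i, j in 0..G-1 with p = p(i, j):
#' autocorrelation (sum i j p), contrast (sum (i-j)^2 p), correlation
#' (standardized covariance of i and j), cluster prominence and cluster
#' shading (fourth/third moments of i + j about mu_x + mu_y), dissimilarity
#' (sum |i-j| p), energy (sum p^2), entropy (-sum p log p), homogeneity
#' (sum p / (1 + |i-j|)), difference variance (sum k^2 p_(x-y)(k)),
#' difference entropy (entropy of p_(x-y)), information measure of
#' correlation ((HXY - HXY1) / max(HX, HY)), inverse difference normalized
#' (sum p / (1 + |i-j|/G)) and inverse difference moment
#' (sum p / (1 + (i-j)^2)). Natural logarithms throughout.
#'
#' A constant ROI gives a single-cell matrix with zero marginal spread;
#' correlation (and the information measure) are then defined as 0 and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param g a [compute_glcm()] result.
#' @return Named numeric vector of the 14 features.
#' @export
haralick_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  m <- compute_marginals(g)
  G <- g$G
  lev <- 0:(G - 1)
  p <- g$p
  I <- matrix(lev, G, G)          # row level i
  J <- t(I)                      # col level j
  Dif <- abs(I - J)
  S <- I + J
  degenerate <- (m$sigma_x == 0 || m$sigma_y == 0)
  correlation <- if (degenerate) 0 else
    sum((I - m$mu_x) * (J - m$mu_y) * p) / (m$sigma_x * m$sigma_y)
  hmax <- max(m$HX, m$HY)
  imc <- if (hmax == 0) 0 else (m$HXY - m$HXY1) / hmax
  k <- 0:(G - 1)
  out <- c(
    autocorrelation = sum(I * J * p),
    contrast = sum((I - J)^2 * p),
    correlation = correlation,
    cluster_prominence = sum((S - m$mu_x - m$mu_y)^4 * p),
    cluster_shading = sum((S - m$mu_x - m$mu_y)^3 * p),
    dissimilarity = sum(Dif * p),
    energy = sum(p^2),
    entropy = neg_plogp(p),
    homogeneity = sum(p / (1 + Dif)),
    difference_variance = sum(k^2 * m$p_minus),
    difference_entropy = neg_plogp(m$p_minus),
    info_measure_correlation = imc,
    inverse_difference_normalized = sum(p / (1 + Dif / G)),
    inverse_difference_moment = sum(p / (1 + (I - J)^2))
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Direction-aggregated texture feature vector of a ROI
#'
#' Computes the 14 co-occurrence features for each requested direction and
#' either averages them (default, the usual rotation-tolerant summary) or
#' returns them per direction.
#'
#' @param img a normalized [roi_image()].
#' @param d pixel distance (default 1).
#' @param G gray-level count for quantization (default 32).
#' @param directions degrees, subset of `c(0, 45, 90, 135)`.
#' @param aggregate `"mean"` for the average over directions, or
#'   `"per_direction"` for a 14 x length(directions) matrix.
#' @return Named vector of 14 features, or a matrix when
#'   `aggregate = "per_direction"`.
#' @export
texture_feature_vector <- function(img, d = 1L, G = 32L,
                                   directions = c(0, 45, 90, 135),
                                   aggregate = c("mean", "per_direction")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(directions) >= 1)
  q <- quantize_gray_levels(img, G = G)
  per <- vapply(directions,
                function(th) haralick_features(compute_glcm(q, d = d, theta = th)),
                numeric(14))
  colnames(per) <- paste0("deg", directions)
  if (aggregate == "per_direction") return(per)
  rowMeans(per)
}
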