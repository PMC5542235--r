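test_that("gray-level quantization maps 0-255 onto equal-width level slices", {
  img <- norm_img(matrix(c(255, 0, 128, 64), 2, 2))
  q <- quantize_gray_levels(img, 32)
  expect_equal(as.numeric(q$pixels), c(31, 0, 16, 8))
  expect_equal(attr(q, "G"), 32L)
  q2 <- quantize_gray_levels(img, 2)
  expect_equal(as.numeric(q2$pixels), c(1, 0, 1, 0))
  expect_error(quantize_gray_levels(img, 1), "parameter")
  expect_error(quantize_gray_levels(roi_image(matrix(1:4, 2, 2) * 1.0,
                                              matrix(TRUE, 2, 2), "u"), 8),
               "normalized")
})

worked_image <- function() {
  px <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 0, 2, 2, 2,
                 2, 2, 3, 3), 4, 4, byrow = TRUE)
  quantized_img(px, G = 4)
}

test_that("the 4x4 worked co-occurrence matrix matches the hand enumeration", {
  g <- compute_glcm(worked_image(), d = 1, theta = 0)
  expect_equal(g$n_pairs, 24)
  counts <- g$p * g$n_pairs
  # hand-enumerated symmetric counts; off-diagonal unordered pairs split
  # evenly across (i,j) and (j,i)
  expected <- matrix(0, 4, 4)
  expected[1, 1] <- 4; expected[2, 2] <- 4; expected[3, 3] <- 6; expected[4, 4] <- 2
  expected[1, 2] <- expected[2, 1] <- 2  # (0,1) pairs: 4 total
  expected[1, 3] <- expected[3, 1] <- 1  # (0,2) pairs: 2 total
  expected[3, 4] <- expected[4, 3] <- 1  # (2,3) pairs: 2 total
  expect_equal(counts, expected)
  expect_equal(sum(g$p), 1)
  expect_equal(g$p, t(g$p))
})

test_that("marginals agree with brute-force summation and closed forms", {
  g <- compute_glcm(worked_image(), d = 1, theta = 0)
  m <- compute_marginals(g)
  # brute force over the probability table
  G <- g$G
  px <- rowSums(g$p); py <- colSums(g$p)
  lev <- 0:(G - 1)
  expect_equal(m$px, px)
  expect_equal(m$mu_x, sum(lev * px))
  expect_equal(m$mu_y, m$mu_x)  # symmetric GLCM
  expect_equal(m$sigma_x, m$sigma_y)
  expect_equal(sum(m$p_plus), 1)
  expect_equal(sum(m$p_minus), 1)

  # uniform 2x2 table
  gu <- structure(list(p = matrix(0.25, 2, 2), G = 2L, d = 1L, theta = 0,
                       n_pairs = 4L), class = "glcm")
  mu <- compute_marginals(gu)
  expect_equal(mu$mu_x, 0.5)
  expect_equal(mu$sigma_x, 0.5)
  expect_equal(mu$HX, log(2))

  # constant image at one level
  ci <- quantized_img(matrix(3L, 4, 4), G = 8)
  mc <- compute_marginals(compute_glcm(ci, 1, 0))
  expect_equal(mc$mu_x, 3)
  expect_equal(mc$sigma_x, 0)
  expect_equal(mc$p_minus[1], 1)
})

test_that("closed-form feature limits hold for constant and uniform tables", {
  ci <- quantized_img(matrix(5L, 6, 6), G = 8)
  h <- haralick_features(compute_glcm(ci, 1, 0))
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["inverse_difference_moment"]], 1)
  expect_equal(h[["homogeneity"]], 1)
  expect_equal(h[["correlation"]], 0)  # degenerate convention
  expect_true(attr(h, "degenerate"))

  K <- 9
  gu <- structure(list(p = matrix(1 / K, 3, 3), G = 3L, d = 1L, theta = 0,
                       n_pairs = K), class = "glcm")
  hu <- haralick_features(gu)
  expect_equal(hu[["energy"]], 1 / K)
  expect_equal(hu[["entropy"]], log(K))
})

test_that("all 14 features match the brute-force oracle on random masked images", {
  set.seed(99)
  for (rep in 1:25) {
    im <- random_masked_image(size = sample(6:14, 1), G = sample(3:8, 1))
    theta <- sample(c(0, 45, 90, 135), 1)
    img <- quantized_img(im$levels, im$mask, G = im$G)
    g <- compute_glcm(img, d = 1, theta = theta)
    oc <- oracle_glcm(im$levels, im$mask, im$G, theta)
    expect_equal(g$p, oc / sum(oc))
    expect_equal(unclass(haralick_features(g)), oracle_features(g$p),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("feature bounds and entropy cap hold across random inputs", {
  set.seed(123)
  for (rep in 1:20) {
    im <- random_masked_image(size = 12, G = 8)
    img <- quantized_img(im$levels, im$mask, G = im$G)
    h <- haralick_features(compute_glcm(img, 1, sample(c(0, 45, 90, 135), 1)))
    expect_gt(h[["energy"]], 0); expect_lte(h[["energy"]], 1)
    expect_gte(h[["entropy"]], 0)
    expect_gte(h[["contrast"]], 0)
    expect_gte(h[["correlation"]], -1); expect_lte(h[["correlation"]], 1 + 1e-12)
    # IDM <= homogeneity <= 1, entropy <= log(nonzero cells)
    expect_lte(h[["inverse_difference_moment"]], h[["homogeneity"]] + 1e-12)
    expect_lte(h[["homogeneity"]], 1 + 1e-12)
    g <- compute_glcm(img, 1, 0)
    expect_lte(haralick_features(g)[["entropy"]], log(sum(g$p > 0)) + 1e-12)
  }
})

test_that("directional features respond to oriented structure and rotation", {
  # rows of constant value alternating by row: only the vertical (90 deg)
  # direction crosses stripes
  stripes <- matrix(rep(c(0, 255), length.out = 8), 8, 8)  # varies along rows
  simg <- norm_img(stripes)
  per <- texture_feature_vector(simg, G = 8, aggregate = "per_direction")
  expect_gt(per["contrast", "deg90"], per["contrast", "deg0"])
  expect_equal(per["contrast", "deg0"], 0)

  # rotating the image by 90 degrees swaps 0<->90 and 45<->135
  set.seed(4)
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  p0 <- texture_feature_vector(norm_img(px), G = 8, aggregate = "per_direction")
  rot <- t(px)[ncol(px):1, ]
  p90 <- texture_feature_vector(norm_img(rot), G = 8, aggregate = "per_direction")
  expect_equal(p90[, "deg90"], p0[, "deg0"], tolerance = 1e-12)
  expect_equal(p90[, "deg0"], p0[, "deg90"], tolerance = 1e-12)
  expect_equal(p90[, "deg135"], p0[, "deg45"], tolerance = 1e-12)
  # direction-averaged features are rotation invariant
  expect_equal(rowMeans(p90), rowMeans(p0), tolerance = 1e-12)

  # isotropic white noise: per-direction contrast within sampling noise
  set.seed(10)
  iso <- matrix(sample(0:255, 64^2, replace = TRUE), 64, 64)
  pi_ <- texture_feature_vector(norm_img(iso), G = 8, aggregate = "per_direction")
  expect_lt(diff(range(pi_["contrast", ])) / mean(pi_["contrast", ]), 0.1)

  # constant image: aggregated energy 1 in both modes
  cimg <- norm_img(matrix(77, 6, 6))
  expect_equal(unname(texture_feature_vector(cimg, G = 8)["energy"]), 1)
  expect_equal(unname(texture_feature_vector(cimg, G = 8,
    aggregate = "per_direction")["energy", "deg45"]), 1)
})

test_that("degenerate pair geometries raise errors", {
  row_mask <- matrix(FALSE, 4, 4); row_mask[2, ] <- TRUE
  img <- quantized_img(matrix(1L, 4, 4), row_mask, G = 4)
  expect_error(compute_glcm(img, 1, 90), "degenerate")
  expect_error(compute_glcm(quantized_img(matrix(0L, 1, 5), G = 2), 1, 90),
               "degenerate")
})
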