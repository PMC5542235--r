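# Shape rasterizers used as independent fixtures ------------------------

rasterize_disk <- function(r, n = 2 * r + 9) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

rasterize_ellipse <- function(a, b, n = 2 * max(a, b) + 9) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - ctr) / a)^2 + ((j - ctr) / b)^2 <= 1)
}

rasterize_star <- function(r, amp, lobes = 6, n = 2 * (r + amp) + 9) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    phi <- atan2(i - ctr, j - ctr)
    sqrt((i - ctr)^2 + (j - ctr)^2) <= r + amp * cos(lobes * phi)
  })
}

norm_img <- function(pixels, mask = NULL, id = "t") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  roi_image(pixels, mask, id, normalized = TRUE)
}

quantized_img <- function(levels, mask = NULL, G = max(levels) + 1L) {
  img <- norm_img(levels, mask)
  attr(img, "G") <- as.integer(G)
  img
}

# Brute-force GLCM oracle ------------------------------------------------
# Independent of compute_glcm: explicit pixel-pair loops.

oracle_offset <- function(theta, d) {
  switch(as.character(theta),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

oracle_glcm <- function(levels, mask, G, theta, d = 1) {
  off <- oracle_offset(theta, d)
  counts <- matrix(0, G, G)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- levels[r, c]; j <- levels[r2, c2]
        counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
        counts[j + 1, i + 1] <- counts[j + 1, i + 1] + 1
      }
    }
  }
  counts
}

# Brute-force evaluation of the 14 texture features by explicit double
# loops over the probability table; written directly from the feature
# definitions, sharing no code with haralick_features().
oracle_features <- function(p) {
  G <- nrow(p)
  lev <- 0:(G - 1)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  pplus <- numeric(2 * G - 1); pminus <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    pplus[(i - 1) + (j - 1) + 1] <- pplus[(i - 1) + (j - 1) + 1] + p[i, j]
    pminus[abs(i - j) + 1] <- pminus[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  acc <- 0; con <- 0; cor <- 0; cp <- 0; cs <- 0; dis <- 0; ene <- 0
  hom <- 0; idn <- 0; idm <- 0; hxy1 <- 0
  for (i in 1:G) for (j in 1:G) {
    ii <- i - 1; jj <- j - 1; pij <- p[i, j]
    acc <- acc + ii * jj * pij
    con <- con + (ii - jj)^2 * pij
    cor <- cor + (ii - mux) * (jj - muy) * pij
    cp <- cp + (ii + jj - mux - muy)^4 * pij
    cs <- cs + (ii + jj - mux - muy)^3 * pij
    dis <- dis + abs(ii - jj) * pij
    ene <- ene + pij^2
    hom <- hom + pij / (1 + abs(ii - jj))
    idn <- idn + pij / (1 + abs(ii - jj) / G)
    idm <- idm + pij / (1 + (ii - jj)^2)
    if (pij > 0) hxy1 <- hxy1 - pij * log(px[i] * py[j])
  }
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.numeric(p))
  dv <- sum((0:(G - 1))^2 * pminus)
  c(autocorrelation = acc, contrast = con,
    correlation = if (sx == 0 || sy == 0) 0 else cor / (sx * sy),
    cluster_prominence = cp, cluster_shading = cs, dissimilarity = dis,
    energy = ene, entropy = hxy, homogeneity = hom,
    difference_variance = dv, difference_entropy = ent(pminus),
    info_measure_correlation = if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy),
    inverse_difference_normalized = idn, inverse_difference_moment = idm)
}

# random masked image for oracle-equivalence sweeps
random_masked_image <- function(size = 12, G = 8) {
  lev <- matrix(sample(0:(G - 1), size * size, replace = TRUE), size)
  mask <- matrix(stats::runif(size * size) < 0.7, size)
  # guarantee at least one pair in every direction
  mask[2:3, 2:3] <- TRUE
  list(levels = lev, mask = mask, G = as.integer(G))
}

# Synthetic tables for classifier tests ----------------------------------

sim_table <- function(n0 = 20, n1 = 20, effect = 3, noise_features = 0) {
  lab <- c(rep(0L, n0), rep(1L, n1))
  d <- data.frame(label = lab)
  d$signal <- stats::rnorm(n0 + n1) + effect * lab
  if (noise_features > 0)
    for (k in seq_len(noise_features))
      d[[paste0("noise", k)]] <- stats::rnorm(n0 + n1)
  feature_table(d)
}

# small synthetic cohort on disk, cached per test run
small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 5, n_wt = 10, n_mut = 5, image_size = 64, base_radius = 16) {
    key <- paste(seed, n_wt, n_mut, image_size, base_radius, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("idhrad_cohort_", key))
      spec <- cohort_spec(n_wt = n_wt, n_mut = n_mut, image_size = image_size,
                          base_radius = base_radius, seed = seed)
      cache[[key]] <- generate_cohort(spec, dir)
    }
    cache[[key]]
  }
})
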