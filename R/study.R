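#' Extract the full radiomic feature table of a cohort
#'
#' Loads every case of the manifest, normalizes it, and computes all three
#' feature families with family-prefixed names: `morph.` (area, perimeter,
#' compactness, NRL mean/SD), `int.` (histogram mean, variance, skewness,
#' kurtosis) and `tex.` (the 14 direction-averaged co-occurrence
#' features). Any failing case aborts the extraction with its id -- silent
#' dropping would change every downstream number at cohort sizes of a few
#' dozen. The result is deterministic for a fixed configuration.
#'
#' @param manifest a `cohort_manifest` from [load_cohort()], or a path to
#'   a manifest CSV.
#' @param glcm_levels gray levels for texture quantization (default 32).
#' @param glcm_distance co-occurrence distance (default 1).
#' @param directions co-occurrence directions in degrees.
#' @param kurtosis_excess intensity-kurtosis convention, see
#'   [histogram_moments()].
#' @return A [feature_table()] with 23 feature columns plus `case_id` and
#'   `label`.
#' @export
extract_features <- function(manifest, glcm_levels = 32L, glcm_distance = 1L,
                             directions = c(0, 45, 90, 135),
                             kurtosis_excess = TRUE) {
  if (is.character(manifest)) manifest <- load_cohort(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$case_id[i]
    feats <- tryCatch({
      img <- load_roi_image(manifest$image[i], manifest$mask[i], case_id = id)
      img <- normalize_intensity(img)
      mo <- morphology_features(img)
      it <- intensity_features(img, kurtosis_excess = kurtosis_excess)
      tx <- texture_feature_vector(img, d = glcm_distance, G = glcm_levels,
                                   directions = directions)
      c(stats::setNames(mo, paste0("morph.", names(mo))),
        stats::setNames(it, paste0("int.", names(it))),
        stats::setNames(tx, paste0("tex.", names(tx))))
    }, error = function(e) {
      stop(sprintf("feature extraction failed for case '%s': %s",
                   id, conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- data.frame(case_id = id, label = manifest$label[i],
                            t(feats), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  feature_table(do.call(rbind, rows))
}

feature_family <- function(table, family) {
  feats <- ft_features(table)
  if (family == "combined") return(feats)
  prefix <- c(morphology = "morph.", intensity = "int.", texture = "tex.")[family]
  out <- feats[startsWith(feats, prefix)]
  if (length(out) == 0)
    stop(sprintf("no '%s' features in the table", family), call. = FALSE)
  out
}

#' Run the comparative feature-set study
#'
#' For each requested feature set (morphology, intensity, texture, or the
#' combined set of all three), selects features by backward elimination,
#' validates by leave-one-out, and summarizes accuracy, sensitivity,
#' specificity and Cohen's kappa. Every requested pair of feature sets is
#' then compared metric-by-metric with the chi-squared test on
#' correct/incorrect counts.
#'
#' @param x a [feature_table()], a `cohort_manifest`, or a manifest path
#'   (features are extracted on the fly for the latter two).
#' @param feature_sets subset of
#'   `c("morphology", "intensity", "texture", "combined")`.
#' @param mode,criterion,ridge passed to [idh_model()].
#' @param select run backward elimination per set (default `TRUE`).
#' @param ... extraction settings passed to [extract_features()] when `x`
#'   is not already a feature table.
#' @return Object of class `study_report`: `models` (named list of
#'   [idh_model()] fits), `performance` (data frame of per-set metrics and
#'   counts), `comparisons` (data frame of pairwise chi-squared tests;
#'   `p` is `NA` where the table is degenerate, e.g. both sets perfect).
#' @export
run_study <- function(x, feature_sets = c("morphology", "intensity", "texture"),
                      mode = c("pooled", "nested"),
                      criterion = c("loocv", "wald"),
                      select = TRUE, ridge = 1e-4, ...) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  feature_sets <- match.arg(feature_sets,
                            c("morphology", "intensity", "texture", "combined"),
                            several.ok = TRUE)
  if (!inherits(x, "feature_table")) x <- extract_features(x, ...)
  models <- list()
  for (fs in feature_sets) {
    feats <- feature_family(x, fs)
    d <- as.data.frame(x)[c("case_id", "label", feats)]
    models[[fs]] <- idh_model(label ~ ., d, select = select, mode = mode,
                              criterion = criterion, ridge = ridge)
  }
  perf <- do.call(rbind, lapply(names(models), function(fs) {
    r <- models[[fs]]$report
    cc <- r$confusion
    data.frame(feature_set = fs, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               kappa = r$kappa, kappa_band = r$kappa_band,
               tp = cc[["tp"]], fn = cc[["fn"]], fp = cc[["fp"]],
               tn = cc[["tn"]], stringsAsFactors = FALSE)
  }))
  comparisons <- study_comparisons(models)
  structure(list(models = models, performance = perf,
                 comparisons = comparisons, mode = mode,
                 criterion = criterion),
            class = "study_report")
}

metric_counts <- function(report, metric) {
  cc <- report$confusion
  switch(metric,
         accuracy = c(cc[["tp"]] + cc[["tn"]], sum(cc)),
         sensitivity = c(cc[["tp"]], cc[["tp"]] + cc[["fn"]]),
         specificity = c(cc[["tn"]], cc[["tn"]] + cc[["fp"]]))
}

study_comparisons <- function(models) {
  sets <- names(models)
  if (length(sets) < 2)
    return(data.frame(metric = character(), set_a = character(),
                      set_b = character(), chi2 = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  pairs <- utils::combn(sets, 2, simplify = FALSE)
  rows <- list()
  for (metric in c("accuracy", "sensitivity", "specificity")) {
    for (pr in pairs) {
      a <- metric_counts(models[[pr[1]]]$report, metric)
      b <- metric_counts(models[[pr[2]]]$report, metric)
      res <- tryCatch(compare_chi_squared(a[1], a[2], b[1], b[2]),
                      error = function(e) list(chi2 = NA_real_, p = NA_real_))
      rows[[length(rows) + 1L]] <-
        data.frame(metric = metric, set_a = pr[1], set_b = pr[2],
                   chi2 = res$chi2, p = res$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Radiomic feature-set study (%s selection, %s validation)\n\n",
              x$criterion, x$mode))
  p <- x$performance
  fmt <- function(num, den, v) sprintf("%2.0f%% (%d/%d)", 100 * v, num, den)
  grid <- data.frame(row.names = p$feature_set,
    accuracy = mapply(fmt, p$tp + p$tn, p$tp + p$fn + p$fp + p$tn, p$accuracy),
    sensitivity = mapply(fmt, p$tp, p$tp + p$fn, p$sensitivity),
    specificity = mapply(fmt, p$tn, p$tn + p$fp, p$specificity),
    kappa = sprintf("%.2f (%s)", p$kappa, p$kappa_band))
  print(t(grid))
  for (fs in p$feature_set) {
    cat(sprintf("\n%s: selected %s\n", fs,
                paste(x$models[[fs]]$subset, collapse = ", ")))
  }
  if (nrow(x$comparisons)) {
    cat("\nPairwise chi-squared comparisons:\n")
    cmp <- x$comparisons
    cmp$chi2 <- round(cmp$chi2, 3)
    cmp$p <- signif(cmp$p, 3)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes per-set performance, selected subsets, pairwise comparisons and
#' per-case leave-one-out probabilities.
#'
#' @param report a [run_study()] result.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  obj <- list(
    mode = report$mode, criterion = report$criterion,
    performance = report$performance,
    selected = lapply(report$models, function(m) m$subset),
    comparisons = report$comparisons,
    predictions = lapply(report$models, function(m) m$predictions)
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a feature table as CSV
#'
#' Cases as rows; `case_id`, `label`, then feature columns.
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_feature_table()] or of the same
#'   layout.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: feature table '%s' does not exist", path),
         call. = FALSE)
  feature_table(utils::read.csv(path, check.names = FALSE,
                                stringsAsFactors = FALSE))
}
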