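#' Validate a per-case feature table
#'
#' The classifier consumes a data frame with one row per case: an optional
#' `case_id` column, a binary `label` column (1 = IDH-mutant, 0 = wild
#' type) and numeric feature columns. This checks completeness (no missing
#' or non-finite values), unique case ids and feature names, and at least
#' two cases in each class.
#'
#' @param df data frame as above.
#' @param label_col name of the label column (default `"label"`).
#' @param id_col name of the case-id column; created as `case_1 ...` when
#'   absent.
#' @return The validated data frame with class `feature_table`, columns
#'   reordered to `case_id`, `label`, features.
#' @export
feature_table <- function(df, label_col = "label", id_col = "case_id") {
  stopifnot(is.data.frame(df))
  if (!label_col %in% names(df))
    stop(sprintf("no label column '%s'", label_col), call. = FALSE)
  lab <- df[[label_col]]
  if (!all(lab %in% c(0, 1)))
    stop("validation error: labels must be binary 0/1", call. = FALSE)
  if (!id_col %in% names(df)) {
    df[[id_col]] <- paste0("case_", seq_len(nrow(df)))
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("validation error: duplicated case ids", call. = FALSE)
  feats <- setdiff(names(df), c(label_col, id_col))
  if (length(feats) == 0)
    stop("feature table has no feature columns", call. = FALSE)
  if (anyDuplicated(feats))
    stop("validation error: duplicated feature names", call. = FALSE)
  vals <- df[feats]
  if (!all(vapply(vals, is.numeric, logical(1))))
    stop("validation error: feature columns must be numeric", call. = FALSE)
  if (!all(vapply(vals, function(x) all(is.finite(x)), logical(1))))
    stop("validation error: non-finite feature values", call. = FALSE)
  if (min(table(factor(lab, levels = c(0, 1)))) < 2)
    stop("validation error: need at least 2 cases per class", call. = FALSE)
  out <- data.frame(case_id = ids, label = as.integer(lab), vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

ft_features <- function(table) setdiff(names(table), c("case_id", "label"))

check_subset <- function(table, subset) {
  if (length(subset) == 0)
    stop("feature subset must be non-empty", call. = FALSE)
  missing <- setdiff(subset, ft_features(table))
  if (length(missing))
    stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  subset
}

#' Fit a binary logistic-regression model on a feature subset
#'
#' Maximum-likelihood logistic regression of the IDH label on standardized
#' features (per-feature mean and standard deviation are estimated on the
#' training cases and stored in the model, so prediction applies the same
#' transform). If the fit shows quasi-complete separation -- probable with
#' 7 mutants against 32 wild-types -- the model falls back to a weakly
#' ridge-penalized fit (penalty `ridge` on standardized coefficients,
#' intercept unpenalized) and is flagged.
#'
#' @param table a [feature_table()].
#' @param subset character vector of feature names; default all features.
#' @param ridge penalty used only on detected separation (default `1e-4`).
#' @return Object of class `logistic_model`: `intercept`, `coefficients`
#'   (named, on the standardized scale), `feature_subset`, `center`,
#'   `scale`, `separation` flag.
#' @export
fit_logistic <- function(table, subset = ft_features(table), ridge = 1e-4) {
  table <- if (inherits(table, "feature_table")) table else feature_table(table)
  subset <- check_subset(table, subset)
  y <- table$label
  if (length(unique(y)) < 2)
    stop("fit error: only one class present", call. = FALSE)
  X <- as.matrix(table[subset])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1  # constant feature: leave centered at 0
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, Z), y,
                   family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta)) || max(abs(beta[-1])) > 20)
    sep <- TRUE
  if (sep)
    beta <- ridge_logistic(Z, y, lambda = ridge)
  structure(list(intercept = unname(beta[1]),
                 coefficients = stats::setNames(beta[-1], subset),
                 feature_subset = subset, center = ctr, scale = scl,
                 separation = sep),
            class = "logistic_model")
}

# ridge-penalized logistic regression by iteratively reweighted least
# squares; lambda on slopes only. Used as the separation fallback.
ridge_logistic <- function(Z, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(Z)
  X1 <- cbind(1, Z)
  beta <- rep(0, p + 1)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d feature(s)%s\n", length(x$feature_subset),
              if (x$separation) " [separation fallback: ridge]" else ""))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Predicted mutation probabilities from a logistic model
#'
#' @param object a [fit_logistic()] model.
#' @param newdata data frame containing the model's feature columns.
#' @param type `"response"` (probability, default), `"link"` (log-odds) or
#'   `"class"` (0/1 at the 0.5 threshold).
#' @param ... unused.
#' @return Numeric (or integer for `"class"`) vector, one value per row.
#' @export
predict.logistic_model <- function(object, newdata,
                                   type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$feature_subset, names(newdata))
  if (length(missing))
    stop(sprintf("newdata lacks feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  X <- as.matrix(as.data.frame(newdata)[object$feature_subset])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  eta <- drop(object$intercept + Z %*% object$coefficients)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) >= 0.5))
}

#' Leave-one-out cross-validated predictions
#'
#' Each case is predicted by a model trained on the remaining n - 1 cases;
#' feature standardization is re-estimated inside every fold, so no
#' information from the held-out case enters its own prediction. The
#' predicted class is 1 when the mutation probability reaches 0.5.
#'
#' @param table a [feature_table()] with at least 3 cases.
#' @param subset feature names to use; default all.
#' @param ridge separation fallback penalty, see [fit_logistic()].
#' @return Data frame of class `case_predictions`: `case_id`,
#'   `probability`, `predicted`, `truth`; one row per case, input order.
#' @export
loocv <- function(table, subset = ft_features(table), ridge = 1e-4) {
  table <- if (inherits(table, "feature_table")) table else feature_table(table)
  subset <- check_subset(table, subset)
  n <- nrow(table)
  if (n < 3) stop("leave-one-out needs at least 3 cases", call. = FALSE)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train$label)) < 2)
      stop(sprintf("fold error: training set for held-out case '%s' has a single class",
                   table$case_id[i]), call. = FALSE)
    m <- fit_logistic(train, subset, ridge = ridge)
    prob[i] <- predict(m, table[i, , drop = FALSE], type = "response")
  }
  structure(data.frame(case_id = table$case_id, probability = prob,
                       predicted = as.integer(prob >= 0.5),
                       truth = table$label, stringsAsFactors = FALSE),
            class = c("case_predictions", "data.frame"))
}

loocv_error <- function(table, subset, ridge = 1e-4) {
  pr <- loocv(table, subset, ridge = ridge)
  mean(pr$predicted != pr$truth)
}

#' Stepwise backward feature elimination
#'
#' Greedy wrapper selection: starting from `start_subset`, each step
#' evaluates the leave-one-out error of dropping every remaining feature
#' and removes the one whose removal gives the lowest error. Steps are
#' accepted while the best removal does not increase the current error
#' (ties favor the smaller subset; among tied features, alphabetical
#' order), so the retained subset is the lowest-error set visited and the
#' procedure is fully deterministic. With `criterion = "wald"` the drop
#' choice instead removes the feature with the largest Wald p-value while
#' that p-value exceeds `p_out` (the classical regression-style backward
#' procedure); errors along the trace are still leave-one-out errors.
#'
#' @param table a [feature_table()].
#' @param start_subset feature names to start from; default all.
#' @param criterion `"loocv"` (default) or `"wald"`.
#' @param p_out Wald removal threshold (default 0.10), `criterion = "wald"`
#'   only.
#' @param ridge separation fallback penalty.
#' @return Object of class `elimination_trace`: `steps` (data frame of
#'   `removed` / `error` after each accepted removal), `start_error`,
#'   `final_subset`, `final_error`.
#' @export
backward_eliminate <- function(table, start_subset = ft_features(table),
                               criterion = c("loocv", "wald"), p_out = 0.10,
                               ridge = 1e-4) {
  criterion <- match.arg(criterion)
  table <- if (inherits(table, "feature_table")) table else feature_table(table)
  subset <- sort(check_subset(table, start_subset))
  cur_err <- loocv_error(table, subset, ridge = ridge)
  start_err <- cur_err
  removed <- character(0)
  errors <- numeric(0)
  while (length(subset) > 1) {
    if (criterion == "loocv") {
      cand_err <- vapply(subset, function(f)
        loocv_error(table, setdiff(subset, f), ridge = ridge), numeric(1))
      best <- min(cand_err)
      if (best > cur_err) break
      drop_f <- subset[which(cand_err == best)[1]]  # subset is sorted
      cur_err <- best
    } else {
      pv <- wald_p_values(table, subset, ridge = ridge)
      if (max(pv) <= p_out) break
      drop_f <- subset[which.max(pv)]
      cur_err <- loocv_error(table, setdiff(subset, drop_f), ridge = ridge)
    }
    subset <- setdiff(subset, drop_f)
    removed <- c(removed, drop_f)
    errors <- c(errors, cur_err)
  }
  structure(list(steps = data.frame(removed = removed, error = errors,
                                    stringsAsFactors = FALSE),
                 start_error = start_err,
                 final_subset = subset, final_error = cur_err),
            class = "elimination_trace")
}

# Wald p-values of the slope coefficients of an unpenalized fit (falls
# back to the ridge fit's curvature on separation).
wald_p_values <- function(table, subset, ridge = 1e-4) {
  m <- fit_logistic(table, subset, ridge = ridge)
  X <- as.matrix(table[subset])
  Z <- sweep(sweep(X, 2, m$center), 2, m$scale, `/`)
  X1 <- cbind(1, Z)
  eta <- drop(X1 %*% c(m$intercept, m$coefficients))
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X1 * w) %*% X1
  if (m$separation) info <- info + diag(c(0, rep(ridge, ncol(Z))))
  se <- sqrt(diag(solve(info)))[-1]
  z <- m$coefficients / se
  stats::setNames(2 * stats::pnorm(-abs(z)), subset)
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> start error %.3f -> final error %.3f\n",
              x$start_error, x$final_error))
  if (nrow(x$steps)) {
    cat("removed:\n")
    print(x$steps, row.names = FALSE)
  } else {
    cat("no features removed\n")
  }
  cat("retained:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}
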