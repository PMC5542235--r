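#' Fit a radiomic IDH-status classifier
#'
#' The package's central model object: binary logistic regression of IDH
#' mutation status on radiomic features, with optional stepwise backward
#' feature elimination selected by leave-one-out error, and leave-one-out
#' validation of the result.
#'
#' Two validation placements are offered. `mode = "pooled"` (default)
#' selects the feature subset once on all cases and then runs leave-one-out
#' on that fixed subset -- the classical radiomics protocol, which leaks
#' the selection step and is therefore optimistic. `mode = "nested"`
#' re-runs the elimination inside every leave-one-out fold, so the held-out
#' case never influences the subset that predicts it; the reported subset
#' is still the full-data selection, but the performance estimate is
#' leakage-free.
#'
#' @param formula model formula, e.g. `label ~ .` for all features; the
#'   left-hand side names the binary label column (1 = IDH-mutant). A
#'   `case_id` column, when present, identifies cases in the output.
#' @param data data frame with one row per case.
#' @param select run backward elimination (default `TRUE`); otherwise the
#'   full right-hand side is used as-is.
#' @param mode `"pooled"` or `"nested"` (see above).
#' @param criterion elimination criterion, `"loocv"` error (default) or
#'   `"wald"` p-values; see [backward_eliminate()].
#' @param ridge separation fallback penalty, see [fit_logistic()].
#' @return Object of class `idh_model`: the validated `table`, selection
#'   `trace` (or `NULL`), selected `subset`, final fitted `model`
#'   (a `logistic_model` on all cases), leave-one-out `predictions`
#'   (a `case_predictions` frame) and their `report`
#'   (a `performance_report`).
#' @examples
#' set.seed(7)
#' d <- data.frame(label = rep(c(0, 1), each = 10))
#' d$good <- d$label + rnorm(20, sd = 0.4)
#' d$noise <- rnorm(20)
#' m <- idh_model(label ~ ., d)
#' summary(m)
#' @export
idh_model <- function(formula, data, select = TRUE,
                      mode = c("pooled", "nested"),
                      criterion = c("loocv", "wald"), ridge = 1e-4) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  cl <- match.call()
  data <- as.data.frame(data)
  label_col <- as.character(formula[[2]])
  rhs_df <- data[setdiff(names(data), c(label_col, "case_id"))]
  tf <- stats::terms(formula, data = cbind(rhs_df, stats::setNames(
    data[label_col], label_col)))
  feats <- attr(tf, "term.labels")
  keep <- c(intersect("case_id", names(data)), label_col, feats)
  ft <- feature_table(data[keep], label_col = label_col)
  trace <- NULL
  subset <- feats
  if (select) {
    trace <- backward_eliminate(ft, feats, criterion = criterion,
                                ridge = ridge)
    subset <- trace$final_subset
  }
  preds <- if (mode == "nested" && select) {
    nested_loocv(ft, feats, criterion = criterion, ridge = ridge)
  } else {
    loocv(ft, subset, ridge = ridge)
  }
  model <- fit_logistic(ft, subset, ridge = ridge)
  structure(list(call = cl, formula = formula, table = ft, mode = mode,
                 criterion = criterion, select = select, trace = trace,
                 subset = subset, model = model, predictions = preds,
                 report = performance_report(preds), ridge = ridge),
            class = "idh_model")
}

# leakage-free variant: redo elimination inside each fold
nested_loocv <- function(ft, feats, criterion, ridge) {
  n <- nrow(ft)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    train <- ft[-i, , drop = FALSE]
    class(train) <- class(ft)
    if (length(unique(train$label)) < 2)
      stop(sprintf("fold error: training set for held-out case '%s' has a single class",
                   ft$case_id[i]), call. = FALSE)
    tr <- backward_eliminate(train, feats, criterion = criterion, ridge = ridge)
    m <- fit_logistic(train, tr$final_subset, ridge = ridge)
    prob[i] <- predict(m, ft[i, , drop = FALSE], type = "response")
  }
  structure(data.frame(case_id = ft$case_id, probability = prob,
                       predicted = as.integer(prob >= 0.5),
                       truth = ft$label, stringsAsFactors = FALSE),
            class = c("case_predictions", "data.frame"))
}

#' @export
print.idh_model <- function(x, ...) {
  cat("Radiomic IDH logistic model\n")
  cat(sprintf("  %d cases (%d mutant), %s selection (%s), %s validation\n",
              nrow(x$table), sum(x$table$label),
              if (x$select) "backward" else "no", x$criterion, x$mode))
  cat(sprintf("  features: %s\n", paste(x$subset, collapse = ", ")))
  cat(sprintf("  leave-one-out accuracy %.3f, kappa %.3f (%s)\n",
              x$report$accuracy, x$report$kappa, x$report$kappa_band))
  invisible(x)
}

#' @export
summary.idh_model <- function(object, ...) {
  structure(list(model = object), class = "summary.idh_model")
}

#' @export
print.summary.idh_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$trace)) {
    cat("\nBackward elimination:\n")
    print(m$trace)
  }
  cat("\nFinal coefficients (standardized features):\n")
  print(stats::coef(m))
  if (m$model$separation)
    cat("note: separation detected; ridge fallback used\n")
  cat("\nLeave-one-out performance:\n")
  print(m$report)
  invisible(x)
}

#' @export
coef.idh_model <- function(object, ...) {
  c(`(Intercept)` = object$model$intercept, object$model$coefficients)
}

#' @export
predict.idh_model <- function(object, newdata = NULL,
                              type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$table
  predict(object$model, newdata, type = type)
}

#' @export
fitted.idh_model <- function(object, ...) {
  predict(object$model, object$table, type = "response")
}

#' @export
residuals.idh_model <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$table$label
  mu <- fitted(object)
  if (type == "response") return(y - mu)
  d2 <- -2 * (y * log(pmax(mu, 1e-15)) + (1 - y) * log(pmax(1 - mu, 1e-15)))
  sign(y - mu) * sqrt(pmax(d2, 0))
}

#' Simulate label vectors from the fitted model
#'
#' Draws Bernoulli labels from the model's fitted mutation probabilities,
#' one column per replicate, as a parametric-bootstrap building block.
#'
#' @param object an [idh_model()].
#' @param nsim number of replicates.
#' @param seed optional integer passed to `set.seed`.
#' @param ... unused.
#' @return Data frame of `nsim` simulated 0/1 label columns.
#' @export
simulate.idh_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$table$case_id
  out
}

#' Plot leave-one-out mutation probabilities by true status
#'
#' Strip chart of per-case cross-validated probabilities against the true
#' class, with the 0.5 decision threshold; misclassified cases sit on the
#' wrong side of the line.
#'
#' @param x an [idh_model()].
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.idh_model <- function(x, ...) {
  pr <- x$predictions
  grp <- factor(pr$truth, levels = c(0, 1),
                labels = c("IDH wild-type", "IDH-mutant"))
  graphics::stripchart(pr$probability ~ grp, vertical = TRUE, pch = 19,
                       method = "jitter", jitter = 0.08,
                       col = c("#3366aa", "#cc3344"),
                       ylab = "leave-one-out P(mutant)", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Serialize a logistic model to JSON
#'
#' Dumps subset, coefficients, standardization constants and the
#' separation flag, so a fitted classifier can be stored or shipped.
#'
#' @param model a `logistic_model` or an [idh_model()] (its final model is
#'   taken).
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  if (inherits(model, "idh_model")) model <- model$model
  stopifnot(inherits(model, "logistic_model"))
  obj <- list(feature_subset = model$feature_subset,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              center = as.list(model$center),
              scale = as.list(model$scale),
              separation = model$separation)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
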