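test_that("feature tables are validated for completeness and class balance", {
  d <- data.frame(label = c(0, 0, 1, 1), f1 = 1:4, f2 = c(0.5, 1, 2, 3))
  ft <- feature_table(d)
  expect_s3_class(ft, "feature_table")
  expect_equal(ft$case_id, paste0("case_", 1:4))
  expect_error(feature_table(data.frame(label = c(0, 2, 1), f = 1:3)), "binary")
  expect_error(feature_table(data.frame(label = c(0, 0, 0, 1), f = 1:4)),
               "2 cases per class")
  d2 <- d; d2$f1[2] <- NA
  expect_error(feature_table(d2), "non-finite|numeric")
})

test_that("logistic fits point the right way and standardize internally", {
  set.seed(1)
  d <- data.frame(label = rep(c(0L, 1L), each = 15))
  d$f <- d$label + stats::rnorm(30, sd = 0.05)
  ft <- feature_table(d)
  m <- fit_logistic(ft, "f")
  expect_gt(m$coefficients[["f"]], 0)
  p <- predict(m, ft, type = "response")
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict(m, ft, type = "class"), as.integer(p >= 0.5))
  expect_error(fit_logistic(feature_table(
    data.frame(label = c(0, 0, 1, 1), f = 1:4))[1:2, ], "f"), "class")
})

test_that("a perfectly separable table triggers the flagged ridge fallback", {
  d <- data.frame(label = rep(c(0L, 1L), each = 5), f = c(1:5, 101:105) * 1.0)
  m <- fit_logistic(feature_table(d), "f")
  expect_true(m$separation)
  expect_true(all(is.finite(c(m$intercept, m$coefficients))))
  p <- predict(m, d, type = "response")
  expect_true(all(p > 0 & p < 1))
})

test_that("an uninformative feature yields a small coefficient and majority-rate LOOCV", {
  set.seed(202)
  d <- data.frame(label = c(rep(0L, 130), rep(1L, 70)), f = stats::rnorm(200))
  ft <- feature_table(d)
  m <- fit_logistic(ft, "f")
  expect_lt(abs(m$coefficients[["f"]]), 0.5)
  pr <- loocv(ft, "f")
  maj <- 130 / 200
  expect_lt(abs(mean(pr$predicted == pr$truth) - maj),
            2.5 * sqrt(maj * (1 - maj) / 200))
})

test_that("leave-one-out bookkeeping holds and is invariant to case order", {
  set.seed(77)
  ft <- sim_table(n0 = 7, n1 = 5, effect = 2, noise_features = 1)
  pr <- loocv(ft)
  expect_equal(nrow(pr), 12)
  expect_equal(pr$case_id, ft$case_id)   # each case held out once, in order
  expect_equal(pr$predicted, as.integer(pr$probability >= 0.5))
  perm <- sample(nrow(ft))
  ftp <- ft[perm, ]; class(ftp) <- class(ft)
  prp <- loocv(ftp)
  expect_equal(prp$probability[order(perm)], pr$probability, tolerance = 1e-9)
  expect_error(loocv(ft[1:2, ]), "at least 3")
})

test_that("strong separation is recovered and destroyed by permutation", {
  set.seed(55)
  ft <- sim_table(n0 = 32, n1 = 7, effect = 3)
  pr <- loocv(ft, "signal")
  expect_gte(mean(pr$predicted == pr$truth), 0.9)
  set.seed(56)
  d2 <- as.data.frame(ft)
  d2$label <- sample(d2$label)
  prp <- loocv(feature_table(d2), "signal")
  maj <- 32 / 39
  expect_lt(abs(mean(prp$predicted == prp$truth) - maj),
            2.5 * sqrt(maj * (1 - maj) / 39))
})

test_that("backward elimination keeps the informative feature and drops noise", {
  set.seed(303)
  ft <- sim_table(n0 = 20, n1 = 20, effect = 3, noise_features = 3)
  tr <- backward_eliminate(ft)
  expect_true("signal" %in% tr$final_subset)
  expect_lte(tr$final_error, tr$start_error)
  # accepted errors never increase along the trace
  if (nrow(tr$steps) > 1) expect_true(all(diff(tr$steps$error) <= 0))

  # all-noise table: trace terminates, error near the majority rate
  set.seed(304)
  dn <- data.frame(label = c(rep(0L, 26), rep(1L, 13)))
  for (k in 1:3) dn[[paste0("noise", k)]] <- stats::rnorm(39)
  trn <- backward_eliminate(feature_table(dn))
  expect_true(length(trn$final_subset) >= 1)
  expect_lt(trn$final_error, 0.5)

  # nothing to remove from a single-feature start
  tr1 <- backward_eliminate(ft, "signal")
  expect_equal(nrow(tr1$steps), 0)
  expect_equal(tr1$final_subset, "signal")
})

test_that("the Wald-criterion variant also retains the informative feature", {
  set.seed(404)
  ft <- sim_table(n0 = 20, n1 = 20, effect = 3, noise_features = 2)
  tr <- backward_eliminate(ft, criterion = "wald")
  expect_true("signal" %in% tr$final_subset)
})

test_that("the idh_model object carries its methods end to end", {
  set.seed(21)
  d <- data.frame(label = rep(c(0L, 1L), each = 12))
  d$good <- d$label + stats::rnorm(24, sd = 0.4)
  d$junk <- stats::rnorm(24)
  m <- idh_model(label ~ ., d)
  expect_s3_class(m, "idh_model")
  expect_true("good" %in% m$subset)
  expect_equal(nrow(m$predictions), 24)
  expect_equal(sum(m$report$confusion), 24)
  expect_named(coef(m)[1], "(Intercept)")
  expect_equal(length(fitted(m)), 24)
  expect_equal(residuals(m, type = "response"), d$label - fitted(m))
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(24, 3))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(summary(m)), "Leave-one-out performance")
  # nested mode produces one prediction per case too
  mn <- idh_model(label ~ ., d, mode = "nested")
  expect_equal(nrow(mn$predictions), 24)
  # JSON dump round-trips the subset and coefficients
  j <- jsonlite::fromJSON(model_to_json(m))
  expect_equal(j$feature_subset, m$subset)
  expect_equal(j$separation, m$model$separation)
})
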