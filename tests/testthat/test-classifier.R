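# Confusion-matrix metric identities, cross-validation behavior, and the
# sampling Shapley attribution.

test_that("metrics reproduce the defining equations", {
  got <- classification_metrics(9, 1, 3, 7)
  expect_equal(got[["precision"]], 0.9)
  expect_equal(got[["recall"]], 0.75)
  expect_equal(got[["f1"]], 0.818182, tolerance = 1e-6)
  expect_equal(got[["accuracy"]], 0.8)
  # perfect classifier
  expect_equal(unname(classification_metrics(5, 0, 0, 5)), rep(1, 4))
  # no true positives found
  got0 <- classification_metrics(0, 0, 4, 6)
  expect_equal(got0[["recall"]], 0)
  expect_true(is.na(got0[["precision"]]))
  expect_error(classification_metrics(0, 0, 0, 0), class = "adlsense_config_error")
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(41, {
    cm <- matrix(sample(0:200, 4 * 500, replace = TRUE), ncol = 4)
    cm <- cm[rowSums(cm) > 0 & cm[, 1] + cm[, 2] > 0 & cm[, 1] + cm[, 3] > 0, ]
    for (i in seq_len(nrow(cm))) {
      m <- classification_metrics(cm[i, 1], cm[i, 2], cm[i, 3], cm[i, 4])
      # independent arithmetic
      p <- cm[i, 1] / (cm[i, 1] + cm[i, 2])
      r <- cm[i, 1] / (cm[i, 1] + cm[i, 3])
      expect_equal(m[["precision"]], p)
      expect_equal(m[["recall"]], r)
      if (p + r > 0) expect_equal(m[["f1"]], 2 * p * r / (p + r))
      expect_equal(m[["accuracy"]], (cm[i, 1] + cm[i, 4]) / sum(cm[i, ]))
    }
  })
})

sep_data <- function(n = 120, informative = TRUE, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c("normal", "dementia"), each = n / 2)
    x <- data.frame(
      sig = if (informative) ifelse(y == "dementia", 1, 0) + rnorm(n, 0, 0.01) else rnorm(n),
      noise1 = rnorm(n), noise2 = rnorm(n)
    )
    list(x = x, y = y)
  })
}

test_that("cross-validation is perfect on separable data, chance on noise", {
  d <- sep_data(informative = TRUE)
  rep1 <- rf_crossval(d$x, d$y, folds = 5, seed = 1, num_trees = 100)
  expect_equal(rep1$metrics[["accuracy"]], 1)
  expect_true(all(rowSums(rep1$per_fold[, c("tp", "fp", "fn", "tn")]) > 0))
  # fold partition: every row tested exactly once
  expect_equal(sum(rep1$per_fold$tp + rep1$per_fold$fp + rep1$per_fold$fn + rep1$per_fold$tn), 120)
  expect_equal(sort(unique(rep1$fold_of)), 1:5)
  # pooled metrics recomputed from summed counts
  expect_equal(
    rep1$metrics[["accuracy"]],
    (rep1$pooled[["tp"]] + rep1$pooled[["tn"]]) / sum(rep1$pooled)
  )
  # label-independent features: accuracy near the majority share
  d0 <- sep_data(informative = FALSE, n = 200, seed = 6)
  accs <- vapply(1:3, function(s) {
    rf_crossval(d0$x, sample(d0$y), folds = 5, seed = s, num_trees = 100)$metrics[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  # deterministic given the seed
  rep2 <- rf_crossval(d$x, d$y, folds = 5, seed = 1, num_trees = 100)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_error(rf_crossval(d$x[1:8, ], d$y[1:8], folds = 10), class = "adlsense_config_error")
})

test_that("sampling Shapley attribution ranks informative features first", {
  d <- sep_data(n = 80)
  rep1 <- rf_crossval(d$x, d$y, folds = 4, seed = 2, num_trees = 100)
  imp <- shapley_importance(rep1$model, d$x[1:20, ], d$x, n_perm = 15, seed = 3)
  expect_equal(imp$feature[1], "sig")
  # a constant feature contributes exactly zero
  x2 <- d$x
  x2$flat <- 1
  rep2 <- rf_crossval(x2, d$y, folds = 4, seed = 2, num_trees = 100)
  imp2 <- shapley_importance(rep2$model, x2[1:15, ], x2, n_perm = 10, seed = 4)
  expect_equal(unname(imp2$mean_abs_shap[imp2$feature == "flat"]), 0)
  # with one background row, attributions sum to the prediction difference
  bg <- d$x[1, , drop = FALSE]
  ev <- d$x[45, , drop = FALSE]
  imp3 <- shapley_importance(rep1$model, ev, bg, n_perm = 8, seed = 5)
  phi <- attr(imp3, "phi")
  pr <- function(z) {
    unname(predict(rep1$model, data = z, num.threads = 1)$predictions[, "dementia"])
  }
  expect_equal(sum(phi), pr(ev) - pr(bg), tolerance = 1e-10)
})

test_that("duplicated informative features share Shapley credit", {
  d <- sep_data(n = 80)
  xd <- d$x
  xd$sig2 <- xd$sig + rnorm(80, 0, 1e-6)
  repd <- rf_crossval(xd, d$y, folds = 4, seed = 2, num_trees = 200)
  impd <- shapley_importance(repd$model, xd[1:20, ], xd, n_perm = 15, seed = 6)
  reps <- rf_crossval(d$x, d$y, folds = 4, seed = 2, num_trees = 200)
  imps <- shapley_importance(reps$model, d$x[1:20, ], d$x, n_perm = 15, seed = 6)
  combined <- sum(impd$mean_abs_shap[impd$feature %in% c("sig", "sig2")])
  single <- unname(imps$mean_abs_shap[imps$feature == "sig"])
  expect_equal(combined, single, tolerance = 0.25)
  # and the two copies split it roughly evenly
  pair <- impd$mean_abs_shap[impd$feature %in% c("sig", "sig2")]
  expect_lt(abs(diff(pair)) / max(pair), 0.5)
})

test_that("the 3 x 2 evaluation design fills every cell", {
  cf <- small_features()
  pers <- personalize_features(cf$features, small_cohort()$profiles)
  mat <- run_matrix(cf$features, pers, cf$schema,
    folds = 3, seed = 9, num_trees = 60
  )
  expect_equal(nrow(mat$summary), 6)
  expect_setequal(unique(mat$summary$feature_set), c("IoT", "ADL", "IoT+ADL"))
  expect_true(all(mat$summary$accuracy >= 0 & mat$summary$accuracy <= 100))
  # the personalized IoT+ADL cell uses the full schema plus anomaly columns
  expect_equal(mat$reports[["IoT+ADL_personalized"]]$p, 3 * length(cf$schema$all))
  expect_equal(mat$reports[["IoT+ADL_raw"]]$p, length(cf$schema$all))
  # per-cell determinism under the same seed
  mat2 <- run_matrix(cf$features, pers, cf$schema,
    folds = 3, seed = 9, num_trees = 60
  )
  expect_identical(mat$summary, mat2$summary)
})
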