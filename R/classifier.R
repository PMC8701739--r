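# Random-forest normal-vs-dementia classification: stratified 10-fold
# cross-validation, confusion-matrix metrics, and sampling Shapley feature
# attribution. The positive class is dementia throughout.

#' Confusion-matrix metrics
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1` the harmonic mean
#' of the two, `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A metric with a zero
#' denominator is `NA` (f1 is 0 when precision and recall are both 0).
#'
#' @param tp,fp,fn,tn Confusion counts (positive class = dementia).
#' @return Named numeric vector: `precision`, `recall`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) stop_config("empty confusion matrix")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / total
  )
}

confusion_counts <- function(truth, pred, positive = "dementia") {
  c(
    tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive),
    tn = sum(pred != positive & truth != positive)
  )
}

# stratified fold assignment: shuffles within class, deals folds round-robin
stratified_folds <- function(y, folds) {
  if (any(table(y) < folds)) stop_config("need at least `folds` rows per class")
  f <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Random-forest cross-validation
#'
#' Record-level stratified k-fold cross-validation of a random forest
#' (positive class dementia). Pooled metrics are recomputed from the summed
#' confusion counts across folds, not averaged percentages. Deterministic
#' given `seed`.
#'
#' @param x Data frame / matrix of numeric features.
#' @param y Labels (`normal` / `dementia`), factor or character.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @param mtry Features per split (default floor(sqrt(p))).
#' @return An `adl_model_report`: per-fold confusion counts, pooled
#'   confusion, pooled metrics, the forest refit on all rows (for
#'   attribution), and the fold assignment.
#' @export
rf_crossval <- function(x, y, folds = 10, seed = 1, num_trees = 500,
                        mtry = NULL) {
  x <- as.data.frame(x)
  y <- factor(y, levels = c("normal", "dementia"))
  stopifnot(nrow(x) == length(y))
  mtry <- mtry %||% max(1, floor(sqrt(ncol(x))))
  fold_of <- withr::with_seed(derive_seed(seed, 7), stratified_folds(y, folds))
  per_fold <- matrix(0L, folds, 4, dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    fit <- ranger::ranger(
      x = x[tr, , drop = FALSE], y = y[tr],
      num.trees = num_trees, mtry = min(mtry, ncol(x)),
      seed = derive_seed(seed, 11, k), num.threads = 1,
      verbose = FALSE
    )
    pred <- predict(fit,
      data = x[!tr, , drop = FALSE], num.threads = 1,
      seed = derive_seed(seed, 19, k)
    )$predictions
    per_fold[k, ] <- confusion_counts(y[!tr], pred)
  }
  pooled <- colSums(per_fold)
  final <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, mtry = min(mtry, ncol(x)),
    seed = derive_seed(seed, 13), num.threads = 1, probability = TRUE,
    verbose = FALSE
  )
  structure(
    list(
      per_fold = as_tibble(per_fold) |> mutate(fold = dplyr::row_number()),
      pooled = pooled,
      metrics = classification_metrics(pooled[["tp"]], pooled[["fp"]], pooled[["fn"]], pooled[["tn"]]),
      model = final, folds = folds, fold_of = fold_of,
      n = nrow(x), p = ncol(x), seed = seed
    ),
    class = "adl_model_report"
  )
}

#' @export
print.adl_model_report <- function(x, ...) {
  cat(
    "adl_model_report:", x$folds, "-fold CV on", x$n, "rows x", x$p,
    "features\n  pooled confusion (TP FP FN TN):", x$pooled, "\n  ",
    paste(names(x$metrics), sprintf("%.4f", x$metrics), collapse = "  "), "\n"
  )
  invisible(x)
}

#' Sampling Shapley feature attribution
#'
#' Monte-Carlo permutation estimator of Shapley values for the model's
#' predicted probability of the positive class: for each evaluation row and
#' random feature order, features are switched one at a time from a sampled
#' background row to the evaluation row, and each feature is credited its
#' marginal change in prediction. Importance is the mean absolute Shapley
#' value over evaluation rows. Within each permutation the per-row
#' attributions sum exactly to the prediction difference from the background
#' row.
#'
#' @param model A probability forest (e.g. `$model` of [rf_crossval()]).
#' @param x_eval Rows to explain.
#' @param x_background Background rows (default `x_eval`).
#' @param n_perm Permutations per evaluation row (default 20).
#' @param seed Integer seed.
#' @return Tibble `feature`, `mean_abs_shap`, sorted descending.
#' @export
shapley_importance <- function(model, x_eval, x_background = x_eval,
                               n_perm = 20, seed = 1) {
  x_eval <- as.data.frame(x_eval)
  x_background <- as.data.frame(x_background)
  if (!identical(names(x_eval), names(x_background))) {
    stop_config("evaluation and background features differ")
  }
  p <- ncol(x_eval)
  feats <- names(x_eval)
  predict_pos <- function(d) {
    pr <- predict(model, data = d, num.threads = 1, seed = derive_seed(seed, 3))$predictions
    if (is.matrix(pr)) pr[, "dementia"] else as.numeric(pr == "dementia")
  }
  phi <- matrix(0, nrow(x_eval), p, dimnames = list(NULL, feats))
  withr::with_seed(derive_seed(seed, 17), {
    for (i in seq_len(nrow(x_eval))) {
      for (r in seq_len(n_perm)) {
        ord <- sample.int(p)
        z <- x_background[sample.int(nrow(x_background), 1), , drop = FALSE]
        # chain of p+1 hybrids: background -> progressively x_eval[i, ]
        chain <- z[rep(1, p + 1), , drop = FALSE]
        for (j in seq_len(p)) {
          chain[(j + 1):(p + 1), ord[j]] <- x_eval[i, ord[j]]
        }
        pr <- predict_pos(chain)
        phi[i, ord] <- phi[i, ord] + diff(pr) / n_perm
      }
    }
  })
  out <- tibble(feature = feats, mean_abs_shap = unname(colMeans(abs(phi))))
  attr(out, "phi") <- phi
  arrange(out, dplyr::desc(.data$mean_abs_shap))
}

#' Evaluate the 3 x 2 feature-set design
#'
#' Cross-validates the forest on every cell of {IoT, ADL, IoT+ADL} x
#' {before, after personalization} and tabulates pooled precision, recall,
#' F1 and accuracy per cell. Feature sets select columns by schema family;
#' in the personalized cells each family keeps its own anomaly columns.
#'
#' @param features_raw Labelled raw feature tibble.
#' @param features_pers Labelled personalized feature tibble.
#' @param schema The [feature_schema()] the tables were built with.
#' @param folds,seed,num_trees,mtry Passed to [rf_crossval()].
#' @param importance Compute Shapley attribution for the personalized
#'   IoT+ADL cell (default `FALSE`).
#' @param importance_rows,importance_perms Size of the attribution sample.
#' @return List: `reports` (named list of `adl_model_report`), `summary`
#'   (tibble: feature_set, personalized, precision/recall/f1/accuracy as
#'   percentages), and `importance` (tibble or `NULL`).
#' @export
run_matrix <- function(features_raw, features_pers, schema, folds = 10,
                       seed = 1, num_trees = 500, mtry = NULL,
                       importance = FALSE, importance_rows = 20,
                       importance_perms = 12) {
  sets <- list(IoT = schema$iot, ADL = schema$adl, `IoT+ADL` = schema$all)
  pick <- function(tbl, cols) {
    anom <- intersect(c(paste0("anomaly_", cols), paste0("anomaly_day_", cols)), names(tbl))
    tbl[, c(intersect(cols, names(tbl)), anom), drop = FALSE]
  }
  reports <- list()
  rows <- list()
  for (sn in names(sets)) {
    for (mode in c("raw", "personalized")) {
      tbl <- if (mode == "raw") features_raw else features_pers
      rep <- rf_crossval(
        pick(tbl, sets[[sn]]), tbl$label,
        folds = folds, seed = derive_seed(seed, match(sn, names(sets)), match(mode, c("raw", "personalized"))),
        num_trees = num_trees, mtry = mtry
      )
      key <- paste(sn, mode, sep = "_")
      reports[[key]] <- rep
      rows[[key]] <- tibble(
        feature_set = sn, personalized = mode == "personalized",
        precision = 100 * rep$metrics[["precision"]],
        recall = 100 * rep$metrics[["recall"]],
        f1 = 100 * rep$metrics[["f1"]],
        accuracy = 100 * rep$metrics[["accuracy"]]
      )
    }
  }
  imp <- NULL
  if (importance) {
    best <- reports[["IoT+ADL_personalized"]]
    xb <- pick(features_pers, sets[["IoT+ADL"]])
    idx <- withr::with_seed(
      derive_seed(seed, 23),
      sample.int(nrow(xb), min(importance_rows, nrow(xb)))
    )
    imp <- shapley_importance(
      best$model, xb[idx, , drop = FALSE], xb[idx, , drop = FALSE],
      n_perm = importance_perms, seed = derive_seed(seed, 29)
    )
  }
  list(reports = reports, summary = bind_rows(rows), importance = imp)
}
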