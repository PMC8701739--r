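# Cognitive-ability-stratified IQR personalization: each person's own
# feature history defines per-feature quartile bounds Q1 - k*IQR / Q3 +
# k*IQR, with the multiplier k shrinking as MMSE falls, so the same
# deviation is flagged more readily for lower cognitive levels.

COGNITIVE_GROUPS <- data.frame(
  group_label = c("no_decline", "very_mild", "mild", "moderate"),
  mmse_min = c(30L, 27L, 24L, 0L),
  mmse_max = c(30L, 29L, 26L, 23L),
  k = c(1.5, 1.2, 1.0, 0.5)
)

#' Assign the cognitive group and IQR multiplier for an MMSE score
#'
#' MMSE 30 is no cognitive decline (k = 1.5), 27-29 very mild (k = 1.2),
#' 24-26 mild (k = 1.0), and 23 or below moderate decline (k = 0.5). The
#' multiplier is monotone non-increasing in declining cognition, so lower
#' cognitive levels get stricter anomaly criteria.
#'
#' @param mmse MMSE score(s), 0-30.
#' @return Tibble: `mmse`, `group_label`, `k`.
#' @export
assign_cognitive_group <- function(mmse) {
  if (any(mmse < 0 | mmse > 30)) stop_config("mmse must lie in 0..30")
  idx <- vapply(mmse, function(m) {
    which(m >= COGNITIVE_GROUPS$mmse_min & m <= COGNITIVE_GROUPS$mmse_max)[1]
  }, integer(1))
  tibble(
    mmse = mmse,
    group_label = COGNITIVE_GROUPS$group_label[idx],
    k = COGNITIVE_GROUPS$k[idx]
  )
}

#' Fit per-feature IQR anomaly bounds from history
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7); bounds are
#' `Q1 - k * IQR` and `Q3 + k * IQR`. Histories shorter than `min_history`
#' yield an unavailable baseline (`available = FALSE`), under which no value
#' is flagged.
#'
#' @param history Numeric matrix or data frame of past bins (rows) by
#'   features (columns).
#' @param k IQR multiplier from [assign_cognitive_group()].
#' @param min_history Minimum number of history bins (default 24).
#' @return Tibble: `feature`, `q1`, `q3`, `iqr`, `lower`, `upper`,
#'   `n_history`, `available`.
#' @export
fit_baseline <- function(history, k, min_history = 24) {
  if (!k %in% COGNITIVE_GROUPS$k) stop_config("k must be one of 1.5, 1.2, 1.0, 0.5")
  m <- as.matrix(history)
  n <- nrow(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (n < min_history) {
    return(tibble(
      feature = colnames(m), q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
      lower = NA_real_, upper = NA_real_, n_history = n, available = FALSE
    ))
  }
  q <- apply(m, 2, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7)
  q1 <- unname(q[1, ])
  q3 <- unname(q[2, ])
  iqr <- q3 - q1
  tibble(
    feature = colnames(m), q1 = q1, q3 = q3, iqr = iqr,
    lower = q1 - k * iqr, upper = q3 + k * iqr,
    n_history = n, available = TRUE
  )
}

# flag values outside [lower, upper]; unavailable baselines flag nothing
flag_anomalies <- function(values, baseline) {
  lo <- baseline$lower[match(colnames(values), baseline$feature)]
  hi <- baseline$upper[match(colnames(values), baseline$feature)]
  av <- baseline$available[match(colnames(values), baseline$feature)]
  fl <- sweep(values, 2, lo, "<") | sweep(values, 2, hi, ">")
  fl[, !av | is.na(av)] <- FALSE
  storage.mode(fl) <- "integer"
  fl
}

#' Personalized anomaly transform for one person's feature vectors
#'
#' Baselines are causal and expanding: each calendar day is scored against
#' the quartile bounds of *all* bins strictly before that day (refreshed at
#' day boundaries), and at least `min_history` prior bins are required
#' before flags switch on. Emits, per feature, a per-bin indicator
#' `anomaly_<feature>` and a within-day running anomaly count
#' `anomaly_day_<feature>`. The personalized dataset keeps the raw features
#' (mode `"augment"`) or replaces them (mode `"replace"`).
#'
#' @param features Feature tibble for one person (`person_id`, `bin_start`,
#'   feature columns).
#' @param k IQR multiplier for the person's cognitive group.
#' @param feature_cols Feature columns to score (default: all numeric
#'   feature columns).
#' @param min_history Minimum history bins (default 24).
#' @param mode `"augment"` (default) or `"replace"`.
#' @return Tibble with the anomaly columns appended (or substituted).
#' @export
anomaly_transform <- function(features, k, feature_cols = NULL,
                              min_history = 24, mode = c("augment", "replace")) {
  mode <- match.arg(mode)
  stopifnot(length(unique(features$person_id)) <= 1)
  features <- arrange(features, .data$bin_start)
  feature_cols <- feature_cols %||%
    setdiff(names(features), c("person_id", "bin_start", "label"))
  vals <- as.matrix(features[, feature_cols])
  t <- as.numeric(features$bin_start)
  day <- floor_bin(t, 86400)
  flags <- matrix(0L, nrow(vals), ncol(vals), dimnames = list(NULL, feature_cols))
  for (d in unique(day)) {
    hist_rows <- which(day < d)
    score_rows <- which(day == d)
    if (length(hist_rows) >= min_history) {
      bl <- fit_baseline(vals[hist_rows, , drop = FALSE], k, min_history)
      flags[score_rows, ] <- flag_anomalies(vals[score_rows, , drop = FALSE], bl)
    }
  }
  # within-day running counts
  daycnt <- flags
  for (d in unique(day)) {
    r <- which(day == d)
    daycnt[r, ] <- apply(flags[r, , drop = FALSE], 2, cumsum)
  }
  colnames(flags) <- paste0("anomaly_", feature_cols)
  colnames(daycnt) <- paste0("anomaly_day_", feature_cols)
  base <- if (mode == "augment") {
    features
  } else {
    features[, setdiff(names(features), feature_cols)]
  }
  dplyr::bind_cols(base, as_tibble(flags), as_tibble(daycnt))
}

#' Personalize a labelled cohort feature table
#'
#' Looks up each person's IQR multiplier from their MMSE score (Table of
#' cognitive groups in [assign_cognitive_group()]) and applies
#' [anomaly_transform()] person by person.
#'
#' @param features Labelled feature tibble (from [cohort_features()]).
#' @param profiles Profile tibble with `person_id` and `mmse`.
#' @param min_history,mode Passed to [anomaly_transform()].
#' @return Personalized feature tibble (row order: person, then time).
#' @export
personalize_features <- function(features, profiles, min_history = 24,
                                 mode = c("augment", "replace")) {
  mode <- match.arg(mode)
  ks <- assign_cognitive_group(profiles$mmse)$k
  names(ks) <- profiles$person_id
  missing <- setdiff(unique(features$person_id), names(ks))
  if (length(missing)) {
    stop_config(paste0("no profile for person(s): ", paste(missing, collapse = ", ")))
  }
  feature_cols <- setdiff(names(features), c("person_id", "bin_start", "label"))
  parts <- lapply(split(features, features$person_id), function(f) {
    anomaly_transform(f, ks[[f$person_id[1]]], feature_cols, min_history, mode)
  })
  bind_rows(parts)
}
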