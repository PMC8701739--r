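# Group statistics: Shapiro-Wilk normality screening, Wilcoxon rank-sum
# two-group comparison, and Spearman rank-correlation structure of
# appliance use.

#' Spearman rank correlation coefficient
#'
#' With tie-free data this is the classical statistic
#' `r = 1 - 6 * sum(d_i^2) / (n * (n^2 - 1))` where `d_i` are the rank
#' differences. With ties, average ranks are used and the coefficient is the
#' product-moment correlation of the ranks (the classical formula assumes
#' distinct ranks). Constant input has undefined rank correlation and
#' returns `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_config("need at least 3 observations")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop_config("need at least 3 complete observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x)
  ry <- rank(y)
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  if (!ties) {
    d <- rx - ry
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    cor(rx, ry)
  }
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample of size 3-5000.
#' @return Tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b` (NA).
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop_config("Shapiro-Wilk requires sample size in 3..5000")
  }
  r <- shapiro.test(x)
  tibble(
    test = "shapiro_wilk", statistic = unname(r$statistic),
    p_value = r$p.value, n_a = length(x), n_b = NA_integer_
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution for small tie-free samples (both below 20),
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return Tibble: `test`, `statistic` (W), `p_value`, `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop_config("samples too small for rank-sum test")
  exact <- length(a) < 20 && length(b) < 20
  r <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble(
    test = "wilcoxon_rank_sum", statistic = unname(r$statistic),
    p_value = r$p.value, n_a = length(a), n_b = length(b)
  )
}

#' Two-group comparison battery over feature variables
#'
#' For each variable: Shapiro-Wilk per group first; if either group rejects
#' normality at `alpha`, the groups are compared with the Wilcoxon rank-sum
#' test, otherwise with a two-sample t-test (a branch rarely taken for
#' sensor count data). No multiple-testing correction by default, matching
#' per-variable reporting at `alpha = 0.05`; Benjamini-Hochberg adjusted
#' p-values are appended when `adjust = TRUE`.
#'
#' @param data Data frame with a group column and numeric variables.
#' @param vars Character vector of variable names to compare.
#' @param group_col Name of the two-level group column (default `"label"`).
#' @param alpha Normality screening level (default 0.05).
#' @param adjust Add BH-adjusted p-values (default `FALSE`).
#' @return Tidy tibble: `variable`, `branch`, `statistic`, `p_value`,
#'   `significant`, plus `p_adj` when `adjust`.
#' @export
compare_groups <- function(data, vars, group_col = "label", alpha = 0.05,
                           adjust = FALSE) {
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop_config("group column must have exactly two levels")
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    a <- data[[v]][g == lv[1]]
    b <- data[[v]][g == lv[2]]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    sw_reject <- function(x) {
      if (length(unique(x)) < 3) return(TRUE) # degenerate: not normal
      if (length(x) > 5000) x <- sample(x, 5000)
      shapiro.test(x)$p.value < alpha
    }
    nonnormal <- sw_reject(a) || sw_reject(b)
    r <- if (nonnormal) {
      suppressWarnings(wilcox.test(a, b, correct = TRUE))
    } else {
      t.test(a, b)
    }
    tibble(
      variable = v, branch = if (nonnormal) "wilcoxon" else "t_test",
      statistic = unname(r$statistic), p_value = r$p.value,
      n_a = length(a), n_b = length(b)
    )
  })
  out <- bind_rows(rows)
  out$significant <- out$p_value < alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Per-group Spearman correlation matrices of appliance use
#'
#' Computes the Spearman correlation matrix of daily appliance-use counts
#' within each group and lists variable pairs ordered by the absolute
#' between-group difference in correlation.
#'
#' @param counts Data frame: one row per person-day, a group column, and one
#'   numeric count column per appliance.
#' @param vars Appliance count columns to correlate.
#' @param group_col Two-level group column (default `"label"`).
#' @return List: `matrices` (named list of correlation matrices) and `diff`
#'   (tibble `var_a`, `var_b`, per-group r, `abs_diff`, sorted descending).
#' @export
appliance_correlations <- function(counts, vars, group_col = "label") {
  g <- factor(counts[[group_col]])
  lv <- levels(g)
  mats <- lapply(lv, function(l) {
    d <- counts[g == l, vars, drop = FALSE]
    m <- diag(1, length(vars))
    dimnames(m) <- list(vars, vars)
    for (i in seq_along(vars)) {
      for (j in seq_along(vars)) {
        if (j > i) {
          r <- suppressWarnings(spearman_r(d[[vars[i]]], d[[vars[j]]]))
          m[i, j] <- m[j, i] <- r
        }
      }
    }
    m
  })
  names(mats) <- lv
  pairs <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  diff <- tibble(
    var_a = vars[pairs[, 1]], var_b = vars[pairs[, 2]],
    r_a = mats[[1]][pairs], r_b = mats[[2]][pairs]
  )
  names(diff)[3:4] <- paste0("r_", lv)
  diff$abs_diff <- abs(diff[[3]] - diff[[4]])
  diff <- arrange(diff, dplyr::desc(.data$abs_diff))
  list(matrices = mats, diff = diff)
}

#' Daily appliance-use counts for the correlation analysis
#'
#' Aggregates channel episodes to one row per person-day with a count column
#' per selected role.
#'
#' @param cohort Output of [generate_cohort()].
#' @param roles Appliance roles to count (defaults to the commonly installed
#'   set: entrance, microwave, stove, TV, washer, pill organizer,
#'   refrigerator, rice cooker, kitchen sink, bathroom faucet).
#' @param thresholds Named list as [default_thresholds()].
#' @return Tibble: `person_id`, `date`, `label`, one count column per role.
#' @export
daily_use_counts <- function(cohort,
                             roles = c(
                               "entrance_door", "microwave", "stove_temp",
                               "tv_plug", "washer_plug", "pill_organizer",
                               "refrigerator", "rice_cooker",
                               "kitchen_sink_faucet", "bathroom_faucet"
                             ),
                             thresholds = default_thresholds()) {
  role_of <- setNames(cohort$household$roster$role, cohort$household$roster$channel_id)
  parts <- lapply(names(cohort$events), function(pid) {
    eps <- channel_episodes(cohort$events[[pid]], thresholds)
    eps$role <- unname(role_of[eps$channel_id])
    eps <- eps[!is.na(eps$role) & eps$role %in% roles, , drop = FALSE]
    eps$date <- as.Date(eps$start, tz = TZ)
    cnt <- dplyr::count(eps, .data$date, .data$role)
    wide <- tidyr::pivot_wider(cnt,
      names_from = "role", values_from = "n",
      values_fill = 0L
    )
    for (r in setdiff(roles, names(wide))) wide[[r]] <- 0L
    wide$person_id <- pid
    wide[, c("person_id", "date", roles)]
  })
  out <- bind_rows(parts)
  join_labels(out, cohort$profiles)
}
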