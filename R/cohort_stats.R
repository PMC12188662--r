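#' Striatal dopamine turnover
#'
#' The metabolite-to-transmitter ratio `(DOPAC + HVA) / dopamine`,
#' vectorised over animals. Invariant to rescaling all three analytes by a
#' common factor.
#'
#' @param dopamine,dopac,hva concentrations (ng per mg protein);
#'   `dopamine > 0`, metabolites >= 0.
#' @return turnover ratio(s).
#' @export
#' @examples
#' dopamine_turnover(10, 2, 3)  # 0.5
dopamine_turnover <- function(dopamine, dopac, hva) {
  if (any(dopamine <= 0)) {
    stop("turnover undefined: dopamine must be > 0", call. = FALSE)
  }
  if (any(dopac < 0) || any(hva < 0)) {
    stop("metabolite concentrations must be >= 0", call. = FALSE)
  }
  (dopac + hva) / dopamine
}

#' Directional fold change between two group means
#'
#' Reports the ratio of the larger mean to the smaller, with its direction:
#' an x-fold increase when `mean_cmp > mean_ref` (cmp/ref) and an x-fold
#' decrease when `mean_cmp < mean_ref` (ref/cmp). Computed on raw means.
#'
#' @param mean_ref,mean_cmp positive group means (reference, comparison).
#' @return list with `fold` (>= 1) and `direction`
#'   (`"increase"`, `"decrease"` or `"none"`).
#' @export
fold_change <- function(mean_ref, mean_cmp) {
  if (mean_ref <= 0 || mean_cmp <= 0) {
    stop("fold change requires positive means", call. = FALSE)
  }
  if (mean_cmp > mean_ref) {
    list(fold = mean_cmp / mean_ref, direction = "increase")
  } else if (mean_cmp < mean_ref) {
    list(fold = mean_ref / mean_cmp, direction = "decrease")
  } else {
    list(fold = 1.0, direction = "none")
  }
}

#' Correlation between two pipeline outputs
#'
#' Spearman's rank correlation (`method = "rank"`, the non-parametric
#' default used for skewed biological measures) or Pearson's linear
#' correlation (`method = "linear"`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"rank"` or `"linear"`.
#' @return list with `coefficient` and `n`.
#' @export
correlate <- function(x, y, method = c("rank", "linear")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- cor(x, y, method = if (method == "rank") "spearman" else "pearson")
  list(coefficient = r, n = length(x))
}

#' Tukey-style outlier exclusion at 3x the interquartile range
#'
#' Excludes values beyond `Q1 - 3 IQR` or `Q3 + 3 IQR` (the study's
#' "outliers >= 3x the interquartile range" rule read as Tukey far-out
#' fences), applied per group and metric by [group_summaries()].
#'
#' @param x numeric vector.
#' @return list: `kept`, `excluded`, `fences`.
#' @export
exclude_outliers <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 3 * iqr; hi <- q[2] + 3 * iqr
  out <- x < lo | x > hi
  list(kept = x[!out], excluded = x[out], fences = c(lower = lo, upper = hi))
}

#' Per-group mean and standard error of a cohort metric
#'
#' @param cohort data.frame with a `group` column.
#' @param metric name of the numeric column to summarise.
#' @param remove_outliers apply [exclude_outliers()] per group first.
#' @return data.frame: `group`, `metric_name`, `n`, `n_missing`,
#'   `n_excluded`, `mean`, `sem` (`NA` when `n < 2`).
#' @export
group_summaries <- function(cohort, metric, remove_outliers = FALSE) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (!metric %in% names(cohort)) {
    stop(sprintf("unknown metric column '%s'", metric), call. = FALSE)
  }
  groups <- unique(cohort$group)
  rows <- lapply(groups, function(g) {
    x <- cohort[[metric]][cohort$group == g]
    n_missing <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) < 1L) stop(sprintf("group '%s' has no values", g),
                             call. = FALSE)
    n_excluded <- 0L
    if (remove_outliers && length(x) >= 4L) {
      ex <- exclude_outliers(x)
      n_excluded <- length(ex$excluded)
      x <- ex$kept
    }
    data.frame(group = g, metric_name = metric, n = length(x),
               n_missing = n_missing, n_excluded = n_excluded,
               mean = mean(x),
               sem = if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level derived statistics from a combined report table
#'
#' Computes per-group summaries of a metric and the directional fold change
#' of each group against a reference group.
#'
#' @param combined combined per-stack table (see [combine_reports()]) with
#'   `group` assigned per stack.
#' @param metric metric column name.
#' @param reference_group group name used as fold-change reference.
#' @param remove_outliers apply the 3x-IQR rule per group.
#' @return list: `summaries` (data.frame), `fold_changes` (data.frame with
#'   `group`, `fold`, `direction`).
#' @export
cohort_metrics <- function(combined, metric, reference_group,
                           remove_outliers = FALSE) {
  summ <- group_summaries(combined, metric, remove_outliers)
  if (!reference_group %in% summ$group) {
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  }
  ref_mean <- summ$mean[summ$group == reference_group]
  fc <- lapply(summ$group, function(g) {
    f <- fold_change(ref_mean, summ$mean[summ$group == g])
    data.frame(group = g, fold = f$fold, direction = f$direction,
               stringsAsFactors = FALSE)
  })
  list(summaries = summ, fold_changes = do.call(rbind, fc))
}
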