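# pairwise IoU between every overlapping (pred, truth) instance pair;
# returns data.frame(pred, truth, iou)
pairwise_instance_iou <- function(pred, truth) {
  pred <- label_array(pred); truth <- label_array(truth)
  np <- max(0L, max(pred)); nt <- max(0L, max(truth))
  if (np == 0L || nt == 0L) {
    return(data.frame(pred = integer(0), truth = integer(0), iou = numeric(0)))
  }
  area_p <- tabulate(pred[pred > 0L], nbins = np)
  area_t <- tabulate(truth[truth > 0L], nbins = nt)
  sel <- pred > 0L & truth > 0L
  if (!any(sel)) {
    return(data.frame(pred = integer(0), truth = integer(0), iou = numeric(0)))
  }
  code <- (as.numeric(pred[sel]) - 1) * nt + as.numeric(truth[sel])
  tab <- table(code)
  codes <- as.numeric(names(tab))
  ip <- floor((codes - 1) / nt) + 1
  it <- codes - (ip - 1) * nt
  inter <- as.numeric(tab)
  data.frame(pred = as.integer(ip), truth = as.integer(it),
             iou = inter / (area_p[ip] + area_t[it] - inter))
}

#' Match predicted to true instances and count the confusion entries
#'
#' One-to-one greedy matching by descending pairwise IoU; a pair is
#' eligible iff its IoU is at least `match_iou_min` (default 0.5, the
#' de-facto instance-segmentation standard). TP = matched pairs, FP =
#' unmatched predictions, FN = unmatched truths, so `TP + FP` equals the
#' number of predictions and `TP + FN` the number of truths. Works on 2D or
#' 3D label images.
#'
#' @param pred_labels,true_labels integer label arrays of equal shape.
#' @param match_iou_min eligibility threshold in `[0, 1]`.
#' @return named integer vector `c(TP, FP, FN)`.
#' @export
match_instances <- function(pred_labels, true_labels, match_iou_min = 0.5) {
  p <- label_array(pred_labels); t <- label_array(true_labels)
  if (!identical(dim(p), dim(t))) stop("label shape mismatch", call. = FALSE)
  p <- relabel_dense(p); t <- relabel_dense(t)
  np <- length(unique(p[p > 0L])); nt <- length(unique(t[t > 0L]))
  pairs <- pairwise_instance_iou(p, t)
  pairs <- pairs[pairs$iou >= match_iou_min, , drop = FALSE]
  # deterministic greedy: IoU descending, ties by pred then truth id
  pairs <- pairs[order(-pairs$iou, pairs$pred, pairs$truth), , drop = FALSE]
  used_p <- logical(np); used_t <- logical(nt)
  tp <- 0L
  for (i in seq_len(nrow(pairs))) {
    ip <- pairs$pred[i]; it <- pairs$truth[i]
    if (used_p[ip] || used_t[it]) next
    used_p[ip] <- TRUE; used_t[it] <- TRUE
    tp <- tp + 1L
  }
  c(TP = tp, FP = np - tp, FN = nt - tp)
}

#' F1 score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; symmetric in FP and FN.
#'
#' @param tp,fp,fn non-negative counts, not all zero.
#' @return ratio in `[0, 1]`.
#' @export
#' @examples
#' f1_score(5, 2, 1)  # 10/13
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  denom <- 2 * tp + fp + fn
  if (denom == 0) {
    stop("F1 undefined: no predictions and no truths", call. = FALSE)
  }
  2 * tp / denom
}

#' Squared Pearson correlation of predicted vs true counts
#'
#' @param pred_counts,true_counts numeric vectors of equal length >= 3.
#' @return R^2 in `[0, 1]`.
#' @export
count_correlation <- function(pred_counts, true_counts) {
  if (length(pred_counts) != length(true_counts) || length(pred_counts) < 3L) {
    stop("need equal-length count vectors of length >= 3", call. = FALSE)
  }
  if (var(pred_counts) == 0 || var(true_counts) == 0) {
    stop("count correlation undefined: zero variance", call. = FALSE)
  }
  cor(pred_counts, true_counts)^2
}

#' Cronbach's alpha for inter-rater reliability
#'
#' Treats raters as the "items" of the classical reliability design:
#' `alpha = k/(k-1) * (1 - sum_j var_j / var_total)` where `var_j` is the
#' sample variance of rater j's scores across the rated items and
#' `var_total` the sample variance of the per-item rater sums (n-1
#' denominators). Invariant to a constant offset between raters.
#'
#' @param ratings numeric matrix, raters in rows, rated items in columns
#'   (>= 2 of each).
#' @return alpha (<= 1; 1 means perfect consistency).
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  k <- nrow(ratings)
  if (k < 2L || ncol(ratings) < 2L) {
    stop("need >= 2 raters and >= 2 items", call. = FALSE)
  }
  var_total <- var(colSums(ratings))
  if (var_total == 0) {
    stop("alpha undefined: zero variance of item totals", call. = FALSE)
  }
  var_raters <- sum(apply(ratings, 1, var))
  k / (k - 1) * (1 - var_raters / var_total)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Bundles the instance-matching confusion counts, F1 and parameters into
#' one report row.
#'
#' @param pred_labels,true_labels label arrays of equal shape.
#' @param match_iou_min matching threshold.
#' @return one-row data.frame (`TP`, `FP`, `FN`, `f1`, `match_iou_min`).
#' @export
evaluate_segmentation <- function(pred_labels, true_labels,
                                  match_iou_min = 0.5) {
  m <- match_instances(pred_labels, true_labels, match_iou_min)
  data.frame(TP = m[["TP"]], FP = m[["FP"]], FN = m[["FN"]],
             f1 = f1_score(m[["TP"]], m[["FP"]], m[["FN"]]),
             match_iou_min = match_iou_min)
}
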