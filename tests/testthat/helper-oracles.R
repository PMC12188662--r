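# Independent oracles used across the suite. Each recomputes a quantity from
# its definition (loops, exhaustive enumeration) rather than reusing the
# package's vectorised path.

# exhaustive argmax of Yen's maximum-correlation criterion over all candidate
# splits of a histogram; returns the bin-centre threshold
oracle_yen <- function(counts, centers) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf
  best_t <- NA_integer_
  for (t in seq_len(n - 1L)) {
    P <- sum(p[1:t])
    S1 <- sum(p[1:t]^2)
    S2 <- sum(p[(t + 1L):n]^2)
    if (P <= 0 || P >= 1 || S1 <= 0 || S2 <= 0) next
    crit <- -log(S1 * S2) + 2 * log(P * (1 - P))
    if (crit > best) {
      best <- crit
      best_t <- t
    }
  }
  centers[best_t + 1L]
}

# per-voxel histogram identical to the package's binning, recomputed plainly
oracle_histogram <- function(vals, n_bins) {
  lo <- min(vals); hi <- max(vals)
  bin <- pmin(floor((vals - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- integer(n_bins)
  for (b in bin) counts[b] <- counts[b] + 1L
  centers <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  list(counts = counts, centers = centers)
}

# maximum number of one-to-one (pred, truth) matches with IoU >= thr, by
# exhaustive search over all injective assignments (instance counts <= 8)
oracle_optimal_tp <- function(iou_mat, thr) {
  np <- nrow(iou_mat); nt <- ncol(iou_mat)
  best <- 0L
  recurse <- function(p, used_t, tp) {
    if (p > np) {
      best <<- max(best, tp)
      return(invisible())
    }
    recurse(p + 1L, used_t, tp)  # leave prediction p unmatched
    for (t in seq_len(nt)) {
      if (!used_t[t] && iou_mat[p, t] >= thr) {
        used_t[t] <- TRUE
        recurse(p + 1L, used_t, tp + 1L)
        used_t[t] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt), 0L)
  best
}

# dense pairwise IoU matrix between instances of two label arrays
oracle_iou_matrix <- function(pred, truth) {
  np <- max(pred); nt <- max(truth)
  m <- matrix(0, np, nt)
  for (ip in seq_len(np)) {
    a <- pred == ip
    for (it in seq_len(nt)) {
      b <- truth == it
      u <- sum(a | b)
      m[ip, it] <- if (u == 0) 0 else sum(a & b) / u
    }
  }
  m
}

# Pearson correlation from its covariance definition, scalar loops
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Spearman rho: Pearson on midranks, ranks computed by counting
oracle_spearman <- function(x, y) {
  rank_of <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  oracle_pearson(rank_of(x), rank_of(y))
}

# Cronbach's alpha from its definitional sums (raters in rows)
oracle_cronbach <- function(ratings) {
  k <- nrow(ratings)
  item_totals <- colSums(ratings)
  n <- length(item_totals)
  vt <- sum((item_totals - mean(item_totals))^2) / (n - 1)
  vsum <- 0
  for (j in seq_len(k)) {
    r <- ratings[j, ]
    vsum <- vsum + sum((r - mean(r))^2) / (n - 1)
  }
  k / (k - 1) * (1 - vsum / vt)
}

# two label volumes agree up to a relabelling (same voxel partition)
labels_equivalent <- function(a, b) {
  a <- if (is.list(a)) a$data else a
  b <- if (is.list(b)) b$data else b
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  sel <- a > 0L
  if (!any(sel)) return(TRUE)
  pairs <- unique(cbind(a[sel], b[sel]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
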