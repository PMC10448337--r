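#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney pairwise statistic
#' `P(score_pos > score_neg) + 0.5 P(equal)`; the curve takes every
#' distinct score as a threshold (ties grouped) and reports (FPR, TPR)
#' points including the (0,0) and (1,1) corners.
#'
#' @param scores Numeric prediction scores (higher = more deleterious).
#' @param labels 0/1 (or benign/deleterious) class labels.
#' @return List with `auc`, `fpr`, `tpr`, `thresholds`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as01(labels)
  if (length(y) != length(scores)) stop("scores/labels length mismatch")
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- which(c(diff(ss) != 0, TRUE))      # last index of each tie group
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  list(auc = auc,
       fpr = c(0, fp / nneg, 1),
       tpr = c(0, tp / npos, 1),
       thresholds = c(Inf, ss[grp_end], -Inf))
}

.as01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("benign", "deleterious")
    if (any(bad)) stop("labels must be benign/deleterious or 0/1")
    as.integer(labels == "deleterious")
  } else {
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    as.integer(labels)
  }
}

#' Precision-recall-gain curve and area
#'
#' Precision-gain and recall-gain rescale precision/recall against the
#' always-positive baseline at prevalence `pi`:
#' `pg = (prec - pi) / ((1 - pi) prec)`, `rg = (rec - pi) / ((1 - pi) rec)`.
#' The area is the trapezoid integral of precision-gain over recall-gain
#' restricted to `[0, 1]`, with linear interpolation at the `rg = 0`
#' crossing.  Worse-than-baseline rankers give negative raw areas; the
#' display value is clipped at 0.
#'
#' @inheritParams roc_auc
#' @return List with `auc_raw`, `auc` (clipped display value),
#'   `recall_gain`, `precision_gain`.
#' @export
prg_auc <- function(scores, labels) {
  y <- .as01(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  pi0 <- npos / length(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- which(c(diff(ss) != 0, TRUE))
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  # recall-gain requires tp > 0; cuts that add only negatives keep the same
  # recall but lower precision, so only the first (undominated) point per
  # true-positive count defines the curve
  keep <- tp > 0 & !duplicated(tp)
  tp <- tp[keep]; fp <- fp[keep]
  rec <- tp / npos
  prec <- tp / (tp + fp)
  rg <- (rec - pi0) / ((1 - pi0) * rec)
  pg <- (prec - pi0) / ((1 - pi0) * prec)
  auc_raw <- .prg_area(rg, pg)
  list(auc_raw = auc_raw, auc = max(auc_raw, 0),
       recall_gain = rg, precision_gain = pg)
}

# trapezoid area of the piecewise-linear (rg, pg) path over rg in [0, 1]
.prg_area <- function(rg, pg) {
  n <- length(rg)
  if (n == 0L) return(0)
  if (n == 1L) return(if (rg[1] >= 1) pg[1] else 0)
  area <- 0
  for (i in seq_len(n - 1L)) {
    x1 <- rg[i]; x2 <- rg[i + 1L]
    y1 <- pg[i]; y2 <- pg[i + 1L]
    if (x2 <= 0 || x1 >= 1 || x2 <= x1) next
    if (x1 < 0) {                       # clip at rg = 0
      y1 <- y1 + (0 - x1) / (x2 - x1) * (y2 - y1)
      x1 <- 0
    }
    if (x2 > 1) {
      y2 <- y1 + (1 - x1) / (x2 - x1) * (y2 - y1)
      x2 <- 1
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  area
}

#' DeLong test for two correlated ROC AUCs
#'
#' Placement-value (structural components) form of the DeLong variance
#' for two score vectors evaluated on the same examples, with a two-sided
#' normal p value for the AUC difference.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared 0/1 labels.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- .as01(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("scores/labels length mismatch")
  }
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  comp <- function(s) {
    X <- s[pos]; Y <- s[neg]
    # placement of each positive among negatives and vice versa
    v10 <- vapply(X, function(x) (sum(x > Y) + 0.5 * sum(x == Y)) / n,
                  numeric(1))
    v01 <- vapply(Y, function(yv) (sum(X > yv) + 0.5 * sum(X == yv)) / m,
                  numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (d != 0) warning("degenerate DeLong variance; p set to 1")
    return(list(auc_a = a$auc, auc_b = b$auc, var_diff = var_diff,
                z = 0, p_value = 1))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, var_diff = var_diff, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Corner threshold and specificity on a negatives-only set
#'
#' For evaluation sets containing only benign examples an ROC is
#' undefined; instead a threshold is chosen on labeled training data as
#' the score whose ROC point lies closest (Euclidean) to the ideal corner
#' (FPR 0, TPR 1), and the specificity is the fraction of test scores
#' falling below that threshold.
#'
#' @param train_scores,train_labels Labeled training scores (both classes
#'   present).
#' @param test_scores Scores of the all-negative evaluation set.
#' @return List with `threshold` and `specificity`.
#' @export
specificity_at_corner <- function(train_scores, train_labels, test_scores) {
  y <- .as01(train_labels)
  if (all(y == y[1])) stop("training labels must contain both classes")
  thresholds <- sort(unique(train_scores))
  npos <- sum(y == 1); nneg <- sum(y == 0)
  best_t <- Inf; best_d <- 1                      # empty prediction: (0, 0)
  for (t in thresholds) {
    pred <- train_scores >= t
    tpr <- sum(pred & y == 1) / npos
    fpr <- sum(pred & y == 0) / nneg
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (d < best_d - 1e-15) { best_d <- d; best_t <- t }
  }
  list(threshold = best_t,
       specificity = mean(test_scores < best_t))
}
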