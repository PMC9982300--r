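#' Accuracy matrix for continual-learning transfer metrics
#'
#' `R[i, j]` is the score on distribution `j` after completing task `i`;
#' `b_bar[j]` is the score of the randomly initialized (untrained) model on
#' distribution `j`. The diagonal feeds backward transfer, the superdiagonal
#' forward transfer.
#'
#' @param R Numeric matrix of scores in `[0, 1]`.
#' @param b_bar Numeric vector of random-initialization reference scores,
#'   one per distribution.
#' @return An object of class `accuracy_matrix`.
#' @export
accuracy_matrix <- function(R, b_bar) {
  R <- as.matrix(R)
  if (length(b_bar) != ncol(R))
    stop("b_bar must have one entry per distribution (column of R)")
  ok <- is.na(R) | (R >= 0 & R <= 1)
  if (!all(ok)) stop("accuracy matrix entries must lie in [0, 1]")
  structure(list(R = R, b_bar = as.numeric(b_bar)),
            class = "accuracy_matrix")
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat(sprintf("<accuracy_matrix> %d tasks x %d distributions\n",
              nrow(x$R), ncol(x$R)))
  print(round(x$R, 3))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive is scored higher, ties
#' counted one half. Implemented via midranks, so it is exact.
#'
#' @param scores Numeric classifier scores (higher means more positive).
#' @param labels Binary labels (0 = negative, 1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  s1 <- sum(labels == 1L); s0 <- sum(labels == 0L)
  if (s1 == 0L || s0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - s1 * (s1 + 1) / 2) / (s1 * s0)
}

#' Normal-approximation confidence interval for an AUC
#'
#' Uses the classic standard-error plug-in based on the two class sizes:
#' `q0 = A(1-A)`, `q1 = A/(2-A) - A^2`, `q2 = 2A^2/(1+A) - A^2`,
#' `se = sqrt((q0 + (s1-1)q1 + (s2-1)q2) / (s1 s2))`, interval
#' `A ± z_{1-alpha/2} * se`.
#'
#' @param auc Point estimate in `(0, 1)`.
#' @param s1,s2 Sizes of the two label groups (each `>= 2`).
#' @param alpha Two-sided level (default 0.05).
#' @return Numeric `c(lo, hi)`; for a degenerate `auc` of exactly 0 or 1 a
#'   zero-width interval is returned with a warning.
#' @export
auc_confidence_interval <- function(auc, s1, s2, alpha = 0.05) {
  stopifnot(s1 >= 2, s2 >= 2)
  if (auc <= 0 || auc >= 1) {
    if (auc %in% c(0, 1)) {
      warning("degenerate AUC of ", auc, ": zero-width interval")
      return(c(auc, auc))
    }
    stop("auc must lie in [0, 1]")
  }
  q0 <- auc * (1 - auc)
  q1 <- auc / (2 - auc) - auc^2
  q2 <- 2 * auc^2 / (1 + auc) - auc^2
  se <- sqrt((q0 + (s1 - 1) * q1 + (s2 - 1) * q2) / (s1 * s2))
  z <- stats::qnorm(1 - alpha / 2)
  c(auc - z * se, auc + z * se)
}

#' Backward transfer
#'
#' Mean, over all but the last distribution, of the final-row score minus the
#' just-learned (diagonal) score. Negative values quantify forgetting.
#'
#' @param matrix An [accuracy_matrix()] (square, diagonal populated).
#' @return Scalar BWT.
#' @export
bwt <- function(matrix) {
  R <- matrix$R
  Dn <- ncol(R)
  if (nrow(R) < 2L || Dn < 2L) stop("BWT needs at least two distributions")
  i <- seq_len(Dn - 1L)
  mean(R[nrow(R), i] - R[cbind(i, i)])
}

#' Forward transfer
#'
#' Mean, over distributions 2..D, of the score on distribution `i` after
#' task `i-1`, minus the random-initialization reference `b_bar[i]`: the
#' benefit of earlier learning on a not-yet-seen distribution.
#'
#' @param matrix An [accuracy_matrix()] with the superdiagonal and `b_bar`
#'   populated.
#' @return Scalar FWT.
#' @export
fwt <- function(matrix) {
  R <- matrix$R
  Dn <- ncol(R)
  if (Dn < 2L) stop("FWT needs at least two distributions")
  i <- 2:Dn
  vals <- R[cbind(i - 1L, i)]
  if (any(is.na(vals))) stop("missing superdiagonal entries in R")
  mean(vals - matrix$b_bar[i])
}

#' Gradient fluctuation
#'
#' Frequency of gradient direction changes during training: per parameter the
#' sign series is formed (zeros inherit the previous sign, a leading zero
#' counts as +1), then `R = mean((d_i - d_{i-1})^2) * n/(n-1)`... precisely
#' `(1/(n-1)) * sum_i (d_i - d_{i-1})^2`, and the result is averaged over
#' parameters. Values lie in `[0, 4]`: 0 for a constant sign, 4 for strict
#' alternation.
#'
#' @param grad_series Numeric matrix of per-round gradients (rows = rounds,
#'   columns = parameters), or a vector for a single parameter. Sign values
#'   (-1/0/1) are accepted.
#' @return Mean fluctuation over parameters.
#' @export
gradient_fluctuation <- function(grad_series) {
  if (is.null(dim(grad_series))) grad_series <- matrix(grad_series, ncol = 1L)
  n <- nrow(grad_series)
  if (n < 2L) stop("gradient fluctuation needs at least two rounds")
  d <- sign(grad_series)
  for (j in seq_len(ncol(d))) {
    col <- d[, j]
    if (col[1L] == 0) col[1L] <- 1
    for (i in 2:n) if (col[i] == 0) col[i] <- col[i - 1L]
    d[, j] <- col
  }
  mean(colSums((d[-1L, , drop = FALSE] - d[-n, , drop = FALSE])^2) / (n - 1))
}

#' Critical difference of the Bonferroni-Dunn test
#'
#' `CD = q * sqrt(k (k + 1) / (6 N))` for `k` compared methods over `N`
#' dataset-fold combinations at critical value `q`. Average ranks further
#' apart than CD differ significantly.
#'
#' @param k Number of methods (`>= 2`).
#' @param N Number of comparisons (`n` datasets times `m` folds).
#' @param q Critical value of the test at the chosen level.
#' @return The critical difference, in average-rank units.
#' @export
bonferroni_dunn_cd <- function(k, N, q) {
  stopifnot(k >= 2, N >= 1, q >= 0)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Average ranks of methods across comparisons
#'
#' Rank 1 is best (higher score better) within each row; ties receive
#' midranks; ranks are averaged over rows. Together with
#' [bonferroni_dunn_cd()] this supports the decision rule "method
#' significantly better when the baseline's average rank exceeds the
#' method's by more than CD" (strict inequality).
#'
#' @param scores Numeric matrix, rows = dataset-fold combinations,
#'   columns = methods. No missing cells allowed.
#' @return Named numeric vector of average ranks.
#' @export
average_ranks <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("missing cells in the score table")
  ranks <- t(apply(scores, 1L, function(row)
    rank(-row, ties.method = "average")))
  if (ncol(scores) == 1L) ranks <- matrix(ranks, ncol = 1L)
  out <- colMeans(ranks)
  names(out) <- colnames(scores)
  out
}

#' Mean cross-entropy of predicted class probabilities
#'
#' `-(1/N) sum_n log p_hat[n, label_n]`, with the true-label probability
#' clamped at `1e-12` (with a warning) if it underflows to zero.
#'
#' @param probabilities `N x K` matrix of class probabilities (rows must sum
#'   to 1 within `1e-6`).
#' @param labels Integer labels in `{0..K-1}`.
#' @return Scalar cross-entropy (natural log).
#' @export
cross_entropy <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  y1 <- as.integer(labels) + 1L
  p <- probabilities[cbind(seq_len(nrow(probabilities)), y1)]
  if (any(p <= 0)) {
    warning("zero probability at a true label; clamping at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Continual-learning metrics report
#'
#' Convenience wrapper computing the standard report from a training history:
#' final-task AUC (with confidence interval), BWT, FWT and gradient
#' fluctuation.
#'
#' @param fit An `ru_fit` from [train_ru()].
#' @param eval_dataset Optional dataset for the final AUC; defaults to the
#'   last distribution's diagonal entry only.
#' @param alpha Level for the AUC confidence interval.
#' @return Named list with `auc`, `auc_ci`, `bwt`, `fwt`,
#'   `grad_fluctuation`, and the accuracy matrix.
#' @export
metrics_report <- function(fit, eval_dataset = NULL, alpha = 0.05) {
  h <- fit$history
  am <- h$accuracy_matrix
  out <- list(bwt = bwt(am), fwt = fwt(am),
              grad_fluctuation = gradient_fluctuation(h$grad_sign),
              accuracy_matrix = am)
  if (!is.null(eval_dataset)) {
    probs <- predict_proba(fit$params, eval_dataset, h$config$adjust)
    y <- dataset_labels(eval_dataset)
    a <- auc_roc(probs[, 2L], y)
    out$auc <- a
    out$auc_ci <- auc_confidence_interval(a, sum(y == 1L), sum(y == 0L),
                                          alpha)
  } else {
    out$auc <- am$R[nrow(am$R), ncol(am$R)]
  }
  out
}
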