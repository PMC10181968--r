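#' ROC area under the curve with DeLong confidence interval
#'
#' AUC computed from the Mann-Whitney statistic with half credit for ties
#' (the probability that a random positive scores above a random negative).
#' The variance follows DeLong's placement decomposition; the 95% CI is
#' Wald on the AUC scale, truncated to \[0, 1\].
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (0/1), both classes present.
#' @return object of class `roc_result`: `auc`, `var`, `ci` (length 2),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be present")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  # placements: per-positive and per-negative mean comparison scores
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  v <- s10 / m + s01 / n
  ci <- pmin(pmax(auc + qnorm(c(0.025, 0.975)) * sqrt(v), 0), 1)
  structure(list(auc = auc, var = v, ci = ci, n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}
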