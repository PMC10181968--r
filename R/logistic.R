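# Maximum-likelihood logistic regression via iteratively reweighted least
# squares, likelihood-ratio machinery, backward LR variable selection, and
# integration of QCT covariates into an existing risk model.

logistic_loglik <- function(eta, y) {
  # numerically stable: log p = -log1p(exp(-eta)), log(1-p) = -log1p(exp(eta))
  sum(ifelse(y == 1, -log1p(exp(-eta)), -log1p(exp(eta))))
}

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood fit with Wald standard errors. Convergence is
#' declared when the relative change in log-likelihood falls below `tol`
#' (default 1e-10) or after `max_iter` iterations. Rank-deficient designs
#' raise an error naming the collinear columns; (quasi-)complete
#' separation raises an explicit non-convergence error.
#'
#' @param x numeric matrix or data.frame of covariates (no intercept
#'   column; one is added unless `add_intercept = FALSE`).
#' @param y binary outcome vector (0/1).
#' @param add_intercept prepend an intercept column (default TRUE).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return object of class `logistic_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `n`, `converged`, `fitted`, and a `table` with odds ratios,
#'   95% Wald confidence intervals and p values.
#' @export
fit_logistic <- function(x, y, add_intercept = TRUE, tol = 1e-10,
                         max_iter = 100L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters (n=", n,
                   ", p=", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- rep(0, p)
  ll_old <- logistic_loglik(drop(X %*% beta), y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    ll <- logistic_loglik(drop(X %*% beta), y)
    if (!is.finite(ll)) stop("log-likelihood diverged; non-convergence")
    if (abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  # separation: fitted probabilities pinned to 0/1 on a perfectly
  # classified sample drive |beta| to infinity
  if (max(abs(beta)) > 1e3 ||
      (all(abs(y - mu) < 1e-6) && max(abs(eta)) > 15))
    stop("perfect separation detected; maximum-likelihood estimate ",
         "does not exist (non-convergence)")
  if (!converged)
    stop("IRLS failed to converge in ", max_iter, " iterations")
  W <- mu * (1 - mu)
  info <- crossprod(X, X * W)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  zval <- beta / se
  tab <- data.frame(
    term = colnames(X), estimate = beta, se = se,
    or = exp(beta), or_low = exp(beta - 1.96 * se),
    or_high = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(zval)), row.names = NULL)
  structure(list(coefficients = setNames(beta, colnames(X)), se = se,
                 vcov = vcov, loglik = logistic_loglik(eta, y),
                 n = n, converged = converged, fitted = mu, table = tab,
                 terms = colnames(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n, " logLik =", format(x$loglik), "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' @param full,reduced `logistic_fit` objects, reduced nested in full.
#' @return list of class `model_comparison`: `lr`, `df`, `p_value`, labels.
#' @export
lr_test <- function(full, reduced, labels = c("full", "reduced")) {
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 1L) stop("models are not nested (df < 1)")
  lr <- 2 * (full$loglik - reduced$loglik)
  lr <- max(lr, 0)
  structure(list(lr = lr, df = df, p_value = pchisq(lr, df, lower.tail = FALSE),
                 labels = labels),
            class = "model_comparison")
}

#' Backward variable selection by likelihood-ratio tests
#'
#' Starting from all candidate covariates, iteratively refits the model
#' without each remaining covariate, computes the LR p value for its
#' removal, and drops the covariate with the largest p while that p is at
#' least `p_remove`. Ties are broken deterministically by covariate name
#' order. Intended to follow a univariate screen (candidates with
#' univariate p below 0.05).
#'
#' @param data data.frame holding covariates and outcome.
#' @param candidates character vector of candidate covariate names.
#' @param outcome outcome column name (0/1).
#' @param p_remove removal threshold, default 0.10.
#' @return list with `selected` (character), `fit` (final `logistic_fit`,
#'   NULL if everything was removed), and `path` (data.frame log of drops).
#' @export
backward_select_lr <- function(data, candidates, outcome = "malignant",
                               p_remove = 0.10) {
  if (!length(candidates)) stop("no candidate covariates")
  current <- sort(candidates)
  y <- data[[outcome]]
  keep_rows <- complete.cases(data[, c(candidates, outcome), drop = FALSE])
  data <- data[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  path <- data.frame(step = integer(), dropped = character(),
                     lr = numeric(), p_value = numeric())
  fit_set <- function(vars) {
    if (!length(vars))
      return(fit_logistic(matrix(numeric(0), nrow = length(y), ncol = 0), y))
    fit_logistic(as.matrix(data[, vars, drop = FALSE]), y)
  }
  fit <- fit_set(current)
  step <- 0L
  repeat {
    if (!length(current)) break
    drops <- vapply(current, function(v) {
      red <- fit_set(setdiff(current, v))
      tst <- lr_test(fit, red)
      c(lr = tst$lr, p = tst$p_value)
    }, numeric(2))
    # largest removal p; ties resolved by (sorted) name order
    worst <- which.max(drops["p", ])
    if (drops["p", worst] < p_remove) break
    step <- step + 1L
    path <- rbind(path, data.frame(step = step,
                                   dropped = current[worst],
                                   lr = drops["lr", worst],
                                   p_value = drops["p", worst]))
    current <- setdiff(current, current[worst])
    fit <- fit_set(current)
  }
  list(selected = current, fit = if (length(current)) fit else NULL,
       path = path)
}

#' Integrate QCT covariates into an existing risk model
#'
#' The base model's predicted probabilities enter as their logit, fitted
#' with a free (recalibration) coefficient; the extended model adds the
#' QCT covariates. Base and extended models are properly nested, so the
#' added value of the QCT covariates is a likelihood-ratio test with as
#' many degrees of freedom as covariates added. An offset mode (base logit
#' with fixed unit coefficient) is available.
#'
#' @param base_prob base-model probabilities in (0, 1).
#' @param qct data.frame/matrix of QCT covariates (e.g. `mld_hu`,
#'   `pei_pct`), complete cases only.
#' @param outcome binary outcome vector.
#' @param mode `"logit_covariate"` (default) or `"offset"`.
#' @return list with `base_fit`, `extended_fit`, `comparison` (LR test),
#'   `auc_base`, `auc_extended` (both `roc_result`).
#' @export
extend_with_qct <- function(base_prob, qct, outcome,
                            mode = c("logit_covariate", "offset")) {
  mode <- match.arg(mode)
  if (any(base_prob <= 0 | base_prob >= 1))
    stop("base probabilities must lie strictly in (0, 1)")
  if (sd(base_prob) == 0) stop("degenerate base probabilities (all equal)")
  qct <- as.matrix(qct)
  if (any(is.na(qct))) stop("QCT covariates must be complete")
  lo <- qlogis(base_prob)
  if (mode == "logit_covariate") {
    base_fit <- fit_logistic(cbind(base_logit = lo), outcome)
    extended_fit <- fit_logistic(cbind(base_logit = lo, qct), outcome)
  } else {
    # offset mode: base logit carried with fixed coefficient 1; both
    # models keep a free intercept so they stay properly nested
    base_fit <- fit_logistic_offset(matrix(numeric(0), length(outcome), 0),
                                    outcome, lo)
    extended_fit <- fit_logistic_offset(qct, outcome, lo)
  }
  cmp <- lr_test(extended_fit, base_fit, labels = c("extended", "base"))
  list(base_fit = base_fit, extended_fit = extended_fit, comparison = cmp,
       auc_base = roc_auc(base_fit$fitted, outcome),
       auc_extended = roc_auc(extended_fit$fitted, outcome))
}

# logistic fit with a fixed offset term (for the offset integration mode)
fit_logistic_offset <- function(x, y, offset, tol = 1e-10, max_iter = 100L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  beta <- rep(0, ncol(X))
  ll_old <- logistic_loglik(drop(X %*% beta) + offset, y)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta - offset + (y - mu) / w
    beta <- lm.wfit(X, z, w)$coefficients
    ll <- logistic_loglik(drop(X %*% beta) + offset, y)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  eta <- drop(X %*% beta) + offset
  mu <- plogis(eta)
  vcov <- solve(crossprod(X, X * (mu * (1 - mu))))
  structure(list(coefficients = setNames(beta, colnames(X)),
                 se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = logistic_loglik(eta, y), n = length(y),
                 converged = TRUE, fitted = mu, table = NULL,
                 terms = colnames(X)),
            class = "logistic_fit")
}
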