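# Group comparison machinery: Mann-Whitney U with exact small-sample
# enumeration, and chi-square for categoricals, with group descriptives.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The statistic
#' is `U = #\{x_i < y_j\} + 0.5 #\{x_i = y_j\}`. When both groups have at
#' most `exact_max` observations, the exact permutation distribution of U
#' is enumerated over all assignments of the pooled values (valid under
#' ties); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max per-group size bound for exact enumeration (default 8).
#' @return list with `U` (for x), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty group")
  u_stat <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(x, y)
    splits <- utils::combn(n1 + n2, n1)
    us <- apply(splits, 2, function(ix)
      u_stat(pooled[ix], pooled[-ix]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(U = U, p_value = min(1, p), method = method)
}

#' Benign vs malignant group comparison of one cohort variable
#'
#' Continuous variables: group medians with IQRs and a two-sided
#' Mann-Whitney U test. Categorical variables: counts and percentages per
#' level and a Pearson chi-square test without continuity correction.
#'
#' @param cohort validated cohort data.frame.
#' @param variable column name to compare.
#' @param type `"auto"` (numeric with > 4 distinct values is continuous),
#'   `"continuous"` or `"categorical"`.
#' @param by binary grouping column, default `"malignant"`.
#' @return list with per-group descriptives and the test result.
#' @export
compare_groups <- function(cohort, variable,
                           type = c("auto", "continuous", "categorical"),
                           by = "malignant") {
  type <- match.arg(type)
  v <- cohort[[variable]]
  if (is.null(v)) stop("no such column: ", variable)
  g <- cohort[[by]]
  if (length(unique(g)) != 2L) stop("grouping column must have two levels")
  ok <- !is.na(v)
  v <- v[ok]; g <- g[ok]
  if (!length(v) || min(table(g)) == 0L) stop("empty group")
  if (type == "auto")
    type <- if (is.numeric(v) && length(unique(v)) > 4L) "continuous"
            else "categorical"
  if (length(unique(v)) < 2L) stop("variable '", variable, "' is constant")
  glev <- sort(unique(g))
  if (type == "continuous") {
    x0 <- v[g == glev[1]]; x1 <- v[g == glev[2]]
    mw <- mann_whitney_u(x0, x1)
    list(variable = variable, type = "continuous",
         summary = data.frame(
           group = as.character(glev),
           n = c(length(x0), length(x1)),
           median = c(median(x0), median(x1)),
           q1 = c(quantile(x0, 0.25), quantile(x1, 0.25)),
           q3 = c(quantile(x0, 0.75), quantile(x1, 0.75))),
         U = mw$U, p_value = mw$p_value, method = mw$method)
  } else {
    tab <- table(factor(v), factor(g))
    cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
    pct <- prop.table(tab, margin = 2) * 100
    list(variable = variable, type = "categorical",
         counts = tab, percent = pct,
         statistic = unname(cs$statistic), df = unname(cs$parameter),
         p_value = cs$p.value, method = "chi_square")
  }
}
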