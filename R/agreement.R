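#' Intra-rater reliability: Cronbach's alpha over rating columns
#'
#' `alpha = k/(k-1) * (1 - sum_i var_i / var_total)` over the `k` columns
#' (raters or rounds), with `var_total` the variance of the row sums.
#' Interpretation bands: excellent > 0.9; good 0.75-0.90; moderate 0.50-0.75;
#' poor < 0.5. Identical columns give alpha = 1 by convention (including the
#' zero-variance case); zero total variance with unequal columns is undefined
#' and raised as an error. `method = "icc3k"` computes the two-way mixed
#' consistency ICC(3,k) from ANOVA mean squares, which equals alpha on
#' complete data.
#'
#' @param table numeric matrix, specimens x raters (no missing cells).
#' @param method `"alpha"` or `"icc3k"`.
#' @return list of class `iccResult`: `value`, `band`, `k`, `n`, `method`.
#' @export
iccCronbach <- function(table, method = c("alpha", "icc3k")) {
  method <- match.arg(method)
  x <- as.matrix(table)
  if (anyNA(x)) stop("ratings table has missing cells")
  n <- nrow(x); k <- ncol(x)
  if (k < 2L || n < 2L) stop("need at least 2 rows and 2 columns")
  identicalCols <- all(x == x[, 1L])
  if (identicalCols) {
    value <- 1
  } else if (method == "alpha") {
    vt <- var(rowSums(x))
    if (vt == 0)
      stop("total variance is zero with unequal columns: alpha undefined")
    value <- k / (k - 1) * (1 - sum(apply(x, 2L, var)) / vt)
  } else {
    grand <- mean(x)
    rowM <- rowMeans(x); colM <- colMeans(x)
    msr <- k * sum((rowM - grand)^2) / (n - 1)
    sse <- sum((x - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    if (msr == 0) stop("zero between-specimen variance: ICC undefined")
    value <- (msr - mse) / msr
  }
  band <- if (value > 0.9) "excellent"
          else if (value >= 0.75) "good"
          else if (value >= 0.5) "moderate"
          else "poor"
  structure(list(value = value, band = band, k = k, n = n, method = method),
            class = "iccResult")
}

#' @export
print.iccResult <- function(x, ...) {
  cat(sprintf("ICC (%s): %.4f [%s]  (n = %d specimens, k = %d ratings)\n",
              if (x$method == "alpha") "Cronbach's alpha" else "ICC(3,k)",
              x$value, x$band, x$n, x$k))
  invisible(x)
}

#' Inter-rater agreement: weighted Cohen's kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with disagreement weights
#' `w_ij = |i - j| / (c - 1)` (linear, default) or its square (quadratic),
#' observed cell proportions `O` and chance expectation `E` from the
#' marginals. Bands: almost perfect 0.81-1.00; substantial 0.61-0.80;
#' moderate 0.41-0.60; fair 0.21-0.40; slight 0.01-0.20; none <= 0.
#'
#' @param r1,r2 equal-length rating vectors on the same ordinal scale.
#' @param weights `"linear"` or `"quadratic"`.
#' @param categories the ordinal category set (default: sorted union of the
#'   observed values; pass e.g. `0:2` to fix the scale).
#' @return list of class `kappaResult`: `value`, `band`, `weights`, `n`.
#'   A single shared category in both raters leaves kappa undefined
#'   (`value = NA`, band `"undefined"`).
#' @export
weightedKappa <- function(r1, r2, weights = c("linear", "quadratic"),
                          categories = NULL) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2)) stop("input error: rating vectors differ in length")
  if (is.null(categories)) categories <- sort(unique(c(r1, r2)))
  if (!all(c(r1, r2) %in% categories))
    stop("input error: ratings outside the declared category set")
  cN <- length(categories)
  if (cN < 2L) {
    return(structure(list(value = NA_real_, band = "undefined",
                          weights = weights, n = length(r1)),
                     class = "kappaResult"))
  }
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  O <- table(f1, f2) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(cN)
  W <- abs(outer(idx, idx, "-")) / (cN - 1)
  if (weights == "quadratic") W <- W^2
  denom <- sum(W * E)
  value <- if (denom == 0) {
    # both raters constant on the same category: perfect agreement
    if (all(r1 == r2)) 1 else NA_real_
  } else 1 - sum(W * O) / denom
  band <- if (is.na(value)) "undefined"
          else if (value <= 0) "none"
          else if (value <= 0.20) "slight"
          else if (value <= 0.40) "fair"
          else if (value <= 0.60) "moderate"
          else if (value <= 0.80) "substantial"
          else "almost perfect"
  structure(list(value = value, band = band, weights = weights, n = length(r1)),
            class = "kappaResult")
}

#' @export
print.kappaResult <- function(x, ...) {
  cat(sprintf("weighted Cohen's kappa (%s): %s [%s]  (n = %d)\n",
              x$weights,
              if (is.na(x$value)) "undefined" else sprintf("%.4f", x$value),
              x$band, x$n))
  invisible(x)
}
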