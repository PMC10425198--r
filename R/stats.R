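#' Welch's unequal-variance t-test
#'
#' Wraps [stats::t.test()] with the degenerate-input conventions the DA
#' engine relies on: two constant, equal groups give `t = 0, p = 1`; two
#' constant, unequal groups give `p = 0` with a warning.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return One-row tibble with `t` (sign of `mean(x) - mean(y)`),
#'   Satterthwaite `df` and two-sided `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 observations")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(tibble(t = 0, df = length(x) + length(y) - 2, p = 1))
    warn("both groups constant but unequal; p = 0 by convention")
    return(tibble(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value))
}

#' Kruskal-Wallis rank-sum test
#'
#' Wraps [stats::kruskal.test()] (tie-corrected H, chi-squared reference with
#' k - 1 df); an input whose values are all identical returns `H = 0, p = 1`
#' by convention.
#'
#' @param groups List of >= 2 numeric vectors, one per group.
#' @return One-row tibble with `H`, `df` and `p`.
#' @examples
#' kruskal_wallis_test(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need a list of >= 2 groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) abort("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = length(groups) - 1, p = 1))
  }
  fit <- stats::kruskal.test(values, g)
  tibble(H = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of average ranks and a two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` df;
#' `|rho| = 1` gives `p = 0` by convention.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble with `rho`, `n` and `p`.
#' @examples
#' spearman_cor(c(1, 2, 3), c(3, 1, 2))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) abort("zero rank variance: constant input")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    return(tibble(rho = sign(rho), n = n, p = 0))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble(rho = rho, n = n, p = 2 * pt(-abs(tstat), df = n - 2))
}

# ---- vectorized per-row machinery (cross-checked against t.test /
# kruskal.test in the test suite) ----

row_means_vars <- function(X) {
  n <- ncol(X)
  m <- rowMeans(X)
  v <- rowSums((X - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}

# Welch t for every row of X between column sets i1 (reference) and i2;
# diff = mean2 - mean1. Degenerate rows follow welch_t_test() conventions.
row_welch <- function(X, i1, i2) {
  a <- row_means_vars(X[, i1, drop = FALSE])
  b <- row_means_vars(X[, i2, drop = FALSE])
  diff <- b$mean - a$mean
  se2 <- a$var / a$n + b$var / b$n
  tstat <- ifelse(se2 > 0, diff / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (a$var^2 / (a$n^2 * (a$n - 1)) + b$var^2 / (b$n^2 * (b$n - 1))),
               a$n + b$n - 2)
  p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df = df),
              ifelse(diff == 0, 1, 0))
  tstat[se2 == 0 & diff != 0] <- sign(diff[se2 == 0 & diff != 0]) * Inf
  list(diff = diff, t = tstat, df = df, p = p)
}

# tie-corrected Kruskal-Wallis H for every row of X given a group factor
row_kw <- function(X, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  n <- ncol(X)
  idx <- split(seq_len(n), g)
  H <- vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    if (length(unique(x)) == 1) return(0)
    r <- rank(x)
    stat <- 12 / (n * (n + 1)) *
      sum(vapply(idx, function(j) sum(r[j])^2 / length(j), numeric(1))) -
      3 * (n + 1)
    ties <- table(x)
    stat / (1 - sum(ties^3 - ties) / (n^3 - n))
  }, numeric(1))
  p <- ifelse(H == 0, 1, pchisq(H, df = k - 1, lower.tail = FALSE))
  list(H = H, df = k - 1, p = p)
}
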