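#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric tail probabilities for a 2x2 table
#' \deqn{\begin{pmatrix} a & b \\ c & d \end{pmatrix}}
#' The right tail tests enrichment of cell `a` (probability of a table at
#' least as extreme in the direction of large `a`, margins fixed); the left
#' tail tests depletion.  The two-sided p-value is the standard
#' minimum-likelihood definition.
#'
#' @param table 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given separately.
#' @param b,c,d remaining cells when `table` is a scalar.
#' @param tail one of `"right"`, `"left"`, `"two"`.
#' @return p-value (scalar).
#' @examples
#' fisher_exact(matrix(c(5, 2, 1, 10), 2, byrow = TRUE), tail = "right")
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL,
                         tail = c("right", "left", "two")) {
  tail <- match.arg(tail)
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency counts must be finite and non-negative")
  }
  if (sum(cells) < 1) stop("degenerate table: total count is zero")
  # hypergeometric: a successes drawn from m = a+b white, n = c+d black, k = a+c draws
  m <- a + b; n <- c + d; k <- a + c
  switch(tail,
    right = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    left  = stats::phyper(a, m, n, k, lower.tail = TRUE),
    two   = stats::fisher.test(matrix(c(a, c, b, d), 2L, 2L))$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH false discovery rate adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  .check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

.check_pvalues <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid and converts p-values
#' to q-values `q_i = min_{p_j >= p_i} pi0 * n * p_j / rank(p_j)`.  With the
#' smoother method pi0(lambda) is fit with a cubic smoothing spline and
#' extrapolated to lambda = 1; for fewer than 100 p-values a fixed
#' lambda = 0.5 estimate is used instead (the smoother is unstable there).
#'
#' @param p numeric vector of p-values.
#' @param lambda grid of lambda values for pi0 estimation.
#' @param method `"smoother"` (default) or `"fixed"` (single lambda = 0.5).
#' @param pi0 optional override of the null proportion; `pi0 = 1` reduces
#'   the q-values exactly to Benjamini-Hochberg.
#' @return numeric vector of q-values; attribute `"pi0"` carries the
#'   pi0 estimate.
#' @references Storey & Tibshirani (2003) PNAS 100:9440.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          method = c("smoother", "fixed"), pi0 = NULL) {
  .check_pvalues(p)
  method <- match.arg(method)
  n <- length(p)
  if (!is.null(pi0)) {
    # explicit null proportion supplied
  } else if (method == "fixed" || n < 100L) {
    pi0 <- mean(p > 0.5) / 0.5
  }
  if (is.null(pi0) || length(pi0) == 0) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = 1)$y
  }
  pi0 <- min(max(pi0, 1 / n), 1)  # clamp: at least one informative p, at most 1
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Welch's two-sample t-test
#'
#' Two-tailed Welch t statistic with Satterthwaite degrees of freedom.
#'
#' @param a,b numeric vectors (each of length >= 2 with finite variance).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate but well-defined when the means coincide
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation on mid-ranks (ties allowed); the p-value uses the
#' t statistic `rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom (two-tailed).  For |rho| = 1 the p-value is 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use exact permutation p (only for n <= 10; for testing).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("zero variance in ranks: rho undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    rx <- rank(x); ry <- rank(y)
    perms <- .permutations(n)
    obs <- abs(stats::cor(rx, ry))
    cnt <- sum(apply(perms, 1, function(pm) abs(stats::cor(rx, ry[pm])) >= obs - 1e-12))
    return(list(rho = rho, p = cnt / nrow(perms), n = n))
  }
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), p = ht$p.value, n = n)
}

#' Agglomerative Ward clustering
#'
#' Hierarchical clustering with the variance-minimizing Ward criterion on
#' Euclidean distances, cut at `k` clusters.
#'
#' @param x numeric matrix (rows are observations) or data.frame.
#' @param k number of clusters.
#' @return integer vector of cluster labels (1..k); the `hclust` tree is
#'   attached as attribute `"tree"`.
#' @export
ward_cluster <- function(x, k = 2) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds number of observations")
  if (nrow(x) == k) {
    labels <- seq_len(k)
    return(labels)
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}
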