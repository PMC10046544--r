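# Nonparametric test battery. Implemented directly (rather than via
# stats::wilcox.test and friends) because the contract pins down exact
# small-sample enumeration, mid-rank tie handling, tie-corrected normal
# approximations and the reporting convention z = (min(T+, T-) - mu)/sigma
# used in the source tables; the base-R tests serve as independent
# cross-checks in the test-suite.

new_test_result <- function(name, statistic, z_value, p_value, n,
                            method_notes = "") {
  structure(list(name = name, statistic = statistic, z_value = z_value,
                 p_value = p_value, n = n, method_notes = method_notes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, z = %s, p = %.5g (n = %s)%s\n",
              x$name, x$statistic,
              if (is.na(x$z_value)) "NA" else sprintf("%.3f", x$z_value),
              x$p_value, paste(x$n, collapse = "+"),
              if (nzchar(x$method_notes)) paste0(" [", x$method_notes, "]")
              else ""))
  invisible(x)
}

two_sided_p <- function(p_low, p_high) min(1, 2 * min(p_low, p_high))

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classic convention; `zero_method =
#' "pratt"` keeps them in the ranking), tied absolute differences receive
#' mid-ranks. For `n <= exact_cutoff` the two-sided p-value is computed by
#' full enumeration of the 2^n sign assignments; otherwise by normal
#' approximation with tie-corrected variance. The reported z is
#' `(min(T+, T-) - mu_T) / sigma_T` (the convention of the source
#' statistics package, always <= 0).
#'
#' @param x,y paired vectors, or `y = NULL` with `x` the differences.
#' @param exact_cutoff maximum n for exact enumeration.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return a `test_result`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_cutoff = 12,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else x - y
  n_zero <- sum(d == 0)
  if (zero_method == "drop") d <- d[d != 0]
  n <- length(d)
  if (n == 0 || all(d == 0)) {
    stop("undefined-test error: all paired differences are zero")
  }
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    r <- r[d != 0]
    d <- d[d != 0]
    n <- length(d)
  }
  t_plus <- sum(r[d > 0])
  t_minus <- sum(r[d < 0])
  mu <- sum(r) / 2
  ties <- table(r)
  sigma2 <- sum(r^2) / 4
  sigma <- sqrt(sigma2)
  z <- if (sigma > 0) (min(t_plus, t_minus) - mu) / sigma else NA_real_
  notes <- c(if (n_zero > 0) paste0(n_zero, " zero(s) ", zero_method, "ed"),
             if (any(ties > 1)) "midranks for ties")
  if (n <= exact_cutoff) {
    tp <- enumerate_signed_rank(r)
    p <- two_sided_p(mean(tp <= t_plus), mean(tp >= t_plus))
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation, tie-corrected"
  }
  new_test_result("Wilcoxon signed-rank", min(t_plus, t_minus), z, p, n,
                  paste(c(method, notes), collapse = "; "))
}

# Distribution of T+ over all 2^n sign assignments of the rank vector.
enumerate_signed_rank <- function(r) {
  n <- length(r)
  m <- 2^n
  idx <- 0:(m - 1)
  tp <- numeric(m)
  for (k in seq_len(n)) {
    tp <- tp + r[k] * (idx %/% 2^(k - 1) %% 2)
  }
  tp
}

#' Mann-Whitney U test for two independent samples
#'
#' Mid-ranks for ties; exact two-sided p by enumeration of all
#' `choose(n1 + n2, n1)` group assignments when `n1 + n2 <= exact_cutoff`,
#' otherwise the tie-corrected normal approximation. The reported z is
#' `(U1 - n1 n2 / 2) / sigma_U` where U1 belongs to `x`, so swapping the
#' samples flips its sign and leaves p unchanged.
#'
#' @param x,y samples.
#' @param exact_cutoff maximum combined size for exact enumeration.
#' @return a `test_result`.
#' @export
mann_whitney_u <- function(x, y, exact_cutoff = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("argument error: both samples must be non-empty")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  z <- if (sigma > 0) (u1 - mu) / sigma else NA_real_
  if (N <= exact_cutoff) {
    us <- enumerate_rank_sum(r, n1)
    p <- two_sided_p(mean(us <= u1), mean(us >= u1))
    method <- "exact enumeration"
  } else {
    p <- if (is.na(z)) 1 else min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  new_test_result("Mann-Whitney U", min(u1, n1 * n2 - u1), z, p,
                  c(n1, n2),
                  paste(c(method,
                          if (any(ties > 1)) "midranks for ties"),
                        collapse = "; "))
}

# Distribution of U1 over all assignments of n1 of the pooled ranks.
enumerate_rank_sum <- function(r, n1) {
  combs <- utils::combn(length(r), n1)
  colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic `sum (O - E)^2 / E` with `df = (nrow - 1) * (ncol -
#' 1)`; no continuity correction by default (a flag is provided for the
#' 2 x 2 Yates correction).
#'
#' @param contingency matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return a `test_result`.
#' @export
chi_square <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("argument error: counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate-table error: zero marginal total")
  }
  E <- outer(rs, cs) / N
  adj <- if (correct && all(dim(m) == 2)) pmin(abs(m - E), 0.5) else 0
  stat <- sum((abs(m - E) - adj)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_test_result("chi-square", stat, NA_real_, p, N,
                  paste0("df = ", df,
                         if (correct) "; Yates-corrected" else
                           "; no continuity correction"))
}

#' Pearson product-moment correlation test
#'
#' Two-sided p from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return a `test_result` (statistic = r).
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("argument error: need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate error: zero variance")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
    tt <- Inf * sign(r)
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  new_test_result("Pearson correlation", r, NA_real_, p, n,
                  sprintf("t = %.4g, df = %d", tt, n - 2))
}
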