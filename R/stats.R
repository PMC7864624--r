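# Classical tests used by the experiments, written as the direct textbook
# formulas so each is checkable against an independent oracle. All p-values
# are two-sided; Bonferroni correction is min(1, m * p).

test_result <- function(method, statistic, df, p_raw, family_size,
                        degenerate = FALSE) {
  tibble::tibble(
    method = method,
    statistic = statistic,
    df = df,
    p_raw = p_raw,
    p_corrected = bonferroni(p_raw, family_size),
    family_size = as.integer(family_size),
    degenerate = degenerate
  )
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s).
#' @param m Family size (>= 1).
#' @return `min(1, m * p_raw)`, vectorized.
#' @export
bonferroni <- function(p_raw, m) {
  if (any(m < 1)) stop("family size must be >= 1", call. = FALSE)
  pmin(1, m * p_raw)
}

#' One-sample t test
#'
#' Two-sided test of the sample mean against `mu0`:
#' `t = (mean - mu0) / (s / sqrt(n))` on `n - 1` degrees of freedom. A
#' zero-variance sample is degenerate: p is 0 if the mean differs from `mu0`
#' and 1 otherwise (flagged, not thrown).
#'
#' @param values Numeric sample (n >= 2).
#' @param mu0 Null mean.
#' @param family_size Bonferroni family size for `p_corrected`.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_raw`,
#'   `p_corrected`, `family_size`, `degenerate`.
#' @export
one_sample_t <- function(values, mu0, family_size = 1L) {
  n <- length(values)
  if (n < 2L) stop("need at least two values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    diff <- mean(values) != mu0
    return(test_result("one_sample_t",
                       statistic = if (diff) sign(mean(values) - mu0) * Inf else 0,
                       df = n - 1, p_raw = if (diff) 0 else 1,
                       family_size = family_size, degenerate = TRUE))
  }
  t <- (mean(values) - mu0) / (s / sqrt(n))
  test_result("one_sample_t", t, n - 1, 2 * stats::pt(-abs(t), n - 1),
              family_size)
}

#' Two-sample t test (pooled variance by default)
#'
#' Pooled: `df = n_a + n_b - 2`; Welch (`var_equal = FALSE`) uses the
#' Welch-Satterthwaite degrees of freedom. Two-sided.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pool the variances (default `TRUE`).
#' @param family_size Bonferroni family size.
#' @return One-row tibble as in [one_sample_t()].
#' @export
two_sample_t <- function(a, b, var_equal = TRUE, family_size = 1L) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least two values per sample", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    diff <- mean(a) != mean(b)
    return(test_result("two_sample_t",
                       statistic = if (diff) sign(mean(a) - mean(b)) * Inf else 0,
                       df = na + nb - 2, p_raw = if (diff) 0 else 1,
                       family_size = family_size, degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  test_result("two_sample_t", t, df, 2 * stats::pt(-abs(t), df), family_size)
}

# ECDF difference statistic on the pooled sorted support (well defined under
# ties, which are pervasive in team metrics: multiples of 1/427)
ks_statistic <- function(a, b) {
  support <- sort(unique(c(a, b)))
  Fa <- vapply(support, function(s) mean(a <= s), numeric(1))
  Fb <- vapply(support, function(s) mean(b <= s), numeric(1))
  max(abs(Fa - Fb))
}

# exact P(D >= d) for tie-free samples of sizes n, m: counts monotone lattice
# paths (0,0) -> (n,m) whose ECDF gap stays strictly below d everywhere;
# integer band |i*m - j*n| < round(d*n*m) keeps the comparison exact.
ks_exact_p <- function(d, n, m) {
  K <- round(d * n * m)
  if (K <= 0) return(1)
  u <- matrix(0, n + 1L, m + 1L)
  u[1L, 1L] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0L && j == 0L) next
      if (abs(i * m - j * n) >= K) next
      acc <- 0
      if (i > 0L) acc <- acc + u[i, j + 1L]
      if (j > 0L) acc <- acc + u[i + 1L, j]
      u[i + 1L, j + 1L] <- acc
    }
  }
  max(0, min(1, 1 - u[n + 1L, m + 1L] / choose(n + m, n)))
}

# asymptotic two-sided Kolmogorov tail 2*sum((-1)^(k-1) exp(-2 k^2 x^2))
ks_asymptotic_p <- function(d, n, m) {
  x <- sqrt(n * m / (n + m)) * d
  if (x < 1e-12) return(1)
  k <- seq_len(100)
  max(0, min(1, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum ECDF difference evaluated on the pooled sorted support
#' (well defined for the heavily tied team-metric distributions). The
#' two-sided p-value is exact (lattice-path counting over all equally likely
#' interleavings) when both samples have at most 25 observations, asymptotic
#' otherwise. The exact computation assumes tie-free interleavings; under ties
#' it is conservative.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param exact Force exact (`TRUE`) or asymptotic (`FALSE`); default chooses
#'   exact when `max(length(a), length(b)) <= 25`.
#' @param family_size Bonferroni family size.
#' @return One-row tibble as in [one_sample_t()] (`statistic` is D, `df` NA).
#' @export
ks_two_sample <- function(a, b, exact = NULL, family_size = 1L) {
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("both samples must be nonempty", call. = FALSE)
  d <- ks_statistic(a, b)
  if (is.null(exact)) exact <- max(n, m) <= 25L
  p <- if (exact) ks_exact_p(d, n, m) else ks_asymptotic_p(d, n, m)
  test_result("ks_two_sample", d, NA_real_, p, family_size)
}
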