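#' Cliff's delta effect size
#'
#' The nonparametric dominance statistic
#' delta = (#\{a_i > b_j\} - #\{a_i < b_j\}) / (n_a * n_b), in [-1, 1].
#' Ties contribute zero. Computed in O((n+m) log(n+m)) from the sorted
#' second sample, and exactly equal to the brute-force enumeration over
#' all cross-pairs.
#'
#' @param a,b non-empty numeric vectors.
#' @return list of class `effect_size` with `delta`, `n_a`, `n_b`.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stopf("both samples must be non-empty.")
  }
  sb <- sort(b)
  # for each a_i: count of b strictly below, and at or below, a_i
  n_le <- findInterval(a, sb)
  n_lt <- findInterval(a, sb, left.open = TRUE)
  n_gt <- length(b) - n_le
  delta <- (sum(n_lt) - sum(n_gt)) / (length(a) * length(b))
  structure(list(delta = delta, n_a = length(a), n_b = length(b)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cliff's delta = %.4f (n_a = %d, n_b = %d)\n",
              x$delta, x$n_a, x$n_b))
  invisible(x)
}

#' t-based confidence interval for a mean
#'
#' @param values numeric vector with at least 2 values.
#' @param level coverage, in (0, 1).
#' @return list with `mean`, `ci_low`, `ci_high`.
#' @export
mean_ci <- function(values, level = 0.95) {
  if (length(values) < 2L) stopf("need at least 2 values.")
  check_scalar_number(level, "level")
  if (level <= 0 || level >= 1) stopf("`level` must be in (0, 1).")
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = length(values) - 1) *
    stats::sd(values) / sqrt(length(values))
  list(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Power of the one-way ANOVA omnibus F test
#'
#' Power for total sample size `n_total` split equally over `k_groups`,
#' at Cohen's effect size f, using the noncentral F distribution with
#' noncentrality lambda = f^2 * N, df1 = k - 1, df2 = N - k.
#'
#' @param n_total total sample size (> k_groups).
#' @param effect_size_f Cohen's f (> 0).
#' @param k_groups number of groups (>= 2).
#' @param alpha significance level.
#' @return power in (0, 1).
#' @export
anova_power <- function(n_total, effect_size_f, k_groups = 3, alpha = 0.05) {
  k_groups <- check_count(k_groups, "k_groups", lower = 2L)
  check_scalar_number(effect_size_f, "effect_size_f")
  if (effect_size_f <= 0) stopf("`effect_size_f` must be > 0.")
  if (n_total <= k_groups) stopf("`n_total` must exceed `k_groups`.")
  df1 <- k_groups - 1
  df2 <- n_total - k_groups
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = effect_size_f^2 * n_total,
            lower.tail = FALSE)
}

#' A-priori sample size for a one-way ANOVA
#'
#' Smallest balanced total N (a multiple of `k_groups`) at which the
#' omnibus F test reaches the target power. Defaults alpha = .05 and
#' power = .80 are the conventional planning values; the design here does
#' not pin them down otherwise, so both are overridable.
#'
#' @inheritParams anova_power
#' @param power target power in (0, 1).
#' @param n_cap search cap on N; exceeding it is an error.
#' @return required total sample size (integer, multiple of `k_groups`).
#' @export
#' @examples
#' anova_required_sample_size(0.25, k_groups = 3)  # 159
#' anova_required_sample_size(0.30, k_groups = 3)  # 111
anova_required_sample_size <- function(effect_size_f, k_groups = 3,
                                       alpha = 0.05, power = 0.80,
                                       n_cap = 1e6) {
  k_groups <- check_count(k_groups, "k_groups", lower = 2L)
  check_scalar_number(power, "power")
  if (power <= 0 || power >= 1) stopf("`power` must be in (0, 1).")
  n <- 2L * k_groups  # smallest balanced N with positive error df
  while (n <= n_cap) {
    if (anova_power(n, effect_size_f, k_groups, alpha) >= power) {
      return(as.integer(n))
    }
    n <- n + k_groups
  }
  stopf("target power not attainable with N <= %d.", n_cap)
}
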