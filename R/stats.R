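# Normality-gated two-group comparison and correlation.

# Lilliefors (Kolmogorov-Smirnov with estimated mean and sd) distance
.ks_normal_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

# Monte-Carlo null distribution of the Lilliefors distance for sample size
# n; depends only on n, so it is cached per (n, n_mc, seed)
.lilliefors_null <- function(n, n_mc, seed) {
  key <- sprintf("lillie_%d_%d_%d", n, n_mc, seed)
  cached <- .metkin_cache[[key]]
  if (!is.null(cached)) return(cached)
  d <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_mc), nrow = n)
    apply(m, 2, .ks_normal_stat)
  })
  .metkin_cache[[key]] <- d
  d
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance of the sample against a normal with the sample's own mean
#' and standard deviation, with the P value taken from a seeded Monte-Carlo
#' null: `n_mc` normal samples of the same size, each re-standardised, give
#' the null distribution of the distance, and
#' `P = (1 + #(D_null >= D_obs)) / (n_mc + 1)`. The null table depends only
#' on the sample size and is cached, so repeated calls are cheap.
#'
#' @param x numeric sample, size >= 4, not constant.
#' @param n_mc number of Monte-Carlo null samples (default 10000).
#' @param seed integer seed for the null table.
#' @return The P value, with attribute `statistic` (the KS distance).
#' @examples
#' p <- lilliefors_ks(rnorm(20), n_mc = 1000)
#' @export
lilliefors_ks <- function(x, n_mc = 10000, seed = 20160623L) {
  if (!is.numeric(x) || length(x) < 4L)
    stop("sample size must be at least 4", call. = FALSE)
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample", call. = FALSE)
  .assert_scalar_num(n_mc, "n_mc", 1, strict = FALSE)
  d_obs <- .ks_normal_stat(x)
  d_null <- .lilliefors_null(length(x), as.integer(n_mc), as.integer(seed))
  structure((1 + sum(d_null >= d_obs)) / (n_mc + 1), statistic = d_obs)
}

# Mann-Whitney U statistic (ties counted half) from pooled values
.mw_u <- function(pooled, idx_a, n_a) {
  sum(rank(pooled)[idx_a]) - n_a * (n_a + 1) / 2
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact permutation enumeration over all group assignments when the
#' combined sample size is at most 12 (ties handled via midranks; the
#' two-sided P counts assignments whose U is at least as far from its null
#' mean as observed). Larger samples use the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (U of group a), `p_value` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 by enumeration
#' @export
mann_whitney <- function(a, b) {
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (n_a < 1L || n_b < 1L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  u_obs <- .mw_u(pooled, seq_len(n_a), n_a)
  mu <- n_a * n_b / 2
  if (n <= 12L) {
    combos <- utils::combn(n, n_a)
    u_all <- apply(combos, 2, function(idx) .mw_u(pooled, idx, n_a))
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ranks <- rank(pooled)
    ties <- table(ranks)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Normality-gated two-group comparison
#'
#' Mirrors the classical reporting pipeline: both groups are tested for
#' normality with [lilliefors_ks()]; if both pass at `alpha_normality` the
#' groups are compared with a two-sided pooled-variance (Student's)
#' unpaired t test, otherwise with the two-sided Mann-Whitney rank-sum
#' test. Groups smaller than 4 (or constant samples) cannot be tested for
#' normality; the gate then defaults to the t test with `NA` normality P.
#' Significance is declared at P < 0.05.
#'
#' @param a,b numeric per-subject values, each of size >= 2.
#' @param alpha_normality gate level (default 0.05).
#' @param n_mc,seed forwarded to [lilliefors_ks()].
#' @param welch use the Welch (unpooled) t test instead of Student's
#'   (default `FALSE`).
#' @return An object of class `group_comparison` with fields `test_used`
#'   (`"student_t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `fold_change` (mean(a)/mean(b)), `normality_p_a`, `normality_p_b`,
#'   `significant`, group sizes, means and SEMs.
#' @examples
#' compare_groups(c(5, 6, 7, 8), c(1, 2, 3, 4))
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, n_mc = 10000,
                           seed = 20160623L, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  norm_p <- function(x) {
    if (length(x) < 4L || stats::sd(x) == 0) return(NA_real_)
    as.numeric(lilliefors_ks(x, n_mc = n_mc, seed = seed))
  }
  pa <- norm_p(a); pb <- norm_p(b)
  gate_pass <- (is.na(pa) || pa >= alpha_normality) &&
    (is.na(pb) || pb >= alpha_normality)
  if (gate_pass) {
    tt <- stats::t.test(a, b, var.equal = !welch)
    test_used <- "student_t"; statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    mw <- mann_whitney(a, b)
    test_used <- "mann_whitney"; statistic <- mw$statistic
    p <- mw$p_value
  }
  fc <- tryCatch(as.numeric(fold_change(a, b)), error = function(e) NA_real_)
  structure(list(test_used = test_used, statistic = statistic, p_value = p,
                 fold_change = fc, normality_p_a = pa, normality_p_b = pb,
                 significant = is.finite(p) && p < 0.05,
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b),
                 sem_a = stats::sd(a) / sqrt(length(a)),
                 sem_b = stats::sd(b) / sqrt(length(b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s)\n",
              if (x$test_used == "student_t") "Student's t, pooled variance"
              else "Mann-Whitney rank-sum"))
  cat(sprintf("  a: n=%d, %.4g +/- %.3g;  b: n=%d, %.4g +/- %.3g (mean +/- SEM)\n",
              x$n_a, x$mean_a, x$sem_a, x$n_b, x$mean_b, x$sem_b))
  cat(sprintf("  statistic = %.4g, P = %.4g%s; fold-change a/b = %.4g\n",
              x$statistic, x$p_value,
              if (x$significant) " (significant at 0.05)" else "",
              x$fold_change))
  invisible(x)
}

#' Pearson correlation with t-based P value
#'
#' Sample Pearson correlation coefficient with the two-sided P value from
#' the t transform `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p_value`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p_value = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t_stat), df = n - 2))
}
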