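# Group-level statistics: pooled Pearson regression of best frequency on
# best ITD, two-regression t-tests on slope and intercept, Mann-Whitney U
# with the min(U1, U2) reporting convention, and the rank-biserial effect
# size derived from U.

#' Pearson regression (ordinary least squares)
#'
#' @param x,y Numeric vectors (e.g. best ITDs and best frequencies of one
#'   group, pooled across birds); `n >= 3`, `x` not constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (two-sided,
#'   from the correlation t-statistic with n-2 df), `n`, and internal
#'   sums reused by the slope/intercept comparisons.
#' @export
pearson_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("regression needs n >= 3", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant; regression degenerate", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  sse <- syy - slope * sxy
  p <- if (is.na(r2) || r2 >= 1) 0 else {
    r <- sqrt(r2) * sign(slope)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r_squared = r2, p = p, n = n,
       sxx = sxx, sse = sse, x_mean = mean(x))
}

# pooled residual variance of two regressions (df = n1 + n2 - 4)
pooled_sigma2 <- function(a, b) (a$sse + b$sse) / (a$n + b$n - 4L)

#' Compare two regression slopes (Student's t)
#'
#' `t = (b_A - b_B) / SE`, with the standard error built from the pooled
#' residual variance of the two fits; `df = n_A + n_B - 4`; two-sided p.
#'
#' @param a,b Results of [pearson_regression()] (or `x`/`y` lists, which
#'   are fit first).
#' @return List with `t`, `p`, `df`.
#' @export
compare_slopes <- function(a, b) {
  a <- as_regression(a); b <- as_regression(b)
  s2 <- pooled_sigma2(a, b)
  se <- sqrt(s2 * (1 / a$sxx + 1 / b$sxx))
  tstat <- (a$slope - b$slope) / se
  df <- a$n + b$n - 4L
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df), df = df)
}

#' Compare two regression intercepts (Student's t)
#'
#' @inheritParams compare_slopes
#' @return List with `t`, `p`, `df`.
#' @export
compare_intercepts <- function(a, b) {
  a <- as_regression(a); b <- as_regression(b)
  s2 <- pooled_sigma2(a, b)
  se <- sqrt(s2 * (1 / a$n + a$x_mean^2 / a$sxx +
                   1 / b$n + b$x_mean^2 / b$sxx))
  tstat <- (a$intercept - b$intercept) / se
  df <- a$n + b$n - 4L
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df), df = df)
}

as_regression <- function(r) {
  if (is.list(r) && all(c("slope", "sxx", "sse") %in% names(r))) return(r)
  if (is.list(r) && all(c("x", "y") %in% names(r))) {
    return(pearson_regression(r$x, r$y))
  }
  stop("expected a pearson_regression() result or list(x =, y =)",
       call. = FALSE)
}

#' Mann-Whitney U test
#'
#' U is reported with the `min(U1, U2)` convention (the convention under
#' which the published U statistics are consistent with their effect
#' sizes); ties contribute 0.5. The two-sided p-value is exact when
#' `n1 * n2 <= 400` and there are no ties, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric samples.
#' @return List with `U` (= min(U1, U2)), `U1`, `U2`, `p`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty",
                               call. = FALSE)
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)])
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 * n2 <= 400) {
    p <- 2 * stats::pwilcox(u, n1, n2)
    # pwilcox is P(U <= u); when u is the midpoint both tails overlap
    p <- min(p, 1)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    z <- (u - mu + 0.5) / sigma       # continuity-corrected lower tail
    p <- min(2 * stats::pnorm(z), 1)
  }
  list(U = u, U1 = u1, U2 = u2, p = p, n1 = n1, n2 = n2)
}

#' Rank-biserial effect size from a Mann-Whitney U statistic
#'
#' `r = |1 - 2U/(n1*n2)|`: 0 when the groups overlap completely
#' (U = n1*n2/2), 1 when they do not overlap at all (U = 0 or n1*n2).
#' Invariant to which group's U is supplied.
#'
#' @param U U statistic (any of U1, U2 or min).
#' @param n1,n2 Group sizes.
#' @return Effect size in `[0, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) {
    stop("U must lie in [0, n1*n2]", call. = FALSE)
  }
  abs(1 - 2 * U / (n1 * n2))
}

#' Full group comparison report
#'
#' Per-group pooled regressions of best frequency on |best ITD|, pairwise
#' slope/intercept t-tests, and pairwise Mann-Whitney U tests with
#' rank-biserial effect sizes on the frontal neurons' best frequencies.
#'
#' @param summaries Data frame of per-neuron summaries (as produced by
#'   [summarize_neuron()]), with columns `group`, `best_itd_us`,
#'   `best_freq_hz`, `is_frontal`.
#' @param groups Group labels to compare (default: all present).
#' @return List with `regressions`, `regression_tests`, `frontal_tests`
#'   (each pairwise entry holding U, p, rank_biserial_r and a direction
#'   sign), ready for JSON export.
#' @export
group_stats <- function(summaries, groups = unique(summaries$group)) {
  stopifnot(all(c("group", "best_itd_us", "best_freq_hz", "is_frontal")
                %in% names(summaries)))
  regs <- list()
  for (g in groups) {
    d <- summaries[summaries$group == g, ]
    regs[[g]] <- if (nrow(d) >= 3L) {
      tryCatch(pearson_regression(abs(d$best_itd_us), d$best_freq_hz),
               error = function(e) NULL)
    } else NULL
  }
  pair_names <- utils::combn(groups, 2L, paste, collapse = "_vs_")
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  reg_tests <- list()
  frontal_tests <- list()
  for (k in seq_along(pairs)) {
    g1 <- pairs[[k]][1L]; g2 <- pairs[[k]][2L]
    nm <- pair_names[k]
    if (!is.null(regs[[g1]]) && !is.null(regs[[g2]])) {
      reg_tests[[nm]] <- list(slope = compare_slopes(regs[[g1]], regs[[g2]]),
                              intercept = compare_intercepts(regs[[g1]],
                                                             regs[[g2]]))
    }
    f1 <- summaries$best_freq_hz[summaries$group == g1 &
                                   summaries$is_frontal]
    f2 <- summaries$best_freq_hz[summaries$group == g2 &
                                   summaries$is_frontal]
    if (length(f1) >= 1L && length(f2) >= 1L) {
      mw <- mann_whitney_u(f1, f2)
      frontal_tests[[nm]] <- c(
        mw,
        list(rank_biserial_r = rank_biserial(mw$U, mw$n1, mw$n2),
             direction = sign(stats::median(f1) - stats::median(f2))))
    }
  }
  list(groups = groups,
       regressions = lapply(regs, function(r) {
         if (is.null(r)) NULL
         else r[c("slope", "intercept", "r_squared", "p", "n")]
       }),
       regression_tests = reg_tests,
       frontal_tests = frontal_tests,
       conventions = list(
         u_statistic = "min(U1, U2), ties counted 0.5",
         p = "two-sided; exact if n1*n2 <= 400 and no ties, else normal approximation with tie and continuity corrections",
         rank_biserial = "|1 - 2U/(n1*n2)|, direction reported separately"))
}
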