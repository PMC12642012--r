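#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by enumeration: with margins fixed, the
#' hypergeometric probability of every attainable table is computed and
#' the p-value is the sum over tables whose probability does not exceed
#' that of the observed table (the probability-mass rule used by
#' mainstream implementations; a small relative tolerance guards the
#' comparison against floating-point ties).
#'
#' @param a,b,c,d Cell counts, row-wise: `a b / c d`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(15, 0, 4, 6)  # ~0.001
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if ((a + b) + (c + d) == 0 || ((a + c) == 0 && (b + d) == 0))
    stop("both margins must be positive")
  m <- a + c          # first-column margin
  n0 <- b + d         # second-column margin
  k <- a + b          # first-row margin
  support <- max(0L, k - n0):min(k, m)
  # log-probabilities, normalised for numerical safety
  logp <- stats::dhyper(support, m, n0, k, log = TRUE)
  obs <- stats::dhyper(a, m, n0, k, log = TRUE)
  rel_tol <- 1 + 1e-7
  p <- sum(exp(logp)[logp <= obs + log(rel_tol)])
  min(1, p)
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition across `k`
#' groups: `df1 = k - 1`, `df2 = N - k`,
#' `F = (SSB/df1) / (SSW/df2)`.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List with `f`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#'   `f` and `p` are `NA` when all values are identical.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("each group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop("values must be finite")
  k <- length(groups)
  n <- length(x)
  if (n <= k) stop("total sample size must exceed the number of groups")
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    return(list(f = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                ss_between = 0, ss_within = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

#' Cohen's d (pooled-SD standardised mean difference)
#'
#' `|m1 - m2| / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Reported as a magnitude; the direction (sign of `m1 - m2`) is
#' returned separately.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries. Alternatively call
#'   [cohens_d_raw()] on two sample vectors.
#' @return List with `d` (magnitude; `Inf` when both SDs are zero with
#'   unequal means, 0 when equal) and `direction` (-1, 0, 1).
#' @examples
#' cohens_d(226, 13 * 2, 4, 131, 11 * 2, 4)$d  # HR: ~3.94
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  diff <- mean1 - mean2
  d <- if (sp == 0) {
    if (diff == 0) 0 else Inf
  } else abs(diff) / sp
  list(d = d, direction = sign(diff))
}

#' @rdname cohens_d
#' @param x,y Raw sample vectors.
#' @export
cohens_d_raw <- function(x, y) {
  cohens_d(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Welch t-statistic from published summaries
#'
#' Recomputes a Welch two-sample t-test from group means, standard
#' errors and sizes: `t = (m1 - m2) / sqrt(se1^2 + se2^2)`, with
#' Welch-Satterthwaite degrees of freedom using the squared standard
#' errors as variance-of-mean terms.
#'
#' @param mean1,se1,n1,mean2,se2,n2 Group summaries (SE > 0, n >= 2).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summaries <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  v <- se1^2 + se2^2
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Assumption-gated pairwise t-tests with Holm correction
#'
#' For every pair of groups, chooses Welch's t-test when Bartlett's
#' test rejects variance homogeneity (p < `bartlett_alpha`), otherwise
#' a pooled-SD Student t-test; attaches Cohen's d; and Holm-adjusts the
#' two-sided p-values over the declared family (all tested pairs by
#' default). Shapiro-Wilk normality per group is recorded to guide the
#' reporting style (mean +/- SE vs median/IQR); it does not switch the
#' test. Pairs with any group of size < 2 are skipped with a warning.
#'
#' @param groups Named list of numeric vectors.
#' @param bartlett_alpha Variance-homogeneity gate (default 0.05).
#' @return A data frame of class `pairwise_results` with columns
#'   `group1`, `group2`, `test`, `t`, `df`, `p_raw`, `p_holm`, `d`,
#'   plus attributes `family_size` and `shapiro_p` (named per group).
#' @export
pairwise_tests <- function(groups, bartlett_alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  labels <- names(groups)
  shapiro_p <- vapply(groups, function(g) {
    if (length(g) >= 3L && stats::sd(g) > 0)
      stats::shapiro.test(g)$p.value else NA_real_
  }, numeric(1))
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    g1 <- groups[[i1]]; g2 <- groups[[i2]]
    if (length(g1) < 2L || length(g2) < 2L) {
      warning(sprintf("pair %s vs %s skipped: group with n < 2",
                      labels[i1], labels[i2]))
      next
    }
    bart_p <- stats::bartlett.test(list(g1, g2))$p.value
    welch <- is.finite(bart_p) && bart_p < bartlett_alpha
    tt <- stats::t.test(g1, g2, var.equal = !welch)
    d <- cohens_d_raw(g1, g2)
    rows[[j]] <- data.frame(group1 = labels[i1], group2 = labels[i2],
                            test = if (welch) "Welch" else "Student",
                            t = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_raw = tt$p.value, d = d$d,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) stop("no testable pairs")
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res <- res[, c("group1", "group2", "test", "t", "df",
                 "p_raw", "p_holm", "d")]
  structure(res, class = c("pairwise_results", "data.frame"),
            family_size = nrow(res), shapiro_p = shapiro_p)
}

#' Descriptive summary of one group
#'
#' Mean, SE, SD, median and quartiles, plus a Shapiro-Wilk p-value and
#' the implied reporting style (mean +/- SE for normal-looking data,
#' median (Q1, Q3) otherwise).
#'
#' @param values Numeric vector (n >= 1).
#' @param shapiro_alpha Normality gate for the reporting style.
#' @return List with `n`, `mean`, `se`, `sd`, `median`, `q1`, `q3`,
#'   `shapiro_p`, `style`.
#' @export
summary_stat <- function(values, shapiro_alpha = 0.05) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  n <- length(values)
  sdev <- if (n > 1L) stats::sd(values) else NA_real_
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  sp <- if (n >= 3L && isTRUE(sdev > 0))
    stats::shapiro.test(values)$p.value else NA_real_
  list(n = n, mean = mean(values), se = sdev / sqrt(n), sd = sdev,
       median = q[2], q1 = q[1], q3 = q[3], shapiro_p = sp,
       style = if (!is.na(sp) && sp < shapiro_alpha)
         "median (Q1, Q3)" else "mean +/- SE")
}

#' Rule-of-thumb sample size per group
#'
#' `N = DF / k + 1` animals per group for a target error degrees of
#' freedom `DF` spread over `k` groups; used when no pilot data exist.
#'
#' @param df Target degrees of freedom (> 0).
#' @param k Number of groups (>= 1).
#' @return List with `n_raw` and `n` (ceiling-rounded).
#' @examples
#' sample_size_rule(15, 5)$n  # 4
#' @export
sample_size_rule <- function(df, k) {
  stopifnot(df > 0, k >= 1)
  n_raw <- df / k + 1
  list(n_raw = n_raw, n = ceiling(n_raw))
}
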