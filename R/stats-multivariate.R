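#' Principal component analysis of z-scored metrics
#'
#' Correlation-mode PCA: each metric column is centred and scaled to
#' unit variance before the eigendecomposition, so heterogeneous units
#' (bpm, mmHg, mL/min, ...) contribute equally. Constant columns are
#' dropped with a warning. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param x Numeric matrix or data frame, observations in rows and
#'   metrics in columns.
#' @return An object of class `ordination_result`: list with `scores`
#'   (observations x components), `loadings`, `var_explained`
#'   (fractions summing to 1 over all components), `dropped` (names of
#'   constant columns).
#' @export
pca_metrics <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 2L)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-constant metrics left")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 dropped = dropped),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("PCA of %d observations, %d components\n",
              nrow(x$scores), length(ve)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(ve, 4L)), collapse = ", "),
      if (length(ve) > 4L) "..." else "", "\n")
  invisible(x)
}

#' Euclidean distance PerMANOVA
#'
#' Permutational multivariate ANOVA on a distance matrix. With
#' `SS_total = sum(d_ij^2)/N` over all pairs and `SS_within` the
#' analogous within-group sum, the pseudo-F statistic is
#' `((SS_total - SS_within)/(k-1)) / (SS_within/(N-k))`. The p-value is
#' `(number of permuted F >= observed + 1) / (n_perm + 1)`, with label
#' permutations drawn under the given seed.
#'
#' @param dist A `dist` object or symmetric zero-diagonal matrix of
#'   distances between observations.
#' @param labels Group label per observation; at least 2 groups with at
#'   least 2 members each.
#' @param n_perm Number of label permutations (>= 99; default 9999).
#' @param seed Integer seed for the permutations (mandatory).
#' @return List with `pseudo_f`, `p_perm`, `df1`, `df2`, `n_perm`,
#'   `seed`.
#' @export
permanova <- function(dist, labels, n_perm = 9999, seed) {
  if (missing(seed)) stop("a permutation seed is required")
  stopifnot(n_perm >= 99)
  dm <- as.matrix(dist)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8 ||
      any(abs(diag(dm)) > 1e-8))
    stop("dist must be symmetric with zero diagonal")
  labels <- as.character(labels)
  n <- nrow(dm)
  if (length(labels) != n) stop("labels must match the distance matrix")
  tab <- table(labels)
  k <- length(tab)
  if (k < 2L || any(tab < 2L)) stop("need >= 2 groups with >= 2 members each")
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  pseudo_f_for <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- pseudo_f_for(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(i) pseudo_f_for(sample(labels)), numeric(1))
  list(pseudo_f = f_obs,
       p_perm = (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1),
       df1 = k - 1L, df2 = n - k, n_perm = n_perm, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulation-based power of a two-sample Student t-test
#'
#' Monte-Carlo power: draws `reps` pairs of normal samples with the
#' given mean difference and common SD, applies a pooled-SD Student
#' t-test at level `alpha`, and reports the rejection fraction with its
#' Monte-Carlo standard error.
#'
#' @param delta True mean difference.
#' @param sd Common standard deviation.
#' @param n_per_group Sample size per group.
#' @param alpha Significance level (default 0.05).
#' @param reps Simulation replicates (>= 1000 recommended for
#'   reporting; default 2000).
#' @param seed Integer seed.
#' @return List with `power`, `mc_se`, `reps`.
#' @export
power_t_sim <- function(delta, sd, n_per_group, alpha = 0.05,
                        reps = 2000, seed) {
  if (missing(seed)) stop("a simulation seed is required")
  stopifnot(alpha > 0, alpha < 1, reps >= 1, n_per_group >= 2, sd > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_per_group
  # vectorised over replicates: group means and variances suffice
  x <- matrix(stats::rnorm(reps * n, 0, sd), reps)
  y <- matrix(stats::rnorm(reps * n, delta, sd), reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  tstat <- (my - mx) / sqrt(sp2 * 2 / n)
  df <- 2 * n - 2
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  pw <- mean(p < alpha)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / reps), reps = reps)
}

#' Power of a two-sample test of proportions
#'
#' At desk scale (both groups of size <= `exact_max_n`) the power is
#' computed by full enumeration: every outcome pair `(x1, x2)` is
#' weighted by its binomial probability under the alternative and
#' tested with the exact Fisher test at level `alpha`. For larger
#' groups a two-sample normal approximation is used.
#'
#' @param p1,p2 True success probabilities.
#' @param n1,n2 Group sizes.
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Enumeration cut-over (default 30).
#' @return List with `power` and `method` ("enumeration" or "normal").
#' @export
power_proportions <- function(p1, p2, n1, n2, alpha = 0.05,
                              exact_max_n = 30) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    pw <- 0
    w1 <- stats::dbinom(0:n1, n1, p1)
    w2 <- stats::dbinom(0:n2, n2, p2)
    for (x1 in 0:n1) {
      if (w1[x1 + 1] == 0) next
      for (x2 in 0:n2) {
        wt <- w1[x1 + 1] * w2[x2 + 1]
        if (wt == 0) next
        # a degenerate column margin carries no evidence either way
        pval <- if (x1 + x2 == 0 || x1 + x2 == n1 + n2) 1 else
          fisher_exact_2x2(x1, n1 - x1, x2, n2 - x2)
        if (pval < alpha) pw <- pw + wt
      }
    }
    list(power = pw, method = "enumeration")
  } else {
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    if (se1 == 0) return(list(power = as.numeric(
      abs(p1 - p2) > stats::qnorm(1 - alpha / 2) * se0), method = "normal"))
    z <- stats::qnorm(1 - alpha / 2)
    diff <- abs(p1 - p2)
    pw <- stats::pnorm((diff - z * se0) / se1) +
      stats::pnorm((-diff - z * se0) / se1)
    list(power = pw, method = "normal")
  }
}
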