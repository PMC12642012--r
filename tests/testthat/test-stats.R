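# Brute-force Fisher oracle: iterate every table with the observed
# margins and sum hypergeometric probabilities computed from binomial
# coefficients.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

test_that("Fisher exact matches the enumeration oracle and stats::fisher.test", {
  tables <- list(c(15, 0, 4, 6), c(7, 0, 4, 6), c(5, 5, 5, 5),
                 c(1, 9, 9, 1), c(3, 7, 2, 12), c(0, 8, 8, 0),
                 c(2, 2, 2, 2), c(10, 1, 1, 10))
  for (tb in tables) {
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("one-way ANOVA agrees with aov and the t-test identity", {
  set.seed(10)
  g <- list(a = rnorm(6, 0), b = rnorm(6, 1), c = rnorm(7, 0.5))
  res <- one_way_anova(g)
  df <- data.frame(y = unlist(g),
                   grp = rep(names(g), vapply(g, length, integer(1))))
  oracle <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(res$f, oracle[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p, oracle[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 16L)
  # two equal-sized groups: F equals the square of the pooled t
  g2 <- list(x = rnorm(8), y = rnorm(8, 0.7))
  t2 <- stats::t.test(g2$x, g2$y, var.equal = TRUE)$statistic^2
  expect_equal(one_way_anova(g2)$f, unname(t2), tolerance = 1e-9)
  # identical group means: F near zero
  g3 <- list(a = c(1, 2, 3) - 2, b = c(4, 5, 6) - 5)
  expect_equal(one_way_anova(g3)$f, 0, tolerance = 1e-12)
  # all values identical: F undefined
  expect_true(is.na(one_way_anova(list(a = c(1, 1), b = c(1, 1)))$f))
})

test_that("group sizes replicating the study yield its ANOVA bookkeeping", {
  set.seed(33)
  p <- group_presets()
  g <- lapply(seq_len(nrow(p)), function(i)
    rnorm(p$n_kinetics[i], p$hr_mean[i], p$hr_se[i] * sqrt(p$n_kinetics[i])))
  res <- one_way_anova(g)
  expect_equal(res$df1, 4L)
  expect_equal(res$df2, 17L)
})

test_that("pairwise battery picks Student vs Welch by the Bartlett gate", {
  set.seed(20)
  # equal variances: Student branch
  eq <- list(a = rnorm(10, 0, 1), b = rnorm(10, 1, 1))
  res_eq <- pairwise_tests(eq)
  expect_equal(res_eq$test, "Student")
  # 10x variance ratio: Welch branch
  uneq <- list(a = rnorm(12, 0, 1), b = rnorm(12, 1, sqrt(10)))
  res_uneq <- pairwise_tests(uneq)
  expect_equal(res_uneq$test, "Welch")
  # Cohen's d column matches the raw-sample computation
  expect_equal(res_eq$d, cohens_d_raw(eq$a, eq$b)$d, tolerance = 1e-12)
})

test_that("Holm adjustment is monotone, bounded and matches its definition", {
  set.seed(21)
  g <- list(a = rnorm(6), b = rnorm(6, 2), c = rnorm(6, 0.3), d = rnorm(6))
  res <- pairwise_tests(g)
  m <- attr(res, "family_size")
  expect_equal(m, 6L)
  expect_true(all(res$p_holm >= res$p_raw))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_holm[ord]) >= -1e-12))
  # the smallest raw p is multiplied by m when it survives the step-down
  expect_equal(min(res$p_holm), min(1, min(res$p_raw) * m),
               tolerance = 1e-12)
})

test_that("Welch t from summaries reproduces identities", {
  expect_equal(welch_t_from_summaries(5, 1, 4, 5, 1, 4)$t, 0)
  # equal SEs and n: symmetric Satterthwaite limit df = 2(n-1)
  expect_equal(welch_t_from_summaries(3, 1, 7, 5, 1, 7)$df, 12)
  expect_error(welch_t_from_summaries(1, 0, 4, 2, 1, 4), "positive")
})

test_that("Cohen's d: summaries, raw samples, and degenerate cases agree", {
  expect_equal(cohens_d(1, 1, 5, 0, 1, 5)$d, 1)
  expect_equal(cohens_d(3, 2, 4, 3, 1, 6)$d, 0)
  expect_true(is.infinite(cohens_d(1, 0, 4, 0, 0, 4)$d))
  set.seed(30)
  x <- rnorm(9, 2, 1.3); y <- rnorm(14, 0, 0.8)
  from_raw <- cohens_d_raw(x, y)
  from_sum <- cohens_d(mean(x), sd(x), 9, mean(y), sd(y), 14)
  expect_identical(from_raw, from_sum)
})

test_that("PCA: variance conservation, perfect correlation, exact eigenvalues", {
  set.seed(40)
  x <- matrix(rnorm(60), 12, 5)
  pc <- pca_metrics(x)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  expect_true(all(pc$var_explained >= 0))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # two perfectly correlated metrics: PC1 explains everything
  z <- rnorm(10)
  pc2 <- pca_metrics(cbind(z, 3 * z + 2))
  expect_equal(pc2$var_explained[1], 1, tolerance = 1e-9)
  # constructed sample correlation 0.5: eigenvalues 1.5 and 0.5
  u <- c(1, -1, 1, -1) / 2
  v <- c(1, 1, -1, -1) / 2
  pc3 <- pca_metrics(cbind(m1 = u, m2 = 0.5 * u + sqrt(0.75) * v))
  expect_equal(pc3$var_explained, c(0.75, 0.25), tolerance = 1e-9)
  # constant columns are dropped with a warning
  expect_warning(pc4 <- pca_metrics(cbind(a = z, b = 3 * z, cst = 1)),
                 "constant")
  expect_equal(pc4$dropped, "cst")
})

test_that("PCA sign convention makes scores reproducible", {
  set.seed(41)
  x <- matrix(rnorm(48), 12, 4)
  pc1 <- pca_metrics(x)
  pc2 <- pca_metrics(x)
  expect_identical(pc1$scores, pc2$scores)
  top <- apply(pc1$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(top > 0))
})

test_that("PerMANOVA pseudo-F equals classical F on univariate data", {
  set.seed(50)
  g <- list(a = rnorm(5, 0), b = rnorm(6, 1), c = rnorm(5, 2))
  x <- unlist(g)
  labels <- rep(names(g), vapply(g, length, integer(1)))
  pm <- permanova(stats::dist(x), labels, n_perm = 99, seed = 1)
  expect_equal(pm$pseudo_f, one_way_anova(g)$f, tolerance = 1e-9)
})

test_that("PerMANOVA agrees with vegan::adonis2 on multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(51)
  x <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(20, 1), 5))
  labels <- rep(c("a", "b"), each = 5)
  pm <- permanova(stats::dist(x), labels, n_perm = 999, seed = 2)
  ad <- vegan::adonis2(stats::dist(x) ~ g,
                       data = data.frame(g = labels), permutations = 999)
  expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-9)
})

test_that("the PerMANOVA statistic is invariant to observation order", {
  set.seed(52)
  x <- rnorm(12)
  labels <- rep(c("a", "b", "c"), each = 4)
  perm <- sample(12)
  f1 <- permanova(stats::dist(x), labels, n_perm = 99, seed = 3)$pseudo_f
  f2 <- permanova(stats::dist(x[perm]), labels[perm], n_perm = 99,
                  seed = 3)$pseudo_f
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("well-separated clusters reach the minimum attainable p", {
  set.seed(53)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  labels <- rep(c("a", "b"), each = 10)
  pm <- permanova(stats::dist(x), labels, n_perm = 199, seed = 4)
  expect_equal(pm$p_perm, 1 / 200)
})

test_that("PerMANOVA p is reproducible under its seed", {
  set.seed(60)
  x <- rnorm(12)
  labels <- rep(c("a", "b"), each = 6)
  p1 <- permanova(stats::dist(x), labels, n_perm = 199, seed = 9)$p_perm
  p2 <- permanova(stats::dist(x), labels, n_perm = 199, seed = 9)$p_perm
  expect_identical(p1, p2)
})

test_that("simulated power matches the closed-form power curve", {
  pw <- power_t_sim(delta = 3, sd = 1, n_per_group = 4, reps = 4000,
                    seed = 5)
  oracle <- stats::power.t.test(n = 4, delta = 3, sd = 1,
                                sig.level = 0.05)$power
  expect_gt(pw$power, 0.8)
  expect_lt(abs(pw$power - oracle), 4 * pw$mc_se + 0.01)
  # doubling n does not decrease power beyond Monte-Carlo noise
  pw8 <- power_t_sim(delta = 1.5, sd = 1, n_per_group = 8, reps = 4000,
                     seed = 6)
  pw4 <- power_t_sim(delta = 1.5, sd = 1, n_per_group = 4, reps = 4000,
                     seed = 6)
  expect_gt(pw8$power, pw4$power - 3 * pw8$mc_se)
})

test_that("power of the proportion test by exact enumeration", {
  # oracle: weight every outcome pair by its binomial probability and
  # test with stats::fisher.test
  oracle_power <- function(p1, p2, n1, n2, alpha = 0.05) {
    pw <- 0
    for (x1 in 0:n1) for (x2 in 0:n2) {
      wt <- dbinom(x1, n1, p1) * dbinom(x2, n2, p2)
      if (wt == 0) next
      pv <- if (x1 + x2 == 0 || x1 + x2 == n1 + n2) 1 else
        stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                  byrow = TRUE))$p.value
      if (pv < alpha) pw <- pw + wt
    }
    pw
  }
  res <- power_proportions(1.0, 0.4, 15, 10)
  expect_equal(res$method, "enumeration")
  expect_equal(res$power, oracle_power(1.0, 0.4, 15, 10), tolerance = 1e-9)
  # null calibration: exact test is conservative, power <= alpha
  null_res <- power_proportions(0.5, 0.5, 12, 12)
  expect_lte(null_res$power, 0.05)
  # monotone in n
  expect_lte(power_proportions(0.9, 0.3, 4, 4)$power,
             power_proportions(0.9, 0.3, 8, 8)$power)
})

test_that("sample-size rule of thumb", {
  expect_equal(sample_size_rule(15, 5)$n, 4)
  expect_equal(sample_size_rule(10, 5)$n, 3)
  expect_equal(sample_size_rule(12, 1)$n, 13)
  expect_equal(sample_size_rule(16, 5)$n_raw, 16 / 5 + 1)
  expect_equal(sample_size_rule(16, 5)$n, 5)
})

test_that("summary statistics satisfy their internal identities", {
  set.seed(70)
  x <- rnorm(16, 10, 2)
  s <- summary_stat(x)
  expect_equal(s$sd, s$se * sqrt(s$n), tolerance = 1e-12)
  expect_lte(s$q1, s$median)
  expect_lte(s$median, s$q3)
  expect_equal(s$style, "mean +/- SE")
  skew <- exp(rnorm(50, 0, 1.5))
  expect_equal(summary_stat(skew)$style, "median (Q1, Q3)")
})
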