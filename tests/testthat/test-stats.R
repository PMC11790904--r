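test_that("spearman_test handles monotone and degenerate inputs", {
  expect_equal(spearman_test(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10))$rho, -1)
  expect_error(spearman_test(1:10, rep(2, 10)), "undefined-correlation")
  expect_error(spearman_test(1:4, 4:1), "insufficient-sample")
})

test_that("permutation p matches exhaustive enumeration for n <= 7", {
  # independent oracle: explicit loop over every ordering using base R's
  # cor(..., method = "spearman")
  brute_p <- function(x, y) {
    n <- length(y)
    perms <- NULL
    gen <- function(v, acc) {
      if (!length(v)) { perms[[length(perms) + 1L]] <<- acc; return() }
      for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
    perms <- list(); gen(seq_len(n), integer(0))
    obs <- abs(cor(x, y, method = "spearman"))
    mean(vapply(perms, function(p)
      abs(cor(x, y[p], method = "spearman")) >= obs - 1e-12, logical(1)))
  }
  cases <- list(
    list(x = c(3, 1, 4, 1.5, 9), y = c(2.6, 5.3, 5.8, 9.7, 9.3)),
    list(x = c(2, 1, 4, 3, 6, 5), y = c(1, 3, 2, 6, 4, 5)),
    list(x = c(7, 2, 5, 1, 6, 3, 4), y = c(1, 5, 2, 7, 3, 6, 4)))
  for (cs in cases) {
    got <- spearman_test(cs$x, cs$y)
    expect_equal(got$p, brute_p(cs$x, cs$y))
    expect_match(got$method, "exact permutation")
  }
})

test_that("D'Agostino-Pearson matches the reference implementation", {
  # expected values frozen from an independent implementation of the same
  # K^2 statistic (scipy.stats.normaltest)
  x2 <- c(0.5, 1.2, -0.3, 2.4, 0.9, -1.1, 0.2, 1.8, -0.7, 0.4, 1.1, -0.2,
          0.8, 2.9, -1.5, 0.1, 0.6, 1.4, -0.9, 0.3, 2.2, -0.4, 0.7, 1.0, -1.8)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 0.030482271560230048, tolerance = 1e-10)
  expect_equal(r2$p, 0.984874422505092, tolerance = 1e-10)
  x3 <- c(3.1, 4.5, 2.2, 5.9, 3.8, 4.1, 2.9, 6.3, 3.3, 4.8, 2.5, 5.1, 3.6,
          4.0, 7.2, 2.8, 3.9, 4.4, 3.0, 5.5)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 1.916605128758972, tolerance = 1e-10)
  expect_equal(r3$p, 0.38354337392312754, tolerance = 1e-10)
  x4 <- exp(seq(0, 3, length.out = 15))
  r4 <- dagostino_pearson(x4)
  expect_equal(r4$statistic, 4.119175443485295, tolerance = 1e-10)
  expect_equal(r4$p, 0.12750652722880024, tolerance = 1e-10)
  expect_error(dagostino_pearson(1:7), "insufficient-sample")
})

test_that("compare_two walks the decision tree", {
  # identical groups: no difference
  g <- c(1.2, 1.9, 2.7, 3.1, 3.8, 4.4, 5.0, 5.9, 6.3, 7.1)
  expect_gte(compare_two(g, g)$p_two_tailed, 0.99)
  # normal groups, equal variance, 3 SD shift at n = 20 -> Student's t
  set.seed(101)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 3, 1)
  r <- compare_two(a, b)
  expect_equal(r$test_name, "student t-test")
  expect_lt(r$p_two_tailed, 0.01)
  # heavily skewed groups at n = 15 -> Mann-Whitney
  set.seed(102)
  sk1 <- rlnorm(15, 0, 1.5); sk2 <- rlnorm(15, 0.3, 1.5)
  expect_equal(compare_two(sk1, sk2)$test_name, "mann-whitney u")
  # unequal variances on normal data -> Welch
  set.seed(105)
  w <- compare_two(rnorm(25, 0, 1), rnorm(25, 0.5, 6))
  expect_equal(w$test_name, "welch t-test")
  # paired branches
  set.seed(104)
  x <- rnorm(12); y <- x + rnorm(12, 0.1, 0.2)
  expect_match(compare_two(x, y, paired = TRUE)$test_name, "paired t|wilcoxon")
  expect_error(compare_two(1:2, 1:5), "insufficient-sample")
})

test_that("compare_multi gates ANOVA/Tukey vs Kruskal-Wallis/Dunn", {
  g <- c(1.2, 1.9, 2.7, 3.1, 3.8, 4.4, 5.0, 5.9, 6.3, 7.1)
  same <- compare_multi(list(g, g, g))
  expect_gte(same$p_two_tailed, 0.99)
  expect_true(all(same$pairwise$p_adj >= 0.99))
  # one group shifted 3 SD: only its pairs significant
  set.seed(105)
  gs <- list(rnorm(15), rnorm(15), rnorm(15, 3))
  r <- compare_multi(gs)
  pw <- r$pairwise
  hit <- pw$group1 == 3 | pw$group2 == 3
  expect_true(all(pw$p_adj[hit] < 0.05))
  expect_true(all(pw$p_adj[!hit] > 0.05))
  # skewed data select the rank path
  set.seed(106)
  sk <- lapply(1:3, function(i) rlnorm(15, 0.2 * i, 1.5))
  expect_equal(compare_multi(sk)$test_name, "kruskal-wallis + dunn")
  expect_error(compare_multi(list(g, g)), "insufficient-groups")
})

test_that("null type-I error stays near nominal through the tree", {
  # reduced replicate count for the unit suite; the acceptance suite runs
  # the full 2000
  set.seed(107)
  rej <- mean(vapply(1:400, function(i)
    compare_two(rnorm(10), rnorm(10))$p_two_tailed < 0.05, logical(1)))
  expect_lte(rej, 0.08)
})
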