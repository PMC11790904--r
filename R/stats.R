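#' Spearman rank correlation with small-sample permutation p values
#'
#' Average-rank Spearman rho. The two-tailed p value is computed by full
#' permutation enumeration for n <= 7 (<= 5040 orderings), by seeded
#' Monte-Carlo permutation for 8 <= n <= 10, and by the t approximation
#' otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 5, neither constant.
#' @param n_mc Monte-Carlo permutation count for 8 <= n <= 10.
#' @param seed Optional seed for the Monte-Carlo branch.
#' @return `list(rho, p, n, method)` of class `neuromech_test`.
#' @export
spearman_test <- function(x, y, n_mc = 19999, seed = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5L) stop("insufficient-sample: need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  eps <- 1e-12
  if (n <= 7L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "spearman (exact permutation)"
  } else if (n <= 10L) {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_mc)) {
      if (abs(stats::cor(rx, sample(ry))) >= abs(rho) - eps) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_mc + 1)
    method <- "spearman (Monte-Carlo permutation)"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "spearman (t approximation)"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "neuromech_test")
}

# all permutations of 1..n as an (n!) x n matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)
    if (pos < n) {
      tmp <- blk[, pos]
      blk[, pos] <- n
      blk[, n] <- tmp
    }
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' K^2 statistic combining the transformed sample skewness (D'Agostino) and
#' kurtosis (Anscombe-Glynn) z scores; K^2 is chi-squared with 2 df under
#' normality. Intended for n > 7 (the small-sample branch of the decision
#' tree uses Shapiro-Wilk).
#'
#' @param x Numeric vector, n >= 8.
#' @return `list(statistic, p, z_skew, z_kurt)`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("insufficient-sample: D'Agostino-Pearson needs n >= 8")
  if (stats::sd(x) == 0) stop("invalid-input: constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5                       # sample skewness g1
  b2 <- m4 / m2^2                         # sample kurtosis b2

  # skewness z (D'Agostino 1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
             ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)

  K2 <- z_skew^2 + z_kurt^2
  list(statistic = K2, p = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

# normality decision: D'Agostino-Pearson for n > 7, Shapiro-Wilk for 3..7
normality_check <- function(x) {
  n <- length(x)
  if (n < 3L) stop("insufficient-sample: need n >= 3 for normality testing")
  if (stats::sd(x) == 0)
    return(list(test = "constant", p = 0, normal = FALSE))
  if (n > 7L) {
    r <- dagostino_pearson(x)
    list(test = "dagostino-pearson", p = r$p, normal = r$p >= 0.05)
  } else {
    r <- stats::shapiro.test(x)
    list(test = "shapiro-wilk", p = r$p.value, normal = r$p.value >= 0.05)
  }
}

new_test_result <- function(test_name, statistic, p, n, notes) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_two_tailed = min(1, max(0, p)), n = n, notes = notes),
            class = "neuromech_test")
}

#' @export
print.neuromech_test <- function(x, ...) {
  if (!is.null(x$rho)) {
    cat(sprintf("%s: rho = %.4f, p = %.4g, n = %d\n", x$method, x$rho, x$p, x$n))
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %s\n",
                x$test_name, x$statistic, x$p_two_tailed,
                paste(x$n, collapse = "/")))
    if (length(x$notes)) cat("  ", paste(unlist(x$notes), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Two-group comparison following the normality-gated decision tree
#'
#' Normality is assessed per group with D'Agostino-Pearson (n > 7) or
#' Shapiro-Wilk (3 <= n <= 7) at alpha = 0.05. Dependent groups: paired t
#' (differences normal) or Wilcoxon signed-rank. Independent groups, both
#' normal: F test on variances gates Student's t (equal) vs Welch's t
#' (unequal); otherwise Mann-Whitney U. The path taken is recorded in
#' `notes`.
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Logical.
#' @param alpha Gate level for the normality and F tests (default 0.05).
#' @return A `neuromech_test` result with `test_name`, `statistic`,
#'   `p_two_tailed`, `n`, `notes`.
#' @export
compare_two <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("insufficient-sample: each group needs n >= 3")
  notes <- list()
  if (paired) {
    if (length(a) != length(b))
      stop("invalid-input: paired groups must have equal length")
    d <- a - b
    if (all(d == 0))
      return(new_test_result("paired t-test (degenerate: all differences 0)",
                             0, 1, c(length(a), length(b)),
                             list("zero differences")))
    nc <- normality_check(d)
    notes$normality <- sprintf("differences %s p=%.3g -> %s", nc$test, nc$p,
                               if (nc$normal) "normal" else "non-normal")
    if (nc$normal) {
      r <- stats::t.test(a, b, paired = TRUE)
      return(new_test_result("paired t-test", r$statistic, r$p.value,
                             c(length(a), length(b)), notes))
    }
    r <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    return(new_test_result("wilcoxon signed-rank", r$statistic, r$p.value,
                           c(length(a), length(b)), notes))
  }
  na <- normality_check(a); nb <- normality_check(b)
  notes$normality <- sprintf("a: %s p=%.3g; b: %s p=%.3g",
                             na$test, na$p, nb$test, nb$p)
  if (na$normal && nb$normal) {
    fv <- stats::var.test(a, b)
    notes$variance <- sprintf("F test p=%.3g -> %s variance", fv$p.value,
                              if (fv$p.value >= alpha) "equal" else "unequal")
    if (fv$p.value >= alpha) {
      r <- stats::t.test(a, b, var.equal = TRUE)
      return(new_test_result("student t-test", r$statistic, r$p.value,
                             c(length(a), length(b)), notes))
    }
    r <- stats::t.test(a, b, var.equal = FALSE)
    return(new_test_result("welch t-test", r$statistic, r$p.value,
                           c(length(a), length(b)), notes))
  }
  r <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  new_test_result("mann-whitney u", r$statistic, r$p.value,
                  c(length(a), length(b)), notes)
}

# Dunn's post hoc z tests with tie correction; Bonferroni-adjusted p values
dunn_test <- function(groups) {
  k <- length(groups)
  x <- unlist(groups)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tabulate(g, k)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out <- rbind(out, data.frame(group1 = i, group2 = j, z = unname(z),
                                 p_adj = min(1, p * k * (k - 1) / 2)))
  }
  out
}

#' Multi-group comparison (ANOVA/Tukey or Kruskal-Wallis/Dunn)
#'
#' All groups normal (per the n-gated normality rule) selects one-way ANOVA
#' with Tukey's post hoc test; otherwise Kruskal-Wallis with Dunn's multiple
#' comparison test (Bonferroni-adjusted).
#'
#' @param groups List of >= 3 numeric vectors, each n >= 3.
#' @param alpha Normality gate level.
#' @return A `neuromech_test` result; `$pairwise` holds the adjusted
#'   pairwise p values.
#' @export
compare_multi <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("insufficient-groups: need >= 3 groups")
  if (any(vapply(groups, length, integer(1)) < 3L))
    stop("insufficient-sample: each group needs n >= 3")
  ncs <- lapply(groups, normality_check)
  all_normal <- all(vapply(ncs, `[[`, logical(1), "normal"))
  notes <- list(normality = paste(
    vapply(seq_along(ncs), function(i)
      sprintf("g%d: %s p=%.3g", i, ncs[[i]]$test, ncs[[i]]$p), character(1)),
    collapse = "; "))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  n <- vapply(groups, length, integer(1))
  if (all_normal) {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(
      group1 = as.integer(sub("-.*", "", rownames(tk))),
      group2 = as.integer(sub(".*-", "", rownames(tk))),
      p_adj = tk[, "p adj"])
    # degenerate case: zero between- and within-group variance handled by aov
    res <- new_test_result("one-way anova + tukey", an[["F value"]][1],
                           an[["Pr(>F)"]][1], n, notes)
  } else {
    kw <- stats::kruskal.test(x, g)
    pw <- dunn_test(groups)
    res <- new_test_result("kruskal-wallis + dunn", kw$statistic,
                           kw$p.value, n, notes)
  }
  if (is.na(res$p_two_tailed)) res$p_two_tailed <- 1   # no variation anywhere
  res$pairwise <- pw
  res
}
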