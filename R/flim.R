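#' Photon decay histogram
#'
#' Container for a time-correlated single-photon-counting decay: bin edges in
#' ns and non-negative integer photon counts per bin.
#'
#' @param t_edges_ns Monotone increasing bin edges (length `n + 1`), ns.
#' @param counts Photon counts per bin (length `n`).
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(t_edges_ns, counts) {
  if (length(t_edges_ns) != length(counts) + 1L)
    stop("invalid-input: need length(t_edges_ns) == length(counts) + 1")
  if (any(diff(t_edges_ns) <= 0)) stop("invalid-input: bin edges must increase")
  if (any(counts < 0)) stop("fit-error: negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("fit-error: counts must be integers")
  structure(list(t_edges_ns = as.numeric(t_edges_ns),
                 counts = as.numeric(round(counts))),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay histogram: %d bins over [%g, %g] ns, %g photons\n",
              length(x$counts), x$t_edges_ns[1],
              x$t_edges_ns[length(x$t_edges_ns)], sum(x$counts)))
  invisible(x)
}

#' Simulate a (bi-)exponential photon decay histogram
#'
#' Draws photon arrival times from a mixture of exponentials (ideal decay, no
#' instrument response) and bins those inside the acquisition window.
#'
#' @param tau_ns Component lifetimes (1 or 2 values), ns.
#' @param amp Component photon fractions, same length as `tau_ns`; normalized
#'   internally.
#' @param n_photons Number of photons drawn.
#' @param t_max_ns Acquisition window length, ns.
#' @param n_bins Number of histogram bins.
#' @param seed Optional integer seed.
#' @return A [decay_histogram()].
#' @export
simulate_decay <- function(tau_ns = c(1, 5), amp = c(0.4, 0.6),
                           n_photons = 1e5, t_max_ns = 25, n_bins = 250,
                           seed = NULL) {
  stopifnot(length(tau_ns) == length(amp), all(tau_ns > 0), all(amp >= 0))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(tau_ns), n_photons, replace = TRUE,
                     prob = amp / sum(amp))
  t <- stats::rexp(n_photons, rate = 1 / tau_ns[comp])
  t <- t[t < t_max_ns]
  edges <- seq(0, t_max_ns, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(t, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  decay_histogram(edges, counts)
}

biexp_model <- function(t, a1, tau1, a2, tau2) {
  a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
}

# log-linear tail estimate of the slow component
tail_init <- function(t, y) {
  pos <- which(y > 0)
  if (length(pos) < 4L) return(NULL)
  tail_idx <- pos[pos >= pos[max(1L, floor(length(pos) * 0.5))]]
  if (length(tail_idx) < 4L) tail_idx <- pos[max(1, length(pos) - 9):length(pos)]
  zz <- t[tail_idx]; ly <- log(y[tail_idx])
  b <- stats::cov(zz, ly) / stats::var(zz)
  if (!is.finite(b) || b >= 0) return(NULL)
  list(tau = -1 / b, a = exp(mean(ly) - b * mean(zz)))
}

#' Bi-exponential fit of a photon decay
#'
#' Unweighted least-squares fit of `a1*exp(-t/tau1) + a2*exp(-t/tau2)` to the
#' binned counts (every bin used, no cutoff). Components are returned sorted
#' so `tau_long >= tau_short`; the long lifetime is the membrane-tension
#' readout. Initialization is a log-linear fit to the tail for the slow
#' component and to the early-time residual for the fast one; fitting uses
#' `nls` (port, positivity bounds) with a Nelder-Mead fallback. A fit whose
#' lifetimes collapse within 1% of each other is flagged degenerate (mono-
#' exponential data) but still reported.
#'
#' @param hist A [decay_histogram()].
#' @return Object of class `biexp_fit`: `tau_long_ns`, `tau_short_ns`,
#'   `a_long`, `a_short`, `goodness` (residual standard error), `degenerate`.
#' @export
biexp_fit <- function(hist) {
  stopifnot(inherits(hist, "decay_histogram"))
  y <- hist$counts
  if (sum(y > 0) < 10L)
    stop("fit-error: need at least 10 bins with nonzero counts")
  e <- hist$t_edges_ns
  t <- (e[-length(e)] + e[-1]) / 2

  ti <- tail_init(t, y)
  if (is.null(ti)) ti <- list(tau = max(t) / 3, a = max(y) / 2)
  res <- pmax(y - ti$a * exp(-t / ti$tau), 0)
  fi <- tail_init(t[seq_len(max(10L, floor(length(t) / 4)))],
                  res[seq_len(max(10L, floor(length(t) / 4)))])
  if (is.null(fi) || fi$tau >= ti$tau) fi <- list(tau = ti$tau / 4, a = max(res, max(y) * 0.1))

  start <- list(a1 = max(fi$a, 1e-3), t1 = fi$tau, a2 = max(ti$a, 1e-3), t2 = ti$tau)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2), data = df,
               start = start, algorithm = "port",
               lower = c(a1 = 0, t1 = 1e-4, a2 = 0, t2 = 1e-4),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    pars <- c(cf["a1"], cf["t1"], cf["a2"], cf["t2"])
  } else {
    obj <- function(p) {
      m <- biexp_model(t, exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]))
      sum((y - m)^2)
    }
    op <- stats::optim(log(unlist(start)), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    pars <- exp(op$par)
  }
  a1 <- pars[1]; t1 <- pars[2]; a2 <- pars[3]; t2 <- pars[4]
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; tmp <- a1; a1 <- a2; a2 <- tmp }
  degenerate <- (t2 - t1) / t2 < 0.01 || a1 < 1e-9 * (a1 + a2)
  rss <- sum((y - biexp_model(t, a1, t1, a2, t2))^2)
  structure(list(tau_long_ns = t2, tau_short_ns = t1,
                 a_long = a2, a_short = a1,
                 goodness = sqrt(rss / max(1L, length(y) - 4L)),
                 degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("bi-exponential fit: tau_long = %.3f ns (a = %.3g), tau_short = %.3f ns (a = %.3g)%s\n",
              x$tau_long_ns, x$a_long, x$tau_short_ns, x$a_short,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mean lifetime within a region
#'
#' Average of the long-lifetime image over a region mask (the per-region
#' tension readout).
#'
#' @param lifetime_image Numeric matrix of lifetimes, ns.
#' @param mask Logical matrix of the same shape.
#' @return Mean lifetime, ns.
#' @export
region_mean_lifetime <- function(lifetime_image, mask) {
  stopifnot(is.matrix(lifetime_image), is.logical(mask),
            identical(dim(lifetime_image), dim(mask)))
  if (!any(mask)) stop("region-error: empty region mask")
  mean(lifetime_image[mask], na.rm = TRUE)
}

#' Lifetime versus leading-process length correlation
#'
#' Spearman rank correlation between per-cell long lifetimes (membrane
#' tension proxy) and per-cell leading-process lengths.
#'
#' @param tau_ns Per-cell lifetimes, ns.
#' @param length_um Per-cell leading-process lengths, um.
#' @param seed Optional seed for the Monte-Carlo permutation p at small n.
#' @return `list(rho, p, n, method)` from [spearman_test()].
#' @export
lifetime_length_correlation <- function(tau_ns, length_um, seed = NULL) {
  if (length(tau_ns) != length(length_um))
    stop("invalid-input: unequal lengths")
  if (length(tau_ns) < 5L)
    stop("invalid-input: need >= 5 paired observations")
  spearman_test(tau_ns, length_um, seed = seed)
}
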