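#' Polarized soma geometry
#'
#' The soma mask together with the nucleus centroid and the polarity axis
#' (unit vector pointing toward the leading process) define the
#' anterior/posterior split used for rear myosin quantification: the
#' posterior half lies behind the line through the nucleus centroid
#' perpendicular to the axis.
#'
#' Pixel coordinates follow the image convention: x = column index,
#' y = row index (pixel centers, 1-based).
#'
#' @param soma_mask Logical matrix marking soma pixels.
#' @param centroid_xy Nucleus centroid `c(x, y)` in pixel units; must fall
#'   inside the soma mask.
#' @param axis_xy Direction toward the leading process, `c(dx, dy)`;
#'   normalized internally.
#' @return An object of class `polarized_soma`.
#' @export
polarized_soma <- function(soma_mask, centroid_xy, axis_xy) {
  stopifnot(is.matrix(soma_mask), is.logical(soma_mask),
            length(centroid_xy) == 2L, length(axis_xy) == 2L)
  if (!any(soma_mask)) stop("geometry-error: empty soma mask")
  r <- as.integer(round(centroid_xy[2])); c <- as.integer(round(centroid_xy[1]))
  if (r < 1L || r > nrow(soma_mask) || c < 1L || c > ncol(soma_mask) ||
      !soma_mask[r, c])
    stop("geometry-error: centroid lies outside the soma mask")
  nrm <- sqrt(sum(axis_xy^2))
  if (nrm == 0) stop("geometry-error: zero-length axis")
  structure(list(soma_mask = soma_mask, centroid_xy = as.numeric(centroid_xy),
                 axis_xy = as.numeric(axis_xy) / nrm),
            class = "polarized_soma")
}

#' Posterior-half mask of a polarized soma
#'
#' Soma pixels whose offset from the nucleus centroid projects negatively on
#' the polarity axis, i.e. the half of the soma away from the leading
#' process.
#'
#' @param ps A [polarized_soma()].
#' @return Logical matrix of posterior-half pixels.
#' @export
posterior_half_mask <- function(ps) {
  stopifnot(inherits(ps, "polarized_soma"))
  m <- ps$soma_mask
  nr <- nrow(m); nc <- ncol(m)
  X <- matrix(rep(seq_len(nc), each = nr), nr)   # x = column
  Y <- matrix(rep(seq_len(nr), times = nc), nr)  # y = row
  proj <- (X - ps$centroid_xy[1]) * ps$axis_xy[1] +
          (Y - ps$centroid_xy[2]) * ps$axis_xy[2]
  out <- m & proj < 0
  if (!any(out)) stop("geometry-error: posterior half is empty")
  out
}

#' Myosin II activity ratio (pMLC/MLC) within a mask
#'
#' Ratio of the mean phosphorylated myosin light chain intensity to the mean
#' total myosin light chain intensity over the mask (mean-of-means, which is
#' robust to zero pixels and invariant to joint intensity rescaling).
#'
#' @param pmlc_img,mlc_img Intensity matrices of equal shape
#'   (background-corrected).
#' @param mask Logical matrix of the same shape.
#' @return pMLC/MLC ratio.
#' @export
myosin_activity_ratio <- function(pmlc_img, mlc_img, mask) {
  stopifnot(is.matrix(pmlc_img), is.matrix(mlc_img), is.logical(mask),
            identical(dim(pmlc_img), dim(mlc_img)),
            identical(dim(pmlc_img), dim(mask)))
  if (!any(mask)) stop("geometry-error: empty mask")
  denom <- mean(mlc_img[mask])
  if (!is.finite(denom) || denom <= 0)
    stop("invalid-denominator: MLC signal is zero within the mask")
  mean(pmlc_img[mask]) / denom
}

#' Synthesize pMLC/MLC immunostain images for a soma with given rear myosin
#' activity
#'
#' Ground-truth image pair for testing the rear-of-soma quantification: MLC
#' is uniform over a disk soma, pMLC carries a posterior enhancement whose
#' magnitude scales with `rear_activity` (the simulated integrated myosin
#' level). Multiplicative Gaussian noise emulates staining variability.
#'
#' @param rear_activity Rear myosin activity level (dimensionless; the rear
#'   pMLC enhancement is `1 + rear_activity`).
#' @param n_px Image side, pixels.
#' @param noise_sd Multiplicative intensity noise sd.
#' @param seed Optional integer seed.
#' @return `list(pmlc, mlc, soma)` where `soma` is a [polarized_soma()] with
#'   axis +x (leading process to the right, posterior to the left).
#' @export
simulate_polarity_images <- function(rear_activity, n_px = 64,
                                     noise_sd = 0.02, seed = NULL) {
  stopifnot(rear_activity >= 0)
  if (!is.null(seed)) set.seed(seed)
  ctr <- (n_px + 1) / 2
  X <- matrix(rep(seq_len(n_px), each = n_px), n_px)
  Y <- matrix(rep(seq_len(n_px), times = n_px), n_px)
  mask <- (X - ctr)^2 + (Y - ctr)^2 <= (0.4 * n_px)^2
  mlc <- matrix(0, n_px, n_px)
  mlc[mask] <- 100
  pmlc <- matrix(0, n_px, n_px)
  rear <- mask & X < ctr
  pmlc[mask] <- 80
  pmlc[rear] <- 80 * (1 + rear_activity)
  if (noise_sd > 0) {
    mlc[mask] <- mlc[mask] * (1 + stats::rnorm(sum(mask), 0, noise_sd))
    pmlc[mask] <- pmlc[mask] * (1 + stats::rnorm(sum(mask), 0, noise_sd))
  }
  list(pmlc = pmlc, mlc = mlc,
       soma = polarized_soma(mask, c(ctr, ctr), c(1, 0)))
}
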