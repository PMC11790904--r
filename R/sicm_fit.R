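#' Reference current of an approach curve
#'
#' The reference current is the average of the direct current recorded during
#' the waiting period (the plateau segment preceding the approach).
#'
#' @param curve An `approach_curve`.
#' @return Reference current in pA.
#' @export
reference_current <- function(curve) {
  stopifnot(inherits(curve, "approach_curve"))
  p <- curve$plateau
  if (is.null(p) || length(p) != 2L || p[2] < p[1])
    stop("no-reference: approach curve has no plateau segment")
  mean(curve$current[p[1]:p[2]])
}

# centered boxcar mean, window k (odd); edges use shrunk windows
boxcar <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# approach-segment indices (everything after the plateau)
approach_idx <- function(curve) {
  (curve$plateau[2] + 1L):length(curve$z)
}

# data-driven smoothing window for noisy curves: ~1/5 of the expected number
# of in-window samples (the raw in-window count is an unbiased estimate of it)
auto_smooth_n <- function(inorm, window) {
  n_raw <- sum(inorm >= window[1] & inorm <= window[2])
  k <- max(1L, as.integer(round(n_raw / 5)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Set-point crossing height (topography sample)
#'
#' First height, scanning in the approach direction, at which the normalized
#' current reaches the set point; linearly interpolated between the two
#' bracketing samples. With noisy curves a boxcar-smoothed copy can be used
#' for crossing detection via `smooth_n`.
#'
#' @param curve An `approach_curve`.
#' @param i_ref Reference current (pA); defaults to [reference_current()].
#' @param setpoint Set-point fraction (default 0.98).
#' @param smooth_n Odd boxcar width used before crossing detection
#'   (1 = raw samples).
#' @return Crossing height `z_stop` in nm.
#' @export
setpoint_z <- function(curve, i_ref = reference_current(curve),
                       setpoint = 0.98, smooth_n = 1L) {
  idx <- approach_idx(curve)
  z <- curve$z[idx]
  inorm <- curve$current[idx] / i_ref
  if (smooth_n > 1L) inorm <- boxcar(inorm, smooth_n)
  below <- which(inorm <= setpoint)
  if (!length(below)) stop("no-contact: curve never reaches the set point")
  k <- below[1]
  if (k == 1L) return(z[1])
  # interpolate z at inorm == setpoint between samples k-1 and k
  f <- (inorm[k - 1L] - setpoint) / (inorm[k - 1L] - inorm[k])
  z[k - 1L] + f * (z[k] - z[k - 1L])
}

#' Window slope of a normalized approach curve
#'
#' Least-squares line fit of normalized current versus z over the samples
#' whose normalized current lies inside the fit window (default 98.5-99% of
#' the reference current); returns the slope magnitude. When current noise is
#' comparable to the window height, selecting samples by their raw noisy
#' values is ill-posed, so the window is localized on a boxcar-smoothed copy
#' of the curve while the line fit itself uses the raw samples in the
#' selected z-range; with `smooth_n = 1` (noise-free data) this reduces to
#' the plain rule.
#'
#' @param curve An `approach_curve`.
#' @param i_ref Reference current (pA).
#' @param window Normalized-current window, default `c(0.985, 0.99)`.
#' @param smooth_n Odd boxcar width for window localization; `NULL` selects
#'   it from the data (about one fifth of the expected in-window sample
#'   count).
#' @return Slope magnitude `s` (normalized current per nm).
#' @export
window_slope <- function(curve, i_ref = reference_current(curve),
                         window = c(0.985, 0.99), smooth_n = NULL) {
  idx <- approach_idx(curve)
  z <- curve$z[idx]
  inorm <- curve$current[idx] / i_ref
  if (is.null(smooth_n)) smooth_n <- auto_smooth_n(inorm, window)
  sm <- if (smooth_n > 1L) boxcar(inorm, smooth_n) else inorm
  sel <- which(sm >= window[1] & sm <= window[2])
  if (length(sel) < 2L)
    stop("window-too-sparse: fewer than 2 samples inside the slope window")
  zz <- z[sel]; yy <- inorm[sel]
  b <- stats::cov(zz, yy) / stats::var(zz)
  abs(b)
}

#' Young's modulus from the window slope
#'
#' `E = p0 * A * (s_inf / s - 1)^-1`. A slope equal to the substrate slope
#' means the pixel is rigid (infinite modulus).
#'
#' @param s Measured slope magnitude on the surface.
#' @param s_inf Substrate slope magnitude.
#' @param p0 Applied pressure, kPa (default 10).
#' @param A Pipette geometry factor (default 0.4).
#' @param rigid_frac Slopes within this fraction of `s_inf` are flagged rigid
#'   (`E = Inf`); default 0 (only exact equality).
#' @return Young's modulus in kPa; `Inf` for rigid.
#' @export
youngs_modulus <- function(s, s_inf, p0 = 10, A = 0.4, rigid_frac = 0) {
  stopifnot(length(s) == 1L)
  if (!is.finite(s) || s <= 0) stop("invalid-slope: s must be > 0")
  if (s > s_inf * (1 + 1e-12)) stop("invalid-slope: s exceeds substrate slope s_inf")
  if (s >= s_inf * (1 - rigid_frac)) return(Inf)
  p0 * A / (s_inf / s - 1)
}

# fit one curve; returns list(I_ref, z_stop, s, E, n_window, valid, rigid)
fit_approach_curve <- function(curve, pipette, s_inf, rigid_frac, smooth_n) {
  out <- list(I_ref = NA_real_, z_stop = NA_real_, s = NA_real_,
              E = NA_real_, valid = FALSE, rigid = FALSE)
  ok <- try({
    i_ref <- reference_current(curve)
    idx <- approach_idx(curve)
    inorm <- curve$current[idx] / i_ref
    if (is.null(smooth_n)) smooth_n <- auto_smooth_n(inorm, pipette$window)
    s <- window_slope(curve, i_ref, pipette$window, smooth_n)
    z_stop <- setpoint_z(curve, i_ref, pipette$setpoint, smooth_n)
    out$I_ref <- i_ref; out$z_stop <- z_stop; out$s <- s
    if (s >= s_inf * (1 - rigid_frac)) {
      out$rigid <- TRUE; out$E <- Inf
    } else {
      out$E <- youngs_modulus(s, s_inf, pipette$p0, pipette$A)
    }
    out$valid <- TRUE
  }, silent = TRUE)
  if (inherits(ok, "try-error")) out$valid <- FALSE
  out
}

#' Assemble a stiffness map from a scan grid
#'
#' Fits every approach curve (reference current, window slope, set-point
#' height) and inverts the slopes to Young's modulus. The substrate slope
#' `s_inf` is taken, in order of preference: from the explicit argument, as
#' the median window slope over an explicit `substrate_mask`, or from the
#' pipette parameters. Pixels whose slope is within `rigid_frac` of `s_inf`
#' are flagged rigid and populate the substrate mask; pixels whose fit fails
#' are flagged invalid, not imputed.
#'
#' @param grid A `scan_grid`.
#' @param s_inf Optional substrate slope; see Details.
#' @param substrate_mask Optional logical `ny x nx` matrix of known substrate
#'   pixels used to estimate `s_inf`.
#' @param rigid_frac Rigid classification band as a fraction of `s_inf`
#'   (default 0.02).
#' @param smooth_n Window-localization boxcar width (`NULL` = automatic).
#' @return An object of class `stiffness_map` with matrices `E` (kPa,
#'   `Inf` = rigid, `NA` = invalid), `topography` (um), `slope`,
#'   `valid_mask`, `substrate_mask`, and `pixel_size_um`.
#' @export
stiffness_map <- function(grid, s_inf = NULL, substrate_mask = NULL,
                          rigid_frac = 0.02, smooth_n = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  nx <- grid$nx; ny <- grid$ny
  pipette <- grid$pipette

  if (is.null(s_inf)) {
    if (!is.null(substrate_mask)) {
      stopifnot(all(dim(substrate_mask) == c(ny, nx)))
      sl <- rep(NA_real_, nx * ny)
      k <- 0L
      for (i in seq_len(ny)) for (j in seq_len(nx)) {
        k <- k + 1L
        if (substrate_mask[i, j])
          sl[k] <- tryCatch(window_slope(grid$curves[[k]],
                                         window = pipette$window,
                                         smooth_n = smooth_n),
                            error = function(e) NA_real_)
      }
      s_inf <- stats::median(sl, na.rm = TRUE)
      if (!is.finite(s_inf)) stop("empty-map: no usable substrate pixels")
    } else {
      s_inf <- pipette$s_inf
    }
  }

  E <- matrix(NA_real_, ny, nx)
  topo <- matrix(NA_real_, ny, nx)
  slope <- matrix(NA_real_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  rigid <- matrix(FALSE, ny, nx)
  k <- 0L
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    k <- k + 1L
    f <- fit_approach_curve(grid$curves[[k]], pipette, s_inf, rigid_frac, smooth_n)
    if (f$valid) {
      E[i, j] <- f$E
      topo[i, j] <- f$z_stop / 1000
      slope[i, j] <- f$s
      valid[i, j] <- TRUE
      rigid[i, j] <- f$rigid
    }
  }
  if (!any(valid)) stop("empty-map: every pixel failed to fit")
  structure(list(E = E, topography = topo, slope = slope,
                 valid_mask = valid, substrate_mask = rigid,
                 s_inf = s_inf, pixel_size_um = grid$pixel_size_um),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cellE <- x$E[x$valid_mask & !x$substrate_mask]
  cat(sprintf("stiffness map: %dx%d px (%g um/px), %d valid, %d substrate, cell E median %.3g kPa\n",
              ncol(x$E), nrow(x$E), x$pixel_size_um, sum(x$valid_mask),
              sum(x$substrate_mask),
              if (length(cellE)) stats::median(cellE, na.rm = TRUE) else NA))
  invisible(x)
}

# convert a polygon (x_um, y_um) to a pixel-center mask
polygon_mask <- function(poly_x, poly_y, ny, nx, pixel_size_um) {
  xc <- (seq_len(nx) - 0.5) * pixel_size_um
  yc <- (seq_len(ny) - 0.5) * pixel_size_um
  m <- matrix(FALSE, ny, nx)
  np <- length(poly_x)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    # even-odd ray casting
    inside <- FALSE
    k2 <- np
    for (k in seq_len(np)) {
      if ((poly_y[k] > yc[i]) != (poly_y[k2] > yc[i])) {
        xint <- (poly_x[k2] - poly_x[k]) * (yc[i] - poly_y[k]) /
          (poly_y[k2] - poly_y[k]) + poly_x[k]
        if (xc[j] < xint) inside <- !inside
      }
      k2 <- k
    }
    m[i, j] <- inside
  }
  m
}

#' Stiffness change within an ROI across time-ordered maps
#'
#' Mean Young's modulus inside the region of interest at each timepoint,
#' expressed relative to the first timepoint (the first measurement is the
#' control and is 0 by construction; drop it before correlating against
#' length changes).
#'
#' @param maps List of `stiffness_map` objects, time-ordered (>= 2).
#' @param roi Either a logical `ny x nx` matrix or a list/data.frame with
#'   `x_um`, `y_um` polygon vertices.
#' @param drop_first If `TRUE` (default) the leading 0 is omitted, matching
#'   the downstream correlation convention.
#' @return Numeric vector of stiffness changes (kPa).
#' @export
roi_delta_series <- function(maps, roi, drop_first = TRUE) {
  if (length(maps) < 2L) stop("roi-error: need >= 2 timepoints")
  m1 <- maps[[1]]
  ny <- nrow(m1$E); nx <- ncol(m1$E)
  mask <- if (is.matrix(roi) && is.logical(roi)) {
    roi
  } else {
    polygon_mask(roi$x_um, roi$y_um, ny, nx, m1$pixel_size_um)
  }
  stopifnot(identical(dim(mask), c(ny, nx)))
  means <- vapply(maps, function(m) {
    use <- mask & m$valid_mask & is.finite(m$E)
    if (!any(use)) stop("roi-error: ROI has no valid pixels at some timepoint")
    mean(m$E[use])
  }, numeric(1))
  d <- means - means[1]
  if (drop_first) d[-1] else d
}
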