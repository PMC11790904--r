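#' Nanopipette acquisition parameters for SICM stiffness mapping
#'
#' Bundles the constants of the hopping-mode acquisition: applied pressure
#' `p0`, pipette geometry factor `A`, the substrate (free) slope `s_inf` of
#' the normalized approach curve, the set-point fraction at which an approach
#' stops, and the normalized-current window used for the slope line fit.
#'
#' The stiffness inversion is `E = p0 * A * (s_inf / s - 1)^-1`, where `s` is
#' the magnitude of the normalized-current slope measured on the cell and
#' `s_inf` the same slope on the rigid substrate.
#'
#' @param p0 Applied pressure in kPa (default 10).
#' @param A Dimensionless pipette geometry factor (default 0.4).
#' @param s_inf Substrate slope of the normalized current, per nm
#'   (default 2e-4, i.e. the current falls 1% of the reference over 50 nm).
#' @param setpoint Set-point fraction of the reference current at which the
#'   approach stops (default 0.98).
#' @param window Length-2 numeric, the normalized-current window for the
#'   slope line fit (default `c(0.985, 0.99)`).
#' @param i_ref_pA Nominal reference current in pA used by the simulator.
#' @return An object of class `pipette_params`.
#' @export
pipette_params <- function(p0 = 10, A = 0.4, s_inf = 2e-4,
                           setpoint = 0.98, window = c(0.985, 0.99),
                           i_ref_pA = 1000) {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(s_inf), length(s_inf) == 1L, is.finite(s_inf),
            length(window) == 2L, length(setpoint) == 1L)
  if (p0 <= 0) stop("invalid-params: applied pressure p0 must be > 0")
  if (A <= 0) stop("invalid-params: geometry factor A must be > 0")
  if (s_inf <= 0) stop("invalid-params: substrate slope s_inf must be > 0")
  if (!(0 < window[1] && window[1] < window[2] && window[2] < 1))
    stop("invalid-params: need 0 < window_low < window_high < 1")
  if (!(setpoint < window[1]))
    stop("invalid-params: setpoint must lie below the slope window")
  structure(list(p0 = p0, A = A, s_inf = s_inf, setpoint = setpoint,
                 window = window, i_ref_pA = i_ref_pA),
            class = "pipette_params")
}

#' @export
print.pipette_params <- function(x, ...) {
  cat(sprintf(
    "SICM pipette: p0 = %g kPa, A = %g, s_inf = %g /nm, setpoint = %g, window = [%g, %g]\n",
    x$p0, x$A, x$s_inf, x$setpoint, x$window[1], x$window[2]))
  invisible(x)
}

#' Normalized approach-curve slope implied by a Young's modulus
#'
#' Inverts the stiffness equation: on a surface of modulus `E` the normalized
#' current falls with slope magnitude `s = s_inf / (1 + p0 * A / E)`. A rigid
#' surface (`E = Inf`) gives the substrate slope `s_inf`.
#'
#' @param E Young's modulus in kPa; `Inf` marks a rigid (substrate) pixel.
#'   Vectorized.
#' @param pipette A [pipette_params()] object.
#' @return Slope magnitude(s), normalized current per nm.
#' @export
slope_from_modulus <- function(E, pipette) {
  stopifnot(inherits(pipette, "pipette_params"), is.numeric(E))
  if (any(is.na(E)) || any(E <= 0))
    stop("invalid-modulus: E must be > 0 (use Inf for rigid substrate)")
  pipette$s_inf / (1 + pipette$p0 * pipette$A / E)
}

# Build the z sample positions for one hop: a waiting plateau at the start
# height, a coarse descent, then a fine descent once the (noise-free) current
# is within 0.5% of the reference. Fine sampling emulates a ~1 MHz ADC at the
# 20 nm/ms approach speed (0.02 nm / sample).
sicm_z_samples <- function(z_onset, z_stop, z_start, dz_coarse, dz_fine,
                           n_plateau, s) {
  z_fine_top <- z_onset - 0.005 / s        # normalized current 0.995
  z_fine_top <- min(z_fine_top, z_start)
  coarse <- if (z_start > z_fine_top) {
    seq(z_start, z_fine_top, by = -dz_coarse)
  } else numeric(0)
  fine <- seq(if (length(coarse)) coarse[length(coarse)] - dz_fine else z_start,
              z_stop, by = -dz_fine)
  list(plateau = rep(z_start, n_plateau), approach = c(coarse, fine))
}

#' Synthesize one SICM approach curve
#'
#' Generates the ion current recorded while the probe approaches a surface of
#' modulus `E`. The noise-free normalized current is 1 above the interaction
#' onset and falls linearly with slope [slope_from_modulus()] below it; the
#' onset height is placed so that the set-point crossing occurs exactly at
#' `surface_z_nm`, which makes set-point topography equal the phantom surface
#' by construction. A waiting plateau (the reference-current segment)
#' precedes the approach. Gaussian i.i.d. noise of sd `noise_sd * I_ref` is
#' added to every sample.
#'
#' @param E Young's modulus in kPa (`Inf` = rigid substrate).
#' @param pipette A [pipette_params()] object.
#' @param surface_z_nm Height (nm) of the set-point crossing, i.e. the
#'   recorded topography of this pixel.
#' @param noise_sd Fractional current noise (sd as a fraction of the
#'   reference current) per recorded sample.
#' @param seed Optional integer seed; the curve is bit-identical for a fixed
#'   seed.
#' @param z_grid Optional explicit approach z positions (nm, strictly
#'   decreasing); overrides the built-in sampling scheme.
#' @param z_start_nm Start height of the hop above the surface (nm).
#' @param dz_coarse_nm,dz_fine_nm Sampling steps far from / near the surface.
#' @param n_plateau Number of waiting-period samples recorded before the
#'   approach.
#' @param pixel_xy Optional length-2 pixel center (um), stored as metadata.
#' @return An object of class `approach_curve` with fields `z` (nm),
#'   `current` (pA), `plateau` (index range of the waiting segment),
#'   `pixel_xy`.
#' @export
synth_approach_curve <- function(E, pipette, surface_z_nm = 0, noise_sd = 0,
                                 seed = NULL, z_grid = NULL,
                                 z_start_nm = surface_z_nm + 2000,
                                 dz_coarse_nm = 5, dz_fine_nm = 0.02,
                                 n_plateau = 1000, pixel_xy = c(NA_real_, NA_real_)) {
  stopifnot(inherits(pipette, "pipette_params"))
  if (noise_sd < 0) stop("invalid-input: noise_sd must be >= 0")
  s <- slope_from_modulus(E, pipette)
  sp <- pipette$setpoint
  # onset placed so the noise-free curve crosses the set point at surface_z_nm
  z_onset <- surface_z_nm + (1 - sp) / s
  z_stop  <- surface_z_nm - 0.004 / s      # small overshoot past the set point

  if (is.null(z_grid)) {
    zs <- sicm_z_samples(z_onset, z_stop, z_start_nm, dz_coarse_nm,
                         dz_fine_nm, n_plateau, s)
    z <- c(zs$plateau, zs$approach)
    plateau <- c(1L, n_plateau)
    approach_z <- zs$approach
  } else {
    if (!length(z_grid)) stop("invalid-input: empty z_grid")
    if (any(diff(z_grid) >= 0)) stop("invalid-input: z_grid must be strictly decreasing")
    z <- c(rep(z_grid[1], n_plateau), z_grid)
    plateau <- c(1L, n_plateau)
    approach_z <- z_grid
  }

  inorm <- ifelse(z >= z_onset, 1, 1 - s * (z_onset - z))
  inorm[seq_len(n_plateau)] <- 1           # waiting period at reference current
  current <- inorm * pipette$i_ref_pA
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    current <- current + stats::rnorm(length(current), 0, noise_sd * pipette$i_ref_pA)
  }
  structure(list(z = z, current = current, plateau = plateau,
                 pixel_xy = pixel_xy, true_E = E,
                 surface_z_nm = surface_z_nm),
            class = "approach_curve")
}

#' @export
print.approach_curve <- function(x, ...) {
  cat(sprintf("SICM approach curve: %d samples, plateau %d..%d, z in [%.1f, %.1f] nm\n",
              length(x$z), x$plateau[1], x$plateau[2],
              min(x$z), max(x$z)))
  invisible(x)
}

#' Build a phantom neuron with a known stiffness field
#'
#' Lays an elliptical soma and a straight leading process on a rigid
#' substrate, over a pixel grid of `nx x ny` pixel centers spanning
#' `extent_um`. Cell pixels carry a finite Young's modulus; substrate pixels
#' are rigid (`E = Inf`). Topography is a smooth dome over the soma and a
#' ridge over the process. The process is represented both as a pixel label
#' and as an exact polyline of length `process_length_um` emanating from the
#' soma boundary along +x.
#'
#' @param nx,ny Grid size in pixels.
#' @param extent_um Scan extent (square), um.
#' @param soma_center_um Soma center (x, y) in um; defaults to the grid
#'   center shifted left to leave room for the process.
#' @param soma_axes_um Ellipse semi-axes (a, b) in um.
#' @param process_length_um Leading-process length L in um (0 = no process).
#' @param E_soma_kPa,E_process_kPa Young's modulus of soma / process pixels.
#' @param topo_soma_um,topo_process_um Peak topography heights, um.
#' @return An object of class `phantom` with fields `E` (kPa, `Inf` on
#'   substrate), `topography` (um), `labels` (substrate/soma/process),
#'   `process_polyline` (um), `process_length_um`, `pixel_size_um`.
#' @export
make_phantom <- function(nx = 32, ny = 32, extent_um = 10,
                         soma_center_um = NULL,
                         soma_axes_um = c(2.5, 2),
                         process_length_um = 4,
                         E_soma_kPa = 1.0, E_process_kPa = 1.5,
                         topo_soma_um = 1.0, topo_process_um = 0.4) {
  if (process_length_um < 0) stop("geometry-error: process length must be >= 0")
  if (E_soma_kPa <= 0 || E_process_kPa <= 0)
    stop("invalid-modulus: cell moduli must be > 0")
  px <- extent_um / nx
  py <- extent_um / ny
  if (2 * soma_axes_um[1] > extent_um || 2 * soma_axes_um[2] > extent_um)
    stop("geometry-error: soma larger than grid extent")
  if (is.null(soma_center_um))
    soma_center_um <- c(soma_axes_um[1] + px, extent_um / 2)
  # pixel centers, origin top-left, row-major
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * py
  X <- matrix(rep(xc, each = ny), nrow = ny)
  Y <- matrix(rep(yc, times = nx), nrow = ny)

  u <- (X - soma_center_um[1]) / soma_axes_um[1]
  v <- (Y - soma_center_um[2]) / soma_axes_um[2]
  r2 <- u^2 + v^2
  soma <- r2 <= 1

  labels <- matrix("substrate", ny, nx)
  labels[soma] <- "soma"
  topo <- matrix(0, ny, nx)
  topo[soma] <- topo_soma_um * sqrt(pmax(0, 1 - r2[soma]))

  # process: exact segment from the soma boundary along +x
  proc_poly <- NULL
  if (process_length_um > 0) {
    x0 <- soma_center_um[1] + soma_axes_um[1]
    y0 <- soma_center_um[2]
    x1 <- x0 + process_length_um
    if (x1 > extent_um)
      stop("geometry-error: process extends beyond the grid; enlarge extent")
    proc_poly <- cbind(x_um = c(x0, x1), y_um = c(y0, y0))
    on_proc <- !soma & X >= x0 & X <= x1 & abs(Y - y0) <= py / 2
    labels[on_proc] <- "process"
    topo[on_proc] <- topo_process_um
  }

  E <- matrix(Inf, ny, nx)
  E[labels == "soma"] <- E_soma_kPa
  E[labels == "process"] <- E_process_kPa

  structure(list(E = E, topography = topo, labels = labels,
                 process_polyline = proc_poly,
                 process_length_um = process_length_um,
                 nx = nx, ny = ny, extent_um = extent_um,
                 pixel_size_um = px,
                 soma_center_um = soma_center_um),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom neuron: %dx%d px over %g um, process L = %g um, %d cell pixels\n",
              x$nx, x$ny, x$extent_um, x$process_length_um,
              sum(x$labels != "substrate")))
  invisible(x)
}

#' Simulate a hopping-mode SICM scan over a phantom
#'
#' Acquires one [synth_approach_curve()] per pixel (row-major from the
#' top-left pixel center), with per-pixel surface heights from the phantom
#' topography and per-pixel moduli from its stiffness field. A fixed seed
#' yields a bit-identical grid.
#'
#' @param phantom A [make_phantom()] object.
#' @param pipette A [pipette_params()] object.
#' @param noise_sd Fractional current noise per sample.
#' @param seed Integer master seed.
#' @param dz_coarse_nm,dz_fine_nm,n_plateau,z_start_above_nm Sampling
#'   controls forwarded to the curve generator; `z_start_above_nm` is the hop
#'   start height above the local surface.
#' @return An object of class `scan_grid`: list of curves plus grid metadata.
#' @export
simulate_scan <- function(phantom, pipette, noise_sd = 0, seed = 1,
                          dz_coarse_nm = 5, dz_fine_nm = 0.02,
                          n_plateau = 1000, z_start_above_nm = 2000) {
  stopifnot(inherits(phantom, "phantom"), inherits(pipette, "pipette_params"))
  nx <- phantom$nx; ny <- phantom$ny
  px <- phantom$extent_um / nx
  set.seed(seed)
  curves <- vector("list", nx * ny)
  k <- 0L
  for (i in seq_len(ny)) {        # row-major from top-left
    for (j in seq_len(nx)) {
      k <- k + 1L
      curves[[k]] <- synth_approach_curve(
        E = phantom$E[i, j], pipette = pipette,
        surface_z_nm = phantom$topography[i, j] * 1000,
        noise_sd = noise_sd, seed = NULL,
        z_start_nm = phantom$topography[i, j] * 1000 + z_start_above_nm,
        dz_coarse_nm = dz_coarse_nm, dz_fine_nm = dz_fine_nm,
        n_plateau = n_plateau,
        pixel_xy = c((j - 0.5) * px, (i - 0.5) * px))
    }
  }
  structure(list(curves = curves, nx = nx, ny = ny,
                 extent_um = phantom$extent_um,
                 pixel_size_um = px, pipette = pipette,
                 noise_sd = noise_sd, seed = seed,
                 labels = phantom$labels),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("SICM scan grid: %dx%d px over %g x %g um (pixel %g um), %d curves, seed %d\n",
              x$nx, x$ny, x$extent_um, x$extent_um, x$pixel_size_um,
              length(x$curves), x$seed))
  invisible(x)
}
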