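#' Default run configuration
#'
#' Nested list of every tunable the pipeline exposes, with the protocol
#' defaults: p0 = 10 kPa, A = 0.4, set point 0.98, slope window
#' (0.985, 0.99), dF/F0 threshold 0.40, translocation epsilon 0.2 um,
#' stretch strain 0.20, plus the cohort generator defaults.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sicm = list(p0 = 10, A = 0.4, s_inf = 2e-4,
                setpoint = 0.98, window = c(0.985, 0.99)),
    calcium = list(threshold = 0.40, min_separation_s = 10, dt_s = 5),
    migration = list(eps_um = 0.2),
    stretch = list(strain = 0.20),
    cohort = list(n_cells = 50, kappa_kd = 0.2, ca_window_min = 30,
                  n_stretch = 12),
    out_dir = NULL,
    log_level = "info")
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop(sprintf("config-error: unknown key '%s'", here))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, validates every key against
#' [default_config()] (unknown keys are an error naming the offending key
#' path), and fills unspecified values with the defaults. An empty file
#' yields the defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config-error: file does not exist: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

#' Save a run configuration
#' @param config Configuration list.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Write a calcium trace to CSV
#'
#' Columns `t_s`, `f525`, `f650`, and optionally `length_um`.
#'
#' @param record A `cell_record` (or list with those fields).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(record, path) {
  df <- data.frame(t_s = record$t_s, f525 = record$f525, f650 = record$f650)
  if (!is.null(record$length_um)) df$length_um <- record$length_um
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a calcium trace CSV
#' @param path CSV with columns `t_s`, `f525`, `f650`[, `length_um`].
#' @return data.frame.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "f525", "f650")
  if (!all(need %in% names(df)))
    stop("invalid-input: trace CSV needs columns t_s, f525, f650")
  df
}

#' Write a soma track to CSV
#' @param track data.frame `t_min`, `x_um`, `y_um`[, `length_um`, `theta_deg`].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Read a soma track CSV
#' @param path CSV with columns `t_min`, `x_um`, `y_um`.
#' @return data.frame.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_min", "x_um", "y_um") %in% names(df)))
    stop("invalid-input: track CSV needs columns t_min, x_um, y_um")
  df
}

#' Write a matrix image as CSV
#'
#' Plain-text stand-in for the 32-bit TIFF image outputs (no TIFF writer is
#' assumed); values in row-major orientation, no headers.
#'
#' @param m Numeric matrix (e.g. stiffness or lifetime image).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a matrix image CSV written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Write a scan grid to an HDF5 container
#'
#' Layout: `/z` and `/current` as `n_curves x max_samples` matrices (NaN
#' padded; per-curve lengths in `/n_samples`), `/plateau` as `n_curves x 2`
#' index pairs, and acquisition metadata under `/meta`. Requires the
#' `rhdf5` package.
#'
#' @param grid A `scan_grid`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_scan_grid_h5 <- function(grid, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 scan containers")
  stopifnot(inherits(grid, "scan_grid"))
  if (file.exists(path)) unlink(path)
  ns <- vapply(grid$curves, function(c) length(c$z), integer(1))
  mx <- max(ns)
  Z <- matrix(NA_real_, length(ns), mx)
  I <- matrix(NA_real_, length(ns), mx)
  P <- matrix(NA_integer_, length(ns), 2L)
  for (k in seq_along(ns)) {
    Z[k, seq_len(ns[k])] <- grid$curves[[k]]$z
    I[k, seq_len(ns[k])] <- grid$curves[[k]]$current
    P[k, ] <- grid$curves[[k]]$plateau
  }
  rhdf5::h5createFile(path)
  rhdf5::h5write(Z, path, "z")
  rhdf5::h5write(I, path, "current")
  rhdf5::h5write(P, path, "plateau")
  rhdf5::h5write(ns, path, "n_samples")
  rhdf5::h5createGroup(path, "meta")
  pp <- grid$pipette
  rhdf5::h5write(c(pp$p0, pp$A, pp$s_inf, pp$setpoint, pp$window, pp$i_ref_pA),
                 path, "meta/pipette")
  rhdf5::h5write(c(grid$nx, grid$ny), path, "meta/grid_px")
  rhdf5::h5write(grid$extent_um, path, "meta/extent_um")
  rhdf5::h5write(as.integer(grid$seed), path, "meta/seed")
  rhdf5::h5write(grid$noise_sd, path, "meta/noise_sd")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a scan grid from an HDF5 container
#' @param path `.h5` path written by [write_scan_grid_h5()].
#' @return A `scan_grid`.
#' @export
read_scan_grid_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 scan containers")
  Z <- rhdf5::h5read(path, "z")
  I <- rhdf5::h5read(path, "current")
  P <- rhdf5::h5read(path, "plateau")
  ns <- as.integer(rhdf5::h5read(path, "n_samples"))
  pm <- as.numeric(rhdf5::h5read(path, "meta/pipette"))
  gp <- as.integer(rhdf5::h5read(path, "meta/grid_px"))
  extent <- as.numeric(rhdf5::h5read(path, "meta/extent_um"))
  seed <- as.integer(rhdf5::h5read(path, "meta/seed"))
  noise_sd <- as.numeric(rhdf5::h5read(path, "meta/noise_sd"))
  rhdf5::h5closeAll()
  pipette <- pipette_params(p0 = pm[1], A = pm[2], s_inf = pm[3],
                            setpoint = pm[4], window = pm[5:6],
                            i_ref_pA = pm[7])
  curves <- lapply(seq_along(ns), function(k) {
    structure(list(z = Z[k, seq_len(ns[k])], current = I[k, seq_len(ns[k])],
                   plateau = as.integer(P[k, ]),
                   pixel_xy = c(NA_real_, NA_real_)),
              class = "approach_curve")
  })
  structure(list(curves = curves, nx = gp[1], ny = gp[2],
                 extent_um = extent, pixel_size_um = extent / gp[1],
                 pipette = pipette, noise_sd = noise_sd, seed = seed,
                 labels = NULL),
            class = "scan_grid")
}
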