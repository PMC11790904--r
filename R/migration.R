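#' Polyline arc length
#'
#' Sum of consecutive Euclidean segment lengths; a single point has length 0.
#'
#' @param points Two-column matrix (or data.frame) of x/y coordinates, um.
#' @return Arc length, um.
#' @export
polyline_length <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 1L) stop("invalid-input: need at least one point")
  if (nrow(p) == 1L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

track_displacements <- function(track) {
  xy <- as.matrix(track[, c("x_um", "y_um")])
  sqrt(rowSums(diff(xy)^2))
}

check_track <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("t_min", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("insufficient-track: need >= 2 frames")
  if (any(diff(track$t_min) <= 0))
    stop("invalid-input: timestamps must be strictly increasing")
  invisible(track)
}

#' Somal-translocation phase flags
#'
#' An acquisition interval is in the somal translocation phase when the soma
#' moved "any distance" between consecutive frames; against tracking jitter
#' this is operationalized as a frame-to-frame displacement greater than
#' `eps_um` (about one camera pixel).
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um` (2-min protocol).
#' @param eps_um Displacement threshold, um (default 0.2).
#' @return Logical vector, one flag per interval (`n_frames - 1`).
#' @export
translocation_phase <- function(track, eps_um = 0.2) {
  check_track(track)
  track_displacements(track) > eps_um
}

#' Migration speed of a soma track
#'
#' Total path length of the soma divided by the total observation time.
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um`.
#' @return Speed in um/min.
#' @export
migration_speed <- function(track) {
  check_track(track)
  d <- track_displacements(track)
  sum(d) / (track$t_min[nrow(track)] - track$t_min[1])
}

#' Somal translocation speed
#'
#' Distance accrued during somal-translocation intervals divided by, per
#' default, the time spent in those intervals (`denominator = "phase"`; the
#' alternative reading `"total"` divides by the whole observation time).
#' Returns `NA` when the track has no translocation interval.
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um`.
#' @param eps_um Displacement threshold, um.
#' @param denominator `"phase"` (default) or `"total"`.
#' @return Speed in um/min, or `NA_real_` if no interval is flagged.
#' @export
translocation_speed <- function(track, eps_um = 0.2,
                                denominator = c("phase", "total")) {
  denominator <- match.arg(denominator)
  check_track(track)
  d <- track_displacements(track)
  flag <- d > eps_um
  if (!any(flag)) return(NA_real_)
  dt <- diff(track$t_min)
  denom <- if (denominator == "phase") sum(dt[flag])
           else track$t_min[nrow(track)] - track$t_min[1]
  sum(d[flag]) / denom
}

#' Classify leading-process orientation relative to a stretch axis
#'
#' Angles are folded into [0, 90] degrees; 0-30 degrees counts as parallel
#' to the stretch direction, 60-90 degrees as perpendicular, the middle band
#' is unclassified.
#'
#' @param theta_deg Angle(s) of the leading process with respect to the
#'   stretch direction, degrees (any real value; folded internally).
#' @return Character vector: `"parallel"`, `"perpendicular"`, or
#'   `"unclassified"`.
#' @export
stretch_orientation <- function(theta_deg) {
  th <- abs(theta_deg) %% 180
  th <- ifelse(th > 90, 180 - th, th)
  out <- rep("unclassified", length(th))
  out[th <= 30] <- "parallel"
  out[th >= 60] <- "perpendicular"
  out
}

#' Per-cell migration metrics
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um` (and optionally
#'   `length_um`).
#' @param eps_um Translocation displacement threshold, um.
#' @return One-row data.frame: `migration_speed_um_min`,
#'   `translocation_speed_um_min`, `translocation_fraction`,
#'   `mean_length_um` (NA if no length column), `n_frames`.
#' @export
migration_metrics <- function(track, eps_um = 0.2) {
  check_track(track)
  dt <- diff(track$t_min)
  flag <- translocation_phase(track, eps_um)
  data.frame(
    migration_speed_um_min = migration_speed(track),
    translocation_speed_um_min = translocation_speed(track, eps_um),
    translocation_fraction = sum(dt[flag]) / sum(dt),
    mean_length_um = if ("length_um" %in% names(track))
      mean(track$length_um) else NA_real_,
    n_frames = nrow(track))
}

#' Convert um/min to um/h
#' @param speed_um_min Speed in um/min.
#' @return Speed in um/h.
#' @export
um_min_to_um_h <- function(speed_um_min) speed_um_min * 60
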