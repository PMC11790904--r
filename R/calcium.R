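#' Ratiometric calcium series
#'
#' Intracellular calcium is read out as the ratio of the emission intensity
#' at 525 nm to that at 650 nm (the 525 channel rises and the 650 channel
#' falls on Ca2+ binding, so the ratio amplifies transients and cancels joint
#' intensity changes).
#'
#' @param f525,f650 Equal-length intensity series (a.u.); `f650` must be
#'   strictly positive.
#' @return Numeric ratio series.
#' @export
ratio_series <- function(f525, f650) {
  if (length(f525) != length(f650))
    stop("invalid-input: channel series have unequal length")
  if (any(!is.finite(f650)) || any(f650 <= 0))
    stop("invalid-denominator: F650 must be > 0 everywhere")
  f525 / f650
}

#' Baseline-normalize a calcium ratio series
#'
#' The baseline `F0` is the whole-trace average of the ratio and each frame
#' is expressed relative to it, so the normalized series has mean exactly 1.
#'
#' @param r Ratio series from [ratio_series()].
#' @return `list(f0, norm)`.
#' @export
normalize_f0 <- function(r) {
  if (!length(r)) stop("invalid-input: empty ratio series")
  f0 <- mean(r)
  if (!is.finite(f0) || f0 <= 0) stop("invalid-input: non-positive baseline")
  list(f0 = f0, norm = r / f0)
}

#' Detect calcium transients by the dF/F0 rule
#'
#' A frame is supra-threshold when its fractional excursion above baseline,
#' `(F - F0)/F0 = norm - 1`, strictly exceeds `threshold` (default 0.40,
#' i.e. F/F0 > 1.4). Contiguous supra-threshold runs form candidate events;
#' runs separated by less than `min_separation_s` are merged; each run yields
#' one event at its peak frame.
#'
#' @param norm Normalized series from [normalize_f0()].
#' @param threshold Fractional threshold (default 0.40).
#' @param min_separation_s Runs closer than this merge into one event
#'   (default 10 s, two frames at the 5-s protocol).
#' @param dt_s Sampling interval in seconds (default 5).
#' @return A data.frame of class `transient_events` with columns
#'   `onset_index`, `peak_index`, `peak_amplitude`, `onset_s`, `peak_s`.
#'   Zero rows when nothing crosses the threshold.
#' @export
detect_transients <- function(norm, threshold = 0.40, min_separation_s = 10,
                              dt_s = 5) {
  stopifnot(is.numeric(norm), length(norm) >= 1L)
  above <- (norm - 1) > threshold
  empty <- data.frame(onset_index = integer(0), peak_index = integer(0),
                      peak_amplitude = numeric(0), onset_s = numeric(0),
                      peak_s = numeric(0))
  class(empty) <- c("transient_events", "data.frame")
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < min_separation_s
  gap_frames <- min_separation_s / dt_s
  merged <- list(runs[1, ])
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if ((runs[k, "start"] - last["end"] - 1L) * dt_s < min_separation_s &&
          (runs[k, "start"] - last["end"] - 1L) >= 0) {
        last["end"] <- runs[k, "end"]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
  }
  ev <- do.call(rbind, lapply(merged, function(rr) {
    seg <- rr["start"]:rr["end"]
    pk <- seg[which.max(norm[seg])]
    data.frame(onset_index = unname(rr["start"]), peak_index = pk,
               peak_amplitude = norm[pk] - 1,
               onset_s = (unname(rr["start"]) - 1L) * dt_s,
               peak_s = (pk - 1L) * dt_s)
  }))
  class(ev) <- c("transient_events", "data.frame")
  ev
}

#' Transient frequency
#'
#' @param events Events data.frame from [detect_transients()].
#' @param duration_min Observation time in minutes.
#' @return Events per minute.
#' @export
transient_frequency <- function(events, duration_min) {
  if (length(duration_min) != 1L || !is.finite(duration_min) || duration_min <= 0)
    stop("invalid-duration: duration must be > 0")
  nrow(events) / duration_min
}

#' Transient frequency by leading-process length-deviation bin
#'
#' Each sampling interval is assigned to a bin by the deviation of the
#' leading-process length from its trace mean, with half-open bins
#' `(-Inf,-4) [-4,0) [0,4) [4,Inf)` um by default. The per-bin frequency is
#' the number of events whose onset falls in the bin divided by the time
#' spent in the bin; bins never visited are reported as `NA`, not 0.
#'
#' @param length_um Length series aligned with the normalized calcium trace.
#' @param events Events from [detect_transients()] on the aligned trace.
#' @param offsets_um Interior bin edges relative to the mean length
#'   (default `c(-4, 0, 4)`).
#' @param dt_s Sampling interval, s (default 5).
#' @return data.frame with `bin`, `time_min`, `n_events`, `freq_per_min`.
#' @export
frequency_by_length_bin <- function(length_um, events,
                                    offsets_um = c(-4, 0, 4), dt_s = 5) {
  stopifnot(is.numeric(length_um), length(length_um) >= 1L)
  dev <- length_um - mean(length_um)
  edges <- c(-Inf, offsets_um, Inf)
  labs <- paste0("[", utils::head(edges, -1), ",", edges[-1], ")")
  bin <- cut(dev, breaks = edges, right = FALSE, labels = labs)
  time_min <- as.numeric(table(bin)) * dt_s / 60
  n_ev <- integer(length(labs))
  if (nrow(events)) {
    ev_bin <- bin[events$onset_index]
    tb <- table(factor(ev_bin, levels = labs))
    n_ev <- as.integer(tb)
  }
  freq <- ifelse(time_min > 0, n_ev / time_min, NA_real_)
  data.frame(bin = labs, time_min = time_min, n_events = n_ev,
             freq_per_min = freq, stringsAsFactors = FALSE)
}
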