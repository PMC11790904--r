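#' Parameters of the synthetic migrating-neuron cohort
#'
#' The generator implements the integrated mechanochemical feedback loop:
#' leading-process extension raises membrane tension (affine in length), the
#' tension-gated channel raises the Ca2+ transient rate once the process is
#' about 4 um longer than its mean, each transient charges a leaky rear
#' myosin integrator, and the myosin level at the transient sets the size of
#' the somal step that follows (during which the process shortens as the
#' soma advances toward the tip).
#'
#' Defaults encode the printed cohort summaries: mean leading-process length
#' 39.0 um, extension/retraction amplitude 11.3 um, the +4 um rate gate, 5-s
#' calcium sampling, 2-min track sampling over 120 min, and 20% uniaxial
#' stretch.
#'
#' @param n_cells Number of cells in a cohort.
#' @param duration_min Simulated time, min (default 120; calcium analyses
#'   typically use the first 15-30 min).
#' @param dt_s Fine (calcium/length) sampling interval, s.
#' @param track_dt_min Track sampling interval, min.
#' @param L_bar_um Cohort mean leading-process length, um.
#' @param L_between_sd_um Between-cell sd of the per-cell mean length, um.
#' @param excursion_um Extension/retraction amplitude = mean somal step, um.
#' @param tau_L_min Length relaxation time, min.
#' @param v_ext_um_min Leading-process extension speed, um/min.
#' @param L_noise_sd Length process noise sd, um per sqrt(min).
#' @param T0_ns,k_ns_per_um,T_noise_ns Tension (lifetime proxy) intercept,
#'   length coupling, and per-frame noise, ns.
#' @param T0_between_sd_ns Between-cell sd of the baseline lifetime, ns.
#' @param burn_in_min Discarded lead-in simulated before recording starts so
#'   traces begin in the stationary extension/step cycle, min.
#' @param lambda_base_per_min,lambda_gain_per_min Baseline and gated
#'   transient rates, events/min.
#' @param gate_offset_um,gate_width_um Offset (+4 um) and softness of the
#'   logistic rate gate.
#' @param kappa Knockdown factor in [0, 1] multiplying the transient rate
#'   (1 = wild type).
#' @param tau_m_min Rear myosin integrator decay time, min.
#' @param m_increment Myosin increment per transient.
#' @param m_ref Myosin normalization (typical wild-type level at an event).
#' @param refractory_min Refractory window after a transient during which the
#' somal step plays out, min.
#' @param step_size_cv Lognormal coefficient of variation of step sizes.
#' @param f525_0,f650_0 Baseline channel intensities, a.u.
#' @param ca_amp_525,ca_amp_650 Fractional 525-rise / 650-fall per transient.
#' @param ca_decay_s Transient decay time constant, s.
#' @param fluor_noise Fractional per-frame channel noise sd.
#' @param track_jitter_um Soma position jitter per track frame, um.
#' @param strain Uniaxial stretch strain (default 0.20).
#' @param seed Master seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_cells = 50,
                          duration_min = 120, dt_s = 5, track_dt_min = 2,
                          L_bar_um = 39.0, L_between_sd_um = 12,
                          excursion_um = 11.3,
                          tau_L_min = 20, v_ext_um_min = 1.2,
                          L_noise_sd = 0.3,
                          T0_ns = 5.0, k_ns_per_um = 0.02, T_noise_ns = 0.02,
                          T0_between_sd_ns = 0.05, burn_in_min = 30,
                          lambda_base_per_min = 0.05,
                          lambda_gain_per_min = 0.5,
                          gate_offset_um = 4, gate_width_um = 2,
                          kappa = 1,
                          tau_m_min = 6, m_increment = 1, m_ref = 1.6,
                          refractory_min = 2, step_size_cv = 0.15,
                          f525_0 = 100, f650_0 = 100,
                          ca_amp_525 = 0.35, ca_amp_650 = 0.20,
                          ca_decay_s = 15, fluor_noise = 0.01,
                          track_jitter_um = 0.03,
                          strain = 0.20, seed = 1) {
  p <- as.list(environment())
  if (p$kappa < 0 || p$kappa > 1) stop("config-error: kappa must be in [0, 1]")
  pos <- c("duration_min", "dt_s", "track_dt_min", "L_bar_um", "excursion_um",
           "tau_L_min", "gate_width_um", "tau_m_min", "m_ref",
           "refractory_min", "f525_0", "f650_0", "ca_decay_s")
  for (nm in pos) if (p[[nm]] <= 0) stop(sprintf("config-error: %s must be > 0", nm))
  if (p$lambda_base_per_min < 0 || p$lambda_gain_per_min < 0)
    stop("config-error: transient rates must be >= 0")
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "cohort params: n = %d cells, L_bar = %g um, excursion = %g um, kappa = %g, seed = %d\n",
    x$n_cells, x$L_bar_um, x$excursion_um, x$kappa, x$seed))
  invisible(x)
}

#' Simulate one migrating neuron
#'
#' Runs the feedback loop on the fine (5-s) grid for `duration_min` minutes:
#' mean-reverting length dynamics with a constant extension drive, transients
#' drawn from an inhomogeneous Bernoulli process with the length-gated rate,
#' myosin integration, transient-triggered somal steps (the soma advances
#' toward the process tip while the process shortens by the step size), an
#' affine tension (lifetime proxy) series, anti-correlated two-channel
#' fluorescence carrying each transient above the 40% detection threshold,
#' and a 2-min soma track with sub-threshold jitter.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed for this cell.
#' @return An object of class `cell_record` with fields `t_s`, `length_um`,
#'   `tension_ns`, `f525`, `f650`, `myosin`, `true_transient_s`, `track`
#'   (data.frame `t_min`, `x_um`, `y_um`, `length_um`), `L_bar_cell_um`,
#'   `variant`, `params`, `seed`.
#' @export
simulate_cell <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  set.seed(seed)
  dt_min <- p$dt_s / 60
  n_rec <- as.integer(round(p$duration_min * 60 / p$dt_s)) + 1L
  n_burn <- as.integer(round(p$burn_in_min * 60 / p$dt_s))
  n <- n_rec + n_burn
  t_s <- (seq_len(n_rec) - 1L) * p$dt_s

  L_bar_i <- max(10, stats::rnorm(1, p$L_bar_um, p$L_between_sd_um))
  T0_i <- p$T0_ns + stats::rnorm(1, 0, p$T0_between_sd_ns)

  L <- numeric(n); L[1] <- L_bar_i
  m <- numeric(n); m[1] <- 0
  events <- integer(0)
  refr_frames <- as.integer(round(p$refractory_min * 60 / p$dt_s))
  refr_left <- 0L
  step_per_frame <- 0
  soma_v <- numeric(n)          # soma advance per frame, um
  decay_m <- exp(-dt_min / p$tau_m_min)
  Lnoise <- stats::rnorm(n, 0, p$L_noise_sd * sqrt(dt_min))

  for (k in 2:n) {
    m[k] <- m[k - 1] * decay_m
    dL <- (p$v_ext_um_min - (L[k - 1] - L_bar_i) / p$tau_L_min) * dt_min +
      Lnoise[k]
    if (refr_left > 0L) {
      soma_v[k] <- step_per_frame
      dL <- dL - step_per_frame
      refr_left <- refr_left - 1L
    } else {
      lam <- p$kappa * (p$lambda_base_per_min + p$lambda_gain_per_min *
        stats::plogis((L[k - 1] - L_bar_i - p$gate_offset_um) / p$gate_width_um))
      if (stats::runif(1) < lam * dt_min) {
        events <- c(events, k)
        m[k] <- m[k] + p$m_increment
        step <- p$excursion_um * (m[k] / p$m_ref) *
          stats::rlnorm(1, -p$step_size_cv^2 / 2, p$step_size_cv)
        step <- min(step, L[k - 1] * 0.8)   # soma cannot overrun the tip
        step_per_frame <- step / refr_frames
        refr_left <- refr_frames
        soma_v[k] <- step_per_frame
        dL <- dL - step_per_frame
        refr_left <- refr_left - 1L
      }
    }
    L[k] <- max(1, L[k - 1] + dL)
  }

  # drop the burn-in so the record starts in the stationary cycle
  rec_idx <- (n_burn + 1L):n
  L <- L[rec_idx]
  m <- m[rec_idx]
  soma_v <- soma_v[rec_idx]
  events <- events[events > n_burn] - n_burn
  n <- n_rec

  tension <- T0_i + p$k_ns_per_um * (L - p$L_bar_um) +
    stats::rnorm(n, 0, p$T_noise_ns)

  # calcium kernel: instant rise at the event frame, exponential decay
  kernel <- numeric(n)
  for (e in events) {
    idx <- e:min(n, e + as.integer(6 * p$ca_decay_s / p$dt_s))
    kernel[idx] <- kernel[idx] + exp(-(idx - e) * p$dt_s / p$ca_decay_s)
  }
  kernel <- pmin(kernel, 1.5)
  f525 <- p$f525_0 * (1 + p$ca_amp_525 * kernel) *
    (1 + stats::rnorm(n, 0, p$fluor_noise))
  f650 <- p$f650_0 * (1 - p$ca_amp_650 * kernel) *
    (1 + stats::rnorm(n, 0, p$fluor_noise))
  f650 <- pmax(f650, 1e-3)

  soma_x <- cumsum(soma_v)
  stride <- as.integer(round(p$track_dt_min * 60 / p$dt_s))
  tr_idx <- seq(1L, n, by = stride)
  track <- data.frame(
    t_min = (tr_idx - 1L) * p$dt_s / 60,
    x_um = soma_x[tr_idx] + stats::rnorm(length(tr_idx), 0, p$track_jitter_um),
    y_um = stats::rnorm(length(tr_idx), 0, p$track_jitter_um),
    length_um = L[tr_idx])

  structure(list(t_s = t_s, length_um = L, tension_ns = tension,
                 f525 = f525, f650 = f650, myosin = m,
                 true_transient_s = (events - 1L) * p$dt_s,
                 track = track, L_bar_cell_um = L_bar_i,
                 T0_cell_ns = T0_i,
                 variant = if (p$kappa < 1) sprintf("kd(kappa=%g)", p$kappa) else "wt",
                 params = p, seed = seed),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf(
    "cell record [%s]: %.0f min, mean L = %.1f um, %d true transients, seed %d\n",
    x$variant, max(x$t_s) / 60, mean(x$length_um),
    length(x$true_transient_s), x$seed))
  invisible(x)
}

#' Simulate a cohort of cells
#'
#' Maps [simulate_cell()] over per-cell seeds drawn deterministically from
#' the master seed.
#'
#' @param params A [cohort_params()].
#' @return List of `cell_record`s, class `cohort`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_cells < 1L) stop("config-error: n_cells must be >= 1")
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, params$n_cells)
  out <- lapply(seeds, function(s) simulate_cell(params, seed = s))
  structure(out, class = "cohort", seeds = seeds)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort of %d cells [%s]\n", length(x), x[[1]]$variant))
  invisible(x)
}

#' Apply a uniaxial stretch to a simulated cell
#'
#' Parallel stretch scales the leading-process length by `1 + strain` from
#' the stretch onset onward; the transient rate is re-evaluated on the
#' scaled length and the transients and fluorescence after onset are
#' regenerated (seeded). Perpendicular stretch leaves the record unchanged.
#' The soma track and myosin series are not updated: the stretch assay reads
#' out calcium only.
#'
#' @param record A `cell_record`.
#' @param strain Stretch strain > 0 (default from the record's params, 0.20).
#' @param orientation `"parallel"` or `"perpendicular"`.
#' @param onset_frac Fraction of the trace at which the stretch is applied.
#' @return A modified `cell_record` (fields `stretch`, `stretch_onset_s`
#'   added).
#' @export
apply_stretch <- function(record, strain = record$params$strain,
                          orientation = c("parallel", "perpendicular"),
                          onset_frac = 0.5) {
  stopifnot(inherits(record, "cell_record"))
  orientation <- match.arg(orientation)
  if (strain <= 0) stop("invalid-strain: strain must be > 0")
  if (orientation == "perpendicular") {
    record$stretch <- "perpendicular"
    record$stretch_onset_s <- max(record$t_s) * onset_frac
    return(record)
  }
  p <- record$params
  n <- length(record$t_s)
  onset <- as.integer(floor(n * onset_frac)) + 1L
  dt_min <- p$dt_s / 60

  L <- record$length_um
  L[onset:n] <- L[onset:n] * (1 + strain)

  # regenerate transients after onset from the re-evaluated rate
  set.seed(record$seed + 999983L)
  keep <- record$true_transient_s[record$true_transient_s < (onset - 1L) * p$dt_s]
  events <- as.integer(round(keep / p$dt_s)) + 1L
  refr_frames <- as.integer(round(p$refractory_min * 60 / p$dt_s))
  refr_left <- 0L
  for (k in onset:n) {
    if (refr_left > 0L) { refr_left <- refr_left - 1L; next }
    lam <- p$kappa * (p$lambda_base_per_min + p$lambda_gain_per_min *
      stats::plogis((L[k] - record$L_bar_cell_um - p$gate_offset_um) / p$gate_width_um))
    if (stats::runif(1) < lam * dt_min) {
      events <- c(events, k)
      refr_left <- refr_frames
    }
  }
  kernel <- numeric(n)
  for (e in events) {
    idx <- e:min(n, e + as.integer(6 * p$ca_decay_s / p$dt_s))
    kernel[idx] <- kernel[idx] + exp(-(idx - e) * p$dt_s / p$ca_decay_s)
  }
  kernel <- pmin(kernel, 1.5)
  record$f525 <- p$f525_0 * (1 + p$ca_amp_525 * kernel) *
    (1 + stats::rnorm(n, 0, p$fluor_noise))
  record$f650 <- pmax(p$f650_0 * (1 - p$ca_amp_650 * kernel) *
                        (1 + stats::rnorm(n, 0, p$fluor_noise)), 1e-3)
  record$length_um <- L
  record$tension_ns <- record$T0_cell_ns + p$k_ns_per_um * (L - p$L_bar_um) +
    stats::rnorm(n, 0, p$T_noise_ns)
  record$true_transient_s <- (events - 1L) * p$dt_s
  record$stretch <- "parallel"
  record$stretch_onset_s <- (onset - 1L) * p$dt_s
  record$variant <- paste0(record$variant, "+stretch")
  record
}

#' Detected transient events of a cell record
#'
#' Convenience end-to-end wrapper: ratio -> baseline normalization ->
#' threshold detection on (a window of) the record's fluorescence.
#'
#' @param record A `cell_record`.
#' @param t_range_s Optional `c(from, to)` window in seconds.
#' @param threshold dF/F0 threshold (default 0.40).
#' @return `list(events, duration_min, freq_per_min, norm, idx)`.
#' @export
record_transients <- function(record, t_range_s = NULL, threshold = 0.40) {
  idx <- seq_along(record$t_s)
  if (!is.null(t_range_s))
    idx <- which(record$t_s >= t_range_s[1] & record$t_s < t_range_s[2])
  r <- ratio_series(record$f525[idx], record$f650[idx])
  nf <- normalize_f0(r)
  ev <- detect_transients(nf$norm, threshold = threshold,
                          dt_s = record$params$dt_s)
  dur_min <- length(idx) * record$params$dt_s / 60
  list(events = ev, duration_min = dur_min,
       freq_per_min = transient_frequency(ev, dur_min),
       norm = nf$norm, idx = idx)
}

#' Per-cell summary table of a cohort
#'
#' Runs the analysis modules over every record: mean length, mean tension
#' proxy, detected transient frequency (first `ca_window_min` minutes), and
#' migration metrics from the 2-min track.
#'
#' @param cohort A `cohort`.
#' @param ca_window_min Calcium analysis window from trace start, min.
#' @param eps_um Translocation threshold, um.
#' @return data.frame, one row per cell.
#' @export
summarize_cohort <- function(cohort, ca_window_min = 30, eps_um = 0.2) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    tr <- record_transients(rec, c(0, ca_window_min * 60))
    mm <- migration_metrics(rec$track, eps_um)
    cbind(data.frame(cell = i, variant = rec$variant,
                     mean_length_um = mean(rec$length_um),
                     mean_tension_ns = mean(rec$tension_ns),
                     transient_freq_per_min = tr$freq_per_min,
                     n_true_transients = length(rec$true_transient_s)),
          mm)
  }))
}

#' Worked-example helper: excursion amplitude as a percentage of mean length
#'
#' Expresses an extension/retraction amplitude as a percentage of the mean
#' leading-process length (the cohort summary convention: 11.3 um on a
#' 39.0 um mean process is 29.0%).
#'
#' @param amplitude_um Extension/retraction amplitude, um.
#' @param mean_length_um Mean leading-process length, um.
#' @return Percentage.
#' @export
excursion_percent <- function(amplitude_um, mean_length_um) {
  if (any(mean_length_um <= 0)) stop("invalid-input: mean length must be > 0")
  100 * amplitude_um / mean_length_um
}
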