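#' Run the full simulate -> analyze -> report pipeline
#'
#' Simulates a wild-type arm and a channel-knockdown arm, then runs every
#' analysis stage: tension-vs-length Spearman correlation across cells,
#' per-cell detected transient frequencies, pooled transient frequency by
#' length-deviation bin, per-cell migration metrics, a paired 20% stretch
#' experiment (parallel and perpendicular sub-cohorts), and the wild-type vs
#' knockdown statistical comparisons. All randomness derives from the master
#' seed; the same seed yields identical tables.
#'
#' @param config Configuration list from [default_config()]/[load_config()].
#' @param out_dir Optional output directory; when given, every table is
#'   written as CSV plus a JSON summary.
#' @return List of class `neuromech_report`: `cells` (per-cell table, both
#'   arms), `length_bins` (pooled WT bin table), `stretch` (paired pre/post
#'   frequencies), `tests` (named list of `neuromech_test` results),
#'   `summary` (named numerics), `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = config$out_dir) {
  seed <- as.integer(config$seed)
  ca_win <- config$cohort$ca_window_min

  wt_par <- cohort_params(n_cells = config$cohort$n_cells, kappa = 1,
                          strain = config$stretch$strain, seed = seed)
  kd_par <- cohort_params(n_cells = config$cohort$n_cells,
                          kappa = config$cohort$kappa_kd,
                          strain = config$stretch$strain, seed = seed + 1L)
  wt <- simulate_cohort(wt_par)
  kd <- simulate_cohort(kd_par)

  cells_wt <- summarize_cohort(wt, ca_win, config$migration$eps_um)
  cells_kd <- summarize_cohort(kd, ca_win, config$migration$eps_um)
  cells_wt$arm <- "wt"; cells_kd$arm <- "kd"
  cells <- rbind(cells_wt, cells_kd)

  # tension proxy vs process length across wild-type cells
  sp <- spearman_test(cells_wt$mean_tension_ns, cells_wt$mean_length_um)

  # pooled length-deviation binning over the WT arm (calcium window)
  bins <- pooled_length_bins(wt, ca_win)

  # paired stretch experiment on fresh WT cells
  n_st <- config$cohort$n_stretch
  st_par <- cohort_params(n_cells = n_st, kappa = 1,
                          strain = config$stretch$strain, seed = seed + 2L)
  st_cohort <- simulate_cohort(st_par)
  stretch <- do.call(rbind, lapply(seq_len(n_st), function(i) {
    rbind(stretch_pair(st_cohort[[i]], "parallel", i),
          stretch_pair(st_cohort[[i]], "perpendicular", i))
  }))

  par_tab <- stretch[stretch$orientation == "parallel", ]
  per_tab <- stretch[stretch$orientation == "perpendicular", ]
  tests <- list(
    tension_vs_length = sp,
    stretch_parallel = compare_two(par_tab$post_freq, par_tab$pre_freq,
                                   paired = TRUE),
    stretch_perpendicular = compare_two(per_tab$post_freq, per_tab$pre_freq,
                                        paired = TRUE),
    kd_translocation = compare_two(
      cells_wt$translocation_speed_um_min[!is.na(cells_wt$translocation_speed_um_min)],
      cells_kd$translocation_speed_um_min[!is.na(cells_kd$translocation_speed_um_min)]),
    kd_migration = compare_two(cells_wt$migration_speed_um_min,
                               cells_kd$migration_speed_um_min),
    kd_length = compare_two(cells_wt$mean_length_um, cells_kd$mean_length_um))

  summary <- c(
    spearman_rho_tension_length = sp$rho,
    wt_mean_length_um = mean(cells_wt$mean_length_um),
    kd_mean_length_um = mean(cells_kd$mean_length_um),
    wt_migration_speed_um_min = mean(cells_wt$migration_speed_um_min),
    kd_migration_speed_um_min = mean(cells_kd$migration_speed_um_min),
    wt_translocation_speed_um_min =
      mean(cells_wt$translocation_speed_um_min, na.rm = TRUE),
    kd_translocation_speed_um_min =
      mean(cells_kd$translocation_speed_um_min, na.rm = TRUE),
    wt_transient_freq_per_min = mean(cells_wt$transient_freq_per_min),
    kd_transient_freq_per_min = mean(cells_kd$transient_freq_per_min),
    top_bin_freq_per_min = bins$freq_per_min[4],
    bottom_bin_freq_per_min = bins$freq_per_min[1])

  report <- structure(list(cells = cells, length_bins = bins,
                           stretch = stretch, tests = tests,
                           summary = summary, config = config),
                      class = "neuromech_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# pooled event/time counts per length-deviation bin across a cohort
pooled_length_bins <- function(cohort, ca_window_min,
                               offsets_um = c(-4, 0, 4)) {
  tabs <- lapply(cohort, function(rec) {
    tr <- record_transients(rec, c(0, ca_window_min * 60))
    frequency_by_length_bin(rec$length_um[tr$idx], tr$events, offsets_um,
                            dt_s = rec$params$dt_s)
  })
  agg <- tabs[[1]][, c("bin"), drop = FALSE]
  agg$time_min <- Reduce(`+`, lapply(tabs, `[[`, "time_min"))
  agg$n_events <- Reduce(`+`, lapply(tabs, `[[`, "n_events"))
  agg$freq_per_min <- ifelse(agg$time_min > 0, agg$n_events / agg$time_min,
                             NA_real_)
  agg
}

# pre/post stretch transient frequencies for one record
stretch_pair <- function(record, orientation, cell_id) {
  st <- apply_stretch(record, orientation = orientation)
  onset <- st$stretch_onset_s
  total <- max(st$t_s)
  pre <- record_transients(st, c(0, onset))
  post <- record_transients(st, c(onset, total + record$params$dt_s))
  data.frame(cell = cell_id, orientation = orientation,
             pre_freq = pre$freq_per_min, post_freq = post$freq_per_min)
}

#' @export
print.neuromech_report <- function(x, ...) {
  cat("neuromech pipeline report\n")
  cat(sprintf("  cells: %d (%d WT / %d KD)\n", nrow(x$cells),
              sum(x$cells$arm == "wt"), sum(x$cells$arm == "kd")))
  for (nm in names(x$summary))
    cat(sprintf("  %-34s %.4g\n", nm, x$summary[[nm]]))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(report$length_bins, file.path(out_dir, "length_bins.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stretch, file.path(out_dir, "stretch.csv"),
                   row.names = FALSE)
  tests <- lapply(report$tests, function(t) {
    if (!is.null(t$rho)) list(method = t$method, rho = t$rho, p = t$p, n = t$n)
    else list(test = t$test_name, statistic = t$statistic,
              p = t$p_two_tailed, n = t$n)
  })
  jsonlite::write_json(list(summary = as.list(report$summary), tests = tests),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
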