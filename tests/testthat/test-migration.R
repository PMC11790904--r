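make_track <- function(x, y = rep(0, length(x)), dt_min = 2) {
  data.frame(t_min = (seq_along(x) - 1) * dt_min, x_um = x, y_um = y)
}

test_that("polyline_length sums Euclidean segments", {
  expect_equal(polyline_length(rbind(c(0, 0), c(0, 30))), 30)
  expect_equal(polyline_length(rbind(c(5, 5))), 0)
  expect_equal(polyline_length(rbind(c(0, 0), c(3, 0), c(3, 4))), 7)
})

test_that("translocation_phase flags intervals above epsilon", {
  still <- make_track(rep(0, 10))
  expect_false(any(translocation_phase(still)))
  one <- make_track(c(0, 0, 1, 1, 1))
  expect_equal(which(translocation_phase(one)), 2L)
  set.seed(2)
  jitter <- make_track(cumsum(c(0, rnorm(30, 0, 0.03))))
  expect_false(any(translocation_phase(jitter)))   # 0.1 um scale << eps
  expect_error(translocation_phase(make_track(0)), "insufficient-track")
})

test_that("migration_speed uses path length over total time", {
  # 60 um path over 120 min
  tr <- make_track(seq(0, 60, length.out = 61))
  expect_equal(migration_speed(tr), 0.5)
  expect_equal(migration_speed(make_track(rep(0, 10))), 0)
  # back-and-forth 10 um each way over 20 min: path not net displacement
  bf <- data.frame(t_min = c(0, 10, 20), x_um = c(0, 10, 0), y_um = 0)
  expect_equal(migration_speed(bf), 1.0)
})

test_that("translocation_speed divides by phase time by default", {
  # movement confined to half the intervals of a 120-min track: 60 um over
  # 60 min of translocation -> 1.0 um/min
  x <- cumsum(rep(c(2, 0), 30))
  tr <- make_track(c(0, x))
  expect_equal(translocation_speed(tr), 1.0)
  expect_equal(translocation_speed(tr, denominator = "total"), 0.5)
  # all intervals flagged -> equals migration speed
  all_mv <- make_track(seq(0, 60, by = 1))
  expect_equal(translocation_speed(all_mv), migration_speed(all_mv))
  expect_true(is.na(translocation_speed(make_track(rep(0, 10)))))
})

test_that("stretch_orientation classifies the protocol bands", {
  expect_equal(stretch_orientation(20), "parallel")
  expect_equal(stretch_orientation(75), "perpendicular")
  expect_equal(stretch_orientation(45), "unclassified")
  expect_equal(stretch_orientation(c(0, 30, 60, 90)),
               c("parallel", "parallel", "perpendicular", "perpendicular"))
  # normalization: angles outside [0, 90]
  expect_equal(stretch_orientation(c(-20, 160, 110)),
               c("parallel", "parallel", "perpendicular"))
})

test_that("metrics are invariant under rigid motions of the coordinates", {
  set.seed(31)
  x <- cumsum(rnorm(40, 0.3, 0.6)); y <- cumsum(rnorm(40, 0, 0.4))
  tr <- make_track(x, y)
  th <- 0.71
  rot <- make_track(cos(th) * x - sin(th) * y + 12,
                    sin(th) * x + cos(th) * y - 5)
  expect_equal(migration_speed(rot), migration_speed(tr))
  expect_equal(translocation_speed(rot), translocation_speed(tr))
  expect_equal(translocation_phase(rot), translocation_phase(tr))
})

test_that("translocation_speed >= migration_speed whenever both defined", {
  set.seed(8)
  for (i in 1:25) {
    x <- cumsum(rnorm(61, 0.2, 0.5)); y <- cumsum(rnorm(61, 0, 0.3))
    tr <- make_track(x, y)
    ts <- translocation_speed(tr)
    if (!is.na(ts)) expect_gte(ts, migration_speed(tr))
  }
  # and on simulated tracks
  co <- small_cohort(n = 6, seed = 52)
  for (rec in co) {
    ts <- translocation_speed(rec$track)
    if (!is.na(ts)) expect_gte(ts, migration_speed(rec$track))
  }
})

test_that("knockdown cohorts migrate slower with longer processes", {
  wt <- summarize_cohort(simulate_cohort(cohort_params(n_cells = 12, seed = 61)))
  kd <- summarize_cohort(simulate_cohort(cohort_params(n_cells = 12, seed = 62,
                                                       kappa = 0.2)))
  expect_gt(mean(kd$mean_length_um), mean(wt$mean_length_um))
  expect_lt(mean(kd$migration_speed_um_min), mean(wt$migration_speed_um_min))
  expect_lt(mean(kd$translocation_speed_um_min, na.rm = TRUE),
            mean(wt$translocation_speed_um_min, na.rm = TRUE))
})

test_that("migration_metrics assembles the per-cell row", {
  x <- cumsum(rep(c(2, 0), 10))
  tr <- make_track(c(0, x))
  tr$length_um <- 40
  m <- migration_metrics(tr)
  expect_equal(m$translocation_fraction, 0.5)
  expect_equal(m$mean_length_um, 40)
  expect_equal(m$n_frames, nrow(tr))
  expect_equal(um_min_to_um_h(m$migration_speed_um_min),
               60 * m$migration_speed_um_min)
})
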