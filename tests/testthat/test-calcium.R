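test_that("ratio_series computes F525/F650 with validation", {
  f <- c(100, 110, 120)
  expect_equal(ratio_series(f, f), c(1, 1, 1))
  # joint rescaling leaves the ratio unchanged
  expect_equal(ratio_series(3 * f, 3 * rev(f)), ratio_series(f, rev(f)))
  expect_error(ratio_series(f, c(100, 0, 100)), "invalid-denominator")
  expect_error(ratio_series(f, f[1:2]), "invalid-input")
})

test_that("normalize_f0 uses the trace mean and normalizes to mean 1", {
  r <- rep(2, 50)
  nf <- normalize_f0(r)
  expect_equal(nf$f0, 2)
  expect_equal(nf$norm, rep(1, 50))
  set.seed(9)
  r2 <- runif(200, 0.5, 3)
  expect_equal(mean(normalize_f0(r2)$norm), 1)
  expect_error(normalize_f0(numeric(0)), "invalid-input")
})

test_that("detect_transients applies the strict 40% rule with run merging", {
  expect_equal(nrow(detect_transients(rep(1, 100))), 0)
  # three injected 0.6-amplitude peaks, 60 s apart on a unit baseline
  nrm <- rep(1, 200)
  nrm[c(30, 42, 54)] <- 1.6
  ev <- detect_transients(nrm, dt_s = 5)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_amplitude, rep(0.6, 3))
  expect_equal(ev$onset_index, c(30L, 42L, 54L))
  # amplitude exactly at / below the threshold never fires (strict >)
  low <- rep(1, 100); low[50] <- 1.39
  expect_equal(nrow(detect_transients(low)), 0)
  at <- rep(1, 100); at[50] <- 1.40
  expect_equal(nrow(detect_transients(at)), 0)
  # runs closer than the merge window collapse into one event
  near <- rep(1, 100); near[c(40, 41)] <- 1.6
  expect_equal(nrow(detect_transients(near, dt_s = 5)), 1)
  split2 <- rep(1, 100); split2[c(40, 44)] <- 1.6   # 20 s apart
  expect_equal(nrow(detect_transients(split2, dt_s = 5)), 2)
})

test_that("detection is invariant to joint channel rescaling", {
  set.seed(4)
  f525 <- 100 * (1 + 0.6 * (seq_len(180) %in% c(30, 90, 150))) *
    (1 + rnorm(180, 0, 0.01))
  f650 <- 100 * (1 - 0.2 * (seq_len(180) %in% c(30, 90, 150))) *
    (1 + rnorm(180, 0, 0.01))
  ev1 <- detect_transients(normalize_f0(ratio_series(f525, f650))$norm)
  ev2 <- detect_transients(normalize_f0(ratio_series(7.3 * f525, 7.3 * f650))$norm)
  expect_identical(ev1$onset_index, ev2$onset_index)
  expect_identical(ev1$peak_index, ev2$peak_index)
  expect_equal(ev1$peak_amplitude, ev2$peak_amplitude)
  expect_equal(nrow(ev1), 3)
})

test_that("transient_frequency is events per minute", {
  ev3 <- detect_transients(replace(rep(1, 200), c(30, 90, 150), 1.6))
  expect_equal(transient_frequency(ev3, 15), 0.2)   # 3 events / 15 min
  expect_equal(transient_frequency(ev3[0, ], 15), 0)
  expect_error(transient_frequency(ev3, 0), "invalid-duration")
})

test_that("frequency_by_length_bin assigns time and events to bins", {
  # all lengths equal -> only the [0,4) bin is occupied
  nrm <- rep(1, 120)
  ev <- detect_transients(nrm)
  tab <- frequency_by_length_bin(rep(39, 120), ev)
  expect_equal(tab$time_min[tab$bin == "[0,4)"], 120 * 5 / 60)
  expect_true(all(tab$time_min[tab$bin != "[0,4)"] == 0))
  expect_true(all(is.na(tab$freq_per_min[tab$bin != "[0,4)"])))
  # events sum across bins equals the total
  set.seed(12)
  L <- 39 + cumsum(rnorm(600, 0, 0.8))
  nrm2 <- rep(1, 600)
  hit <- sort(sample(10:590, 12))
  hit <- hit[c(TRUE, diff(hit) > 4)]
  nrm2[hit] <- 1.7
  ev2 <- detect_transients(nrm2)
  tab2 <- frequency_by_length_bin(L, ev2)
  expect_equal(sum(tab2$n_events), nrow(ev2))
  expect_equal(sum(tab2$time_min), 600 * 5 / 60)
})

test_that("a length-independent rate yields flat per-bin frequencies", {
  # null model: Poisson events at a constant rate regardless of length
  set.seed(77)
  n <- 12000                           # 1000 min at 5 s
  L <- 39 + 6 * sin(seq(0, 40 * pi, length.out = n)) + rnorm(n, 0, 1)
  rate_per_frame <- 0.25 / 12          # 0.25 events/min
  nrm <- rep(1, n)
  hits <- which(runif(n) < rate_per_frame)
  hits <- hits[c(TRUE, diff(hits) > 6)]
  nrm[hits] <- 1.8
  tab <- frequency_by_length_bin(L, detect_transients(nrm))
  f <- tab$freq_per_min[tab$time_min > 5]
  expect_gte(length(f), 3)
  overall <- sum(tab$n_events) / sum(tab$time_min)
  expect_true(all(abs(f - overall) / overall < 0.5))
})

test_that("cohort wild-type bins rise with length deviation, knockdown stays flat", {
  co <- small_cohort(n = 12, seed = 23)
  tabs <- lapply(co, function(rec) {
    tr <- record_transients(rec, c(0, 1800))
    frequency_by_length_bin(rec$length_um[tr$idx], tr$events)
  })
  n_ev <- Reduce(`+`, lapply(tabs, `[[`, "n_events"))
  t_min <- Reduce(`+`, lapply(tabs, `[[`, "time_min"))
  freq <- n_ev / t_min
  expect_gt(freq[4], freq[1])          # top bin exceeds bottom bin
})
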