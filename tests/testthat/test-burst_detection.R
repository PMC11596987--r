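test_that("the filter bank covers 2-16 Hz in 4 Hz bands stepped by 1 Hz", {
  rec <- sine_recording(freq = 10, duration = 4)
  bank <- filter_bank(rec)
  expect_length(bank, 11)
  expect_identical(names(bank)[1], "2-6")
  expect_identical(names(bank)[11], "12-16")
  rms <- vapply(bank, function(b) sqrt(mean(b[1, 500:900]^2)), 0)
  expect_identical(names(which.max(rms)), "8-12")
  dc <- recording(matrix(1, 1, 1000), 250)
  bank_dc <- filter_bank(dc)
  # interior only: zero-phase filtering leaves slow edge transients
  expect_lt(max(abs(vapply(bank_dc, function(b) max(abs(b[1, 400:600])), 0))),
            1e-3)
})

test_that("zero-crossings are counted, signed, and symmetric", {
  rate <- 250
  x <- sin(2 * pi * 10 * (0:(rate - 1)) / rate)
  cr <- zero_crossings(x, rate)
  expect_identical(nrow(cr), 20L)
  expect_true(all(abs(diff(cr$sign)) == 2))   # alternating
  expect_identical(nrow(zero_crossings(rep(3, 100), rate)), 0L)
  crn <- zero_crossings(-x, rate)
  expect_equal(crn$time, cr$time)
  expect_equal(crn$sign, -cr$sign)
})

test_that("cycles of pure sinusoids have the analytic period", {
  rate <- 250
  for (f in c(6, 10)) {
    x <- sin(2 * pi * f * (0:(rate - 1)) / rate)
    cyc <- build_cycles(x, zero_crossings(x, rate), rate)
    expect_identical(nrow(cyc), as.integer(f - 1))
    expect_true(all(abs(cyc$period - 1 / f) <= 0.004))
    cyc <- cycle_properties(cyc, x)
    expect_true(all(cyc$monotonicity == 1))
    # trough times are sample-quantised, so neighbouring periods
    # can differ by up to two sample intervals
    expect_true(all(cyc$period_consistency > 0.95))
    expect_true(all(abs(cyc$amplitude - 2) < 0.01))
  }
})

test_that("cycle peaks are the argmax between flanking crossings", {
  set.seed(12)
  rate <- 250
  x <- as.numeric(stats::filter(rnorm(2000), rep(1 / 8, 8), sides = 2))
  x[is.na(x)] <- 0
  bf <- signal::butter(2, c(8, 12) / 125, "pass")
  nb <- signal::filtfilt(bf, x)
  cr <- zero_crossings(nb, rate)
  cyc <- build_cycles(x, cr, rate)
  for (i in seq_len(nrow(cyc))) {
    pk <- cyc$peak_idx[i]
    # locate the crossing pair around this peak and brute-force the argmax
    k <- max(which(cr$time <= cyc$peak[i] & cr$sign > 0))
    lo <- ceiling(cr$time[k] * rate) + 1
    hi <- floor(cr$time[k + 1] * rate) + 1
    expect_equal(pk, (lo:hi)[which.max(x[lo:hi])])
  }
})

test_that("period consistency is the shorter/longer neighbour ratio", {
  # trough-aligned cycles of period 0.100 and 0.125 s alternating, so the
  # trough-to-trough period sequence is 0.1, 0.125, 0.1, ... and the
  # neighbour ratio is 0.8
  rate <- 1000
  seg <- function(per) -cos(2 * pi * seq(1 / rate, per, by = 1 / rate) / per)
  x <- rep(c(seg(0.1), seg(0.125)), 4)
  cr <- zero_crossings(x, rate)
  cyc <- cycle_properties(build_cycles(x, cr, rate), x)
  interior <- cyc$period_consistency[3:(nrow(cyc) - 2)]
  expect_true(all(abs(interior - 0.8) < 0.03))
})

test_that("white-noise cycles are less monotone than oscillation cycles", {
  set.seed(31)
  meds <- vapply(1:5, function(s) {
    x <- rnorm(2500)
    bf <- signal::butter(2, c(8, 12) / 125, "pass")
    nb <- signal::filtfilt(bf, x)
    cyc <- cycle_properties(build_cycles(x, zero_crossings(nb, 250), 250), x)
    median(cyc$monotonicity)
  }, 0)
  expect_lt(median(meds), 0.8)
})

test_that("burst detection keeps maximal runs of qualifying cycles", {
  crit <- burst_criteria(min_cycles = 3, monotonicity = 0.5,
                         period_consistency = 0, amplitude_consistency = 0,
                         amp_fraction = 0)
  b5 <- detect_bursts(fake_cycles(rep(TRUE, 5)), crit)
  expect_identical(nrow(b5), 1L)
  expect_identical(b5$n_cycles, 5L)
  b_split <- detect_bursts(fake_cycles(c(TRUE, TRUE, FALSE, TRUE, TRUE)),
                           crit)
  expect_identical(nrow(b_split), 0L)
})

test_that("random qualify sequences match a brute-force run scan", {
  set.seed(17)
  crit <- burst_criteria(min_cycles = 4, monotonicity = 0.5,
                         period_consistency = 0, amplitude_consistency = 0,
                         amp_fraction = 0)
  for (i in 1:300) {
    ok <- runif(sample(5:40, 1)) < 0.6
    got <- detect_bursts(fake_cycles(ok), crit)
    want <- runs_bruteforce(ok, 4)
    expect_identical(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$n_cycles[k], diff(want[[k]]) + 1)
    }
  }
})

test_that("bands are sorted by mean period with half-open edges", {
  expect_identical(classify_band(1 / 6), "theta")
  expect_identical(classify_band(1 / 10), "alpha")
  expect_identical(classify_band(1 / 8), "alpha")
  expect_identical(classify_band(1 / 3.9), "other")
  expect_identical(classify_band(1 / 14), "other")
})

test_that("duplicate detections across bands merge into interval unions", {
  cyc <- fake_cycles(rep(TRUE, 6))
  mk <- function(start, end, n, ch = "ch1") {
    burstlapse:::as_burst_table(list(burstlapse:::burst_row(
      ch, start, end, cyc[seq_len(n), ], 0.1, 1)))
  }
  dup <- rbind(mk(1, 2, 5), mk(1, 2, 5))
  class(dup) <- c("burst_table", "data.frame")
  expect_identical(nrow(merge_bursts(dup)), 1L)
  dis <- rbind(mk(1, 2, 5), mk(3, 4, 5))
  class(dis) <- c("burst_table", "data.frame")
  expect_identical(nrow(merge_bursts(dis)), 2L)
})

test_that("random overlapping sets merge to the brute-force union", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    start <- round(runif(n, 0, 20), 2)
    end <- start + round(runif(n, 0.1, 5), 2)
    cyc <- fake_cycles(rep(TRUE, 4))
    rows <- lapply(seq_len(n), function(j) {
      burstlapse:::burst_row("ch1", start[j], end[j], cyc, 0.1, 1)
    })
    bt <- burstlapse:::as_burst_table(rows)
    got <- merge_bursts(bt)
    want <- union_bruteforce(start, end)
    expect_equal(cbind(got$start, got$end), unname(want))
  }
})

test_that("occupancy marks exactly the half-open burst spans", {
  rec <- recording(matrix(0, 2, 1000), 250, c("a", "b"))
  empty <- burstlapse:::as_burst_table(list())
  expect_false(any(burst_occupancy(empty, rec)))
  cyc <- fake_cycles(rep(TRUE, 8))
  bt <- burstlapse:::as_burst_table(list(
    burstlapse:::burst_row("a", 1.0, 2.0, cyc, 0.1, 1)))
  occ <- burst_occupancy(bt, rec)
  expect_identical(sum(occ["a", ]), 250L)
  expect_identical(sum(occ["b", ]), 0L)
  # merged occupancy equals the union of constituent occupancies
  bt2 <- burstlapse:::as_burst_table(list(
    burstlapse:::burst_row("a", 1.0, 2.0, cyc, 0.1, 1),
    burstlapse:::burst_row("a", 1.5, 2.5, cyc, 0.1, 1)))
  class(bt2) <- c("burst_table", "data.frame")
  occ_m <- burst_occupancy(merge_bursts(bt2), rec)
  expect_identical(occ_m, burst_occupancy(bt2, rec))
})

test_that("the detector recovers clean injected bursts deterministically", {
  cfg <- sim_config(n_channels = 2, duration = 120, seed = 41,
                    burst_cycles = c(6L, 10L), spatial_extent = 1,
                    burst_amplitude = c(meanlog = log(50), sdlog = 0.25),
                    burst_amplitude_min = 40,
                    burst_rate = c(theta = 1.5, alpha = 3))
  bg <- simulate_background(cfg)
  inj <- inject_bursts(bg, cfg)
  pre <- standard_filter_chain(
    recording(inj$recording$data, 250, inj$recording$channels))
  det1 <- detect_recording(pre)
  det2 <- detect_recording(pre)
  expect_identical(det1, det2)
  gt <- inj$ground_truth$bursts
  hits <- vapply(seq_len(nrow(gt)), function(i) {
    ch <- paste0("ch", gt$chan_first[i])
    d <- det1[det1$channel == ch, ]
    any(overlap_len(gt$start[i], gt$end[i], d$start, d$end) >=
          0.5 * (gt$end[i] - gt$start[i]))
  }, NA)
  expect_gt(mean(hits), 0.8)
})

test_that("pure 1/f background yields near-empty occupancy", {
  cfg <- sim_config(n_channels = 2, duration = 120,
                    aperiodic_exponent = 1.5, seed = 77)
  bg <- standard_filter_chain(simulate_background(cfg))
  det <- detect_recording(bg)
  expect_lt(mean(burst_occupancy(det, bg)), 0.05)
})
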