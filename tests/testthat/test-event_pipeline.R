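test_that("outcomes are classified by the RT boundaries", {
  expect_identical(as.character(classify_outcome(0.3)), "fast")
  expect_identical(as.character(classify_outcome(0.7)), "slow")
  expect_identical(as.character(classify_outcome(NA)), "lapse")
  expect_identical(as.character(classify_outcome(0.05)), "falsealarm")
  expect_identical(as.character(classify_outcome(1.2)), "lapse")
  # boundary conventions: half-open intervals
  expect_identical(as.character(classify_outcome(c(0.1, 0.5, 1.0))),
                   c("fast", "slow", "lapse"))
})

make_epoch_fixture <- function(n_trials = 24, rate = 50, nch = 3,
                               dur = 260, occ_p = 0.2, seed = 1,
                               rt = 0.3) {
  set.seed(seed)
  occ <- matrix(runif(nch * dur * rate) < occ_p, nch)
  onsets <- seq(10, dur - 10, length.out = n_trials)
  trials <- trial_table(onset = onsets, rt = rt)
  list(occ = occ, trials = trials, rate = rate)
}

test_that("epoching drops trials by the 50% missing rule", {
  fx <- make_epoch_fixture()
  mask <- matrix(FALSE, 3, ncol(fx$occ))
  # first trial fully masked; second trial ~40% masked
  i1 <- round((fx$trials$onset[1] - 2) * fx$rate):round((fx$trials$onset[1] + 4) * fx$rate)
  mask[, i1] <- TRUE
  n2 <- round((fx$trials$onset[2] - 2) * fx$rate) + 0:(round(0.4 * 6 * fx$rate))
  mask[, n2] <- TRUE
  ep <- epoch_tensor(fx$occ, fx$trials, fx$rate, mask = mask)
  expect_identical(dim(ep$tensor)[1], nrow(fx$trials) - 1L)
  expect_false(1 %in% ep$trial_index)
  expect_true(2 %in% ep$trial_index)
  expect_true(anyNA(ep$tensor[1, , ]))
  expect_equal(length(ep$time), 6 * fx$rate)
})

test_that("false-alarm and eye-closure trials are excluded from epochs", {
  fx <- make_epoch_fixture()
  fx$trials$rt[3] <- 0.05
  fx$trials <- trial_table(fx$trials$onset, replace(fx$trials$rt, 3, 0.05),
                           ec_stimulus = replace(rep(FALSE, 24), 5, TRUE))
  ep <- epoch_tensor(fx$occ, fx$trials, fx$rate)
  expect_false(any(c(3, 5) %in% ep$trial_index))
  ep_ec <- epoch_tensor(fx$occ, fx$trials, fx$rate, exclude_ec = FALSE)
  expect_true(5 %in% ep_ec$trial_index)
})

test_that("random masks reproduce a brute-force retention filter", {
  set.seed(9)
  for (i in 1:60) {
    fx <- make_epoch_fixture(n_trials = 10, seed = i)
    mask <- matrix(runif(length(fx$occ)) < runif(1, 0.2, 0.7), nrow(fx$occ))
    ep <- epoch_tensor(fx$occ, fx$trials, fx$rate, mask = mask)
    kept_brute <- integer(0)
    for (k in seq_len(nrow(fx$trials))) {
      smp <- round((fx$trials$onset[k] - 2) * fx$rate) + 1 +
        0:(6 * fx$rate - 1)
      if (mean(mask[, smp]) <= 0.5) kept_brute <- c(kept_brute, k)
    }
    expect_identical(ep$trial_index, kept_brute)
  }
})

test_that("time courses z-score against session statistics", {
  # occupancy constant everywhere: every epoch equals the session mean,
  # and the session SD over the channel-proportion series is zero only in
  # the degenerate case; use a half-on pattern per channel instead
  rate <- 50
  occ <- matrix(FALSE, 4, 200 * rate)
  occ[1:2, ] <- TRUE                # proportion 0.5 at every sample
  occ[, 1:(10 * rate)] <- TRUE      # brief all-on stretch gives SD > 0
  st <- session_occupancy_stats(occ)
  trials <- trial_table(onset = seq(20, 180, length.out = 20), rt = 0.3)
  ep <- epoch_tensor(occ, trials, rate)
  tc <- participant_timecourse(ep, st, min_trials = 15)
  # all epochs sit in the 0.5 region: z is the same negative constant
  expect_true(all(abs(diff(tc$z["fast", ])) < 1e-12))
  expect_equal(unname(tc$z["fast", 1]), (0.5 - st$mean) / st$sd)
  expect_true(all(is.na(tc$z["lapse", ])))   # no lapse trials
})

test_that("a hand-built toy time course matches manual computation", {
  rate <- 10
  nch <- 3
  occ <- matrix(FALSE, nch, 90 * rate)
  set.seed(14)
  occ[] <- runif(length(occ)) < 0.3
  onsets <- seq(5, 85, length.out = 16)
  trials <- trial_table(onset = onsets, rt = 0.3)
  st <- session_occupancy_stats(occ)
  ep <- epoch_tensor(occ, trials, rate)
  tc <- participant_timecourse(ep, st, min_trials = 15)
  # manual: per trial, proportion of channels with burst at epoch sample 1
  prop1 <- vapply(onsets, function(on) {
    mean(occ[, round((on - 2) * rate) + 1])
  }, 0)
  expect_equal(unname(tc$z["fast", 1]),
               (mean(prop1) - st$mean) / st$sd, tolerance = 1e-12)
})

test_that("outcomes with too many low-coverage time points are dropped", {
  rate <- 50
  nt <- 6 * rate
  # 16 fast trials but mask out 21% of the window for most trials so
  # fewer than 15 trials are clean there
  occ <- matrix(runif(4 * 300 * rate) < 0.2, 4)
  trials <- trial_table(onset = seq(10, 290, length.out = 16), rt = 0.3)
  mask <- matrix(FALSE, 4, ncol(occ))
  bad_len <- ceiling(0.21 * nt)
  for (k in 1:2) {   # two trials masked over the same 21% stretch
    smp <- round((trials$onset[k] - 2) * rate) + 1 + 0:(bad_len - 1)
    mask[, smp] <- TRUE
  }
  ep <- epoch_tensor(occ, trials, rate, mask = mask)
  st <- session_occupancy_stats(occ, mask)
  tc <- participant_timecourse(ep, st, min_trials = 15)
  expect_true(all(is.na(tc$z["fast", ])))
  # with a gap under 20% the outcome is kept and interpolated
  mask2 <- matrix(FALSE, 4, ncol(occ))
  short_len <- floor(0.15 * nt)
  for (k in 1:2) {
    smp <- round((trials$onset[k] - 2) * rate) + 1 + 0:(short_len - 1)
    mask2[, smp] <- TRUE
  }
  ep2 <- epoch_tensor(occ, trials, rate, mask = mask2)
  tc2 <- participant_timecourse(ep2, st, min_trials = 15)
  expect_false(anyNA(tc2$z["fast", ]))
})

test_that("group time-course statistics flag consistent deviations", {
  nt <- 100
  mk <- function(z) {
    structure(list(z = matrix(z, 3, nt,
                              dimnames = list(c("fast", "slow", "lapse"),
                                              NULL)),
                   n_trials = c(fast = 20, slow = 20, lapse = 20),
                   time = seq(-2, 3.99, length.out = nt)),
              class = "participant_timecourse")
  }
  # all-zero inputs: zero variance, nothing significant
  g0 <- group_timecourse_stats(lapply(1:6, function(i) mk(0)))
  expect_false(any(g0$significant, na.rm = TRUE))
  # consistent positive z for every participant: everything significant
  set.seed(3)
  g1 <- group_timecourse_stats(lapply(1:6, function(i) mk(1 + 0.05 * i)))
  expect_true(all(g1$significant))
  expect_true(all(g1$p_fdr >= g1$p))
})

test_that("window topographies use half-open windows and session averages", {
  w <- topography_windows()
  expect_identical(names(w), c("Pre", "Stimulus", "Response", "Post"))
  # a sample at exactly 0.3 s belongs to Response, not Stimulus
  tm <- 0.3
  expect_false(tm >= w$Stimulus[1] && tm < w$Stimulus[2])
  expect_true(tm >= w$Response[1] && tm < w$Response[2])

  rate <- 50
  set.seed(8)
  occ <- matrix(runif(3 * 400 * rate) < 0.2, 3)
  trials <- trial_table(onset = seq(10, 390, length.out = 20), rt = 0.3)
  st <- session_occupancy_stats(occ)
  ep <- epoch_tensor(occ, trials, rate)
  topo <- participant_topography(ep, st, min_trials = 15)
  expect_identical(dim(topo), c(3L, 4L, 3L))
  # with homogeneous random occupancy the window point-probability matches
  # the session channel average up to sampling noise
  expect_true(all(abs(topo["fast", , ]) < 0.05))
  expect_true(all(is.na(topo["lapse", , ])))   # no lapse trials
})

test_that("an injected single-channel surplus is flagged in topography", {
  rate <- 50
  set.seed(10)
  topos <- list()
  for (p in 1:8) {
    # sparse blocky background occupancy: ~30 one-second bursts per
    # channel over 400 s, so a 2 s window contains one ~20% of the time
    occ <- matrix(FALSE, 4, 400 * rate)
    for (ch in 1:4) {
      for (s in runif(30, 0, 399)) {
        occ[ch, round(s * rate):round((s + 1) * rate)] <- TRUE
      }
    }
    trials <- trial_table(onset = seq(10, 390, length.out = 20), rt = 0.3)
    # surplus on channel 2: a pre-stimulus burst in 90% of trials
    for (on in trials$onset[runif(20) < 0.9]) {
      occ[2, round((on - 1.5) * rate):round((on - 1.0) * rate)] <- TRUE
    }
    st <- session_occupancy_stats(occ)
    ep <- epoch_tensor(occ, trials, rate)
    topos[[p]] <- participant_topography(ep, st, min_trials = 15)
  }
  g <- group_topography_stats(topos)
  expect_true(g$significant["fast", "Pre", 2])
  # the surplus channel dominates every other channel's statistic
  expect_true(all(g$t["fast", "Pre", 2] > g$t["fast", "Pre", -2]))
})

test_that("EC lapse fractions by threshold equal brute-force counts", {
  tt <- trial_table(onset = 1:10, rt = c(NA, 0.3, 0.8, 1.2, NA,
                                         0.4, 0.6, NA, 0.9, 0.2),
                    ec_stimulus = c(TRUE, FALSE, FALSE, TRUE, TRUE,
                                    FALSE, FALSE, FALSE, TRUE, FALSE))
  th <- c(0.5, 1.0)
  out <- ec_lapse_fraction_by_threshold(tt, th)
  for (i in seq_along(th)) {
    lapse <- is.na(tt$rt) | tt$rt > th[i]
    expect_equal(out$ec_fraction[i], mean(tt$ec_stimulus[lapse]))
  }
  # degenerate curves
  tt0 <- trial_table(onset = 1:6, rt = NA, ec_stimulus = FALSE)
  expect_true(all(ec_lapse_fraction_by_threshold(tt0)$ec_fraction == 0))
  tt1 <- trial_table(onset = 1:6, rt = NA, ec_stimulus = TRUE)
  expect_true(all(ec_lapse_fraction_by_threshold(tt1)$ec_fraction == 1))
})

test_that("distance quantiles are equal-count and track coupled lapses", {
  tt <- trial_table(onset = 1:12, rt = rep(c(0.3, NA), 6),
                    distance = (1:12) / 12)
  out <- lapse_by_distance_quantiles(tt, k = 6)
  expect_identical(out$n, rep(2L, 6))
  # uniform outcomes give a flat curve
  tt_flat <- trial_table(onset = 1:30, rt = 0.3, distance = runif(30))
  expect_true(all(lapse_by_distance_quantiles(tt_flat)$lapse_percent == 0))
  # distance-coupled lapses rise across quantiles in expectation
  set.seed(20)
  cfg <- sim_config(n_channels = 1, duration = 20000,
                    burst_rate = c(theta = 0, alpha = 0), closure_rate = 0,
                    beta0 = qlogis(0.05), beta_amp = 0, beta_ec = 0,
                    beta_dist = 3, seed = 6)
  gt <- structure(list(bursts = burstlapse:::draw_burst_events(cfg),
                       closures = NULL, config = cfg),
                  class = "ground_truth")
  tr <- simulate_trials(gt, cfg)
  curve <- lapse_by_distance_quantiles(tr)
  expect_gt(cor(curve$quantile, curve$lapse_percent, method = "spearman"),
            0.9)
})
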