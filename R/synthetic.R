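# Synthetic EEG generator: 1/f aperiodic background, Hann-windowed
# oscillatory bursts with ground truth, eye-closure episodes, and a trial
# process whose lapse probability is logistically coupled to pre-stimulus
# burst amplitude and eye closure.

#' Simulation configuration
#'
#' All tunable parameters of the synthetic EEG generator, with defaults
#' chosen to emulate a sustained-attention task session: 1/f background
#' with exponent 1.5, theta (4-8 Hz) and alpha (8-14 Hz) bursts of
#' log-normal amplitude, occasional eye closures, stimuli every 2-10 s and
#' a logistic lapse model.
#'
#' @param n_channels Number of EEG channels.
#' @param duration Recording length in seconds.
#' @param rate Sampling rate in samples/s.
#' @param aperiodic_exponent Power-law slope of the background spectrum
#'   (power ~ f^-exponent).
#' @param background_scale Background standard deviation in microvolts.
#' @param burst_rate Named vector, burst events per minute per channel for
#'   each band.
#' @param burst_freq Named list of \[low, high) frequency ranges in Hz.
#' @param burst_cycles Integer range (min, max) of cycles per event.
#' @param burst_amplitude `c(meanlog, sdlog)` of the log-normal
#'   peak-to-trough event amplitude in microvolts.
#' @param burst_amplitude_min Lower truncation of the event amplitude in
#'   microvolts (0 = none); lets a simulation guarantee a minimum
#'   signal-to-noise ratio.
#' @param spatial_extent Number of adjacent co-active channels per event.
#' @param closure_rate Eye-closure episodes per minute.
#' @param closure_duration `c(meanlog, sdlog)` of log-normal closure
#'   durations in seconds.
#' @param pupil_rate Sampling rate of the confidence trace in Hz.
#' @param isi Inter-stimulus interval range in seconds.
#' @param stim_window Stimulus visibility duration in seconds.
#' @param beta0 Intercept of the logistic lapse model (log-odds).
#' @param beta_amp Coefficient on the maximum pre-stimulus burst amplitude
#'   (per microvolt; window \[-1, 0) s before onset, 0 if no burst).
#' @param beta_ec Coefficient on eye closure during the stimulus window;
#'   `Inf` forces a lapse whenever eyes are closed.
#' @param beta_dist Coefficient on normalised stimulus distance.
#' @param amp_coupling `"linear"` uses the amplitude itself as covariate;
#'   `"top_decile"` uses an indicator that the maximum pre-stimulus
#'   amplitude exceeds the 90th percentile of the event-amplitude
#'   distribution (coupling confined to the largest bursts).
#' @param rt_meanlog,rt_sdlog Log-normal parameters of the reaction-time
#'   distribution, shifted by 0.1 s and truncated below 1 s.
#' @param seed Master seed; every source of randomness derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_channels = 8, duration = 300, rate = 250,
                       aperiodic_exponent = 1.5, background_scale = 10,
                       burst_rate = c(theta = 2, alpha = 4),
                       burst_freq = list(theta = c(4, 8), alpha = c(8, 14)),
                       burst_cycles = c(4L, 12L),
                       burst_amplitude = c(meanlog = log(30), sdlog = 0.4),
                       burst_amplitude_min = 0,
                       spatial_extent = 2,
                       closure_rate = 1,
                       closure_duration = c(meanlog = log(2), sdlog = 0.5),
                       pupil_rate = 120,
                       isi = c(2, 10), stim_window = 0.5,
                       beta0 = stats::qlogis(0.15), beta_amp = 0.03,
                       beta_ec = Inf, beta_dist = 0,
                       amp_coupling = c("linear", "top_decile"),
                       rt_meanlog = log(0.25), rt_sdlog = 0.45,
                       seed = 1L) {
  amp_coupling <- match.arg(amp_coupling)
  cfg <- list(n_channels = n_channels, duration = duration, rate = rate,
              aperiodic_exponent = aperiodic_exponent,
              background_scale = background_scale,
              burst_rate = burst_rate, burst_freq = burst_freq,
              burst_cycles = as.integer(burst_cycles),
              burst_amplitude = burst_amplitude,
              burst_amplitude_min = burst_amplitude_min,
              spatial_extent = spatial_extent,
              closure_rate = closure_rate,
              closure_duration = closure_duration,
              pupil_rate = pupil_rate,
              isi = isi, stim_window = stim_window,
              beta0 = beta0, beta_amp = beta_amp, beta_ec = beta_ec,
              beta_dist = beta_dist, amp_coupling = amp_coupling,
              rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
              seed = as.integer(seed))
  stopifnot(cfg$rate > 0, cfg$duration > 0, cfg$n_channels >= 1,
            all(cfg$burst_rate >= 0), cfg$closure_rate >= 0,
            cfg$isi[1] >= cfg$stim_window,
            all(unlist(cfg$burst_freq) > 0),
            all(unlist(cfg$burst_freq) < cfg$rate / 2))
  class(cfg) <- "sim_config"
  cfg
}

# Derived sub-seeds keep the generator stages independent but all tied to
# the master seed; offsets stay well below 2^31.
sub_seed <- function(cfg, offset) (cfg$seed * 97L + offset) %% 2000000011L

#' Simulate aperiodic 1/f background EEG
#'
#' Spectrally shaped Gaussian noise: white noise is filtered in the
#' frequency domain so power follows f^(-exponent), then rescaled to the
#' configured standard deviation per channel. Channels are independent.
#' The shaping gain is clamped below 0.5 Hz so the high-pass region does
#' not dominate the variance.
#'
#' @param config A [sim_config()].
#' @return An [recording()] of `n_channels` x `duration * rate` samples.
#' @export
simulate_background <- function(config) {
  set.seed(sub_seed(config, 1L))
  n <- round(config$duration * config$rate)
  f <- seq(0, config$rate - config$rate / n, length.out = n)
  f <- pmin(f, config$rate - f)           # two-sided frequency axis
  gain <- pmax(f, 0.5) ^ (-config$aperiodic_exponent / 2)
  gain[1] <- 0                            # no DC
  data <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    x <- stats::rnorm(n)
    y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
    data[ch, ] <- y / stats::sd(y) * config$background_scale
  }
  recording(data, rate = config$rate)
}

# Draw burst events (no waveform synthesis): channel extent, timing,
# frequency, cycles, amplitude per event; non-overlapping per channel.
draw_burst_events <- function(config) {
  set.seed(sub_seed(config, 2L))
  dur_min <- config$duration / 60
  ev <- list()
  for (band in names(config$burst_rate)) {
    lam <- config$burst_rate[[band]] * dur_min * config$n_channels
    n_ev <- stats::rpois(1, lam)
    if (n_ev == 0) next
    fr <- config$burst_freq[[band]]
    freq <- stats::runif(n_ev, fr[1], fr[2])
    ncyc <- sample(seq(config$burst_cycles[1], config$burst_cycles[2]),
                   n_ev, replace = TRUE)
    amp <- stats::rlnorm(n_ev, config$burst_amplitude[["meanlog"]],
                         config$burst_amplitude[["sdlog"]])
    if (config$burst_amplitude_min > 0) {
      amp <- pmax(amp, config$burst_amplitude_min)
    }
    ch0 <- sample(config$n_channels, n_ev, replace = TRUE)
    len <- ncyc / freq
    start <- stats::runif(n_ev, 0, pmax(config$duration - len, 0))
    ev[[band]] <- data.frame(band = band, start = start,
                             end = start + len, freq = freq,
                             n_cycles = ncyc, amplitude = amp,
                             chan_first = ch0,
                             chan_last = pmin(ch0 + config$spatial_extent - 1,
                                              config$n_channels))
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    return(data.frame(band = character(), start = numeric(),
                      end = numeric(), freq = numeric(),
                      n_cycles = integer(), amplitude = numeric(),
                      chan_first = integer(), chan_last = integer()))
  }
  events <- events[order(events$start), , drop = FALSE]
  # reject events overlapping an earlier-kept event on any shared channel:
  # keeps per-channel ground truth unambiguous for recovery scoring
  keep <- rep(TRUE, nrow(events))
  last_end <- rep(-Inf, config$n_channels)
  for (i in seq_len(nrow(events))) {
    chs <- events$chan_first[i]:events$chan_last[i]
    if (any(last_end[chs] > events$start[i])) {
      keep[i] <- FALSE
    } else {
      last_end[chs] <- events$end[i]
    }
  }
  events <- events[keep, , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Inject oscillatory bursts into a recording
#'
#' Each event is a sinusoid at its event frequency multiplied by a Hann
#' envelope spanning the whole event, added identically to a block of
#' adjacent channels. The `amplitude` field is the peak-to-trough
#' excursion at the envelope maximum, so the injected waveform is
#' (amplitude / 2) * hann * sin. Outside the ground-truth intervals the
#' signal is untouched.
#'
#' @param rec An [recording()] (typically from [simulate_background()]).
#' @param config A [sim_config()].
#' @return List with `recording` (bursts added) and `ground_truth` (class
#'   `ground_truth`: the injected events, later enriched with closures and
#'   trial covariates).
#' @export
inject_bursts <- function(rec, config) {
  events <- draw_burst_events(config)
  data <- rec$data
  tt <- rec_times(rec)
  for (i in seq_len(nrow(events))) {
    idx <- span_to_samples(events$start[i], events$end[i], rec$rate,
                           rec$t0, ncol(data))
    smp <- idx[1]:idx[2]
    tloc <- tt[smp] - events$start[i]
    len <- events$end[i] - events$start[i]
    env <- 0.5 * (1 - cos(2 * pi * tloc / len))
    wave <- (events$amplitude[i] / 2) * env *
      sin(2 * pi * events$freq[i] * tloc)
    for (ch in events$chan_first[i]:events$chan_last[i]) {
      data[ch, smp] <- data[ch, smp] + wave
    }
  }
  gt <- structure(list(bursts = events,
                       closures = NULL, trials = NULL,
                       config = config),
                  class = "ground_truth")
  list(recording = recording(data, rec$rate, rec$channels, rec$t0),
       ground_truth = gt)
}

#' Simulate eye-closure episodes and a pupil-confidence trace
#'
#' Closure onsets follow a Poisson process; durations are log-normal.
#' The confidence trace sits near 0.9 with jitter while the eyes are open
#' and near 0.1 while closed, clipped to \[0, 1\].
#'
#' @param config A [sim_config()].
#' @return List with `trace` (`time`, `confidence` at `pupil_rate`) and
#'   `intervals` (data.frame start/end in seconds; possibly empty).
#' @export
simulate_closures <- function(config) {
  set.seed(sub_seed(config, 3L))
  n_ev <- stats::rpois(1, config$closure_rate * config$duration / 60)
  iv <- data.frame(start = numeric(), end = numeric())
  if (n_ev > 0) {
    start <- sort(stats::runif(n_ev, 0, config$duration))
    len <- stats::rlnorm(n_ev, config$closure_duration[["meanlog"]],
                         config$closure_duration[["sdlog"]])
    end <- pmin(start + len, config$duration)
    keep <- c(TRUE, start[-1] > cummax(end)[-n_ev])  # drop overlaps
    iv <- data.frame(start = start[keep], end = end[keep])
  }
  tp <- seq(0, config$duration, by = 1 / config$pupil_rate)
  closed <- rep(FALSE, length(tp))
  for (i in seq_len(nrow(iv))) {
    closed[tp >= iv$start[i] & tp < iv$end[i]] <- TRUE
  }
  conf <- ifelse(closed, 0.1, 0.9) + stats::rnorm(length(tp), 0, 0.05)
  list(trace = list(time = tp, confidence = pmin(pmax(conf, 0), 1)),
       intervals = iv)
}

# max ground-truth burst amplitude intersecting [onset + w1, onset + w2)
# on any channel; 0 if none
max_prestim_amplitude <- function(bursts, onset, window = c(-1, 0)) {
  lo <- onset + window[1]; hi <- onset + window[2]
  hit <- bursts$start < hi & bursts$end > lo
  if (!any(hit)) 0 else max(bursts$amplitude[hit])
}

closed_fraction <- function(intervals, lo, hi) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  ov <- pmin(intervals$end, hi) - pmax(intervals$start, lo)
  sum(pmax(ov, 0)) / (hi - lo)
}

#' Simulate behaviourally coupled trial outcomes
#'
#' Stimulus onsets are laid down with uniform inter-stimulus intervals in
#' the configured range. Each trial's lapse probability is
#' `plogis(beta0 + beta_amp * A + beta_ec * EC + beta_dist * D)` where A
#' is the amplitude covariate (maximum ground-truth burst amplitude in the
#' second before onset, or its top-decile indicator under
#' `amp_coupling = "top_decile"`), EC indicates eyes closed for more than
#' half the stimulus window, and D is the stimulus distance. With
#' `beta_ec = Inf` an EC trial is always a lapse. Given no lapse, the
#' reaction time is 0.1 s plus a log-normal draw truncated below 0.9 s,
#' split into fast/slow at 0.5 s.
#'
#' @param ground_truth A `ground_truth` (from [inject_bursts()]),
#'   optionally with closures attached via [attach_closures()].
#' @param config A [sim_config()].
#' @return A [trial_table()] with attribute `"latent"`: a data.frame of
#'   per-trial lapse probability and covariates.
#' @export
simulate_trials <- function(ground_truth, config) {
  set.seed(sub_seed(config, 4L))
  t_end <- config$duration - 1.5   # leave room for the response window
  onsets <- c()
  t <- config$isi[1] + 1           # first stimulus needs a pre-stim window
  while (t < t_end) {
    onsets <- c(onsets, t)
    t <- t + stats::runif(1, config$isi[1], config$isi[2])
  }
  if (length(onsets) < 1) stop("duration too short for a single trial")
  n <- length(onsets)
  amp_raw <- vapply(onsets, function(o)
    max_prestim_amplitude(ground_truth$bursts, o), 0)
  amp_cov <- if (config$amp_coupling == "top_decile") {
    thr <- stats::qlnorm(0.9, config$burst_amplitude[["meanlog"]],
                         config$burst_amplitude[["sdlog"]])
    as.numeric(amp_raw >= thr)
  } else amp_raw
  ec <- vapply(onsets, function(o)
    closed_fraction(ground_truth$closures, o, o + config$stim_window) > 0.5,
    NA)
  dist <- stats::runif(n)
  eta <- config$beta0 + config$beta_amp * amp_cov + config$beta_dist * dist
  p_lapse <- stats::plogis(eta)
  if (is.infinite(config$beta_ec)) {
    p_lapse[ec] <- 1
  } else {
    p_lapse <- stats::plogis(eta + config$beta_ec * ec)
  }
  lapse <- stats::runif(n) < p_lapse
  rt <- rep(NA_real_, n)
  for (i in which(!lapse)) {
    repeat {
      r <- 0.1 + stats::rlnorm(1, config$rt_meanlog, config$rt_sdlog)
      if (r < 1) { rt[i] <- r; break }
    }
  }
  hemi <- ifelse(floor(onsets / 120) %% 2 == 0, "left", "right")
  tt <- trial_table(onset = onsets, rt = rt, hemifield = hemi,
                    distance = dist, ec_stimulus = ec)
  attr(tt, "latent") <- data.frame(p_lapse = p_lapse, amp = amp_raw,
                                   amp_cov = amp_cov, ec = ec)
  tt
}

#' Attach closure intervals to a ground truth
#' @param ground_truth A `ground_truth`.
#' @param intervals Closure intervals (data.frame start/end).
#' @return The updated `ground_truth`.
#' @export
attach_closures <- function(ground_truth, intervals) {
  ground_truth$closures <- intervals
  ground_truth
}

#' Ground-truth burst occupancy matrix
#'
#' Boolean channels x samples matrix that is TRUE exactly inside injected
#' burst intervals of the requested band, on the injected channels. This
#' is the simulator's exact counterpart of [burst_occupancy()] on detected
#' bursts.
#'
#' @param ground_truth A `ground_truth`.
#' @param band Band name ("theta", "alpha") or NULL for all bands.
#' @return Logical matrix `n_channels` x `duration * rate`.
#' @export
ground_truth_occupancy <- function(ground_truth, band = NULL) {
  cfg <- ground_truth$config
  n <- round(cfg$duration * cfg$rate)
  occ <- matrix(FALSE, cfg$n_channels, n)
  ev <- ground_truth$bursts
  if (!is.null(band)) ev <- ev[ev$band %in% band, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    idx <- span_to_samples(ev$start[i], ev$end[i], cfg$rate, 0, n)
    occ[ev$chan_first[i]:ev$chan_last[i], idx[1]:idx[2]] <- TRUE
  }
  occ
}

#' Materialise ground-truth events as a burst table
#'
#' Converts injected events into the same `burst_table` representation the
#' detector produces, synthesising per-cycle records from the known
#' waveform: cycle peaks at the sinusoid maxima, per-cycle amplitude equal
#' to the Hann envelope at the cycle peak times the event's peak-to-trough
#' amplitude. Lets every downstream analysis run on exact ground truth.
#'
#' @param ground_truth A `ground_truth`.
#' @param channels Channel labels of the parent recording.
#' @return A `burst_table` (see [detect_bursts()]).
#' @export
ground_truth_bursts <- function(ground_truth, channels = NULL) {
  cfg <- ground_truth$config
  if (is.null(channels)) channels <- paste0("ch", seq_len(cfg$n_channels))
  ev <- ground_truth$bursts
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    len <- ev$end[i] - ev$start[i]
    # sinusoid peaks: sin(2*pi*f*t) = 1 at t = (k + 1/4) / f
    pk <- ev$start[i] + (seq_len(ev$n_cycles[i]) - 3 / 4) / ev$freq[i]
    pk <- pk[pk > ev$start[i] & pk < ev$end[i]]
    env <- 0.5 * (1 - cos(2 * pi * (pk - ev$start[i]) / len))
    cyc <- data.frame(start = pk[-length(pk)], end = pk[-1],
                      peak = pk[-length(pk)],
                      period = 1 / ev$freq[i],
                      amplitude = ev$amplitude[i] *
                        (env[-length(env)] + env[-1]) / 2,
                      monotonicity = 1, period_consistency = 1,
                      amplitude_consistency = 1)
    for (ch in ev$chan_first[i]:ev$chan_last[i]) {
      rows[[length(rows) + 1]] <- burst_row(
        channel = channels[ch], start = ev$start[i], end = ev$end[i],
        cycles = cyc, mean_period = 1 / ev$freq[i],
        mean_amplitude = mean(cyc$amplitude))
    }
  }
  as_burst_table(rows)
}

#' Generate a multi-participant synthetic dataset
#'
#' One session block per participant per condition; per-participant seeds
#' derive deterministically from the master seed, so the same master seed
#' always yields an identical dataset.
#'
#' @param config A [sim_config()] template (its seed acts as master seed).
#' @param n_participants Number of participants (0 gives an empty list).
#' @param conditions Condition labels, one block each (default "BL").
#' @param waveform If FALSE, skip waveform synthesis: recordings are
#'   omitted and only ground truth, closures and trials are produced
#'   (used by large calibration runs on ground-truth occupancy).
#' @return List of participants; each is a list of per-condition entries
#'   with `block` (a [session_block()], when `waveform`), `ground_truth`,
#'   `closures`, `trace`, `trials`.
#' @export
make_dataset <- function(config, n_participants, conditions = "BL",
                         waveform = TRUE) {
  if (n_participants == 0) return(list())
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    per <- list()
    for (ci in seq_along(conditions)) {
      cfg <- config
      cfg$seed <- (config$seed + 10007L * p + 131071L * ci) %% 2000000011L
      cls <- simulate_closures(cfg)
      if (waveform) {
        bg <- simulate_background(cfg)
        inj <- inject_bursts(bg, cfg)
        gt <- attach_closures(inj$ground_truth, cls$intervals)
        trials <- simulate_trials(gt, cfg)
        rec <- inj$recording
        conf <- resample_pupil(cls$trace, rec)
        msk <- eeg_mask(closure = closure_mask(conf), recording = rec)
        blk <- session_block(conditions[ci], list(rec), list(trials),
                             list(msk))
      } else {
        ev <- draw_burst_events(cfg)
        gt <- structure(list(bursts = ev, closures = cls$intervals,
                             trials = NULL, config = cfg),
                        class = "ground_truth")
        trials <- simulate_trials(gt, cfg)
        blk <- NULL
      }
      gt$trials <- attr(trials, "latent")
      per[[conditions[ci]]] <- list(block = blk, ground_truth = gt,
                                    closures = cls$intervals,
                                    trace = cls$trace, trials = trials)
    }
    out[[p]] <- per
  }
  out
}
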