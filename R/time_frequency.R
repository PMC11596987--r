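# Morlet-wavelet time-frequency control analysis: session-normalised
# event-locked log-power, outcome contrasts, and band topographies.

#' Log-spaced cycles-per-frequency vector
#'
#' Cycles interpolated log-linearly from 3 (at `anchor[1]`, default 1 Hz)
#' to 15 (at `anchor[2]`, default 35 Hz), so a restricted frequency grid
#' keeps the same cycles-per-frequency mapping as the full 1-35 Hz
#' analysis. Values are clamped to the cycle range outside the anchors.
#'
#' @param freqs Frequency grid in Hz.
#' @param range Cycle range, default `c(3, 15)`.
#' @param anchor Frequencies (Hz) at which the range endpoints apply.
#' @return Numeric vector, one cycle count per frequency.
#' @export
morlet_cycles <- function(freqs, range = c(3, 15), anchor = c(1, 35)) {
  lf <- (log(freqs) - log(anchor[1])) / (log(anchor[2]) - log(anchor[1]))
  lf <- pmin(pmax(lf, 0), 1)
  exp(log(range[1]) + lf * (log(range[2]) - log(range[1])))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet convolution (Gaussian-windowed carrier, temporal SD =
#' cycles / (2 pi f)), magnitude squared, floored at a small positive
#' fraction of the recording's median power, base-10 log. Edges are
#' handled by reflection padding of one maximal wavelet length.
#'
#' @param rec An [recording()].
#' @param freqs Frequency grid in Hz (default 1-35 in 1 Hz steps); the
#'   maximum must stay below rate / 2.
#' @param cycles Cycles per frequency (default [morlet_cycles()]).
#' @param log_floor_frac Power floor as a fraction of median power,
#'   default 1e-12.
#' @return List of class `tfr_tensor`: `power` (channels x frequencies x
#'   samples, log10 power), `freqs`, `cycles`, `rate`, `t0`.
#' @export
morlet_tfr <- function(rec, freqs = 1:35, cycles = NULL,
                       log_floor_frac = 1e-12) {
  stopifnot(max(freqs) < rec$rate / 2)
  if (is.null(cycles)) cycles <- morlet_cycles(freqs)
  stopifnot(length(cycles) == length(freqs))
  nc <- nrow(rec$data); ns <- ncol(rec$data)
  # maximal wavelet half-length (3.5 SD of the widest wavelet)
  sd_t <- cycles / (2 * pi * freqs)
  half <- ceiling(3.5 * max(sd_t) * rec$rate)
  half <- min(half, ns - 1)
  pow <- array(NA_real_, c(nc, length(freqs), ns))
  n_pad <- ns + 2 * half
  nfft <- stats::nextn(n_pad, 2)
  for (ch in seq_len(nc)) {
    x <- rec$data[ch, ]
    xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[ns - seq_len(half)]))
    X <- stats::fft(c(xp, rep(0, nfft - n_pad)))
    for (fi in seq_along(freqs)) {
      hw <- ceiling(3.5 * sd_t[fi] * rec$rate)
      tw <- (-hw:hw) / rec$rate
      w <- exp(-tw^2 / (2 * sd_t[fi]^2)) *
        exp(2i * pi * freqs[fi] * tw)
      w <- w / sum(abs(w))
      W <- stats::fft(c(w, rep(0, nfft - length(w))))
      conv <- stats::fft(X * W, inverse = TRUE) / nfft
      # centre of the wavelet lands hw samples late; drop padding
      est <- conv[hw + half + seq_len(ns)]
      pow[ch, fi, ] <- Mod(est)^2
    }
  }
  floor_ <- log_floor_frac * stats::median(pow)
  if (!is.finite(floor_) || floor_ <= 0) floor_ <- 1e-300
  pow <- log10(pmax(pow, floor_))
  structure(list(power = pow, freqs = freqs, cycles = cycles,
                 rate = rec$rate, t0 = rec$t0),
            class = "tfr_tensor")
}

#' @export
print.tfr_tensor <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr_tensor> %d channels x %d frequencies (%g-%g Hz) x %d samples\n",
              d[1], d[2], min(x$freqs), max(x$freqs), d[3]))
  invisible(x)
}

#' Subtract the session-block mean power
#'
#' The average log-power across every unmasked sample of the session
#' block is subtracted from each time point, per channel and frequency.
#' No further baseline correction is applied to individual trials.
#'
#' @param tfr A [morlet_tfr()] result.
#' @param mask Optional logical channels x samples exclusion matrix;
#'   masked samples are left out of the mean (and set to NA).
#' @return The normalised `tfr_tensor`, with the session mean stored as
#'   `$session_mean` (channels x frequencies).
#' @export
session_normalise <- function(tfr, mask = NULL) {
  d <- dim(tfr$power)
  sess <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[1])) {
    sl <- tfr$power[ch, , , drop = FALSE]
    dim(sl) <- d[2:3]
    if (!is.null(mask)) sl[, mask[ch, ]] <- NA
    sess[ch, ] <- rowMeans(sl, na.rm = TRUE)
    tfr$power[ch, , ] <- sl - sess[ch, ]
  }
  tfr$session_mean <- sess
  tfr
}

#' Epoch a TFR tensor around stimulus onsets
#'
#' Same trial-selection rules as [epoch_tensor()]: false alarms always
#' excluded, eye-closure trials excluded on request, trials with more
#' than half their samples missing dropped.
#'
#' @param tfr A (session-normalised) `tfr_tensor`.
#' @param trials A [trial_table()].
#' @param window Epoch window in seconds, default `c(-2, 4)`.
#' @param mask Optional logical channels x samples exclusion matrix.
#' @param exclude_ec Drop `ec_stimulus` trials (default FALSE: the
#'   time-frequency analysis is run both with and without eye closures).
#' @param max_missing Maximal missing fraction per trial.
#' @return List of class `tfr_epochs`: `tensor` (trials x channels x
#'   frequencies x time), `outcome`, `time`, `freqs`, `rate`.
#' @export
epoch_tfr <- function(tfr, trials, window = c(-2, 4), mask = NULL,
                      exclude_ec = FALSE, max_missing = 0.5) {
  d <- dim(tfr$power)
  nt_win <- round((window[2] - window[1]) * tfr$rate)
  rel <- window[1] + (seq_len(nt_win) - 1) / tfr$rate
  keep <- trials$outcome != "falsealarm"
  if (exclude_ec) keep <- keep & !trials$ec_stimulus
  idx_trials <- which(keep)
  tens <- array(NA_real_, c(length(idx_trials), d[1], d[2], nt_win))
  ok <- rep(TRUE, length(idx_trials))
  for (k in seq_along(idx_trials)) {
    on <- trials$onset[idx_trials[k]]
    i0 <- round((on + window[1] - tfr$t0) * tfr$rate) + 1
    smp <- i0 + seq_len(nt_win) - 1
    valid <- smp >= 1 & smp <= d[3]
    ep <- array(NA_real_, c(d[1], d[2], nt_win))
    ep[, , valid] <- tfr$power[, , smp[valid], drop = FALSE]
    if (!is.null(mask)) {
      for (ch in seq_len(d[1])) {
        bad <- valid & mask[ch, pmax(pmin(smp, d[3]), 1)]
        ep[ch, , bad] <- NA
      }
    }
    if (mean(is.na(ep)) > max_missing) ok[k] <- FALSE
    tens[k, , , ] <- ep
  }
  structure(list(tensor = tens[ok, , , , drop = FALSE],
                 outcome = trials$outcome[idx_trials[ok]],
                 time = rel, freqs = tfr$freqs, rate = tfr$rate),
            class = "tfr_epochs")
}

#' Participant-level outcome-average TFR maps
#'
#' Channel-averaged frequency x time map of session-normalised log-power
#' per trial outcome for one participant.
#'
#' @param epochs An [epoch_tfr()] result.
#' @param outcomes Outcome labels, default fast/slow/lapse.
#' @param min_trials Minimum trials per outcome, default 15.
#' @return Array outcome x frequency x time (NA where excluded).
#' @export
participant_tfr_maps <- function(epochs, outcomes = c("fast", "slow", "lapse"),
                                 min_trials = 15) {
  d <- dim(epochs$tensor)
  out <- array(NA_real_, c(length(outcomes), d[3], d[4]),
               dimnames = list(outcomes, NULL, NULL))
  for (oi in seq_along(outcomes)) {
    sel <- which(epochs$outcome == outcomes[oi])
    if (length(sel) < min_trials) next
    sub <- epochs$tensor[sel, , , , drop = FALSE]
    out[oi, , ] <- apply(sub, c(3, 4), mean, na.rm = TRUE)
  }
  out
}

#' Group time-frequency statistics per outcome
#'
#' One-sample t-tests across participants at every (frequency, time)
#' pixel of the session-normalised maps, identifying deviations from
#' average spectral power per trial outcome; FDR correction over the
#' whole map family. Pixels with zero variance are undefined and never
#' significant.
#'
#' @param map_list List of [participant_tfr_maps()] arrays.
#' @param q FDR level, default 0.05.
#' @param min_n Minimal participants, default 3.
#' @return List of class `tfr_result` with outcome x frequency x time
#'   arrays `t`, `p`, `p_fdr`, `significant`, `g`, `n`.
#' @export
tfr_by_outcome <- function(map_list, q = 0.05, min_n = 3) {
  dm <- dim(map_list[[1]])
  arr <- array(NA_real_, c(length(map_list), dm))
  for (p in seq_along(map_list)) arr[p, , , ] <- map_list[[p]]
  st <- group_onesample_map(arr)
  low_n <- st$n < min_n
  st$t[low_n] <- NA; st$p[low_n] <- NA
  f <- fdr_bh(as.vector(st$p), q)
  res <- list(t = st$t, p = st$p, p_fdr = array(f$p_fdr, dm),
              significant = array(f$significant, dm),
              g = st$g, n = st$n)
  for (nm in names(res)) dimnames(res[[nm]]) <- dimnames(map_list[[1]])
  class(res) <- "tfr_result"
  res
}

#' Default frequency bands for band summaries
#'
#' Delta 1-4, theta 4-8, alpha 8-14, beta 15-25, gamma 25-30 Hz
#' (half-open \[low, high) edges).
#' @return Named list of `c(low, high)` pairs.
#' @export
tfr_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
       beta = c(15, 25), gamma = c(25, 30))
}

#' Per-participant band x window x channel power summary
#'
#' Mean session-normalised log-power within each frequency band and
#' window per channel, averaged over the trials of each outcome.
#'
#' @param epochs An [epoch_tfr()] result.
#' @param bands Named list of band edges, default [tfr_bands()].
#' @param windows Named list of windows, default Pre and Stimulus.
#' @param outcomes Outcome labels.
#' @param min_trials Minimum trials per outcome.
#' @return Array outcome x band x window x channel.
#' @export
participant_band_power <- function(epochs, bands = tfr_bands(),
                                   windows = topography_windows()[c("Pre", "Stimulus")],
                                   outcomes = c("fast", "slow", "lapse"),
                                   min_trials = 15) {
  d <- dim(epochs$tensor)
  out <- array(NA_real_,
               c(length(outcomes), length(bands), length(windows), d[2]),
               dimnames = list(outcomes, names(bands), names(windows),
                               NULL))
  for (oi in seq_along(outcomes)) {
    sel <- which(epochs$outcome == outcomes[oi])
    if (length(sel) < min_trials) next
    for (bi in seq_along(bands)) {
      fsel <- epochs$freqs >= bands[[bi]][1] &
        epochs$freqs < bands[[bi]][2]
      if (!any(fsel)) next
      for (wi in seq_along(windows)) {
        tsel <- epochs$time >= windows[[wi]][1] &
          epochs$time < windows[[wi]][2]
        sub <- epochs$tensor[sel, , fsel, tsel, drop = FALSE]
        out[oi, bi, wi, ] <- apply(sub, 2, mean, na.rm = TRUE)
      }
    }
  }
  out
}

#' Group band-topography statistics
#'
#' One-sample t-tests across participants per channel of the band x
#' window summaries; FDR within each (outcome x band x window)
#' topography.
#'
#' @param bp_list List of [participant_band_power()] arrays.
#' @param q FDR level, default 0.05.
#' @param min_n Minimal participants, default 3.
#' @return List of class `band_topography_result` with outcome x band x
#'   window x channel arrays `t`, `p`, `p_fdr`, `significant`, `g`, `n`.
#' @export
band_topography <- function(bp_list, q = 0.05, min_n = 3) {
  dm <- dim(bp_list[[1]])
  arr <- array(NA_real_, c(length(bp_list), dm))
  for (p in seq_along(bp_list)) arr[p, , , , ] <- bp_list[[p]]
  st <- group_onesample_map(arr)
  low_n <- st$n < min_n
  st$t[low_n] <- NA; st$p[low_n] <- NA
  p_fdr <- sig <- array(NA, dm)
  for (oi in seq_len(dm[1])) for (bi in seq_len(dm[2])) {
    for (wi in seq_len(dm[3])) {
      f <- fdr_bh(st$p[oi, bi, wi, ], q)
      p_fdr[oi, bi, wi, ] <- f$p_fdr
      sig[oi, bi, wi, ] <- f$significant
    }
  }
  res <- list(t = st$t, p = st$p, p_fdr = p_fdr, significant = sig,
              g = st$g, n = st$n)
  for (nm in names(res)) dimnames(res[[nm]]) <- dimnames(bp_list[[1]])
  class(res) <- "band_topography_result"
  res
}
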