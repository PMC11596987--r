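# Standard preprocessing: 40 Hz low-pass, decimation to 250 Hz, 0.5 Hz
# high-pass, eye-closure masking, and mask combination. All filters are
# zero-phase (forward-backward IIR) so event-locked timing is preserved.

# zero-phase Butterworth applied row-wise; `type` as in signal::butter
zp_filter <- function(data, order, w, type) {
  bf <- signal::butter(order, w, type = type)
  t(apply(data, 1, function(x) signal::filtfilt(bf, x)))
}

#' Standard EEG filter chain
#'
#' Low-pass at `lowpass` Hz (two cascaded zero-phase passes of a
#' 4th-order Butterworth, for a steep transition band), integer decimation
#' to `target_rate`, then high-pass at `highpass` Hz. The low-pass doubles
#' as the anti-alias filter for the decimation. The high-pass runs as two
#' cascaded 2nd-order zero-phase sections for numerical stability at the
#' very low normalised cutoff.
#'
#' @param rec An [recording()] with rate >= 100 and rate divisible by
#'   `target_rate`.
#' @param lowpass Low-pass cutoff in Hz (default 40).
#' @param target_rate Output sampling rate (default 250).
#' @param highpass High-pass cutoff in Hz (default 0.5).
#' @return A filtered [recording()] at `target_rate`.
#' @export
standard_filter_chain <- function(rec, lowpass = 40, target_rate = 250,
                                  highpass = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate < 100) {
    stop("sampling rate below 100 Hz cannot honour a 40 Hz low-pass")
  }
  data <- zp_filter(rec$data, 4, lowpass / (rec$rate / 2), "low")
  data <- zp_filter(data, 4, lowpass / (rec$rate / 2), "low")
  if (rec$rate != target_rate) {
    dec <- rec$rate / target_rate
    if (abs(dec - round(dec)) > 1e-9) {
      stop("rate must be an integer multiple of target_rate")
    }
    data <- data[, seq(1, ncol(data), by = round(dec)), drop = FALSE]
  }
  w_hp <- highpass / (target_rate / 2)
  data <- zp_filter(data, 2, w_hp, "high")
  data <- zp_filter(data, 2, w_hp, "high")
  recording(data, target_rate, rec$channels, rec$t0)
}

#' Eye-closure mask from a pupil-confidence trace
#'
#' A sample counts as eyes-closed when pupil confidence is strictly below
#' the threshold (confidence exactly at threshold is open).
#'
#' @param confidence Numeric vector aligned to the recording's samples
#'   (see [resample_pupil()]).
#' @param threshold Confidence threshold, default 0.5.
#' @return Logical vector, TRUE = eyes closed.
#' @export
closure_mask <- function(confidence, threshold = 0.5) {
  confidence < threshold
}

#' Flag trials with eyes closed during the stimulus window
#'
#' Sets `ec_stimulus` to TRUE for trials whose eye-closure fraction within
#' \[onset, onset + stim_window) exceeds 0.5. Such trials are excluded
#' from burst analyses because the lapse would simply be due to eye
#' closure.
#'
#' @param trials A [trial_table()].
#' @param closure Logical closure vector (one value per sample).
#' @param rate Sampling rate of the closure vector.
#' @param stim_window Stimulus window length in seconds (default 0.5, the
#'   stimulus visibility duration).
#' @param t0 Time of the first sample.
#' @return The trial table with `ec_stimulus` updated.
#' @export
flag_ec_trials <- function(trials, closure, rate, stim_window = 0.5,
                           t0 = 0) {
  n <- length(closure)
  frac <- vapply(trials$onset, function(on) {
    idx <- span_to_samples(on, on + stim_window, rate, t0, n)
    if (idx[2] < idx[1]) return(0)
    mean(closure[idx[1]:idx[2]])
  }, 0)
  trials$ec_stimulus <- frac > 0.5
  trials
}

#' Combine artifact and eye-closure masks
#'
#' With `mode = "without_ec"` closed-eye samples are treated the same as
#' artifacts (the default for burst analyses); with `mode = "with_ec"`
#' only the artifact mask applies (the time-frequency analysis is run
#' both ways).
#'
#' @param mask An [eeg_mask()].
#' @param mode "without_ec" or "with_ec".
#' @return Logical channels x samples matrix, TRUE = excluded.
#' @export
combine_masks <- function(mask, mode = c("without_ec", "with_ec")) {
  mode <- match.arg(mode)
  out <- mask$artifact
  if (mode == "without_ec") {
    out <- out | matrix(mask$closure, nrow(out), ncol(out), byrow = TRUE)
  }
  out
}
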