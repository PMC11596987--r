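#' Multichannel EEG recording
#'
#' Lightweight container for a continuous multichannel voltage signal:
#' a channels x samples matrix in microvolts, a sampling rate, ordered
#' unique channel labels and a time origin. Sample i sits at time
#' t0 + (i - 1) / rate; all trial and burst windows are half-open
#' \[start, end).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in samples/s (> 0).
#' @param channels Character vector of unique channel labels; defaults to
#'   rownames of `data` or `ch1..chN`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(data, rate, channels = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data), rate > 0)
  if (is.null(channels)) {
    channels <- rownames(data)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  }
  stopifnot(length(channels) == nrow(data))
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  rownames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels, t0 = t0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate, x$t0))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# sample times of a recording, seconds
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$rate

n_samples <- function(rec) ncol(rec$data)

# first/last sample index (1-based) covering half-open [start, end)
span_to_samples <- function(start, end, rate, t0, n) {
  i0 <- ceiling((start - t0) * rate - 1e-9) + 1
  i1 <- ceiling((end - t0) * rate - 1e-9)
  c(max(1L, i0), min(n, i1))
}

#' Classify a trial outcome from its reaction time
#'
#' Reaction times below 0.1 s are false alarms (anticipatory presses),
#' in \[0.1, 0.5) s fast responses, in \[0.5, 1) s slow responses; absent
#' responses (and RTs of 1 s or more) are lapses.
#'
#' @param rt Numeric vector of reaction times in seconds; NA means no
#'   response.
#' @return Factor with levels falsealarm, fast, slow, lapse.
#' @export
classify_outcome <- function(rt) {
  out <- ifelse(is.na(rt), "lapse",
         ifelse(rt < 0.1, "falsealarm",
         ifelse(rt < 0.5, "fast",
         ifelse(rt < 1.0, "slow", "lapse"))))
  factor(out, levels = outcome_levels())
}

outcome_levels <- function() c("falsealarm", "fast", "slow", "lapse")

#' Per-trial behavioural table
#'
#' One row per stimulus: onset (s from recording start), reaction time
#' (s, NA for lapses), stimulated hemifield, normalised radial distance of
#' the stimulus from fixation in \[0, 1\], and the eye-closure flag
#' (`ec_stimulus`: eyes closed for more than half the stimulus window).
#' The outcome label is always recomputed from the reaction time.
#'
#' @param onset Strictly increasing numeric vector, seconds.
#' @param rt Reaction times, NA for no response.
#' @param hemifield "left"/"right" per trial (recycled).
#' @param distance Radial stimulus distance in \[0, 1\] (recycled).
#' @param ec_stimulus Logical eye-closure flag (recycled, default FALSE).
#' @return A `data.frame` of class `trial_table` with an added `outcome`
#'   column.
#' @export
trial_table <- function(onset, rt = NA_real_, hemifield = "left",
                        distance = 0.5, ec_stimulus = FALSE) {
  n <- length(onset)
  if (n > 1 && any(diff(onset) <= 0)) {
    stop("trial onsets must be strictly increasing")
  }
  rt <- rep_len(as.numeric(rt), n)
  if (any(rt < 0, na.rm = TRUE)) stop("reaction times must be >= 0")
  hemifield <- rep_len(as.character(hemifield), n)
  stopifnot(all(hemifield %in% c("left", "right")))
  distance <- rep_len(as.numeric(distance), n)
  stopifnot(all(distance >= 0 & distance <= 1, na.rm = TRUE))
  df <- data.frame(onset = as.numeric(onset), rt = rt,
                   outcome = classify_outcome(rt),
                   hemifield = hemifield, distance = distance,
                   ec_stimulus = rep_len(as.logical(ec_stimulus), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Artifact and eye-closure masks aligned to a recording
#'
#' @param artifact Logical channels x samples matrix (TRUE = artifact), or
#'   NULL for none.
#' @param closure Logical vector, one value per sample (TRUE = eyes
#'   closed), or NULL for none.
#' @param recording The parent [recording()] used for dimension checks.
#' @return Object of class `eeg_mask` with `artifact` and `closure` always
#'   materialised at full size.
#' @export
eeg_mask <- function(artifact = NULL, closure = NULL, recording) {
  nc <- nrow(recording$data); ns <- ncol(recording$data)
  if (is.null(artifact)) artifact <- matrix(FALSE, nc, ns)
  if (is.null(closure)) closure <- rep(FALSE, ns)
  stopifnot(is.logical(artifact), identical(dim(artifact), c(nc, ns)),
            is.logical(closure), length(closure) == ns)
  rownames(artifact) <- recording$channels
  structure(list(artifact = artifact, closure = closure),
            class = "eeg_mask")
}

#' Session block: pooled recordings of one condition
#'
#' Groups the recordings, trial tables and masks of one condition
#' (baseline `BL` or extended wakefulness `EW`) that are normalised
#' together: session-block statistics (mean burst occupancy, mean spectral
#' power) are computed over every unmasked sample of all members.
#'
#' @param condition Condition label, e.g. "BL" or "EW".
#' @param recordings List of [recording()] objects sharing rate and
#'   channel set.
#' @param trials List of [trial_table()] objects, one per recording.
#' @param masks Optional list of [eeg_mask()] objects, one per recording.
#' @return Object of class `session_block`.
#' @export
session_block <- function(condition, recordings, trials, masks = NULL) {
  stopifnot(length(recordings) >= 1,
            length(trials) == length(recordings))
  rate <- recordings[[1]]$rate
  chans <- recordings[[1]]$channels
  for (r in recordings) {
    if (r$rate != rate || !identical(r$channels, chans)) {
      stop("all recordings in a session block must share rate and channels")
    }
  }
  if (is.null(masks)) {
    masks <- lapply(recordings, function(r) eeg_mask(recording = r))
  }
  stopifnot(length(masks) == length(recordings))
  structure(list(condition = condition, recordings = recordings,
                 trials = trials, masks = masks),
            class = "session_block")
}

#' @export
print.session_block <- function(x, ...) {
  nt <- sum(vapply(x$trials, nrow, 0L))
  cat(sprintf("<session_block> condition %s: %d recording(s), %d trials\n",
              x$condition, length(x$recordings), nt))
  invisible(x)
}

#' Total trial count of a session block
#' @param block A [session_block()].
#' @return Integer trial count summed over member recordings.
#' @export
block_n_trials <- function(block) {
  sum(vapply(block$trials, nrow, 0L))
}
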