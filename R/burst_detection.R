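# Cycle-by-cycle burst detection. Narrow overlapping band-pass filters
# locate zero-crossings; peaks and troughs are then measured on the
# broadband (0.5-40 Hz) signal; cycles run positive peak to positive peak
# and carry rhythmicity properties; maximal runs of qualifying cycles
# become bursts, which are merged across bands and sorted into theta
# (4-8 Hz) and alpha (8-14 Hz) by mean negative-peak-to-peak period.

#' Burst acceptance criteria
#'
#' A run of consecutive cycles becomes a burst when every cycle meets all
#' thresholds and the run has at least `min_cycles` cycles.
#'
#' @param min_cycles Minimum consecutive qualifying cycles (>= 2).
#' @param monotonicity Minimum flank monotonicity in \[0, 1\].
#' @param period_consistency Minimum neighbour period ratio in \[0, 1\].
#' @param amplitude_consistency Minimum neighbour amplitude ratio in
#'   \[0, 1\].
#' @param amp_fraction Relative amplitude criterion: a cycle qualifies
#'   only if its amplitude exceeds this quantile of all cycle amplitudes
#'   of the same channel and filter band. Oscillatory bursts must stand
#'   out of the aperiodic background, which narrow filtering alone makes
#'   look deceptively rhythmic; 0 disables.
#' @return List of class `burst_criteria`.
#' @export
burst_criteria <- function(min_cycles = 4L, monotonicity = 0.6,
                           period_consistency = 0.5,
                           amplitude_consistency = 0.3,
                           amp_fraction = 0.8) {
  stopifnot(min_cycles >= 2,
            monotonicity >= 0 && monotonicity <= 1,
            period_consistency >= 0 && period_consistency <= 1,
            amplitude_consistency >= 0 && amplitude_consistency <= 1,
            amp_fraction >= 0 && amp_fraction < 1)
  structure(list(min_cycles = as.integer(min_cycles),
                 monotonicity = monotonicity,
                 period_consistency = period_consistency,
                 amplitude_consistency = amplitude_consistency,
                 amp_fraction = amp_fraction),
            class = "burst_criteria")
}

#' Narrow overlapping band-pass filter bank
#'
#' Filters each channel in 4 Hz wide bands stepped by 1 Hz from 2 to
#' 16 Hz (\[2,6\], \[3,7\], ..., \[12,16\]): every frequency between 4 and
#' 14 Hz sits within half a bandwidth of a band centre. Zero-phase
#' 2nd-order Butterworth band-passes (4th order after forward-backward).
#'
#' @param rec An [recording()] with rate >= 64.
#' @param low,high Outer band edges in Hz (defaults 2 and 16).
#' @param width Band width in Hz (default 4).
#' @param step Band step in Hz (default 1).
#' @return Named list of channels x samples matrices, one per band, names
#'   like "2-6".
#' @export
filter_bank <- function(rec, low = 2, high = 16, width = 4, step = 1) {
  stopifnot(rec$rate >= 64)
  los <- seq(low, high - width, by = step)
  out <- vector("list", length(los))
  names(out) <- paste0(los, "-", los + width)
  for (i in seq_along(los)) {
    w <- c(los[i], los[i] + width) / (rec$rate / 2)
    bf <- signal::butter(2, w, type = "pass")
    out[[i]] <- t(apply(rec$data, 1,
                        function(x) signal::filtfilt(bf, x)))
  }
  out
}

#' Signed zero-crossings of a narrowband signal
#'
#' Sub-sample crossing times by linear interpolation between the samples
#' flanking each sign change; samples exactly at zero count as crossings
#' when their neighbours have opposite signs (or at the signal edge).
#' Crossing signs alternate: +1 for upward (negative to positive), -1 for
#' downward.
#'
#' @param x Numeric vector (one channel, one band).
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample (default 0).
#' @return data.frame with `time` (s) and `sign` (+1/-1); empty for
#'   signals without sign changes.
#' @export
zero_crossings <- function(x, rate, t0 = 0) {
  n <- length(x)
  empty <- data.frame(time = numeric(), sign = numeric())
  if (n < 2) return(empty)
  a <- x[-n]; b <- x[-1]
  strad <- which(a * b < 0)
  t_str <- (strad - 1) + a[strad] / (a[strad] - b[strad])
  s_str <- sign(b[strad])
  zer <- which(x == 0)
  keep <- logical(length(zer)); s_zer <- numeric(length(zer))
  for (k in seq_along(zer)) {
    i <- zer[k]
    prv <- if (i > 1) x[i - 1] else 0
    nxt <- if (i < n) x[i + 1] else 0
    if (nxt != 0 && (prv == 0 || sign(prv) != sign(nxt))) {
      keep[k] <- TRUE; s_zer[k] <- sign(nxt)
    }
  }
  tms <- c(t_str, zer[keep] - 1)
  sgn <- c(s_str, s_zer[keep])
  ord <- order(tms)
  data.frame(time = t0 + tms[ord] / rate, sign = sgn[ord])
}

#' Build cycles from broadband peaks between zero-crossings
#'
#' Between an upward and the next downward crossing the broadband signal's
#' maximum is a positive peak; between a downward and the next upward
#' crossing its minimum is a trough. A cycle spans positive peak to next
#' positive peak and contains one trough. The period is measured trough to
#' trough (negative-peak-to-peak); the first cycle, which lacks a
#' preceding trough, uses its peak-to-peak span. Amplitude is the mean
#' peak-to-trough excursion of the two flanks. Argmax ties take the
#' earliest sample.
#'
#' @param x Broadband signal of one channel (0.5-40 Hz preprocessed).
#' @param crossings data.frame from [zero_crossings()] on the narrowband
#'   signal.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample.
#' @return data.frame of class `cycle_table`: `start`, `end`, `peak`
#'   (times, s), `trough`, `period`, `amplitude`, plus empty property
#'   columns filled by [cycle_properties()]. Empty if fewer than 4
#'   crossings.
#' @export
build_cycles <- function(x, crossings, rate, t0 = 0) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      peak = numeric(), trough = numeric(),
                      period = numeric(), amplitude = numeric(),
                      monotonicity = numeric(),
                      period_consistency = numeric(),
                      amplitude_consistency = numeric())
  class(empty) <- c("cycle_table", "data.frame")
  if (nrow(crossings) < 4) return(empty)
  n <- length(x)
  # sample range of each inter-crossing segment
  n_seg <- nrow(crossings) - 1
  i0 <- pmax(1L, ceiling((crossings$time[-(n_seg + 1)] - t0) * rate) + 1L)
  i1 <- pmin(n, floor((crossings$time[-1] - t0) * rate) + 1L)
  ok_seg <- i1 >= i0
  seg_sign <- crossings$sign[seq_len(n_seg)][ok_seg]
  i0 <- i0[ok_seg]; i1 <- i1[ok_seg]
  if (!length(i0)) return(empty)
  # extremum per segment, vectorised: label every covered sample with its
  # segment, order by (segment, oriented value, index) and keep the first
  lens <- i1 - i0 + 1L
  smp <- sequence(lens) - 1L + rep(i0, lens)
  seg_of <- rep(seq_along(i0), lens)
  val <- x[smp] * rep(ifelse(seg_sign > 0, -1, 1), lens)
  ord <- order(seg_of, val, smp)
  first <- !duplicated(seg_of[ord])
  ext_idx <- smp[ord][first]
  ext_pos <- seg_sign[seg_of[ord][first]] > 0
  pk <- ext_idx[ext_pos]; tr <- ext_idx[!ext_pos]
  if (length(pk) < 2) return(empty)
  m <- length(pk)
  t_of <- function(i) t0 + (i - 1) / rate
  # trough inside cycle i: deepest trough strictly between the two peaks
  p0 <- pk[-m]; p1 <- pk[-1]
  lo <- findInterval(p0, tr) + 1L
  hi <- findInterval(p1 - 1L, tr)
  tin <- rep(NA_integer_, m - 1)
  single <- hi == lo
  tin[single] <- tr[lo[single]]
  for (ci in which(hi > lo)) {
    cand <- tr[lo[ci]:hi[ci]]
    tin[ci] <- cand[which.min(x[cand])]
  }
  keep <- !is.na(tin)
  p0 <- p0[keep]; p1 <- p1[keep]; tin <- tin[keep]
  if (!length(p0)) return(empty)
  # negative-peak-to-peak period: this cycle's trough minus the previous
  # cycle's; the first cycle falls back to its peak-to-peak span
  period <- c(if (length(tin) > 1) diff(tin) / rate, NULL)
  period <- c((p1[1] - p0[1]) / rate, period)
  tprev <- tr[tr < p0[1]]
  if (length(tprev)) period[1] <- (tin[1] - max(tprev)) / rate
  amp <- (x[p0] - x[tin] + x[p1] - x[tin]) / 2
  cyc <- data.frame(start = t_of(p0), end = t_of(p1), peak = t_of(p0),
                    trough = t_of(tin), period = period, amplitude = amp,
                    peak_idx = p0, peak_idx2 = p1, trough_idx = tin,
                    monotonicity = NA_real_,
                    period_consistency = NA_real_,
                    amplitude_consistency = NA_real_)
  class(cyc) <- c("cycle_table", "data.frame")
  cyc
}

#' Fill per-cycle rhythmicity properties
#'
#' Monotonicity is the fraction of sample-to-sample differences with the
#' expected sign over the descending (peak to trough) and ascending
#' (trough to next peak) flanks of the broadband signal. Period and
#' amplitude consistency are the worst shorter/longer ratio of the
#' cycle's value against each neighbour (boundary cycles have one
#' neighbour). All properties lie in \[0, 1\].
#'
#' @param cycles A `cycle_table` from [build_cycles()].
#' @param x The broadband signal the cycles were built on.
#' @return The `cycle_table` with properties filled.
#' @export
cycle_properties <- function(cycles, x) {
  m <- nrow(cycles)
  if (m == 0) return(cycles)
  # prefix sums of correctly signed differences make per-flank counts O(1)
  dx <- diff(x)
  cs_dn <- c(0, cumsum(dx <= 0))
  cs_up <- c(0, cumsum(dx >= 0))
  p0 <- cycles$peak_idx; tt <- cycles$trough_idx; p1 <- cycles$peak_idx2
  good <- (cs_dn[tt] - cs_dn[p0]) + (cs_up[p1] - cs_up[tt])
  cycles$monotonicity <- good / (p1 - p0)
  ratio <- function(a, b) pmin(a, b) / pmax(a, b)
  nb_min <- function(v) {
    if (m == 1) return(1)
    rp <- ratio(v[-1], v[-m])          # ratio of cycle i to cycle i+1
    pmin(c(Inf, rp), c(rp, Inf))
  }
  cycles$period_consistency <- nb_min(cycles$period)
  cycles$amplitude_consistency <- nb_min(pmax(cycles$amplitude, 1e-12))
  cycles
}

# one burst record; cycles kept as a nested data.frame
burst_row <- function(channel, start, end, cycles, mean_period,
                      mean_amplitude, source_band = NA_character_) {
  freq <- 1 / mean_period
  list(channel = channel, start = start, end = end,
       n_cycles = nrow(cycles), mean_period = mean_period,
       frequency = freq, band = classify_band(mean_period),
       mean_amplitude = mean_amplitude, source_band = source_band,
       cycles = cycles)
}

as_burst_table <- function(rows) {
  if (length(rows) == 0) {
    df <- data.frame(channel = character(), start = numeric(),
                     end = numeric(), n_cycles = integer(),
                     mean_period = numeric(), frequency = numeric(),
                     band = character(), mean_amplitude = numeric(),
                     source_band = character())
    df$cycles <- list()
  } else {
    df <- data.frame(
      channel = vapply(rows, `[[`, "", "channel"),
      start = vapply(rows, `[[`, 0, "start"),
      end = vapply(rows, `[[`, 0, "end"),
      n_cycles = vapply(rows, function(r) as.integer(r$n_cycles), 0L),
      mean_period = vapply(rows, `[[`, 0, "mean_period"),
      frequency = vapply(rows, `[[`, 0, "frequency"),
      band = vapply(rows, `[[`, "", "band"),
      mean_amplitude = vapply(rows, `[[`, 0, "mean_amplitude"),
      source_band = vapply(rows, `[[`, "", "source_band"),
      stringsAsFactors = FALSE)
    df$cycles <- lapply(rows, `[[`, "cycles")
  }
  class(df) <- c("burst_table", "data.frame")
  df
}

#' @export
print.burst_table <- function(x, ...) {
  cat(sprintf("<burst_table> %d bursts", nrow(x)))
  if (nrow(x)) {
    tb <- table(x$band)
    cat(" (", paste(names(tb), tb, sep = ": ", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Sort a burst into a frequency band by mean period
#'
#' Frequency f = 1 / mean period; theta for f in \[4, 8) Hz, alpha for
#' f in \[8, 14) Hz, otherwise "other" (half-open band convention, so
#' exactly 8 Hz is alpha).
#'
#' @param mean_period Mean negative-peak-to-peak period in seconds.
#' @param bands Named list of \[low, high) ranges in Hz.
#' @return Band name ("theta", "alpha", or "other").
#' @export
classify_band <- function(mean_period,
                          bands = list(theta = c(4, 8),
                                       alpha = c(8, 14))) {
  f <- 1 / mean_period
  for (b in names(bands)) {
    if (f >= bands[[b]][1] && f < bands[[b]][2]) return(b)
  }
  "other"
}

#' Detect bursts as runs of qualifying cycles
#'
#' Maximal runs of consecutive cycles in which every cycle meets all
#' thresholds, of length at least `min_cycles`, become bursts. Burst mean
#' period is the mean negative-peak-to-peak cycle period (this sets the
#' band label), mean amplitude the mean cycle amplitude.
#'
#' @param cycles A `cycle_table` with properties filled.
#' @param criteria A [burst_criteria()].
#' @param channel Channel label to stamp on the bursts.
#' @param source_band Filter-band name that produced the crossings.
#' @return A `burst_table` (possibly empty).
#' @export
detect_bursts <- function(cycles, criteria = burst_criteria(),
                          channel = "ch1", source_band = NA_character_) {
  if (nrow(cycles) == 0) return(as_burst_table(list()))
  ok <- cycles$monotonicity >= criteria$monotonicity &
    cycles$period_consistency >= criteria$period_consistency &
    cycles$amplitude_consistency >= criteria$amplitude_consistency
  if (criteria$amp_fraction > 0) {
    thr <- stats::quantile(cycles$amplitude, criteria$amp_fraction,
                           names = FALSE)
    ok <- ok & cycles$amplitude > thr
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (k in which(r$values & r$lengths >= criteria$min_cycles)) {
    sub <- cycles[starts[k]:ends[k], , drop = FALSE]
    rows[[length(rows) + 1]] <- burst_row(
      channel = channel, start = sub$start[1],
      end = sub$end[nrow(sub)], cycles = sub,
      mean_period = mean(sub$period),
      mean_amplitude = mean(sub$amplitude),
      source_band = source_band)
  }
  as_burst_table(rows)
}

#' Merge duplicate detections across filter bands
#'
#' The overlapping filter bands necessarily detect the same event several
#' times. Per channel, bursts whose half-open time spans overlap are
#' merged into one; the representative cycles, period and amplitude come
#' from the constituent with the most cycles (earliest on ties), the span
#' is the union, and the band label is re-derived from the
#' representative's mean period.
#'
#' @param bursts A `burst_table` pooled across bands.
#' @return A merged `burst_table` sorted by channel and start.
#' @export
merge_bursts <- function(bursts) {
  if (nrow(bursts) == 0) return(bursts)
  rows <- list()
  for (ch in unique(bursts$channel)) {
    bx <- bursts[bursts$channel == ch, , drop = FALSE]
    bx <- bx[order(bx$start), , drop = FALSE]
    grp_start <- bx$start[1]; grp_end <- bx$end[1]; members <- 1L
    flush <- function(members, grp_start, grp_end) {
      best <- members[which.max(bx$n_cycles[members])]
      rep_ <- bx[best, ]
      burst_row(channel = ch, start = grp_start, end = grp_end,
                cycles = rep_$cycles[[1]],
                mean_period = rep_$mean_period,
                mean_amplitude = rep_$mean_amplitude,
                source_band = rep_$source_band)
    }
    for (i in seq_len(nrow(bx))[-1]) {
      if (bx$start[i] < grp_end) {
        grp_end <- max(grp_end, bx$end[i])
        members <- c(members, i)
      } else {
        rows[[length(rows) + 1]] <- flush(members, grp_start, grp_end)
        grp_start <- bx$start[i]; grp_end <- bx$end[i]; members <- i
      }
    }
    rows[[length(rows) + 1]] <- flush(members, grp_start, grp_end)
  }
  out <- as_burst_table(rows)
  out[order(out$channel, out$start), , drop = FALSE]
}

#' Boolean burst occupancy matrix
#'
#' Channels x samples matrix, TRUE exactly inside the half-open spans of
#' the requested band's bursts on their channel.
#'
#' @param bursts A `burst_table`.
#' @param rec The parent [recording()] (provides dimensions and times).
#' @param band Band name, or NULL for all bands.
#' @return Logical matrix, same shape as `rec$data`.
#' @export
burst_occupancy <- function(bursts, rec, band = NULL) {
  occ <- matrix(FALSE, nrow(rec$data), ncol(rec$data),
                dimnames = list(rec$channels, NULL))
  bx <- bursts
  if (!is.null(band)) bx <- bx[bx$band %in% band, , drop = FALSE]
  for (i in seq_len(nrow(bx))) {
    idx <- span_to_samples(bx$start[i], bx$end[i], rec$rate, rec$t0,
                           ncol(occ))
    if (idx[2] >= idx[1]) occ[bx$channel[i], idx[1]:idx[2]] <- TRUE
  }
  occ
}

#' Run the full burst detector on a recording
#'
#' Applies the filter bank, finds zero-crossings per band, measures cycles
#' and their properties on the broadband signal, detects qualifying runs,
#' and merges duplicate detections across bands per channel.
#'
#' @param rec A preprocessed [recording()] (0.5-40 Hz broadband).
#' @param criteria A [burst_criteria()].
#' @param bank Optional precomputed [filter_bank()] output.
#' @return A merged `burst_table`.
#' @export
detect_recording <- function(rec, criteria = burst_criteria(),
                             bank = NULL) {
  if (is.null(bank)) bank <- filter_bank(rec)
  rows <- list()
  for (ch in seq_along(rec$channels)) {
    broad <- rec$data[ch, ]
    per_ch <- list()
    for (bname in names(bank)) {
      nb <- bank[[bname]][ch, ]
      cr <- zero_crossings(nb, rec$rate, rec$t0)
      cyc <- build_cycles(broad, cr, rec$rate, rec$t0)
      cyc <- cycle_properties(cyc, broad)
      bt <- detect_bursts(cyc, criteria, channel = rec$channels[ch],
                          source_band = bname)
      if (nrow(bt)) per_ch[[length(per_ch) + 1]] <- bt
    }
    if (length(per_ch)) {
      pooled <- do.call(rbind, per_ch)
      class(pooled) <- c("burst_table", "data.frame")
      rows[[length(rows) + 1]] <- merge_bursts(pooled)
    }
  }
  if (!length(rows)) return(as_burst_table(list()))
  out <- do.call(rbind, rows)
  class(out) <- c("burst_table", "data.frame")
  out
}
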