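# Event-locked analysis: epoching of occupancy (or closure) around
# stimulus onsets with the exclusion/interpolation rules, outcome-resolved
# z-scored time courses, window topographies, and behavioural tabulations.

#' Epoch an occupancy matrix around stimulus onsets
#'
#' Cuts trials x channels x time tensors over a half-open window around
#' each stimulus onset. Masked samples become missing (NA); trials with
#' more than 50% missing data are dropped, as are false-alarm trials and
#' (for burst analyses) trials with eyes closed during the stimulus.
#'
#' @param occ Logical channels x samples matrix ([burst_occupancy()] or a
#'   1-row closure matrix).
#' @param trials A [trial_table()].
#' @param rate Sampling rate of `occ` in Hz.
#' @param window Epoch window in seconds relative to onset, default
#'   `c(-2, 4)`.
#' @param mask Optional logical channels x samples exclusion matrix (from
#'   [combine_masks()]).
#' @param exclude_ec Drop `ec_stimulus` trials (default TRUE).
#' @param max_missing Maximal tolerated missing fraction per trial.
#' @param t0 Time of the first sample.
#' @return List of class `occupancy_epochs`: `tensor` (trials x channels
#'   x time, logical with NA = missing), `outcome` (factor per kept
#'   trial), `time` (seconds relative to onset), `trial_index` (row of
#'   `trials` each epoch came from), `rate`.
#' @export
epoch_tensor <- function(occ, trials, rate, window = c(-2, 4),
                         mask = NULL, exclude_ec = TRUE,
                         max_missing = 0.5, t0 = 0) {
  if (is.vector(occ)) occ <- matrix(occ, nrow = 1)
  nc <- nrow(occ); ns <- ncol(occ)
  nt_win <- round((window[2] - window[1]) * rate)
  rel <- window[1] + (seq_len(nt_win) - 1) / rate
  keep <- trials$outcome != "falsealarm"
  if (exclude_ec) keep <- keep & !trials$ec_stimulus
  idx_trials <- which(keep)
  tens <- array(NA, dim = c(length(idx_trials), nc, nt_win))
  ok_trial <- rep(TRUE, length(idx_trials))
  for (k in seq_along(idx_trials)) {
    on <- trials$onset[idx_trials[k]]
    i0 <- round((on + window[1] - t0) * rate) + 1
    smp <- i0 + seq_len(nt_win) - 1
    valid <- smp >= 1 & smp <= ns
    ep <- matrix(NA, nc, nt_win)
    ep[, valid] <- occ[, smp[valid], drop = FALSE]
    if (!is.null(mask)) {
      mk <- matrix(FALSE, nc, nt_win)
      mk[, valid] <- mask[, smp[valid], drop = FALSE]
      ep[mk] <- NA
    }
    if (mean(is.na(ep)) > max_missing) ok_trial[k] <- FALSE
    tens[k, , ] <- ep
  }
  idx_trials <- idx_trials[ok_trial]
  tens <- tens[ok_trial, , , drop = FALSE]
  structure(list(tensor = tens,
                 outcome = droplevels(trials$outcome[idx_trials],
                                      exclude = NULL),
                 time = rel, trial_index = idx_trials, rate = rate),
            class = "occupancy_epochs")
}

#' @export
print.occupancy_epochs <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<occupancy_epochs> %d trials x %d channels x %d samples [%g, %g] s\n",
              d[1], d[2], d[3], min(x$time), max(x$time) + 1 / x$rate))
  invisible(x)
}

#' Session-block occupancy statistics
#'
#' Mean and standard deviation of the channel-proportion series (fraction
#' of non-missing channels with a burst at each sample) over every
#' unmasked sample of the session block. Used as the z-scoring reference
#' for event-locked time courses. Also returns the per-channel average
#' occupancy (fraction of unmasked time points with a burst per channel),
#' the topography reference.
#'
#' @param occ_list List of occupancy matrices, one per recording of the
#'   block (a single matrix is accepted).
#' @param mask_list Matching list of exclusion matrices, or NULL.
#' @return List with `mean`, `sd` (channel-proportion series) and
#'   `channel_avg` (named per-channel occupancy).
#' @export
session_occupancy_stats <- function(occ_list, mask_list = NULL) {
  if (is.matrix(occ_list)) occ_list <- list(occ_list)
  if (is.matrix(mask_list)) mask_list <- list(mask_list)
  props <- c()
  ch_hit <- 0; ch_n <- 0
  for (i in seq_along(occ_list)) {
    occ <- occ_list[[i]]
    o <- occ * 1
    if (!is.null(mask_list)) o[mask_list[[i]]] <- NA
    navail <- colSums(!is.na(o))
    p <- colSums(o, na.rm = TRUE) / navail
    props <- c(props, p[navail > 0])
    ch_hit <- ch_hit + rowSums(o == 1, na.rm = TRUE)
    ch_n <- ch_n + rowSums(!is.na(o))
  }
  list(mean = mean(props), sd = stats::sd(props),
       channel_avg = ch_hit / pmax(ch_n, 1))
}

#' Per-participant event-locked occupancy time course
#'
#' For each trial outcome: at every time point, the proportion of
#' non-missing channels with a burst is computed per trial, averaged over
#' trials with clean data, and z-scored to the session-block mean and
#' standard deviation. Time points with fewer than `min_trials` clean
#' trials are linearly interpolated from their neighbours; an outcome is
#' excluded for the participant when such gaps exceed `max_gap` of the
#' window or when it has fewer than `min_trials` trials in total.
#'
#' @param epochs An [epoch_tensor()] result.
#' @param session_stats A [session_occupancy_stats()] result.
#' @param min_trials Minimum clean trials per time point (and per
#'   outcome), default 15.
#' @param max_gap Maximal tolerated interpolated fraction, default 0.2.
#' @param outcomes Outcome labels to compute (default fast/slow/lapse).
#' @return List of class `participant_timecourse`: `z` (outcome x time
#'   matrix, NA rows for excluded outcomes), `n_trials` (per outcome),
#'   `time`.
#' @export
participant_timecourse <- function(epochs, session_stats,
                                   min_trials = 15, max_gap = 0.2,
                                   outcomes = c("fast", "slow", "lapse")) {
  nt <- length(epochs$time)
  z <- matrix(NA_real_, length(outcomes), nt,
              dimnames = list(outcomes, NULL))
  n_trials <- stats::setNames(integer(length(outcomes)), outcomes)
  for (oi in seq_along(outcomes)) {
    sel <- which(epochs$outcome == outcomes[oi])
    n_trials[oi] <- length(sel)
    if (length(sel) < min_trials) next
    sub <- aperm(epochs$tensor[sel, , , drop = FALSE], c(2, 1, 3)) * 1
    nch_ok <- colSums(!is.na(sub), dims = 1)       # trials x time
    hits <- sub; hits[is.na(hits)] <- 0
    prop <- colSums(hits, dims = 1) / nch_ok
    prop[nch_ok == 0] <- NA
    clean <- colSums(!is.na(prop))
    series <- colMeans(prop, na.rm = TRUE)
    series[clean < min_trials] <- NA
    gap <- mean(clean < min_trials)
    if (gap > max_gap) next
    if (anyNA(series)) {
      good <- which(!is.na(series))
      if (length(good) >= 2) {
        series <- stats::approx(good, series[good], xout = seq_len(nt),
                                rule = 2)$y
      }
    }
    z[oi, ] <- (series - session_stats$mean) / session_stats$sd
  }
  structure(list(z = z, n_trials = n_trials, time = epochs$time),
            class = "participant_timecourse")
}

#' Lowess-smooth an event-locked series
#'
#' @param series Numeric vector sampled at `rate`.
#' @param rate Sampling rate in Hz.
#' @param span Smoothing window in seconds (default 0.2).
#' @return Smoothed series.
#' @export
smooth_timecourse <- function(series, rate, span = 0.2) {
  lowess_smooth(series, rate, span)
}

#' Group statistics on participant time courses
#'
#' Per outcome and time point, a two-sided one-sample t-test of the
#' participants' z values against zero, with Benjamini-Hochberg FDR
#' applied across all time points and outcomes of the call (one family
#' per figure) and Hedge's g per point.
#'
#' @param tc_list List of [participant_timecourse()] results.
#' @param q FDR level, default 0.05.
#' @param min_n Minimal participants per outcome (default 3).
#' @return List of class `timecourse_result` with outcome x time matrices
#'   `mean_z`, `t`, `p`, `p_fdr`, `significant`, `g`, `n`, plus `time`.
#' @export
group_timecourse_stats <- function(tc_list, q = 0.05, min_n = 3) {
  outcomes <- rownames(tc_list[[1]]$z)
  nt <- ncol(tc_list[[1]]$z)
  arr <- array(NA_real_, c(length(tc_list), length(outcomes), nt))
  for (p in seq_along(tc_list)) arr[p, , ] <- tc_list[[p]]$z
  st <- group_onesample_map(arr)
  low_n <- st$n < min_n
  st$t[low_n] <- NA; st$p[low_n] <- NA; st$g[low_n] <- NA
  fdr <- fdr_bh(as.vector(st$p), q)
  res <- list(mean_z = st$mean, t = st$t, p = st$p,
              p_fdr = array(fdr$p_fdr, dim(st$p)),
              significant = array(fdr$significant, dim(st$p)),
              g = st$g, n = st$n, time = tc_list[[1]]$time)
  for (nm in c("mean_z", "t", "p", "p_fdr", "significant", "g", "n")) {
    rownames(res[[nm]]) <- outcomes
  }
  class(res) <- "timecourse_result"
  res
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat("<timecourse_result>\n")
  for (o in rownames(x$t)) {
    cat(sprintf("  %-6s n = %d, %d/%d time points FDR-significant\n", o,
                max(x$n[o, ]), sum(x$significant[o, ], na.rm = TRUE),
                ncol(x$t)))
  }
  invisible(x)
}

#' Default topography windows
#'
#' The four analysis windows around stimulus onset (seconds, half-open):
#' Pre \[-2, 0), Stimulus \[0, 0.3), Response \[0.3, 1), Post \[2, 4).
#' @return Named list of `c(start, end)` pairs.
#' @export
topography_windows <- function() {
  list(Pre = c(-2, 0), Stimulus = c(0, 0.3),
       Response = c(0.3, 1), Post = c(2, 4))
}

#' Per-participant window topography
#'
#' For every outcome, window and channel: the proportion of trials with a
#' burst at each time point of the window, averaged over the window
#' (equivalently the mean occupancy over the window's trial x time cells,
#' missing cells excluded), minus the session-block average occupancy of
#' that channel. Outcomes with fewer than `min_trials` trials yield NA.
#'
#' @param epochs An [epoch_tensor()] result.
#' @param session_stats A [session_occupancy_stats()] result (supplies
#'   `channel_avg`).
#' @param windows Named list of windows, default [topography_windows()].
#' @param min_trials Minimum trials per outcome, default 15.
#' @param outcomes Outcome labels, default fast/slow/lapse.
#' @return Array outcome x window x channel of differences.
#' @export
participant_topography <- function(epochs, session_stats,
                                   windows = topography_windows(),
                                   min_trials = 15,
                                   outcomes = c("fast", "slow", "lapse")) {
  nc <- dim(epochs$tensor)[2]
  out <- array(NA_real_, c(length(outcomes), length(windows), nc),
               dimnames = list(outcomes, names(windows), NULL))
  for (oi in seq_along(outcomes)) {
    sel <- which(epochs$outcome == outcomes[oi])
    if (length(sel) < min_trials) next
    for (wi in seq_along(windows)) {
      w <- windows[[wi]]
      tsel <- epochs$time >= w[1] & epochs$time < w[2]
      sub <- epochs$tensor[sel, , tsel, drop = FALSE] * 1
      out[oi, wi, ] <- apply(sub, 2, mean, na.rm = TRUE) -
        session_stats$channel_avg
    }
  }
  out
}

#' Group window-topography statistics
#'
#' One-sample t-tests across participants per channel, FDR-corrected
#' within each (window x outcome) topography separately.
#'
#' @param topo_list List of [participant_topography()] arrays.
#' @param q FDR level, default 0.05.
#' @param min_n Minimal participants, default 3.
#' @return List of class `topography_result` with outcome x window x
#'   channel arrays `t`, `p`, `p_fdr`, `significant`, `g`, `n`.
#' @export
group_topography_stats <- function(topo_list, q = 0.05, min_n = 3) {
  dm <- dim(topo_list[[1]])
  arr <- array(NA_real_, c(length(topo_list), dm))
  for (p in seq_along(topo_list)) arr[p, , , ] <- topo_list[[p]]
  st <- group_onesample_map(arr)
  low_n <- st$n < min_n
  st$t[low_n] <- NA; st$p[low_n] <- NA
  p_fdr <- sig <- array(NA, dm)
  for (oi in seq_len(dm[1])) {
    for (wi in seq_len(dm[2])) {
      f <- fdr_bh(st$p[oi, wi, ], q)
      p_fdr[oi, wi, ] <- f$p_fdr
      sig[oi, wi, ] <- f$significant
    }
  }
  dn <- dimnames(topo_list[[1]])
  res <- list(t = st$t, p = st$p, p_fdr = p_fdr, significant = sig,
              g = st$g, n = st$n)
  for (nm in names(res)) dimnames(res[[nm]]) <- dn
  class(res) <- "topography_result"
  res
}

#' Fraction of lapses with eyes closed, by RT threshold
#'
#' For each threshold, lapses are redefined as trials with reaction time
#' above the threshold (or no response); the curve gives the fraction of
#' those lapses that carry the eye-closure flag.
#'
#' @param trials A [trial_table()].
#' @param thresholds Ascending numeric RT thresholds in seconds.
#' @return data.frame with `threshold`, `n_lapses`, `ec_fraction`.
#' @export
ec_lapse_fraction_by_threshold <- function(trials,
                                           thresholds = seq(0.5, 2, 0.25)) {
  stopifnot(!is.unsorted(thresholds))
  res <- lapply(thresholds, function(th) {
    lapse <- is.na(trials$rt) | trials$rt > th
    data.frame(threshold = th, n_lapses = sum(lapse),
               ec_fraction = if (any(lapse)) {
                 mean(trials$ec_stimulus[lapse])
               } else NA_real_)
  })
  do.call(rbind, res)
}

#' Lapse percentage by stimulus-distance quantile
#'
#' Trials are split into `k` equal-count bins by radial distance from
#' fixation (bin 1 closest); the output is the percentage of each bin's
#' trials that are lapses. Ties in distance are broken by stable trial
#' order.
#'
#' @param trials A [trial_table()].
#' @param k Number of quantile bins, default 6.
#' @param eo_only Consider eyes-open trials only (default TRUE).
#' @return data.frame with `quantile`, `n`, `mean_distance`,
#'   `lapse_percent`.
#' @export
lapse_by_distance_quantiles <- function(trials, k = 6, eo_only = TRUE) {
  tt <- trials[trials$outcome != "falsealarm", , drop = FALSE]
  if (eo_only) tt <- tt[!tt$ec_stimulus, , drop = FALSE]
  if (nrow(tt) < k) stop("need at least k trials with distance")
  ord <- order(tt$distance)
  bin <- equal_count_bins(nrow(tt), k)
  lapse <- tt$outcome[ord] == "lapse"
  data.frame(quantile = seq_len(k),
             n = as.vector(table(bin)),
             mean_distance = as.vector(tapply(tt$distance[ord], bin, mean)),
             lapse_percent = as.vector(tapply(lapse, bin, mean)) * 100)
}

# assign n ordered items to k bins with sizes differing by at most 1
equal_count_bins <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  rep(seq_len(k), sizes)
}
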