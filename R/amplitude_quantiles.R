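# Pre-stimulus burst-amplitude quantile analysis: does the amplitude of
# oscillatory bursts in the second before a stimulus predict a lapse?

#' Pre-stimulus burst-amplitude records
#'
#' For every trial (excluding false alarms and, by default, eye-closure
#' trials) and every burst whose span intersects the pre-stimulus window,
#' one record is emitted with the burst's amplitude averaged over the
#' cycles whose peak lies inside the window. A trial with several
#' pre-stimulus bursts contributes one record per burst, each carrying
#' the trial's outcome.
#'
#' @param bursts A `burst_table` (detected or ground truth).
#' @param trials A [trial_table()].
#' @param window Window relative to onset in seconds, default `c(-1, 0)`.
#' @param exclude_ec Drop `ec_stimulus` trials (default TRUE).
#' @param band Restrict to one band ("theta"/"alpha"), or NULL for all.
#' @return data.frame with `trial`, `onset`, `outcome`, `channel`,
#'   `band`, `amplitude`, `n_cycles_in_window`.
#' @export
prestim_burst_amplitudes <- function(bursts, trials, window = c(-1, 0),
                                     exclude_ec = TRUE, band = NULL) {
  keep <- trials$outcome != "falsealarm"
  if (exclude_ec) keep <- keep & !trials$ec_stimulus
  bx <- bursts
  if (!is.null(band)) bx <- bx[bx$band %in% band, , drop = FALSE]
  recs <- list()
  for (ti in which(keep)) {
    lo <- trials$onset[ti] + window[1]
    hi <- trials$onset[ti] + window[2]
    hit <- which(bx$start < hi & bx$end > lo)
    for (bi in hit) {
      cyc <- bx$cycles[[bi]]
      inwin <- cyc$peak >= lo & cyc$peak < hi
      if (!any(inwin)) next
      recs[[length(recs) + 1]] <- data.frame(
        trial = ti, onset = trials$onset[ti],
        outcome = as.character(trials$outcome[ti]),
        channel = bx$channel[bi], band = bx$band[bi],
        amplitude = mean(cyc$amplitude[inwin]),
        n_cycles_in_window = sum(inwin),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(trial = integer(), onset = numeric(),
                      outcome = character(), channel = character(),
                      band = character(), amplitude = numeric(),
                      n_cycles_in_window = integer()))
  }
  do.call(rbind, recs)
}

#' Amplitude-quantile lapse curve for one participant
#'
#' Records are sorted into `k` equal-count amplitude quantiles (computed
#' within the session block; ties broken by stable order). Per quantile
#' the fraction of records whose trial resulted in a lapse is computed,
#' then the `k` values are z-scored within the participant.
#'
#' @param records Output of [prestim_burst_amplitudes()] for one
#'   participant, band and session block.
#' @param k Number of quantiles, default 10.
#' @return List of class `quantile_curve` with `mean_amplitude`,
#'   `lapse_proportion`, `z` (each length `k`), `n` (bin counts), or NULL
#'   when fewer than `k` records are available (participant excluded).
#' @export
quantile_lapse_curve <- function(records, k = 10) {
  if (nrow(records) < k) return(NULL)
  ord <- order(records$amplitude)
  bin <- equal_count_bins(nrow(records), k)
  amp <- records$amplitude[ord]
  lapse <- records$outcome[ord] == "lapse"
  prop <- as.vector(tapply(lapse, bin, mean))
  zs <- if (stats::sd(prop) > 0) {
    (prop - mean(prop)) / stats::sd(prop)
  } else {
    rep(0, k)
  }
  structure(list(mean_amplitude = as.vector(tapply(amp, bin, mean)),
                 lapse_proportion = prop, z = zs,
                 n = as.vector(table(bin))),
            class = "quantile_curve")
}

#' Pairwise quantile tests across participants
#'
#' Paired t-tests between all quantile pairs of the participants'
#' z-scored lapse curves, Benjamini-Hochberg corrected over the
#' k(k-1)/2 pairs of the panel, with Hedge's g.
#'
#' @param curves List of [quantile_lapse_curve()] results (NULL entries,
#'   excluded participants, are dropped).
#' @param q FDR level, default 0.05.
#' @return data.frame of class `quantile_tests` with `q1`, `q2`, `t`,
#'   `p`, `p_fdr`, `significant`, `g`, `n`.
#' @export
quantile_pair_tests <- function(curves, q = 0.05) {
  curves <- curves[!vapply(curves, is.null, NA)]
  if (length(curves) < 3) stop("need at least 3 participants")
  zmat <- do.call(rbind, lapply(curves, `[[`, "z"))
  k <- ncol(zmat)
  pairs <- utils::combn(k, 2)
  res <- data.frame(q1 = pairs[1, ], q2 = pairs[2, ])
  stats_ <- lapply(seq_len(ncol(pairs)), function(i) {
    paired_t(zmat[, pairs[2, i]], zmat[, pairs[1, i]])
  })
  res$t <- vapply(stats_, `[[`, 0, "t")
  res$p <- vapply(stats_, `[[`, 0, "p")
  res$g <- vapply(stats_, `[[`, 0, "g")
  res$n <- vapply(stats_, `[[`, 0L, "n")
  f <- fdr_bh(res$p, q)
  res$p_fdr <- f$p_fdr
  res$significant <- f$significant
  class(res) <- c("quantile_tests", "data.frame")
  res
}
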