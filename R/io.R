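# Readers and writers: EDF for raw signals, TSV for trial tables, CSV for
# pupil-confidence traces, RDS + JSON sidecar for derived containers.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' European Data Format: a fixed 256-byte header, one 256-byte header block
#' per signal, and 16-bit little-endian samples scaled between the physical
#' and digital ranges. The whole recording is stored as a single data
#' record, so amplitudes round-trip within one 16-bit quantisation step of
#' the per-channel range. Header date/time fields are fixed so identical
#' recordings produce byte-identical files.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$channels)
  nsamp <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("burstlapse", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(1, 8), num_field(nsamp / rec$rate, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    r <- max(abs(rec$data[i, ]), 1e-6)
    pmin_[i] <- -r; pmax_[i] <- r
  }
  field <- function(f, w) paste(vapply(seq_len(ns), f, ""), collapse = "")
  writeChar(paste0(
    field(function(i) pad_field(rec$channels[i], 16), 16),
    field(function(i) pad_field("", 80), 80),
    field(function(i) pad_field("uV", 8), 8),
    field(function(i) num_field(pmin_[i], 8), 8),
    field(function(i) num_field(pmax_[i], 8), 8),
    field(function(i) pad_field(-32768, 8), 8),
    field(function(i) pad_field(32767, 8), 8),
    field(function(i) pad_field("", 80), 80),
    field(function(i) pad_field(nsamp, 8), 8),
    field(function(i) pad_field("", 32), 32)), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   65535 - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF/EDF+ files with a common sampling rate across
#' signals. Samples are rescaled to physical units (microvolts) using the
#' per-signal physical/digital ranges from the header.
#'
#' @param path EDF file path.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) < 256) stop("malformed EDF: file shorter than header")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur)) {
    stop("malformed EDF: bad header counts")
  }
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin_ <- as.numeric(rdn(8)); dmax_ <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr / dur)) != 1) {
    stop("EDF signals with mixed sampling rates are not supported")
  }
  rate <- spr[1] / dur
  seek(con, hdr_bytes)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2,
                     signed = TRUE, endian = "little")
      if (length(dig) < spr[i]) stop("malformed EDF: truncated data record")
      phys <- pmin_[i] + (dig - dmin_[i]) *
        (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  recording(data, rate = rate, channels = labels)
}

#' Write a trial table to TSV
#'
#' @param trials A [trial_table()].
#' @param path Output path. Columns: onset, rt (empty for no response),
#'   hemifield, distance, ec_stimulus, outcome.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(trials)
  df$outcome <- as.character(df$outcome)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from TSV
#'
#' Expects a header row with at least `onset` and `rt`; optional columns
#' `hemifield`, `distance`, `ec_stimulus`, `outcome`. Outcomes are
#' recomputed from the reaction times and validated against any stored
#' labels; non-monotone onsets are an error.
#'
#' @param path TSV path.
#' @return A [trial_table()].
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  req <- c("onset", "rt")
  if (!all(req %in% names(df))) {
    stop("trial TSV must contain columns: ", paste(req, collapse = ", "))
  }
  tt <- trial_table(
    onset = df$onset, rt = df$rt,
    hemifield = if ("hemifield" %in% names(df)) df$hemifield else "left",
    distance = if ("distance" %in% names(df)) df$distance else 0.5,
    ec_stimulus = if ("ec_stimulus" %in% names(df)) df$ec_stimulus else FALSE)
  if ("outcome" %in% names(df) &&
      !all(as.character(tt$outcome) == as.character(df$outcome))) {
    stop("stored outcome labels disagree with reaction times")
  }
  tt
}

#' Write a pupil-confidence trace to CSV
#' @param trace List with numeric `time` (s) and `confidence` (\[0, 1\]).
#' @param path Output path; columns timestamp, confidence.
#' @return `path`, invisibly.
#' @export
write_pupil <- function(trace, path) {
  utils::write.csv(data.frame(timestamp = trace$time,
                              confidence = trace$confidence),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pupil-confidence trace from CSV
#'
#' @param path CSV with columns `timestamp` (s) and `confidence`;
#'   confidence values are clipped to \[0, 1\].
#' @return List with `time` and `confidence`.
#' @export
read_pupil <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "confidence") %in% names(df))) {
    stop("pupil CSV must contain columns timestamp, confidence")
  }
  list(time = as.numeric(df$timestamp),
       confidence = pmin(pmax(as.numeric(df$confidence), 0), 1))
}

#' Align a pupil trace to a recording's sample grid
#'
#' Nearest-sample alignment: each EEG sample takes the confidence value of
#' the nearest pupil timestamp. Irregular timestamps are allowed; the
#' output always has exactly one value per EEG sample.
#'
#' @param trace List with `time`, `confidence` (as from [read_pupil()]).
#' @param rec Target [recording()].
#' @return Numeric vector, length = number of samples of `rec`.
#' @export
resample_pupil <- function(trace, rec) {
  tt <- rec_times(rec)
  if (max(trace$time) < tt[1] || min(trace$time) > tt[length(tt)]) {
    stop("pupil trace does not overlap the recording")
  }
  ord <- order(trace$time)
  ts <- trace$time[ord]; cs <- trace$confidence[ord]
  # nearest-neighbour: pick whichever of the flanking timestamps is closer
  idx <- findInterval(tt, ts)
  idx_lo <- pmax(idx, 1L)
  idx_hi <- pmin(idx + 1L, length(ts))
  use_hi <- (ts[idx_hi] - tt) < (tt - ts[idx_lo])
  out <- cs[ifelse(use_hi, idx_hi, idx_lo)]
  out[idx == 0] <- cs[1]
  out
}

#' Save a derived-results container
#'
#' Derived objects (epoch tensors, occupancy matrices, statistics) are
#' stored as a single uncompressed RDS file of nested named arrays plus a
#' human-readable JSON sidecar describing the contents. Writes are
#' deterministic: the same object always produces byte-identical files.
#'
#' @param x Object to store.
#' @param path Output path (conventionally `.rds`); the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param meta Optional named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
save_container <- function(x, path, meta = list()) {
  saveRDS(x, path, compress = FALSE, version = 3)
  describe <- function(el) {
    if (is.list(el) && !is.data.frame(el)) {
      lapply(el, describe)
    } else {
      list(class = class(el)[1],
           dim = if (!is.null(dim(el))) dim(el) else length(el))
    }
  }
  sidecar <- c(list(format = "burstlapse-container", version = 1L,
                    contents = describe(x)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a derived-results container
#' @param path Path given to [save_container()].
#' @return The stored object.
#' @export
load_container <- function(path) readRDS(path)
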