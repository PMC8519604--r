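#' Construct a multi-channel EEG recording
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of 10-20 system labels,
#'   one per channel.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric channels x samples matrix")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stopf("recording contains missing or non-finite values")
  }
  fs <- check_number(fs, "fs", min = 1e-9)
  if (!is.null(channel_names) && length(channel_names) != nrow(data)) {
    stopf("channel_names must have one entry per channel")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read a recording from a delimited numeric matrix file
#'
#' Expects a channels x samples matrix with no header, as written by
#' [write_recording_csv()].
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param sep Field separator (default comma).
#' @inheritParams eeg_recording
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path, fs, channel_names = NULL, sep = ",") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  eeg_recording(m, fs, channel_names)
}

#' @rdname read_recording_csv
#' @param recording An [eeg_recording()].
#' @export
write_recording_csv <- function(recording, path, sep = ",") {
  utils::write.table(recording$data, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Split a recording into fixed-length windows
#'
#' Windows are contiguous when `overlap = 0`; a trailing partial window is
#' dropped.  A window longer than the recording yields an empty list with a
#' warning.
#'
#' @param recording An [eeg_recording()].
#' @param window_s Window length in seconds; `fs * window_s` must be an
#'   integer number of samples.
#' @param overlap Fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @return A list of channels x window-samples matrices.
#' @export
segment <- function(recording, window_s = 0.5, overlap = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  L <- recording$fs * window_s
  if (abs(L - round(L)) > 1e-9 || round(L) < 1) {
    stopf("fs * window_s must be a positive integer (got %g)", L)
  }
  L <- as.integer(round(L))
  overlap <- check_number(overlap, "overlap", min = 0)
  if (overlap >= 1) stopf("`overlap` must be in [0, 1)")
  n <- ncol(recording$data)
  if (n < L) {
    warning("recording shorter than one window; returning no segments")
    return(list())
  }
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  lapply(starts, function(s) recording$data[, s:(s + L - 1L), drop = FALSE])
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a Butterworth band-pass forwards and backwards
#' (`signal::filtfilt`), so the output is zero-phase and the same shape as
#' the input.
#'
#' @param recording An [eeg_recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order of the prototype (default 4).
#' @return A filtered [eeg_recording()].
#' @export
bandpass <- function(recording, lo = 1, hi = 30, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  lo <- check_number(lo, "lo", min = 1e-12)
  hi <- check_number(hi, "hi")
  nyq <- recording$fs / 2
  if (hi >= nyq) stopf("`hi` must be below the Nyquist frequency %g", nyq)
  if (lo >= hi) stopf("`lo` must be below `hi`")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- t(apply(recording$data, 1L,
                 function(ch) signal::filtfilt(bf, ch)))
  eeg_recording(out, recording$fs, recording$channel_names)
}

#' One-sided log power spectral density at integer frequencies
#'
#' Single-window periodogram: each channel is mean-detrended, zero-padded
#' to a whole number of seconds (so the DFT bins fall on exact 1 Hz steps),
#' transformed, and the one-sided PSD is read off at 1..`f_max` Hz.  The
#' PSD is scaled so that its sum over the one-sided bins approximates the
#' signal variance (Parseval), floored at `floor` before taking log10.
#' Frequencies above the Nyquist are filled with the log floor.
#'
#' @param window Numeric channels x samples matrix (one segment).
#' @param fs Sampling rate in Hz.
#' @param f_max Highest integer frequency to report (default 100).
#' @param floor Power floor applied before the logarithm (default 1e-12).
#' @return A channels x `f_max` matrix of log10 power.
#' @export
log_psd <- function(window, fs, f_max = 100, floor = 1e-12) {
  if (is.vector(window)) window <- matrix(window, nrow = 1L)
  if (!is.numeric(window) || anyNA(window) || any(!is.finite(window))) {
    stopf("`window` must be a finite numeric matrix")
  }
  if (ncol(window) < 2L) stopf("window needs at least 2 samples")
  t(psd_columns(t(window), fs, f_max, floor))
}

# Core periodogram on columns: x is samples x m, returns f_max x m log10
# PSD. Shared by log_psd() and the batched feature extractor.
psd_columns <- function(x, fs, f_max, floor = 1e-12) {
  L <- nrow(x)
  m <- ncol(x)
  fs_i <- as.integer(round(fs))
  nfft <- fs_i * max(1L, as.integer(ceiling(L / fs_i)))
  x <- sweep(x, 2L, colMeans(x))       # detrend: remove per-window mean
  if (nfft > L) x <- rbind(x, matrix(0, nfft - L, m))
  X <- stats::mvfft(x)
  nyq_bin <- nfft %/% 2
  kmax <- min(f_max, nyq_bin)
  k <- seq_len(kmax)
  p <- (abs(X[k + 1L, , drop = FALSE])^2) * (2 / (L * nfft))
  if (kmax == nyq_bin && nfft %% 2 == 0) p[kmax, ] <- p[kmax, ] / 2
  out <- matrix(log10(floor), f_max, m)
  out[k, ] <- log10(pmax(p, floor))
  out
}

#' Define a frequency band
#'
#' Bands are inclusive integer ranges: the band 4-7 Hz contains the 4
#' points 4, 5, 6, 7.
#'
#' @param name Band label.
#' @param lo,hi Integer band edges in Hz, `1 <= lo <= hi`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, lo, hi) {
  lo <- check_count(lo, "lo", min = 1L)
  hi <- check_count(hi, "hi", min = lo)
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "band_spec")
}

#' The theta, alpha and beta EEG bands
#'
#' Theta 4-7 Hz, alpha 8-13 Hz and beta 14-30 Hz: the canonical rhythms
#' whose power shifts with mental fatigue.  Together they contribute
#' 4 + 6 + 17 = 27 points per channel.
#'
#' @return A list of three [band_spec()] objects.
#' @export
default_bands <- function() {
  list(band_spec("theta", 4, 7),
       band_spec("alpha", 8, 13),
       band_spec("beta", 14, 30))
}

band_indices <- function(bands, f_max) {
  idx <- unlist(lapply(bands, function(b) {
    if (b$hi > f_max) {
      stopf("band %s (%d-%d Hz) exceeds available frequencies (f_max = %d)",
            b$name, b$lo, b$hi, f_max)
    }
    b$lo:b$hi
  }))
  as.integer(idx)
}

#' Assemble band-power features from a PSD matrix
#'
#' Concatenates the PSD values inside each band, channel-major: all of
#' channel 1's band points (bands in the given order, ascending frequency
#' within a band), then channel 2's, and so on.  With 61 channels and the
#' [default_bands()] this yields a 61 x 27 = 1,647-dimensional vector.
#'
#' @param psd A channels x frequencies matrix as returned by [log_psd()].
#' @param bands List of [band_spec()] objects.
#' @return A numeric feature vector of length
#'   `channels * sum(hi - lo + 1)`.
#' @export
band_features <- function(psd, bands = default_bands()) {
  if (is.vector(psd)) psd <- matrix(psd, nrow = 1L)
  idx <- band_indices(bands, ncol(psd))
  as.vector(t(psd[, idx, drop = FALSE]))
}

#' Extraction settings for the band-power pipeline
#'
#' @param window_s Segment length in seconds (default 0.5).
#' @param overlap Segment overlap fraction (default 0, non-overlapping).
#' @param bands List of [band_spec()]s (default theta/alpha/beta).
#' @param f_max Highest PSD frequency in Hz (default 100).
#' @param bandpass `c(lo, hi)` band-pass applied to raw recordings before
#'   segmentation, or `NULL` to skip (default 1-30 Hz).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_s = 0.5, overlap = 0,
                           bands = default_bands(), f_max = 100,
                           bandpass = c(1, 30)) {
  structure(list(window_s = window_s, overlap = overlap, bands = bands,
                 f_max = check_count(f_max, "f_max"),
                 bandpass = bandpass),
            class = "feature_config")
}

# batched recording -> segments x features matrix (one pass of mvfft)
features_of_recording <- function(recording, config) {
  if (!is.null(config$bandpass)) {
    recording <- bandpass(recording, config$bandpass[1], config$bandpass[2])
  }
  wins <- segment(recording, config$window_s, config$overlap)
  n_ch <- nrow(recording$data)
  idx <- band_indices(config$bands, config$f_max)
  if (length(wins) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = n_ch * length(idx)))
  }
  L <- ncol(wins[[1]])
  # stack every (window, channel) series as a column, channel fastest
  x <- matrix(unlist(lapply(wins, t), use.names = FALSE), nrow = L)
  psd <- psd_columns(x, recording$fs, config$f_max)  # f_max x (n_ch*n_win)
  sel <- psd[idx, , drop = FALSE]                    # points x (n_ch*n_win)
  n_win <- length(wins)
  dim(sel) <- c(length(idx) * n_ch, n_win)
  t(sel)  # channel-major within each row
}

#' Construct a feature matrix object
#'
#' @param features Segments x D numeric matrix of log band power.
#' @param labels Optional per-segment class labels, 0 = awake, 1 = fatigue
#'   (or `NULL` for an unlabeled target subject).
#' @param subject_id Subject identifier.
#' @param layout Optional descriptor of the channel-major band ordering.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels = NULL, subject_id = NA_character_,
                           layout = NULL) {
  if (!is.matrix(features)) stopf("`features` must be a matrix")
  if (!is.null(labels) && length(labels) != nrow(features)) {
    stopf("labels must have one entry per segment")
  }
  structure(list(features = features,
                 labels = if (is.null(labels)) NULL else as.integer(labels),
                 subject_id = subject_id, layout = layout),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d segments x %d features%s\n",
              x$subject_id, nrow(x$features), ncol(x$features),
              if (is.null(x$labels)) " (unlabeled)" else ""))
  invisible(x)
}

#' Extract per-subject band-power feature matrices from a cohort
#'
#' Runs the full preprocessing chain — optional 1-30 Hz zero-phase
#' band-pass, 0.5 s non-overlapping segmentation, one-sided log-PSD at
#' integer frequencies, theta/alpha/beta band assembly — on each subject's
#' awake and fatigue recordings and stacks them into a labeled
#' [feature_matrix()] (awake segments labeled 0, fatigue 1).
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()], or a list of
#'   `list(subject_id, awake = eeg_recording, fatigue = eeg_recording)`.
#' @param config A [feature_config()].
#' @return A list of [feature_matrix()] objects, one per subject.
#' @export
extract_features <- function(cohort, config = feature_config()) {
  if (length(cohort) == 0L) return(list())
  n_ch <- vapply(cohort, function(s) nrow(s$awake$data), integer(1))
  if (length(unique(n_ch)) != 1L) {
    stopf("channel count differs across subjects: %s",
          paste(unique(n_ch), collapse = ", "))
  }
  layout <- list(n_channels = n_ch[[1]],
                 bands = vapply(config$bands, function(b)
                   sprintf("%s:%d-%d", b$name, b$lo, b$hi), character(1)))
  lapply(cohort, function(subj) {
    fa <- features_of_recording(subj$awake, config)
    ff <- features_of_recording(subj$fatigue, config)
    feature_matrix(rbind(fa, ff),
                   labels = c(rep(0L, nrow(fa)), rep(1L, nrow(ff))),
                   subject_id = subj$subject_id, layout = layout)
  })
}

#' Write or read a feature matrix as CSV with a JSON sidecar
#'
#' The CSV holds the numeric matrix (plus a `label` column when labels are
#' present); the sidecar `<path>.json` records the subject id and feature
#' layout.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV file path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns a [feature_matrix()].
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$features)
  if (!is.null(fm$labels)) df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = fm$subject_id, layout = fm$layout,
               labeled = !is.null(fm$labels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  feature_matrix(unname(as.matrix(df)), labels,
                 subject_id = meta$subject_id %||% NA_character_,
                 layout = meta$layout)
}
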