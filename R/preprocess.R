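#' Construct an EEG recording object
#'
#' Container for a multichannel recording: a `n_channels x n_samples`
#' matrix in microvolts, channel labels resolved against the built-in
#' 10-20 montage, the sampling rate, and a reference tag.
#'
#' @param data `n_channels x n_samples` numeric matrix.
#' @param channel_labels Channel labels (10-20 names; legacy T3/T4/T5/T6
#'   accepted).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param reference `"original"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate_hz,
                          reference = "original") {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(channel_labels), sampling_rate_hz > 0)
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique")
  }
  montage <- montage_1020(channel_labels)  # errors on unknown labels
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate_hz = sampling_rate_hz, montage = montage,
                 reference = match.arg(reference,
                                       c("original", "average"))),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz, x$reference))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Reads either an EDF file or a plain delimited matrix (samples as
#' rows, channels as columns, header row of 10-20 labels) into an
#' [eeg_recording()]. Channel labels are resolved against the built-in
#' montage; unknown labels raise an error naming the offending channel.
#'
#' @param path File path.
#' @param format `"edf"` or `"delimited"`.
#' @param sampling_rate_hz Required for delimited input (EDF carries its
#'   own rate).
#' @param sep Field separator for delimited input (default tab).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("edf", "delimited"),
                           sampling_rate_hz = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    raw <- read_edf(path)
    eeg_recording(raw$data, raw$channel_labels, raw$sampling_rate_hz)
  } else {
    if (is.null(sampling_rate_hz)) {
      stop("sampling_rate_hz is required for delimited input")
    }
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
    eeg_recording(t(as.matrix(tab)), colnames(tab), sampling_rate_hz)
  }
}

#' Write an EEG matrix as a delimited text table
#'
#' Channels as columns with a header row of labels; samples as rows.
#'
#' @param data `n_channels x n_samples` matrix.
#' @param channel_labels Channel labels for the header.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_eeg_delimited <- function(data, channel_labels, path, sep = "\t") {
  tab <- as.data.frame(t(data))
  colnames(tab) <- channel_labels
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Zero-phase filtering: odd reflect padding of 3 x the filter length at
# each end, a forward and a reverse pass, each started from the
# steady-state initial conditions for its first sample (the
# Matlab/SciPy filtfilt edge treatment) so level mismatches at the
# record edges do not ring into the data.
filtfilt_padded <- function(b, a, x, pad = 3 * max(length(a), length(b))) {
  n <- length(x)
  pad <- min(n - 1, pad)
  h0 <- sum(b) / sum(a)
  one_pass <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z0, length(b) - 1),
                              init.y = rep(z0 * h0, length(a) - 1)))
  }
  if (pad < 1) {
    return(rev(one_pass(rev(one_pass(x)))))
  }
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_channelwise <- function(rec, fn) {
  out <- rec
  out$data <- t(apply(rec$data, 1, fn))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Zero-phase notch filter
#'
#' Applies a second-order IIR notch (quality factor 30) at `freq_hz` to
#' every channel, forward and backward, giving zero phase and deep
#' attenuation at the line frequency.
#'
#' @param rec An [eeg_recording()].
#' @param freq_hz Notch frequency in Hz (default 50); must be below the
#'   Nyquist frequency.
#' @param q Quality factor (centre frequency / -3 dB bandwidth).
#' @return The filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, freq_hz = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (freq_hz >= nyq) stop("notch frequency must be below Nyquist (",
                           nyq, " Hz)")
  w0 <- 2 * pi * freq_hz / rec$sampling_rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_channelwise(rec, function(x) filtfilt_padded(b, a, x))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' (effective order 8, zero phase), with odd reflect padding at the
#' edges.
#'
#' @param rec An [eeg_recording()].
#' @param lo_hz,hi_hz Band edges in Hz (defaults 1 and 45); must satisfy
#'   `0 < lo_hz < hi_hz < Nyquist`.
#' @param order Butterworth prototype order (default 2, giving an
#'   order-4 band-pass transfer function per pass).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, lo_hz = 1, hi_hz = 45, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq)) {
    stop("band edges must satisfy 0 < lo_hz < hi_hz < Nyquist")
  }
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  apply_channelwise(rec, function(x) filtfilt_padded(bf$b, bf$a, x))
}

#' Detect bad channels by outlying temporal standard deviation
#'
#' A channel is flagged as bad when its temporal standard deviation,
#' expressed as a robust z-score across channels (median/MAD based),
#' exceeds `z_threshold`.
#'
#' @param rec An [eeg_recording()] with at least 4 channels.
#' @param z_threshold Robust z-score threshold (default 4).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_threshold = 4) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$data) >= 4)
  sds <- apply(rec$data, 1, stats::sd)
  med <- stats::median(sds)
  madv <- stats::mad(sds)
  if (madv == 0) return(character(0))
  z <- (sds - med) / madv
  rec$channel_labels[z > z_threshold]
}

#' Dataset exclusion rule on bad-channel count
#'
#' A recording is excluded from further analysis when more than
#' `max_bad` channels are flagged bad.
#'
#' @param bad Character vector of bad channel labels.
#' @param max_bad Maximum tolerated number of bad channels (default 2).
#' @return `"keep"` or `"exclude"`.
#' @export
exclude_if_too_many_bad <- function(bad, max_bad = 2) {
  if (length(bad) > max_bad) "exclude" else "keep"
}

# Perrin-style spherical-spline kernel between unit vectors with cosine
# matrix `cosang`; order-m spline, Legendre series truncated at n_terms.
spline_g <- function(cosang, m = 4, n_terms = 50) {
  g <- matrix(0, nrow(cosang), ncol(cosang))
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  p_cur <- cosang                                  # P_1
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
      p_prev <- p_cur
      p_cur <- p_new
    }
    g <- g + (2 * n + 1) / (n * (n + 1))^m * p_cur
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the time series of the listed bad channels with a
#' spherical-spline (order-4, regularized) interpolation from the
#' remaining good channels, using the unit-sphere montage positions.
#' Good channels are untouched.
#'
#' @param rec An [eeg_recording()].
#' @param bad Character vector of channel labels to reconstruct (may be
#'   empty, in which case the recording is returned unchanged).
#' @param m Spline order (default 4).
#' @param lambda Ridge regularization added to the kernel diagonal
#'   (default 1e-5).
#' @param n_terms Legendre series truncation (default 50).
#' @return The [eeg_recording()] with bad channels reconstructed.
#' @export
interpolate_spherical <- function(rec, bad, m = 4, lambda = 1e-5,
                                  n_terms = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  bad <- resolve_1020_labels(bad)
  labs <- resolve_1020_labels(rec$channel_labels)
  bad_idx <- match(bad, labs)
  if (anyNA(bad_idx)) stop("bad channels not present in the recording")
  good_idx <- setdiff(seq_along(labs), bad_idx)
  if (length(good_idx) < 4) stop("too few good channels to interpolate")
  xyz <- as.matrix(rec$montage[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  cos_gg <- tcrossprod(xyz[good_idx, , drop = FALSE])
  cos_bg <- xyz[bad_idx, , drop = FALSE] %*% t(xyz[good_idx, , drop = FALSE])
  cos_gg <- pmin(pmax(cos_gg, -1), 1)
  cos_bg <- pmin(pmax(cos_bg, -1), 1)
  g_gg <- spline_g(cos_gg, m = m, n_terms = n_terms)
  g_bg <- spline_g(cos_bg, m = m, n_terms = n_terms)
  ng <- length(good_idx)
  amat <- rbind(cbind(g_gg + lambda * diag(ng), rep(1, ng)),
                c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good_idx, , drop = FALSE],
               rep(0, ncol(rec$data)))
  sol <- solve(amat, rhs)
  coef <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  out <- rec
  out$data[bad_idx, ] <- g_bg %*% coef +
    matrix(c0, length(bad_idx), ncol(rec$data), byrow = TRUE)
  out
}

#' Re-reference a recording to the average reference
#'
#' Subtracts the per-sample mean across channels; idempotent.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced [eeg_recording()] with reference tag
#'   `"average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out$reference <- "average"
  out
}

#' Select low-artifact analysis epochs
#'
#' Partitions the recording into non-overlapping candidate windows of
#' `length_s` seconds, scores each by its total channel variance, and
#' returns the `n` lowest-variance windows in temporal order. The rule
#' is deterministic; ties are broken by window position.
#'
#' @param rec An [eeg_recording()].
#' @param n Number of epochs (default 5).
#' @param length_s Epoch length in seconds (default 10).
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   `n_channels x n_epoch_samples` matrices), `start_samples`,
#'   `epoch_length_s`, `sampling_rate_hz`, `channel_labels`.
#' @export
select_epochs <- function(rec, n = 5, length_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(length_s * rec$sampling_rate_hz)
  n_win <- floor(ncol(rec$data) / len)
  if (n_win < n) {
    stop("recording too short: ", n_win, " candidate windows for ", n,
         " requested epochs")
  }
  starts <- (seq_len(n_win) - 1) * len + 1
  score <- vapply(starts, function(s) {
    sum(apply(rec$data[, s:(s + len - 1), drop = FALSE], 1, stats::var))
  }, 0)
  keep <- sort(order(score)[seq_len(n)])
  epochs <- lapply(starts[keep], function(s) {
    rec$data[, s:(s + len - 1), drop = FALSE]
  })
  structure(list(epochs = epochs, start_samples = starts[keep],
                 epoch_length_s = length_s,
                 sampling_rate_hz = rec$sampling_rate_hz,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' Build an epoch set directly from a matrix
#'
#' Splits a continuous `n_channels x n_samples` matrix into consecutive
#' fixed-length epochs without any quality scoring; a convenience for
#' synthetic data whose epochs are defined by construction.
#'
#' @param data `n_channels x n_samples` matrix.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n Number of epochs.
#' @param length_s Epoch length in seconds.
#' @return An `epoch_set`.
#' @export
epochs_from_matrix <- function(data, sampling_rate_hz, n = 5,
                               length_s = 10) {
  len <- round(length_s * sampling_rate_hz)
  stopifnot(ncol(data) >= n * len)
  epochs <- lapply(seq_len(n), function(i) {
    data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
  })
  structure(list(epochs = epochs,
                 start_samples = (seq_len(n) - 1) * len + 1,
                 epoch_length_s = length_s,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = rownames(data)),
            class = "epoch_set")
}

#' Run the full preprocessing chain
#'
#' Notch filter, band-pass filter, bad-channel detection with the
#' dataset exclusion rule, spherical-spline reconstruction, average
#' referencing, and epoch selection, in the standard order. An
#' artifact-removal hook (`artifact_fn`) is applied between the notch
#' and band-pass stages; it defaults to a no-op so users with real
#' recordings can insert their own cleaner.
#'
#' @param rec An [eeg_recording()].
#' @param notch_hz Line frequency (default 50).
#' @param band Band edges in Hz (default `c(1, 45)`).
#' @param bad_z_threshold Robust z threshold for bad channels (default 4).
#' @param max_bad_channels Exclusion rule bound (default 2).
#' @param n_epochs,epoch_length_s Epoch selection parameters (5 and 10).
#' @param artifact_fn Function `eeg_recording -> eeg_recording` applied
#'   after the notch filter (default identity).
#' @param verbose Emit one log line per stage (default FALSE).
#' @return A list with `epochs` (an `epoch_set`, or NULL if excluded),
#'   `bad_channels`, `decision` (`"keep"`/`"exclude"`), and the
#'   preprocessed `recording`.
#' @export
preprocess_recording <- function(rec, notch_hz = 50, band = c(1, 45),
                                 bad_z_threshold = 4,
                                 max_bad_channels = 2, n_epochs = 5,
                                 epoch_length_s = 10,
                                 artifact_fn = identity,
                                 verbose = FALSE) {
  log_line <- function(...) if (verbose) message("[preprocess] ", ...)
  rec <- notch_filter(rec, notch_hz)
  log_line("notch at ", notch_hz, " Hz")
  rec <- artifact_fn(rec)
  rec <- bandpass_filter(rec, band[1], band[2])
  log_line("band-pass ", band[1], "-", band[2], " Hz")
  bad <- detect_bad_channels(rec, bad_z_threshold)
  log_line("bad channels: ",
           if (length(bad)) paste(bad, collapse = ", ") else "none")
  decision <- exclude_if_too_many_bad(bad, max_bad_channels)
  if (decision == "exclude") {
    log_line("excluded: more than ", max_bad_channels, " bad channels")
    return(list(epochs = NULL, bad_channels = bad, decision = decision,
                recording = rec))
  }
  rec <- interpolate_spherical(rec, bad)
  rec <- rereference_average(rec)
  eps <- select_epochs(rec, n = n_epochs, length_s = epoch_length_s)
  log_line("epochs at samples ",
           paste(eps$start_samples, collapse = ", "))
  list(epochs = eps, bad_channels = bad, decision = decision,
       recording = rec)
}
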