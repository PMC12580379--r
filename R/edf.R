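# Minimal European Data Format (EDF) support: continuous 16-bit signals,
# one-second data records, physical dimension microvolts. Covers what the
# pipeline writes and reads; not a general EDF+ implementation (no
# annotations, no discontinuous records).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  .edf_pad(s, width)
}

#' Write an EEG matrix to an EDF file
#'
#' Writes a continuous recording as 16-bit EDF with one-second data
#' records and physical units of microvolts. The trailing partial
#' second, if any, is dropped (with a warning).
#'
#' @param data `n_channels x n_samples` numeric matrix (microvolts).
#' @param channel_labels Character vector of channel labels.
#' @param sampling_rate_hz Integer sampling rate (samples per record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, channel_labels, sampling_rate_hz, path) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  fs <- as.integer(round(sampling_rate_hz))
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop("recording shorter than one data record (1 s)")
  if (ncol(data) > n_rec * fs) {
    warning("dropping trailing partial data record (",
            ncol(data) - n_rec * fs, " samples)")
    data <- data[, seq_len(n_rec * fs), drop = FALSE]
  }

  # physical scaling per channel; the header stores the physical range as
  # ASCII, so digitize against the value parsed back from that string
  pmax_str <- character(ns); pmin_str <- character(ns)
  dig <- matrix(0L, nrow = ns, ncol = ncol(data))
  fmt_pm <- function(pm) {
    # both "x" and "-x" must fit in 8 ASCII chars and parse identically
    for (digs in c(6, 5, 4, 3)) {
      s <- trimws(formatC(pm, format = "g", digits = digs))
      if (nchar(s) <= 7) return(s)
    }
    trimws(formatC(pm, format = "e", digits = 1))
  }
  for (i in seq_len(ns)) {
    pm <- max(abs(data[i, ]), 1e-6)
    s <- fmt_pm(pm)
    pm_parsed <- as.numeric(s)
    pmax_str[i] <- .edf_pad(s, 8)
    pmin_str[i] <- .edf_pad(paste0("-", s), 8)
    d <- round(data[i, ] / pm_parsed * 32767)
    dig[i, ] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.24", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, .edf_pad, "", width = width),
                    collapse = ""), con, eos = NULL)
  }
  fld(channel_labels, 16)
  fld(rep("", ns), 80)                      # transducer
  fld(rep("uV", ns), 8)                     # physical dimension
  fld(pmin_str, 8)
  fld(pmax_str, 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)                      # prefiltering
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG matrix
#'
#' Reads a continuous 16-bit EDF recording and rescales digital values
#' to physical units using the per-signal header ranges. All signals
#' must share one sampling rate.
#'
#' @param path EDF file path.
#' @return List with `data` (`n_channels x n_samples`), `channel_labels`,
#'   and `sampling_rate_hz`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  n_header <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF header: ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("signals with heterogeneous sampling rates are not supported")
  }
  seek(con, n_header)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- data * scale + (pmin - dmin * scale)
  rownames(data) <- labels
  list(data = data, channel_labels = labels,
       sampling_rate_hz = spr[1] / rec_dur)
}
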