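# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched, and identical seeds give identical draws.
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate synthetic microstate template topographies
#'
#' Builds `k` smooth, dipolar-looking scalp maps over an electrode
#' montage. Each map is the potential of a randomly placed and oriented
#' current dipole inside the unit sphere, evaluated at the electrode
#' positions, then average-referenced and normalized to unit Euclidean
#' norm. Candidate maps are redrawn until all pairwise absolute spatial
#' correlations are below `max_abs_corr`, so the templates are mutually
#' distinguishable.
#'
#' @param n_channels Number of electrodes (default 19).
#' @param k Number of template maps (>= 1).
#' @param montage Data frame with columns `label`, `x`, `y`, `z` giving
#'   unit-sphere electrode positions; default the built-in 10-20 montage.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param max_abs_corr Distinguishability bound on pairwise absolute
#'   spatial correlation (default 0.8, exclusive).
#' @return An object of class `microstate_templates`: a list with `maps`
#'   (`k x n_channels`, zero-mean unit-norm rows), `labels`, and
#'   `channel_labels`.
#' @export
#' @examples
#' tpl <- generate_templates(k = 4, seed = 1)
#' round(rowSums(tpl$maps), 12)  # average-referenced rows
generate_templates <- function(n_channels = 19, k = 4,
                               montage = montage_1020(), seed = 1,
                               max_abs_corr = 0.8) {
  stopifnot(k >= 1, n_channels >= 2)
  if (nrow(montage) < n_channels) {
    stop("montage provides only ", nrow(montage), " positions for ",
         n_channels, " channels")
  }
  montage <- montage[seq_len(n_channels), , drop = FALSE]
  if (k > n_channels - 1) {
    stop("k must be <= n_channels - 1 (maps live in the average-reference ",
         "subspace of dimension n_channels - 1)")
  }
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  with_private_seed(seed, {
    maps <- matrix(NA_real_, k, n_channels)
    i <- 1; tries <- 0
    while (i <= k) {
      tries <- tries + 1
      if (tries > 500 * k) {
        stop("could not draw ", k, " mutually distinguishable maps")
      }
      # dipole at radius <= 0.6 with random moment
      p <- stats::runif(3, -1, 1)
      p <- p / max(1, sqrt(sum(p^2))) * stats::runif(1, 0, 0.6)
      m <- stats::rnorm(3)
      m <- m / sqrt(sum(m^2))
      d <- sweep(xyz, 2, p)
      r3 <- (rowSums(d^2))^(3 / 2)
      v <- as.numeric(d %*% m) / r3
      v <- v - mean(v)
      nrm <- sqrt(sum(v^2))
      if (nrm < 1e-12) next
      v <- v / nrm
      ok <- TRUE
      if (i > 1) {
        cors <- abs(maps[seq_len(i - 1), , drop = FALSE] %*% v)
        ok <- all(cors < max_abs_corr)
      }
      if (ok) {
        maps[i, ] <- v
        i <- i + 1
      }
    }
    colnames(maps) <- montage$label
    rownames(maps) <- paste0("M", seq_len(k))
    structure(list(maps = maps,
                   labels = rownames(maps),
                   channel_labels = montage$label),
              class = "microstate_templates")
  })
}

#' Specify a semi-Markov microstate state sequence
#'
#' Validates and packages the generative parameters of the state
#' sequence: a row-stochastic transition matrix over *distinct* states
#' (zero diagonal; self-transitions are not events), per-state mean
#' dwell times, the sampling rate, total duration, and a seed.
#'
#' @param transition_matrix `K x K` row-stochastic matrix with zero
#'   diagonal.
#' @param mean_dwell_ms Per-state mean dwell time in milliseconds
#'   (recycled to length K). Must exceed two sampling intervals.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param total_duration_s Total duration in seconds.
#' @param seed Integer seed.
#' @return An object of class `state_sequence_spec`.
#' @export
state_sequence_spec <- function(transition_matrix,
                                mean_dwell_ms = 60,
                                sampling_rate_hz = 500,
                                total_duration_s = 50,
                                seed = 1) {
  tm <- as.matrix(transition_matrix)
  k <- nrow(tm)
  stopifnot(k >= 2, ncol(tm) == k)
  if (any(abs(diag(tm)) > 0)) {
    stop("transition_matrix must have a zero diagonal ",
         "(self-transitions are not events)")
  }
  if (any(abs(rowSums(tm) - 1) > 1e-12)) {
    stop("transition_matrix rows must sum to 1 within 1e-12")
  }
  mean_dwell_ms <- rep_len(mean_dwell_ms, k)
  stopifnot(sampling_rate_hz > 0, total_duration_s > 0)
  if (any(mean_dwell_ms <= 2 * 1000 / sampling_rate_hz)) {
    stop("mean_dwell_ms must exceed two sampling intervals so runs span ",
         "multiple samples")
  }
  structure(list(transition_matrix = tm, mean_dwell_ms = mean_dwell_ms,
                 sampling_rate_hz = sampling_rate_hz,
                 total_duration_s = total_duration_s, seed = seed, k = k),
            class = "state_sequence_spec")
}

#' Uniform off-diagonal transition matrix
#'
#' Row-stochastic `k x k` matrix with zero diagonal and equal
#' probability `1/(k-1)` for every distinct-state transition.
#'
#' @param k Number of states (>= 2).
#' @return A `k x k` matrix.
#' @export
uniform_transitions <- function(k) {
  tm <- matrix(1 / (k - 1), k, k)
  diag(tm) <- 0
  tm
}

#' Stationary state occupancy of a state-sequence specification
#'
#' For the semi-Markov process defined by the embedded distinct-state
#' chain and per-state mean dwell times, the long-run fraction of time
#' in state `s` is proportional to `pi_s * dwell_s`, where `pi` is the
#' stationary distribution of the embedded chain.
#'
#' @param spec A [state_sequence_spec()].
#' @return Numeric vector of length K summing to 1.
#' @export
stationary_occupancy <- function(spec) {
  stopifnot(inherits(spec, "state_sequence_spec"))
  tm <- spec$transition_matrix
  k <- nrow(tm)
  # stationary distribution of the embedded chain: pi' P = pi'
  a <- rbind(t(tm) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_emb <- as.numeric(qr.solve(a, b))
  occ <- pi_emb * spec$mean_dwell_ms
  occ / sum(occ)
}

#' Simulate a per-sample microstate label sequence
#'
#' Alternating-renewal simulation: the dwell in the current state is
#' drawn from a geometric distribution on samples with mean
#' `mean_dwell_ms * sampling_rate_hz / 1000` (support >= 1 sample), then
#' the process jumps to a distinct state according to the transition
#' matrix.
#'
#' @param spec A [state_sequence_spec()].
#' @return Integer vector of state indices (1..K), of length
#'   `round(total_duration_s * sampling_rate_hz)`.
#' @export
simulate_state_sequence <- function(spec) {
  stopifnot(inherits(spec, "state_sequence_spec"))
  n <- round(spec$total_duration_s * spec$sampling_rate_hz)
  k <- spec$k
  mean_dwell_samples <- spec$mean_dwell_ms * spec$sampling_rate_hz / 1000
  with_private_seed(spec$seed, {
    labels <- integer(n)
    s <- sample.int(k, 1)
    pos <- 0L
    while (pos < n) {
      # geometric on {1, 2, ...} with mean L: 1 + rgeom(p), p = 1/L
      dwell <- 1L + stats::rgeom(1, prob = 1 / mean_dwell_samples[s])
      take <- min(dwell, n - pos)
      labels[(pos + 1L):(pos + take)] <- s
      pos <- pos + take
      s <- sample.int(k, 1, prob = spec$transition_matrix[s, ])
    }
    labels
  })
}

#' Synthesize multichannel EEG from templates and a state sequence
#'
#' Each sample's topography is its state's template map scaled by a
#' positive amplitude envelope (rectified 10 Hz low-pass-filtered
#' Gaussian process with mean 1), plus spatially smoothed Gaussian noise
#' scaled so that the ratio of state-signal RMS to noise RMS equals
#' `snr`. Both the signal and noise are average-referenced, so every
#' column of the output has zero mean across channels.
#'
#' @param templates A `microstate_templates` object.
#' @param labels Integer state-index series (1..K).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param snr Positive signal-to-noise ratio (RMS/RMS). `Inf` gives
#'   noiseless data.
#' @param seed Integer seed.
#' @param amplitude_uV Mean per-sample signal amplitude in microvolts
#'   (default 10).
#' @param noise_smoothness Spatial kernel width (chord distance on the
#'   unit sphere) of the noise smoother (default 0.5).
#' @return An object of class `synthetic_eeg`: list with `data`
#'   (`n_channels x n_samples`, microvolts), `truth_labels`,
#'   `truth_templates`, `snr`, `sampling_rate_hz`, `channel_labels`.
#' @export
synthesize_eeg <- function(templates, labels, sampling_rate_hz = 500,
                           snr = 4, seed = 1, amplitude_uV = 10,
                           noise_smoothness = 0.5) {
  stopifnot(inherits(templates, "microstate_templates"))
  k <- nrow(templates$maps)
  if (any(labels < 1 | labels > k)) stop("labels must index into templates")
  if (!(snr > 0)) stop("snr must be positive")
  n_ch <- ncol(templates$maps)
  n_s <- length(labels)
  with_private_seed(seed, {
    # amplitude envelope: rectified low-pass Gaussian process, mean 1
    g <- stats::rnorm(n_s)
    bf <- signal::butter(2, min(10 / (sampling_rate_hz / 2), 0.99),
                         type = "low")
    env <- abs(filtfilt_padded(bf$b, bf$a, g))
    env <- env / mean(env)
    sig <- t(templates$maps)[, labels, drop = FALSE] *
      rep(env * amplitude_uV, each = n_ch)
    if (is.finite(snr)) {
      xyz <- montage_xyz(templates$channel_labels)
      d2 <- as.matrix(stats::dist(xyz))^2
      kern <- exp(-d2 / (2 * noise_smoothness^2))
      noise <- kern %*% matrix(stats::rnorm(n_ch * n_s), n_ch, n_s)
      # band-limit the noise to the EEG analysis band (1-45 Hz): real
      # scalp background activity is temporally correlated, not white
      nyq <- sampling_rate_hz / 2
      nb <- signal::butter(2, c(min(1 / nyq, 0.5), min(45 / nyq, 0.99)),
                           type = "pass")
      noise <- t(apply(noise, 1, function(x) {
        filtfilt_padded(nb$b, nb$a, x)
      }))
      noise <- sweep(noise, 2, colMeans(noise))  # average reference
      sig_rms <- sqrt(mean(sig^2))
      noise <- noise * (sig_rms / snr / sqrt(mean(noise^2)))
      data <- sig + noise
    } else {
      data <- sig
    }
    rownames(data) <- templates$channel_labels
    structure(list(data = data, truth_labels = labels,
                   truth_templates = templates, snr = snr,
                   sampling_rate_hz = sampling_rate_hz,
                   channel_labels = templates$channel_labels),
              class = "synthetic_eeg")
  })
}

#' Specify a synthetic bilateral actigraphy series
#'
#' Packages the generative targets for a paired per-minute wrist
#' activity-count series: length, target inter-arm Pearson correlation,
#' target upper-limb activity ratio (ULAR, percent), the moderate
#' activity threshold and the target fraction of minutes above it, and
#' the day/night window.
#'
#' @param n_minutes Series length in minutes (>= 60).
#' @param target_r Target Pearson correlation between the arms' series.
#' @param target_ular_pct Target ULAR in percent (affected / unaffected
#'   count sums x 100).
#' @param moderate_threshold Counts/min above which a minute counts as
#'   moderate activity (default 500).
#' @param frac_moderate Target fraction of minutes above the threshold
#'   on the unaffected arm.
#' @param day_start,night_start Clock times ("HH:MM") bounding the day
#'   window (defaults 06:00 and 22:00).
#' @param affected_side `"left"` or `"right"` (default left).
#' @param start_time Timestamp of the first minute (default midnight,
#'   2024-01-01, UTC).
#' @param seed Integer seed.
#' @return An object of class `actigraphy_spec`.
#' @export
actigraphy_spec <- function(n_minutes = 1440, target_r = 0.62,
                            target_ular_pct = 30, moderate_threshold = 500,
                            frac_moderate = 0.1,
                            day_start = "06:00", night_start = "22:00",
                            affected_side = "left",
                            start_time = "2024-01-01 00:00:00",
                            seed = 1) {
  stopifnot(n_minutes >= 60, target_r >= -1, target_r <= 1,
            target_ular_pct > 0, frac_moderate >= 0, frac_moderate <= 1)
  affected_side <- match.arg(affected_side, c("left", "right"))
  structure(list(n_minutes = n_minutes, target_r = target_r,
                 target_ular_pct = target_ular_pct,
                 moderate_threshold = moderate_threshold,
                 frac_moderate = frac_moderate,
                 day_start = day_start, night_start = night_start,
                 affected_side = affected_side, start_time = start_time,
                 seed = seed),
            class = "actigraphy_spec")
}

#' Synthesize a paired per-minute actigraphy series
#'
#' The unaffected arm's counts follow a log-normal per-minute process
#' whose location is calibrated (by root finding) so the expected
#' fraction of minutes above `moderate_threshold` matches
#' `frac_moderate`, with a lower night-time activity level. The
#' affected arm is a Gaussian-copula copy whose latent correlation is
#' tuned analytically so the log-normal pair's Pearson correlation
#' matches `target_r`, then scaled so the count-sum ratio matches
#' `target_ular_pct`. Infeasible targets produce a warning, not a
#' silent failure; achieved metrics are reported alongside the series.
#'
#' @param spec An [actigraphy_spec()].
#' @param sigma Log-scale SD of the per-minute count process
#'   (default 0.8).
#' @param night_factor Multiplicative activity level at night relative
#'   to day (default 0.25).
#' @return An object of class `actigraphy_pair`: data frame fields
#'   `timestamps`, `affected_counts`, `unaffected_counts`, `day_mask`,
#'   plus `achieved` (list with empirical `r`, `ular_pct`,
#'   `frac_moderate`), `affected_side`, and the spec.
#' @export
synthesize_actigraphy <- function(spec, sigma = 0.8, night_factor = 0.25) {
  stopifnot(inherits(spec, "actigraphy_spec"))
  n <- spec$n_minutes
  ts <- as.POSIXct(spec$start_time, tz = "UTC") + 60 * (seq_len(n) - 1)
  day <- split_day_night(ts, spec$day_start, spec$night_start)
  log_fac <- ifelse(day, 0, log(night_factor))
  thr <- spec$moderate_threshold

  # location mu so that the expected fraction of minutes above thr
  # (marginally, mixing day and night levels) equals frac_moderate
  frac_at <- function(mu) {
    mean(stats::pnorm((mu + log_fac - log(thr)) / sigma))
  }
  if (spec$frac_moderate <= 0) {
    mu <- log(thr) - 8 * sigma
  } else if (spec$frac_moderate >= frac_at(log(thr) + 8 * sigma)) {
    warning("frac_moderate target ", spec$frac_moderate,
            " not achievable; using the maximum attainable level")
    mu <- log(thr) + 8 * sigma
  } else {
    mu <- stats::uniroot(function(m) frac_at(m) - spec$frac_moderate,
                         lower = log(thr) - 12 * sigma,
                         upper = log(thr) + 8 * sigma)$root
  }

  with_private_seed(spec$seed, {
    z1 <- stats::rnorm(n)
    e <- stats::rnorm(n)
    u_raw <- exp(mu + log_fac + sigma * z1)
    # tune the latent (copula) correlation so the realized Pearson r of
    # the generated pair matches the target; the analytic log-normal
    # relation only holds in expectation and the day/night mean
    # structure shifts it
    a_at <- function(rho) {
      z2 <- if (rho >= 1) z1 else rho * z1 + sqrt(1 - rho^2) * e
      exp(mu + log_fac + sigma * z2)
    }
    r_at <- function(rho) stats::cor(a_at(rho), u_raw)
    rho <- if (spec$target_r >= 1) {
      1
    } else if (r_at(-1) >= spec$target_r) {
      warning("target_r = ", spec$target_r, " is below the attainable ",
              "minimum for the log-normal pair; clamping to the most ",
              "negative feasible correlation")
      -1
    } else {
      stats::uniroot(function(r) r_at(r) - spec$target_r,
                     lower = -1, upper = 1, tol = 1e-10)$root
    }
    a_raw <- a_at(rho)
    scale_a <- (spec$target_ular_pct / 100) * sum(u_raw) / sum(a_raw)
    unaffected <- round(u_raw)
    affected <- round(scale_a * a_raw)
    achieved <- list(
      r = stats::cor(affected, unaffected),
      ular_pct = 100 * sum(affected) / sum(unaffected),
      frac_moderate = mean(unaffected > thr)
    )
    structure(list(timestamps = ts, affected_counts = affected,
                   unaffected_counts = unaffected, day_mask = day,
                   affected_side = spec$affected_side,
                   achieved = achieved, spec = spec),
              class = "actigraphy_pair")
  })
}
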