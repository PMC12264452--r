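# Time-frequency stage: sliding Hanning-window power, dB baseline
# normalization, band/time-window averaging.

#' Sliding Hanning-window time-frequency power
#'
#' Short-time single-taper (Hanning) power at each channel, frequency and
#' time bin, computed per trial and averaged across trials before any
#' normalization, so the result is total (evoked + induced) power. The
#' window length is frequency-adaptive: `cycles / f`, floored and capped
#' (defaults 100-400 ms); pass `fixed_window_s` for a fixed-length window.
#' Power is scaled so a pure sinusoid of amplitude A yields A^2 at its
#' frequency. Time bins whose window would extend beyond the epoch are
#' marked invalid (NA) rather than zero-padded.
#'
#' @param epochs An [eeg_epochs()].
#' @param freqs Analysis frequencies in Hz (default 3-80 in 0.5 Hz steps).
#' @param step_ms Spacing of time bins, ms.
#' @param cycles Cycles per window in adaptive mode.
#' @param win_range_s Floor and cap of the adaptive window length, seconds.
#' @param fixed_window_s Fixed window length in seconds (overrides the
#'   adaptive rule).
#' @return Object of class `eeg_tfr`: list with `power`
#'   (channels x freqs x times, microvolts squared, NA where invalid),
#'   `freqs`, `times` (bin centers, s), `channels`, `baseline_mode`
#'   (`"none"`), `valid` (freqs x times logical).
#' @export
tfr_hanning <- function(epochs, freqs = seq(3, 80, by = 0.5), step_ms = 10,
                        cycles = 4, win_range_s = c(0.1, 0.4),
                        fixed_window_s = NULL) {
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) stop("frequencies must stay below Nyquist (fs/2)")
  times <- epochs$times
  n_ch <- dim(epochs$data)[1]; n_s <- dim(epochs$data)[2]
  n_tr <- dim(epochs$data)[3]
  step_n <- max(1L, round(step_ms / 1000 * fs))
  centers_idx <- seq(1L, n_s, by = step_n)
  t_centers <- times[centers_idx]

  win_len_s <- function(f) {
    if (!is.null(fixed_window_s)) fixed_window_s
    else min(win_range_s[2], max(win_range_s[1], cycles / f))
  }
  for (f in freqs) {
    if (f < 1 / win_len_s(f) - 1e-9) {
      stop("frequency ", f, " Hz is below the spectral resolution (",
           signif(1 / win_len_s(f), 3), " Hz) of its ",
           signif(win_len_s(f), 3), " s window; lengthen the window")
    }
  }
  longest <- max(vapply(freqs, win_len_s, numeric(1)))
  if (longest > (n_s - 1) / fs) {
    stop("epoch shorter than the longest analysis window (",
         signif(longest, 3), " s)")
  }

  # flatten to samples x (channel*trial) for vectorized windowed products
  xmat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = n_s)
  pow <- array(NA_real_, dim = c(n_ch, length(freqs), length(centers_idx)))
  valid <- matrix(FALSE, length(freqs), length(centers_idx))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    half_n <- floor(win_len_s(f) * fs / 2)
    wn <- 2L * half_n + 1L
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wn) / (wn + 1))
    trel <- (seq_len(wn) - 1L - half_n) / fs
    kern <- taper * exp(-2i * pi * f * trel) * (2 / sum(taper))
    for (ti in seq_along(centers_idx)) {
      ci <- centers_idx[ti]
      lo <- ci - half_n; hi <- ci + half_n
      if (lo < 1L || hi > n_s) next
      v <- crossprod(kern, xmat[lo:hi, , drop = FALSE])  # 1 x (ch*tr)
      p <- matrix(Mod(v)^2, n_ch, n_tr)
      pow[, fi, ti] <- rowMeans(p)
      valid[fi, ti] <- TRUE
    }
  }
  structure(list(power = pow, freqs = freqs, times = t_centers,
                 channels = epochs$channels, baseline_mode = "none",
                 valid = valid, group = epochs$group,
                 session = epochs$session),
            class = "eeg_tfr")
}

#' dB baseline normalization
#'
#' `10 * log10(power / mean baseline power)` per channel and frequency,
#' with the baseline mean taken over the valid time bins inside the
#' baseline interval (default -200..0 ms).
#'
#' @param tfr An `eeg_tfr` with `baseline_mode == "none"`.
#' @param baseline Length-2 interval in seconds, closed.
#' @return An `eeg_tfr` with `baseline_mode == "dB"`.
#' @export
baseline_db <- function(tfr, baseline = c(-0.2, 0)) {
  if (tfr$baseline_mode != "none") stop("tfr is already baseline-normalized")
  in_base <- tfr$times >= baseline[1] - 1e-9 & tfr$times <= baseline[2] + 1e-9
  out <- tfr
  for (fi in seq_along(tfr$freqs)) {
    bidx <- which(in_base & tfr$valid[fi, ])
    if (length(bidx) == 0) {
      stop("no valid baseline bin at ", tfr$freqs[fi],
           " Hz; extend the epoch or the baseline")
    }
    base <- rowMeans(tfr$power[, fi, bidx, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(base)) || any(base <= 0)) {
      stop("non-positive baseline power at ", tfr$freqs[fi], " Hz")
    }
    out$power[, fi, ] <- 10 * log10(tfr$power[, fi, ] / base)
  }
  out$baseline_mode <- "dB"
  out
}

band_bins <- function(freqs, low, high) {
  # half-open [low, high); the top band edge (80 Hz) is closed so the grid
  # maximum is never dropped
  sel <- freqs >= low - 1e-9 & freqs < high - 1e-9
  if (high >= max(freqs) - 1e-9) sel <- sel | abs(freqs - high) < 1e-9
  sel
}

#' Band- and window-averaged power
#'
#' Mean of the TFR over the frequency bins of a band and the time bins of
#' an analysis window (default 50-350 ms), per channel. Frequency bins
#' belong to a band if their center lies in `[low, high)`; the upper gamma
#' edge is closed.
#'
#' @param tfr An `eeg_tfr` (typically dB-baselined).
#' @param band A band label from [eeg_bands()] or a `c(low, high)` pair in
#'   Hz.
#' @param time_window Length-2 interval in seconds.
#' @return Named per-channel vector.
#' @export
band_average <- function(tfr, band, time_window = c(0.05, 0.35)) {
  if (is.character(band)) {
    b <- eeg_bands(); i <- match(band, b$band)
    if (is.na(i)) stop("unknown band: ", band)
    band <- c(b$low[i], b$high[i])
  }
  fsel <- which(band_bins(tfr$freqs, band[1], band[2]))
  tsel <- which(tfr$times >= time_window[1] - 1e-9 &
                  tfr$times <= time_window[2] + 1e-9)
  if (length(fsel) == 0 || length(tsel) == 0) {
    stop("band/time selection is empty on this TFR grid")
  }
  sub <- tfr$power[, fsel, tsel, drop = FALSE]
  if (all(is.na(sub))) stop("selection contains no valid time bins")
  out <- apply(sub, 1, mean, na.rm = TRUE)
  names(out) <- tfr$channels
  out
}

#' Band power over time
#'
#' Mean over a band's frequency bins at every time bin, per channel --
#' the channels x time map used for spatio-temporal cluster statistics on
#' oscillatory power.
#'
#' @inheritParams band_average
#' @return Channels x times matrix (NA at invalid bins).
#' @export
band_timecourse <- function(tfr, band) {
  if (is.character(band)) {
    b <- eeg_bands(); i <- match(band, b$band)
    if (is.na(i)) stop("unknown band: ", band)
    band <- c(b$low[i], b$high[i])
  }
  fsel <- which(band_bins(tfr$freqs, band[1], band[2]))
  if (length(fsel) == 0) stop("band contains no frequency bins")
  out <- apply(tfr$power[, fsel, , drop = FALSE], c(1, 3), mean)
  dimnames(out) <- list(tfr$channels, NULL)
  out
}
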