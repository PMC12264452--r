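# ERP stage: minimal preprocessing, trial averaging with baseline
# correction, windowed component amplitudes, difference waves.

#' Standard component windows
#'
#' N100 75-125 ms, P150 130-190 ms, N200 210-290 ms, P300 280-380 ms,
#' closed intervals in milliseconds relative to stimulus onset.
#'
#' @return Data frame `label, start_ms, end_ms`.
#' @export
component_windows <- function() {
  data.frame(label = c("N100", "P150", "N200", "P300"),
             start_ms = c(75, 130, 210, 280),
             end_ms = c(125, 190, 290, 380),
             stringsAsFactors = FALSE)
}

#' Minimal epoch preprocessing
#'
#' Zero-phase Butterworth band-pass (default 1-80 Hz, order 4, applied
#' forward and backward so component latencies are preserved), optional
#' 50 Hz notch, then rejection of any trial whose absolute amplitude
#' exceeds `reject_uv` on any channel.
#'
#' @param epochs An [eeg_epochs()].
#' @param band Length-2 band-pass edges in Hz (`NULL` to skip filtering).
#' @param notch_50 Apply a 48-52 Hz band-stop.
#' @param reject_uv Artifact rejection threshold in microvolts (`Inf` to
#'   keep all trials).
#' @return Filtered [eeg_epochs()] with attribute `n_dropped`.
#' @export
preprocess_epochs <- function(epochs, band = c(1, 80), notch_50 = FALSE,
                              reject_uv = 100) {
  x <- epochs$data
  fs <- epochs$fs
  nyq <- fs / 2
  if (!is.null(band)) {
    hi <- min(band[2], 0.95 * nyq)
    bf <- signal::butter(4, c(band[1], hi) / nyq, type = "pass")
    x <- filt_epochs(x, bf)
  }
  if (notch_50) {
    if (nyq > 52) {
      bs <- signal::butter(2, c(48, 52) / nyq, type = "stop")
      x <- filt_epochs(x, bs)
    }
  }
  peak <- apply(abs(x), 3, max)
  keep <- peak <= reject_uv
  if (!any(keep)) stop("all trials rejected at threshold ", reject_uv, " uV")
  out <- eeg_epochs(x[, , keep, drop = FALSE], fs = fs, t0 = epochs$times[1],
                    channels = epochs$channels, group = epochs$group,
                    session = epochs$session, kind = epochs$kind)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

filt_epochs <- function(x, flt) {
  d <- dim(x)
  for (tr in seq_len(d[3])) {
    m <- matrix(x[, , tr], nrow = d[1])
    x[, , tr] <- t(apply(m, 1, function(v) signal::filtfilt(flt, v)))
  }
  x
}

#' Trial-average ERP with baseline correction
#'
#' Averages epochs across trials, then subtracts each channel's mean over
#' the baseline interval (default -200..0 ms).
#'
#' @param epochs An [eeg_epochs()].
#' @param baseline Length-2 interval in seconds (closed); must lie within
#'   the epoch.
#' @return Object of class `erp_waveform`: list with `data`
#'   (channels x time matrix, microvolts), `times` (s), `channels`,
#'   `n_trials`, `group`, `session`.
#' @export
average_erp <- function(epochs, baseline = c(-0.2, 0)) {
  if (n_trials(epochs) < 1) stop("need at least one trial")
  if (baseline[1] < min(epochs$times) - 1e-9 ||
      baseline[2] > max(epochs$times) + 1e-9) {
    stop("baseline interval outside the epoch")
  }
  avg <- apply(epochs$data, c(1, 2), mean)
  bidx <- time_indices(epochs$times, baseline)
  avg <- avg - rowMeans(avg[, bidx, drop = FALSE])
  structure(list(data = avg, times = epochs$times, channels = epochs$channels,
                 n_trials = n_trials(epochs), group = epochs$group,
                 session = epochs$session),
            class = "erp_waveform")
}

#' Windowed mean component amplitude
#'
#' Mean amplitude of the ERP over a closed latency window and a channel
#' subset (default: the frontal-central reporting electrodes present in
#' the data). Windowed means rather than peak picking: they are robust to
#' noise and make the measure linear in the waveform.
#'
#' @param erp An `erp_waveform`.
#' @param window Either a component label from [component_windows()] or a
#'   length-2 interval in milliseconds.
#' @param channels Channel labels to average (must be non-empty and exist).
#' @return Mean amplitude in microvolts.
#' @export
component_amplitude <- function(erp, window,
                                channels = intersect(c("FC1", "FCz", "FC2"),
                                                     erp$channels)) {
  if (length(channels) == 0) stop("empty channel subset")
  if (!all(channels %in% erp$channels)) {
    stop("unknown channel(s): ",
         paste(setdiff(channels, erp$channels), collapse = ", "))
  }
  if (is.character(window) && length(window) == 1) {
    cw <- component_windows()
    i <- match(window, cw$label)
    if (is.na(i)) stop("unknown component: ", window)
    window <- c(cw$start_ms[i], cw$end_ms[i])
  }
  tidx <- time_indices(erp$times, window / 1000)
  cidx <- match(channels, erp$channels)
  mean(erp$data[cidx, tidx, drop = FALSE])
}

#' Post-minus-pre difference wave
#'
#' @param post,pre `erp_waveform`s on identical channel and time axes.
#' @return `erp_waveform` of the pointwise difference. Component amplitudes
#'   of the difference equal the difference of component amplitudes
#'   (linearity of the windowed mean).
#' @export
difference_wave <- function(post, pre) {
  if (!identical(post$channels, pre$channels) ||
      length(post$times) != length(pre$times) ||
      max(abs(post$times - pre$times)) > 1e-9) {
    stop("post and pre waveforms must share channel and time axes")
  }
  structure(list(data = post$data - pre$data, times = post$times,
                 channels = post$channels,
                 n_trials = min(post$n_trials, pre$n_trials),
                 group = post$group, session = "post-pre"),
            class = "erp_waveform")
}

#' Write a component amplitude table
#'
#' @param erp An `erp_waveform`.
#' @param path CSV path (columns `channel, component, amplitude_uv`).
#' @return The table invisibly.
#' @export
write_component_table <- function(erp, path = NULL) {
  cw <- component_windows()
  rows <- do.call(rbind, lapply(seq_len(nrow(cw)), function(i) {
    data.frame(channel = erp$channels, component = cw$label[i],
               amplitude_uv = vapply(erp$channels, function(ch)
                 component_amplitude(erp, cw$label[i], ch), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
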