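# EpochSet container: channels x time x trials with stimulus-locked time axis.

#' Construct an epoch set
#'
#' @param data Numeric array, channels x samples x trials (microvolts).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to stimulus onset
#'   (negative for pre-stimulus baseline).
#' @param channels Character vector of channel labels (length = dim 1).
#' @param group,session,kind Optional condition labels carried through the
#'   pipeline (`kind` is `"task"` or `"rest"`).
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, t0, channels,
                       group = NA_character_, session = NA_character_,
                       kind = "task") {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0,
            length(channels) == dim(data)[1])
  times <- t0 + (seq_len(dim(data)[2]) - 1L) / fs
  dimnames(data) <- list(channels, NULL, NULL)
  structure(list(data = data, fs = fs, times = times, channels = channels,
                 group = group, session = session, kind = kind),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %.3f .. %.3f s; group=%s session=%s kind=%s\n",
              min(x$times), max(x$times), x$group, x$session, x$kind))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[3]

#' Index of samples falling in a closed time interval
#'
#' @param times Numeric time axis in seconds.
#' @param interval Length-2 numeric `c(from, to)` in seconds, closed.
#' @return Integer indices.
#' @keywords internal
time_indices <- function(times, interval) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2])
  idx <- which(times >= interval[1] - 1e-12 & times <= interval[2] + 1e-12)
  if (length(idx) == 0) stop("interval [", interval[1], ", ", interval[2],
                             "] contains no samples of the time axis")
  idx
}

#' Save / load an epoch container
#'
#' Epoch sets are stored as an RDS payload next to a JSON metadata sidecar
#' (`<path>.json`) so the shape, sampling rate and labels of a stored
#' container can be inspected without loading the array.
#'
#' @param epochs An `eeg_epochs`.
#' @param path File path for the container.
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns the
#'   `eeg_epochs`.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(shape = dim(epochs$data), fs = epochs$fs,
               t0 = epochs$times[1], channels = epochs$channels,
               group = epochs$group, session = epochs$session,
               kind = epochs$kind)
  saveRDS(epochs, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eeg_epochs")) stop("not an epoch container: ", path)
  x
}
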