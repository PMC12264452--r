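# Phase-locking connectivity and binary graph-theory metrics.

#' Analytic signal via the frequency domain
#'
#' Discrete analytic signal: zero the negative-frequency half of the FFT,
#' double the positive half. The imaginary part is the Hilbert transform
#' of the input.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous band-limited phase
#'
#' Zero-phase FIR band-pass followed by the analytic-signal phase, per
#' channel and trial. The band-pass is a Hamming-windowed `fir1` design
#' (order about 1.5 cycles of the band's low edge) applied forward and
#' backward in the frequency domain (squared magnitude response, zero
#' phase), fused with the analytic-signal step into a single FFT pass per
#' segment. The frequency-domain application is circular; samples inside
#' the edge region (default 100 ms each side) are flagged invalid and
#' excluded from downstream phase-locking estimates.
#'
#' @param epochs An [eeg_epochs()].
#' @param band Band label from [eeg_bands()] or `c(low, high)` in Hz.
#' @param edge_s Edge length flagged on each side, seconds.
#' @return Object of class `eeg_phase`: list with `phase` (channels x
#'   samples x trials, radians), `valid` (logical over samples),
#'   `channels`, `band`, plus a `low_snr` flag when the band holds under
#'   5% of broadband variance.
#' @export
instantaneous_phase <- function(epochs, band, edge_s = 0.1) {
  band_label <- if (is.character(band)) band else paste0(band[1], "-", band[2], "Hz")
  if (is.character(band)) {
    b <- eeg_bands(); i <- match(band, b$band)
    if (is.na(i)) stop("unknown band: ", band)
    band <- c(b$low[i], b$high[i])
  }
  fs <- epochs$fs
  if (band[2] >= fs / 2) stop("band high edge must stay below Nyquist (fs/2)")
  n_s <- dim(epochs$data)[2]
  ord <- min(max(round(1.5 * fs / band[1]), 20), floor((n_s - 1) / 3))
  ord <- ord - ord %% 2  # even order -> symmetric (type I) FIR
  h <- signal::fir1(ord, band / (fs / 2), type = "pass")
  # squared magnitude response (forward-backward) on the segment's grid
  H2 <- Mod(stats::fft(c(h, rep(0, n_s - length(h)))))^2
  # analytic-signal multiplier
  ha <- numeric(n_s); ha[1] <- 1
  if (n_s %% 2 == 0) { ha[n_s / 2 + 1] <- 1; ha[2:(n_s / 2)] <- 2
  } else ha[2:((n_s + 1) / 2)] <- 2
  d <- dim(epochs$data)
  ph <- array(NA_real_, d)
  bp_var <- 0; tot_var <- 0
  for (tr in seq_len(d[3])) {
    m <- matrix(epochs$data[, , tr], nrow = d[1])
    X <- stats::mvfft(t(m))
    bp <- stats::mvfft(X * H2, inverse = TRUE) / n_s     # analytic after H2
    z <- stats::mvfft(X * (H2 * ha), inverse = TRUE) / n_s
    ph[, , tr] <- t(Arg(z))
    bp_var <- bp_var + sum(apply(Re(bp), 2, stats::var))
    tot_var <- tot_var + sum(apply(m, 1, stats::var))
  }
  edge_n <- round(edge_s * fs)
  valid <- rep(TRUE, n_s)
  if (edge_n > 0) {
    valid[seq_len(min(edge_n, n_s))] <- FALSE
    valid[seq.int(max(1L, n_s - edge_n + 1L), n_s)] <- FALSE
  }
  if (!any(valid)) stop("edge flagging removed every sample; shorten edge_s")
  structure(list(phase = ph, valid = valid, channels = epochs$channels,
                 band = band_label,
                 low_snr = tot_var > 0 && bp_var / tot_var < 0.05),
            class = "eeg_phase")
}

#' Phase-locking value matrix
#'
#' `PLV(i, j) = |mean_t exp(1i (phi_i - phi_j))|`, computed within each
#' trial/segment over the valid samples and averaged across segments.
#' Symmetric with zero diagonal by convention; entries lie in `[0, 1]`.
#'
#' @param phases An `eeg_phase`.
#' @return Object of class `plv_matrix`: channels x channels matrix with
#'   `band` attribute.
#' @export
plv_matrix <- function(phases) {
  d <- dim(phases$phase)
  if (d[1] < 2) stop("need at least 2 channels")
  vidx <- which(phases$valid)
  if (length(vidx) == 0) stop("all samples flagged invalid")
  acc <- matrix(0, d[1], d[1])
  for (tr in seq_len(d[3])) {
    e <- exp(1i * phases$phase[, vidx, tr, drop = FALSE][, , 1])
    acc <- acc + Mod(e %*% Conj(t(e))) / length(vidx)
  }
  plv <- acc / d[3]
  plv <- (plv + t(plv)) / 2
  plv[plv > 1] <- 1
  diag(plv) <- 0
  dimnames(plv) <- list(phases$channels, phases$channels)
  structure(plv, class = c("plv_matrix", "matrix"), band = phases$band)
}

#' Proportional threshold to a binary graph
#'
#' Keeps the strongest `density` fraction of the `n(n-1)/2` upper-triangle
#' weights as edges (count = `round(density * P)`), breaking ties
#' deterministically by weight, then by lexicographic node-pair index.
#'
#' @param m Symmetric weight matrix (e.g. a `plv_matrix`).
#' @param density Fraction of possible edges to keep, in `(0, 1]`.
#' @return Object of class `binary_graph`: 0/1 symmetric matrix with zero
#'   diagonal and a `density` attribute.
#' @export
proportional_threshold <- function(m, density = 0.30) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(m)
  iu <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  k <- round(density * length(w))
  ord <- order(-w, iu[, 1], iu[, 2])
  keep <- ord[seq_len(k)]
  a <- matrix(0L, n, n)
  a[cbind(iu[keep, 1], iu[keep, 2])] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(m)
  structure(a, class = c("binary_graph", "matrix"), density = density)
}

#' Small-world metrics of a binary graph
#'
#' Clustering coefficient `Cp` (mean over nodes of triangle density among
#' neighbours, 0 for degree < 2), characteristic path length `Lp` (mean
#' finite shortest-path length over distinct pairs, with a connectedness
#' flag when unreachable pairs were excluded), global efficiency `Eglob`
#' (mean inverse distance over distinct ordered pairs, 0 for unreachable),
#' and local efficiency `Eloc` (global efficiency of each node's
#' neighbour-induced subgraph; 0 for fewer than 2 neighbours).
#'
#' @param g A `binary_graph` (or any 0/1 symmetric adjacency matrix).
#' @return List: `cp`, `lp`, `eglob`, `eloc` (per-node vector),
#'   `eloc_mean`, `connected` (logical).
#' @export
graph_metrics <- function(g) {
  a <- unclass(g)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes")
  if (sum(a) == 0) {
    warning("empty graph: all metrics 0")
    return(list(cp = 0, lp = 0, eglob = 0, eloc = rep(0, n), eloc_mean = 0,
                connected = FALSE))
  }
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  deg <- rowSums(a)
  cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  dmat <- igraph::distances(ig)
  off <- dmat[upper.tri(dmat)]
  finite <- is.finite(off)
  lp <- if (any(finite)) mean(off[finite]) else 0
  inv <- ifelse(is.finite(dmat) & dmat > 0, 1 / dmat, 0)
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    subg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    ds <- igraph::distances(subg)
    m <- length(nb)
    sum(ifelse(is.finite(ds) & ds > 0, 1 / ds, 0)) / (m * (m - 1))
  }, numeric(1))
  list(cp = mean(cc), lp = lp, eglob = eglob, eloc = eloc,
       eloc_mean = mean(eloc), connected = all(finite))
}

#' Mean phase-locking value
#'
#' Mean of the off-diagonal upper triangle -- the whole-matrix summary
#' compared pre vs post per band.
#'
#' @param m A `plv_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
mean_plv <- function(m) mean(m[upper.tri(m)])

#' Write a connectivity matrix as labelled CSV
#'
#' @param m Square matrix with channel dimnames.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(as.matrix(m)), path, row.names = TRUE)
  invisible(path)
}
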