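# Synthetic EEG + 2-back behavior generator.
#
# Emulates a five-arm pre/post stimulation study: per subject and session it
# produces task epochs (1/f background + event-related band-limited bursts +
# stimulus-locked ERP deflections), resting epochs (stationary oscillations
# with configurable inter-channel phase coupling), and a 2-back behavioral
# session. Group-by-session effects are injected through multiplicative /
# additive deltas so that every downstream stage has known ground truth.

#' Frequency bands of interest
#'
#' Conventional EEG band partition used throughout the pipeline: theta 4-8,
#' alpha 8-13, beta1 13-20, beta2 20-30, gamma 30-80 Hz. Band membership of
#' a frequency bin is half-open (`[low, high)`) except the upper edge of
#' gamma, which is closed, so bins are never counted twice.
#'
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta1", "beta2", "gamma"),
             low = c(4, 8, 13, 20, 30),
             high = c(8, 13, 20, 30, 80),
             stringsAsFactors = FALSE)
}

#' Zero effect deltas
#'
#' Explicit no-effect template: every group must state its deltas, absent
#' groups are an error rather than an implicit zero.
#' @return List with zeroed `erp_uv`, `band_db`, `plv`, `rt_s` entries.
#' @export
zero_deltas <- function() {
  list(erp_uv = c(N100 = 0, P150 = 0, N200 = 0, P300 = 0),
       band_db = c(theta = 0, alpha = 0, beta1 = 0, beta2 = 0, gamma = 0),
       plv = c(theta = 0, alpha = 0, beta1 = 0),
       rt_s = 0)
}

merge_delta <- function(delta) {
  z <- zero_deltas()
  for (nm in names(delta)) {
    if (nm == "rt_s") z$rt_s <- delta$rt_s
    else z[[nm]][names(delta[[nm]])] <- delta[[nm]]
  }
  z
}

#' Simulation configuration
#'
#' Default values reproduce the study conditions the pipeline is built for:
#' 1000 Hz sampling, epochs from -200 to 800 ms around the stimulus, 150
#' 2-back trials with 30% targets, five stimulation arms (1/5/10/20 Hz and
#' sham) of 30 subjects each, pre-stimulation reaction-time distributions
#' per arm, and post-session effects concentrated in the 5 Hz arm (P150
#' amplitude up, theta/alpha band power up, theta phase coupling up,
#' reaction time down). All arms, including sham, share a small
#' reaction-time practice gain. Reduced sizes (channels, trials, sampling
#' rate, subjects) can be requested for fast replication runs.
#'
#' @param n_channels Montage size (includes FC1/FCz/FC2; >= 4).
#' @param fs Sampling rate, Hz.
#' @param epoch_window Length-2 seconds relative to stimulus onset; must
#'   cover the baseline (-0.2..0) and analysis (0.05..0.35) windows.
#' @param n_trials Task trials per session.
#' @param target_frac 2-back target fraction, in (0, 1).
#' @param n_rest_segments Resting segments per session.
#' @param rest_segment_s Resting segment length, seconds.
#' @param noise_exponent Spectral slope of the 1/f background.
#' @param noise_sd Background noise standard deviation, microvolts.
#' @param band_amp_uv Named amplitudes (microvolts) of event-related band
#'   bursts (task) / stationary oscillations (rest).
#' @param erp_components Data frame `label, latency_s, sigma_s, amp_uv,
#'   center` of Gaussian-windowed deflections.
#' @param plv_groups Per-band list of `channels` (coupled set) and `plv`
#'   (target phase-locking value in `[0, 1]`).
#' @param coupling_amp_uv Amplitude of the coupled narrowband component.
#' @param hit_rate,fa_rate 2-back hit and false-alarm probabilities.
#' @param rt_shift_s Shift of the shifted-lognormal reaction-time model.
#' @param rt_trial_sdlog Trial-level lognormal sd (log scale).
#' @param groups Arm labels.
#' @param rt_pre_mean_s,rt_pre_sd_s Per-arm subject-mean reaction-time
#'   distribution before stimulation (mean and between-subject sd).
#' @param effect_deltas Named per-arm list of post-session effects:
#'   `erp_uv` (additive component amplitude, microvolts), `band_db`
#'   (band-power change, dB), `plv` (additive phase-locking change),
#'   `rt_s` (additive reaction-time change, seconds; negative = faster).
#'   Every arm in `groups` must appear (use [zero_deltas()]).
#' @param n_subjects Subjects per arm.
#' @param seed Base RNG seed; all subject-level seeds derive from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_channels = 32,
                       fs = 1000,
                       epoch_window = c(-0.2, 0.8),
                       n_trials = 150,
                       target_frac = 0.30,
                       n_rest_segments = 30,
                       rest_segment_s = 2,
                       noise_exponent = 1,
                       noise_sd = 8,
                       band_amp_uv = c(theta = 2.5, alpha = 3, beta1 = 1.2,
                                       beta2 = 0.8, gamma = 0.5),
                       erp_components = default_erp_components(),
                       plv_groups = default_plv_groups(),
                       coupling_amp_uv = 2,
                       hit_rate = 0.88,
                       fa_rate = 0.06,
                       rt_shift_s = 0.30,
                       rt_trial_sdlog = 0.25,
                       groups = c("rTMS1", "rTMS5", "rTMS10", "rTMS20", "sham"),
                       rt_pre_mean_s = c(rTMS1 = 0.793, rTMS5 = 0.778,
                                         rTMS10 = 0.844, rTMS20 = 0.807,
                                         sham = 0.812),
                       rt_pre_sd_s = c(rTMS1 = 0.163, rTMS5 = 0.124,
                                       rTMS10 = 0.177, rTMS20 = 0.145,
                                       sham = 0.195),
                       effect_deltas = default_effect_deltas(),
                       n_subjects = 30,
                       seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (n_channels < 4) stop("n_channels must be at least 4")
  if (epoch_window[1] > -0.2 + 1e-9 || epoch_window[2] < 0.35 - 1e-9) {
    stop("epoch_window must cover the baseline (-0.2..0 s) and the ",
         "analysis window (0.05..0.35 s)")
  }
  if (any(band_amp_uv < 0) || noise_sd < 0) stop("amplitudes must be >= 0")
  if (!(target_frac > 0 && target_frac < 1)) {
    stop("target_frac must lie strictly between 0 and 1")
  }
  missing_groups <- setdiff(groups, names(effect_deltas))
  if (length(missing_groups)) {
    stop("effect_deltas missing for group(s): ",
         paste(missing_groups, collapse = ", "),
         " (explicit zeros required, see zero_deltas())")
  }
  for (g in names(plv_groups)) {
    p <- plv_groups[[g]]$plv
    if (p < 0 || p > 1) stop("target PLV must be in [0, 1]")
  }
  effect_deltas <- lapply(effect_deltas, merge_delta)
  cfg <- list(n_channels = n_channels, fs = fs, epoch_window = epoch_window,
              n_trials = n_trials, target_frac = target_frac,
              n_rest_segments = n_rest_segments,
              rest_segment_s = rest_segment_s,
              noise_exponent = noise_exponent, noise_sd = noise_sd,
              band_amp_uv = band_amp_uv, erp_components = erp_components,
              plv_groups = plv_groups, coupling_amp_uv = coupling_amp_uv,
              hit_rate = hit_rate, fa_rate = fa_rate,
              rt_shift_s = rt_shift_s, rt_trial_sdlog = rt_trial_sdlog,
              groups = groups, rt_pre_mean_s = rt_pre_mean_s,
              rt_pre_sd_s = rt_pre_sd_s, effect_deltas = effect_deltas,
              n_subjects = n_subjects, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default ERP component templates
#'
#' Four canonical working-memory components as Gaussian-windowed
#' deflections whose peaks sit inside the standard reporting windows
#' (N100 75-125, P150 130-190, N200 210-290, P300 280-380 ms), centered on
#' the frontal-central electrodes.
#' @return Data frame `label, latency_s, sigma_s, amp_uv, center`.
#' @export
default_erp_components <- function() {
  data.frame(label = c("N100", "P150", "N200", "P300"),
             latency_s = c(0.100, 0.160, 0.250, 0.330),
             sigma_s = c(0.012, 0.015, 0.020, 0.030),
             amp_uv = c(-4, 5, -4, 6),
             center = c("FCz", "FCz", "FCz", "Cz"),
             stringsAsFactors = FALSE)
}

#' Default phase-coupling targets
#'
#' Long-range theta coupling over a fronto-parietal network and alpha
#' coupling over a parieto-occipital set, with moderate baseline phase
#' locking on top of the spatially local resting-state lattice.
#' @return Per-band list of `channels` and target `plv`.
#' @export
default_plv_groups <- function() {
  list(theta = list(channels = c("FC1", "FCz", "FC2", "Fz", "F3", "F4",
                                 "Pz", "P3", "P4"),
                    plv = 0.05),
       alpha = list(channels = c("Pz", "P3", "P4", "POz", "O1", "O2"),
                    plv = 0.05))
}

#' Default per-arm effects
#'
#' The 5 Hz arm carries the electrophysiological effects (P150 +2
#' microvolts, theta +0.8 dB, alpha +1 dB, theta-PLV +0.15) together with
#' the largest reaction-time gain; the other arms, including sham, carry
#' only their reaction-time change (practice gain for sham).
#' @return Named list of per-arm delta lists.
#' @export
default_effect_deltas <- function() {
  list(
    rTMS1 = list(rt_s = -0.106),
    rTMS5 = list(erp_uv = c(P150 = 2),
                 band_db = c(theta = 0.8, alpha = 1),
                 plv = c(theta = 0.15),
                 rt_s = -0.112),
    rTMS10 = list(rt_s = -0.072),
    rTMS20 = list(rt_s = -0.093),
    sham = list(rt_s = -0.051)
  )
}

# ---- signal building blocks ------------------------------------------------

# 1/f-shaped Gaussian noise, one column per independent realization.
# Spectral shaping: FFT of white noise multiplied by f^(-exponent/2).
onef_noise <- function(n_samples, n_series, fs, exponent, sd_target) {
  if (sd_target == 0) return(matrix(0, n_samples, n_series))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror for negative frequencies
  shape <- c(0, f[-1]^(-exponent / 2))  # kill DC
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n_samples
  sds <- apply(x, 2, stats::sd)
  sweep(x, 2, ifelse(sds > 0, sds, 1), "/") * sd_target
}

# Narrowband unit-sd Gaussian noise (FFT brick-wall in [low, high] Hz).
narrowband_noise <- function(n_samples, n_series, fs, low, high) {
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  fm <- ifelse(f > fs / 2, fs - f, f)
  mask <- as.numeric(fm >= low & fm <= high)
  x <- Re(stats::mvfft(stats::mvfft(w) * mask, inverse = TRUE)) / n_samples
  sds <- apply(x, 2, stats::sd)
  sweep(x, 2, ifelse(sds > 0, sds, 1), "/")
}

# Fraction of the 1/f background power that falls inside [low, high],
# matching the spectral shaping used by onef_noise.
band_noise_fraction <- function(n_samples, fs, exponent, low, high) {
  f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  fm <- ifelse(f > fs / 2, fs - f, f)
  shape2 <- c(0, fm[-1]^(-exponent))
  sum(shape2[fm >= low & fm <= high]) / sum(shape2)
}

band_center <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  if (is.na(i)) stop("unknown band: ", band)
  (b$low[i] + b$high[i]) / 2
}

#' Generate one set of EEG epochs
#'
#' Task epochs are the sum of 1/f background noise, event-related
#' band-limited bursts (Gaussian temporal envelope over the post-stimulus
#' interval, random phase per channel and trial), deterministic
#' Gaussian-windowed ERP deflections with spatial topography, and -- for
#' bands with configured coupling -- a shared narrowband carrier mixed with
#' channel-independent narrowband noise. Resting epochs drop the ERP and
#' use stationary oscillations instead of bursts; their "trials" are
#' non-overlapping segments.
#'
#' The mixing weight of the shared carrier is `sqrt(plv)`, an empirical
#' calibration for which the measured phase-locking value of the coupled
#' set approximates the configured target.
#'
#' Deterministic given the RNG state: seed the session RNG (or use
#' [generate_study()], which derives per-subject seeds) for reproducible
#' arrays.
#'
#' @param cfg A [sim_config()].
#' @param group Arm label (for post-session effect lookup).
#' @param session `"pre"` or `"post"`.
#' @param kind `"task"` or `"rest"`.
#' @param montage Optional pre-built montage (defaults to
#'   `generate_montage(cfg$n_channels)`).
#' @return An [eeg_epochs()].
#' @export
generate_epochs <- function(cfg, group = "sham", session = "pre",
                            kind = c("task", "rest"), montage = NULL) {
  kind <- match.arg(kind)
  if (is.null(montage)) montage <- generate_montage(cfg$n_channels)
  delta <- if (session == "post") cfg$effect_deltas[[group]] else merge_delta(list())
  if (is.null(delta)) stop("no effect_deltas configured for group ", group)
  fs <- cfg$fs
  if (kind == "task") {
    t0 <- cfg$epoch_window[1]
    n_s <- round((cfg$epoch_window[2] - cfg$epoch_window[1]) * fs) + 1L
    n_tr <- cfg$n_trials
  } else {
    t0 <- 0
    n_s <- round(cfg$rest_segment_s * fs)
    n_tr <- cfg$n_rest_segments
  }
  times <- t0 + (seq_len(n_s) - 1L) / fs
  n_ch <- nrow(montage)
  x <- array(0, dim = c(n_ch, n_s, n_tr))

  # background noise
  if (cfg$noise_sd > 0) {
    ns <- onef_noise(n_s, n_ch * n_tr, fs, cfg$noise_exponent, cfg$noise_sd)
    x <- x + array(t(ns), dim = c(n_ch, n_s, n_tr))
  }

  bands <- eeg_bands()
  if (kind == "task") {
    # event-related band bursts: Gaussian envelope over the post-stimulus
    # interval, sinusoid with random phase per channel and trial (induced,
    # not stimulus-locked)
    env <- exp(-(times - 0.2)^2 / (2 * 0.08^2))
    for (bi in seq_len(nrow(bands))) {
      b <- bands$band[bi]
      amp <- cfg$band_amp_uv[[b]]
      if (is.na(amp) || amp == 0) next
      amp <- amp * 10^(delta$band_db[[b]] / 20)
      fc <- band_center(b)
      ph <- matrix(stats::runif(n_ch * n_tr, 0, 2 * pi), n_ch, n_tr)
      for (tr in seq_len(n_tr)) {
        osc <- sin(outer(ph[, tr], 2 * pi * fc * times, "+"))
        x[, , tr] <- x[, , tr] + amp * sweep(osc, 2, env, "*")
      }
    }
    # ERP components, deterministic across trials; additive delta acts on
    # the signed amplitude
    for (ci in seq_len(nrow(cfg$erp_components))) {
      comp <- cfg$erp_components[ci, ]
      amp <- comp$amp_uv + delta$erp_uv[[comp$label]]
      if (amp == 0) next
      w <- topography_weights(montage, comp$center)
      shape <- exp(-(times - comp$latency_s)^2 / (2 * comp$sigma_s^2))
      bump <- amp * outer(w, shape)
      for (tr in seq_len(n_tr)) x[, , tr] <- x[, , tr] + bump
    }
    # phase coupling in task data: additive shared narrowband carrier
    for (b in names(cfg$plv_groups)) {
      grp <- cfg$plv_groups[[b]]
      target <- min(1, max(0, grp$plv + delta$plv[[b]]))
      chans <- intersect(grp$channels, montage$label)
      if (length(chans) < 2 || cfg$coupling_amp_uv == 0 || target == 0) next
      i <- match(b, bands$band)
      wmix <- sqrt(target)
      idx <- match(chans, montage$label)
      for (tr in seq_len(n_tr)) {
        nb <- narrowband_noise(n_s, length(chans) + 1L, fs,
                               bands$low[i], bands$high[i])
        mixed <- wmix * nb[, 1] + sqrt(1 - wmix^2) * nb[, -1, drop = FALSE]
        x[idx, , tr] <- x[idx, , tr] + cfg$coupling_amp_uv * t(mixed)
      }
    }
  } else {
    # resting state: stationary narrowband Gaussian oscillations whose
    # phase drifts. Baseline connectivity is spatially local: each
    # channel's oscillation is a distance-weighted mixture of neighbouring
    # sources (a volume-conduction-like lattice, so nearby electrodes
    # phase-lock strongly and distant ones sit at the finite-sample
    # floor). Channels of a configured coupled set additionally share a
    # long-range common carrier with mixing weight sqrt(target PLV), so
    # raising the target adds long-range synchrony on top of the lattice.
    dmat <- as.matrix(stats::dist(montage[, c("x", "y")]))
    K <- exp(-dmat^2 / (2 * 0.35^2))
    K <- K / sqrt(rowSums(K^2))          # unit-variance local mixtures
    for (bi in seq_len(nrow(bands))) {
      b <- bands$band[bi]
      amp <- cfg$band_amp_uv[[b]]
      if (is.na(amp) || amp == 0) next
      amp <- amp * 10^(delta$band_db[[b]] / 20)
      grp <- cfg$plv_groups[[b]]
      coupled <- if (is.null(grp)) character(0)
                 else intersect(grp$channels, montage$label)
      target <- if (is.null(grp)) 0
                else min(1, max(0, grp$plv + delta$plv[[b]]))
      # Long-range synchrony trades against the local lattice: each
      # channel gives a variance fraction v to a carrier component -- the
      # shared carrier at full weight on the coupled set, with a weaker
      # spillover everywhere else (scalp synchrony spreads beyond the
      # focal network). Raising the coupling target both strengthens
      # coupled-pair locking and flattens the local distance gradient,
      # the signature of a more globally integrated network. The carrier
      # weight compensates for in-band 1/f noise so the effective
      # coupled-pair correlation approximates the configured target.
      spill <- 0.6
      p_noise <- cfg$noise_sd^2 *
        band_noise_fraction(n_s, fs, cfg$noise_exponent,
                            bands$low[bi], bands$high[bi])
      kappa <- amp^2 / (amp^2 + p_noise)
      v <- min(1, target / kappa)
      cidx <- match(coupled, montage$label)
      for (tr in seq_len(n_tr)) {
        nb <- narrowband_noise(n_s, 2L * n_ch + 1L, fs,
                               bands$low[bi], bands$high[bi])
        latt <- t(nb[, 1L + seq_len(n_ch), drop = FALSE] %*% t(K))
        if (length(cidx) >= 2 && v > 0) {
          wch <- rep(spill, n_ch)
          wch[cidx] <- 1
          carrier <- wch * matrix(nb[, 1], n_ch, n_s, byrow = TRUE) +
            sqrt(1 - wch^2) * t(nb[, 1L + n_ch + seq_len(n_ch), drop = FALSE])
          osc <- sqrt(1 - v) * latt + sqrt(v) * carrier
        } else {
          osc <- latt
        }
        x[, , tr] <- x[, , tr] + amp * osc
      }
    }
  }

  eeg_epochs(x, fs = fs, t0 = t0, channels = montage$label,
             group = group, session = session, kind = kind)
}

#' Generate one 2-back behavioral session
#'
#' Letters A-J are drawn uniformly subject to the 2-back constraint: target
#' trials repeat the letter shown two trials earlier, non-target trials are
#' forced to differ from it. The number of targets is the target fraction
#' rounded to the nearest trial. Responses follow configured hit and
#' false-alarm rates; reaction times follow a shifted lognormal whose mean
#' is `rt_mean_s` (plus the arm's post-session shift when
#' `session = "post"`).
#'
#' @param cfg A [sim_config()].
#' @param group Arm label.
#' @param session `"pre"` or `"post"`.
#' @param rt_mean_s Subject-level mean reaction time before any session
#'   shift; defaults to the arm's configured pre mean.
#' @return Object of class `behavior_session`: data frame
#'   `trial, letter, is_target, response, rt_s` with `group`/`session`
#'   attributes.
#' @export
generate_behavior <- function(cfg, group = "sham", session = "pre",
                              rt_mean_s = NULL) {
  n <- cfg$n_trials
  if (n < 10) stop("n_trials must be at least 10")
  if (!(cfg$target_frac > 0 && cfg$target_frac < 1)) {
    stop("target fraction must lie strictly in (0, 1)")
  }
  n_targets <- round(cfg$target_frac * n)
  # targets only possible from trial 3 onward
  target_pos <- sort(sample(3:n, n_targets))
  letters10 <- LETTERS[1:10]
  letter <- character(n)
  for (i in seq_len(n)) {
    if (i %in% target_pos) {
      letter[i] <- letter[i - 2]
    } else if (i > 2) {
      letter[i] <- sample(setdiff(letters10, letter[i - 2]), 1)
    } else {
      letter[i] <- sample(letters10, 1)
    }
  }
  is_target <- seq_len(n) %in% target_pos
  response <- logical(n)
  response[is_target] <- stats::runif(n_targets) < cfg$hit_rate
  response[!is_target] <- stats::runif(n - n_targets) < cfg$fa_rate

  if (is.null(rt_mean_s)) rt_mean_s <- cfg$rt_pre_mean_s[[group]]
  delta <- cfg$effect_deltas[[group]]
  if (is.null(delta)) stop("no effect_deltas configured for group ", group)
  m <- rt_mean_s + if (session == "post") delta$rt_s else 0
  mu_body <- m - cfg$rt_shift_s
  if (mu_body <= 0) stop("reaction-time mean below the shift parameter")
  meanlog <- log(mu_body) - cfg$rt_trial_sdlog^2 / 2
  rt <- cfg$rt_shift_s + stats::rlnorm(n, meanlog, cfg$rt_trial_sdlog)

  out <- data.frame(trial = seq_len(n), letter = letter,
                    is_target = is_target, response = response,
                    rt_s = rt, stringsAsFactors = FALSE)
  structure(out, class = c("behavior_session", "data.frame"),
            group = group, session = session)
}

subject_seed <- function(base_seed, group_index, subject_index) {
  as.integer((as.numeric(base_seed) * 7919 + group_index * 104729 +
                subject_index * 1299709) %% 2147483629)
}

#' Generate one subject's full record
#'
#' Derives a deterministic per-subject seed from the configuration seed,
#' then draws the subject's pre/post task epochs, resting epochs, and
#' behavioral sessions in a fixed order, so any subject can be regenerated
#' independently of the rest of the study.
#'
#' @param cfg A [sim_config()].
#' @param group Arm label.
#' @param subject_index Subject number within the arm.
#' @param montage Optional pre-built montage.
#' @param what Which records to generate (subset of
#'   `c("task", "rest", "behavior")`); skipping the EEG keeps behavioral
#'   simulations cheap.
#' @return List with elements `task`, `rest` (each `list(pre =, post =)` of
#'   [eeg_epochs()]) and `behavior` (`list(pre =, post =)`), plus `group`
#'   and `subject`.
#' @export
generate_subject <- function(cfg, group, subject_index, montage = NULL,
                             what = c("task", "rest", "behavior")) {
  gi <- match(group, cfg$groups)
  if (is.na(gi)) stop("unknown group: ", group)
  if (is.null(montage)) montage <- generate_montage(cfg$n_channels)
  set.seed(subject_seed(cfg$seed, gi, subject_index))
  rt_subj <- stats::rnorm(1, cfg$rt_pre_mean_s[[group]], cfg$rt_pre_sd_s[[group]])
  # keep the subject's mean above the lognormal shift even after the most
  # negative session effect
  rt_floor <- cfg$rt_shift_s + 0.05 - min(0, cfg$effect_deltas[[group]]$rt_s)
  rt_subj <- max(rt_subj, rt_floor)
  rec <- list(group = group, subject = subject_index)
  if ("task" %in% what) {
    rec$task <- list(pre = generate_epochs(cfg, group, "pre", "task", montage),
                     post = generate_epochs(cfg, group, "post", "task", montage))
  }
  if ("rest" %in% what) {
    rec$rest <- list(pre = generate_epochs(cfg, group, "pre", "rest", montage),
                     post = generate_epochs(cfg, group, "post", "rest", montage))
  }
  if ("behavior" %in% what) {
    rec$behavior <- list(pre = generate_behavior(cfg, group, "pre", rt_subj),
                         post = generate_behavior(cfg, group, "post", rt_subj))
  }
  rec
}

#' Generate a full synthetic study
#'
#' All arms, all subjects, pre and post sessions. Memory scales with
#' `n_subjects * n_channels * samples * trials`; for large configurations
#' prefer streaming subject-by-subject via [generate_subject()] (as
#' [run_study()] does).
#'
#' @param cfg A [sim_config()].
#' @param what Records to generate per subject (see [generate_subject()]).
#' @return Object of class `wm_study`: list with `config`, `montage`, and
#'   `subjects` (list of subject records).
#' @export
generate_study <- function(cfg, what = c("task", "rest", "behavior")) {
  montage <- generate_montage(cfg$n_channels)
  subjects <- list()
  for (g in cfg$groups) {
    for (s in seq_len(cfg$n_subjects)) {
      subjects[[length(subjects) + 1L]] <-
        generate_subject(cfg, g, s, montage, what)
    }
  }
  structure(list(config = cfg, montage = montage, subjects = subjects),
            class = "wm_study")
}

#' Read / write behavioral sessions as CSV
#'
#' Columns: `trial, letter, is_target, response, rt_s, group, session`.
#'
#' @param session A `behavior_session`.
#' @param path CSV path.
#' @return `write_behavior_csv` returns `path` invisibly;
#'   `read_behavior_csv` returns a `behavior_session`.
#' @export
write_behavior_csv <- function(session, path) {
  df <- as.data.frame(session)
  df$group <- attr(session, "group")
  df$session <- attr(session, "session")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "letter", "is_target", "response", "rt_s")
  if (!all(need %in% names(df))) {
    stop("behavioral CSV must contain columns: ", paste(need, collapse = ", "))
  }
  structure(df[, need], class = c("behavior_session", "data.frame"),
            group = if ("group" %in% names(df)) df$group[1] else NA_character_,
            session = if ("session" %in% names(df)) df$session[1] else NA_character_)
}
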