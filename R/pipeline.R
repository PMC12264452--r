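# End-to-end study analysis: behavior -> ERP -> time-frequency ->
# connectivity -> statistics, on synthetic or user-supplied data.

#' Study analysis configuration
#'
#' Bundles the simulation configuration with the per-stage analysis
#' parameters. Validated up front; serializable to JSON and back
#' ([write_study_config()]).
#'
#' @param sim A [sim_config()].
#' @param n_perm Permutations per cluster test.
#' @param cf_alpha Cluster-forming pointwise alpha (two-sided).
#' @param cluster_alpha Per-tail cluster alpha (0.025 = two-tailed 0.05).
#' @param density Proportional threshold for binary graphs.
#' @param bands Bands analysed in the time-frequency stage.
#' @param rest_bands Bands analysed in the resting-network stage.
#' @param tfr_freqs Frequency grid of the spectrogram.
#' @param tfr_step_ms Spectrogram time step, ms.
#' @param analysis_window Oscillatory-power analysis window, seconds.
#' @param baseline Baseline interval, seconds.
#' @param preprocess Run the filtering/artifact-rejection stage.
#' @param include Pipeline sections to run (subset of
#'   `c("behavior", "erp", "tfr", "network")`); dropping `"network"`
#'   skips the resting recordings entirely.
#' @param reference Reference arm for between-group comparisons.
#' @return Object of class `study_config`.
#' @export
study_config <- function(sim = sim_config(),
                         n_perm = 5000,
                         cf_alpha = 0.05,
                         cluster_alpha = 0.025,
                         density = 0.30,
                         bands = c("theta", "alpha", "beta1"),
                         rest_bands = c("theta", "alpha"),
                         tfr_freqs = seq(3, 80, by = 0.5),
                         tfr_step_ms = 10,
                         analysis_window = c(0.05, 0.35),
                         baseline = c(-0.2, 0),
                         preprocess = TRUE,
                         include = c("behavior", "erp", "tfr", "network"),
                         reference = "sham") {
  stopifnot(inherits(sim, "sim_config"))
  known <- eeg_bands()$band
  bad <- setdiff(c(bands, rest_bands), known)
  if (length(bad)) stop("undefined band(s): ", paste(bad, collapse = ", "))
  if (!reference %in% sim$groups) stop("reference arm not among groups")
  if (!all(include %in% c("behavior", "erp", "tfr", "network"))) {
    stop("unknown pipeline section in include")
  }
  structure(list(sim = sim, n_perm = n_perm, cf_alpha = cf_alpha,
                 cluster_alpha = cluster_alpha, density = density,
                 bands = bands, rest_bands = rest_bands,
                 tfr_freqs = tfr_freqs, tfr_step_ms = tfr_step_ms,
                 analysis_window = analysis_window, baseline = baseline,
                 preprocess = preprocess, include = include,
                 reference = reference),
            class = "study_config")
}

#' Serialize / restore a study configuration
#'
#' JSON round-trip: `read_study_config(write_study_config(cfg, path))`
#' reproduces the effective parameters exactly.
#'
#' @param cfg A [study_config()].
#' @param path JSON path.
#' @export
write_study_config <- function(cfg, path) {
  payload <- unclass(cfg)
  sim <- unclass(payload$sim)
  # jsonlite drops names of atomic vectors; store named vectors as objects
  for (f in c("band_amp_uv", "rt_pre_mean_s", "rt_pre_sd_s")) {
    sim[[f]] <- as.list(sim[[f]])
  }
  sim$effect_deltas <- lapply(sim$effect_deltas, function(d) {
    d[c("erp_uv", "band_db", "plv")] <-
      lapply(d[c("erp_uv", "band_db", "plv")], as.list)
    d
  })
  payload$sim <- sim
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- p$sim
  sim_args$band_amp_uv <- unlist(sim_args$band_amp_uv)
  sim_args$rt_pre_mean_s <- unlist(sim_args$rt_pre_mean_s)
  sim_args$rt_pre_sd_s <- unlist(sim_args$rt_pre_sd_s)
  sim_args$effect_deltas <- lapply(sim_args$effect_deltas, function(d) {
    d[c("erp_uv", "band_db", "plv")] <-
      lapply(d[c("erp_uv", "band_db", "plv")], unlist)
    d
  })
  sim_args$plv_groups <- lapply(sim_args$plv_groups, function(g)
    list(channels = unlist(g$channels), plv = g$plv))
  sim <- do.call(sim_config, sim_args)
  p$sim <- NULL
  do.call(study_config, c(list(sim = sim), p))
}

subject_features <- function(cfg, group, s, montage, adjacency) {
  # one subject, fully reduced: no raw arrays survive this function
  sim <- cfg$sim
  what <- c(if (any(c("erp", "tfr") %in% cfg$include)) "task",
            if ("network" %in% cfg$include) "rest",
            if ("behavior" %in% cfg$include) "behavior")
  rec <- generate_subject(sim, group, s, montage, what = what)
  out <- list(group = group, subject = s)

  if ("behavior" %in% cfg$include) {
    sc_pre <- score_session(rec$behavior$pre)
    sc_post <- score_session(rec$behavior$post)
    out$behavior <- list(
      rt_pre = sc_pre$mean_rt, rt_post = sc_post$mean_rt,
      dprime_pre = sc_pre$dprime, dprime_post = sc_post$dprime,
      x = change_index(sc_pre$mean_rt, sc_post$mean_rt)$x)
  }
  if (any(c("erp", "tfr") %in% cfg$include)) {
    task <- rec$task
    if (cfg$preprocess) {
      task <- lapply(task, preprocess_epochs)
    }
    if ("erp" %in% cfg$include) {
      erps <- lapply(task, average_erp, baseline = cfg$baseline)
      out$erp_map <- lapply(erps, `[[`, "data")
      out$erp_times <- erps$pre$times
      cw <- component_windows()
      out$components <- lapply(erps, function(e)
        vapply(cw$label, function(l) component_amplitude(e, l), numeric(1)))
    }
    if ("tfr" %in% cfg$include) {
      tfrs <- lapply(task, function(ep)
        baseline_db(tfr_hanning(ep, freqs = cfg$tfr_freqs,
                                step_ms = cfg$tfr_step_ms),
                    baseline = cfg$baseline))
      out$band_map <- lapply(tfrs, function(tf) {
        tsel <- tf$times >= cfg$analysis_window[1] - 1e-9 &
          tf$times <= cfg$analysis_window[2] + 1e-9
        lapply(stats::setNames(cfg$bands, cfg$bands), function(b)
          band_timecourse(tf, b)[, tsel, drop = FALSE])
      })
      out$band_mean <- lapply(tfrs, function(tf)
        vapply(stats::setNames(cfg$bands, cfg$bands), function(b)
          mean(band_average(tf, b, cfg$analysis_window)[
            intersect(c("FC1", "FCz", "FC2"), tf$channels)]), numeric(1)))
    }
  }
  if ("network" %in% cfg$include) {
    out$network <- lapply(rec$rest, function(ep) {
      lapply(stats::setNames(cfg$rest_bands, cfg$rest_bands), function(b) {
        ph <- instantaneous_phase(ep, b)
        plv <- plv_matrix(ph)
        gm <- graph_metrics(proportional_threshold(plv, cfg$density))
        list(mean_plv = mean_plv(plv), cp = gm$cp, lp = gm$lp,
             eglob = gm$eglob, eloc_mean = gm$eloc_mean)
      })
    })
  }
  out
}

group_array <- function(feats, field, session) {
  # stack per-subject channel x time maps into subjects x channels x time
  maps <- lapply(feats, function(f) f[[field]][[session]])
  arr <- array(0, dim = c(length(maps), dim(maps[[1]])))
  for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]
  arr
}

#' Run the full study analysis
#'
#' Generates (or streams) every subject, reduces each to behavioral
#' scores, ERP maps and component amplitudes, band-power maps, and
#' resting-network metrics, then runs the statistical layer: within-group
#' pre/post cluster tests, between-group tests of the post-minus-pre
#' difference against the reference arm (independent-design cluster tests
#' on subject difference maps), ANOVA with Bonferroni/FDR-corrected
#' pairwise comparisons, paired tests with FDR over the network metrics,
#' and per-arm correlations between electrophysiological and behavioral
#' change. Fully deterministic for a fixed configuration seed.
#'
#' @param cfg A [study_config()].
#' @param progress Print per-stage progress lines.
#' @return Object of class `study_report` (nested list; see the vignette).
#' @export
run_study <- function(cfg, progress = FALSE) {
  sim <- cfg$sim
  montage <- generate_montage(sim$n_channels)
  adjacency <- channel_adjacency(montage)
  say <- function(...) if (progress) message(sprintf(...))

  feats <- list()
  for (g in sim$groups) {
    say("features: group %s", g)
    for (s in seq_len(sim$n_subjects)) {
      feats[[length(feats) + 1L]] <- subject_features(cfg, g, s, montage,
                                                      adjacency)
    }
  }
  groups_of <- vapply(feats, `[[`, character(1), "group")
  report <- list(config = cfg, montage = montage,
                 groups = sim$groups, n_subjects = sim$n_subjects)
  ref <- cfg$reference

  if ("behavior" %in% cfg$include) {
    say("stats: behavior")
    beh <- do.call(rbind, lapply(feats, function(f)
      data.frame(group = f$group, subject = f$subject,
                 rt_pre = f$behavior$rt_pre, rt_post = f$behavior$rt_post,
                 rt_diff = f$behavior$rt_pre - f$behavior$rt_post,
                 x = f$behavior$x,
                 dprime_pre = f$behavior$dprime_pre,
                 dprime_post = f$behavior$dprime_post)))
    summary_tab <- do.call(rbind, lapply(split(beh, beh$group), function(d)
      data.frame(group = d$group[1], n = nrow(d),
                 rt_pre_mean = mean(d$rt_pre), rt_pre_sd = stats::sd(d$rt_pre),
                 rt_post_mean = mean(d$rt_post),
                 rt_post_sd = stats::sd(d$rt_post),
                 rt_diff_mean = mean(d$rt_diff), x_mean = mean(d$x),
                 dprime_pre_mean = mean(d$dprime_pre),
                 dprime_post_mean = mean(d$dprime_post))))
    summary_tab <- summary_tab[match(sim$groups, summary_tab$group), ]
    rownames(summary_tab) <- NULL
    report$behavior <- list(
      subjects = beh, summary = summary_tab,
      anova = list(
        pre = compare_groups(beh$rt_pre, beh$group, reference = ref),
        post = compare_groups(beh$rt_post, beh$group, reference = ref),
        diff = compare_groups(beh$rt_diff, beh$group, reference = ref),
        x = compare_groups(beh$x, beh$group, reference = ref)),
      paired = lapply(split(beh, beh$group), function(d)
        paired_test(d$rt_pre, d$rt_post)))
  }

  if ("erp" %in% cfg$include) {
    say("stats: erp")
    cw <- component_windows()
    comp_tab <- do.call(rbind, lapply(feats, function(f)
      cbind(data.frame(group = f$group, subject = f$subject),
            as.data.frame(as.list(c(
              stats::setNames(f$components$pre, paste0(cw$label, "_pre")),
              stats::setNames(f$components$post, paste0(cw$label, "_post")),
              stats::setNames(f$components$post - f$components$pre,
                              paste0("d_", cw$label))))))))
    within <- list()
    for (g in sim$groups) {
      set.seed(sim$seed + 1000L + match(g, sim$groups))
      within[[g]] <- cluster_permutation_test(
        group_array(feats[groups_of == g], "erp_map", "post"),
        group_array(feats[groups_of == g], "erp_map", "pre"),
        adjacency, paired = TRUE, n_perm = cfg$n_perm,
        cf_alpha = cfg$cf_alpha, alpha = cfg$cluster_alpha)
    }
    between <- list()
    ref_d <- group_array(feats[groups_of == ref], "erp_map", "post") -
      group_array(feats[groups_of == ref], "erp_map", "pre")
    for (g in setdiff(sim$groups, ref)) {
      set.seed(sim$seed + 2000L + match(g, sim$groups))
      gd <- group_array(feats[groups_of == g], "erp_map", "post") -
        group_array(feats[groups_of == g], "erp_map", "pre")
      between[[g]] <- cluster_permutation_test(
        gd, ref_d, adjacency, paired = FALSE, n_perm = cfg$n_perm,
        cf_alpha = cfg$cf_alpha, alpha = cfg$cluster_alpha)
    }
    anova_p150 <- compare_groups(comp_tab$d_P150, comp_tab$group,
                                 reference = ref)
    anova_p150$pairwise$p_fdr <-
      stats::p.adjust(anova_p150$pairwise$p_raw, "BH")
    report$erp <- list(components = comp_tab, within = within,
                       between = between, anova_dP150 = anova_p150,
                       erp_times = feats[[1]]$erp_times)
  }

  if ("tfr" %in% cfg$include) {
    say("stats: tfr")
    band_tab <- do.call(rbind, lapply(feats, function(f)
      cbind(data.frame(group = f$group, subject = f$subject),
            as.data.frame(as.list(c(
              stats::setNames(f$band_mean$pre, paste0(cfg$bands, "_pre")),
              stats::setNames(f$band_mean$post, paste0(cfg$bands, "_post")),
              stats::setNames(f$band_mean$post - f$band_mean$pre,
                              paste0("d_", cfg$bands))))))))
    within <- list(); between <- list()
    for (b in cfg$bands) {
      get_map <- function(sel, session) {
        maps <- lapply(feats[sel], function(f) f$band_map[[session]][[b]])
        arr <- array(0, dim = c(length(maps), dim(maps[[1]])))
        for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]
        arr
      }
      within[[b]] <- list()
      for (g in sim$groups) {
        set.seed(sim$seed + 3000L + 10L * match(b, cfg$bands) +
                   match(g, sim$groups))
        within[[b]][[g]] <- cluster_permutation_test(
          get_map(groups_of == g, "post"), get_map(groups_of == g, "pre"),
          adjacency, paired = TRUE, n_perm = cfg$n_perm,
          cf_alpha = cfg$cf_alpha, alpha = cfg$cluster_alpha)
      }
      between[[b]] <- list()
      refd <- get_map(groups_of == ref, "post") - get_map(groups_of == ref, "pre")
      for (g in setdiff(sim$groups, ref)) {
        set.seed(sim$seed + 4000L + 10L * match(b, cfg$bands) +
                   match(g, sim$groups))
        gd <- get_map(groups_of == g, "post") - get_map(groups_of == g, "pre")
        between[[b]][[g]] <- cluster_permutation_test(
          gd, refd, adjacency, paired = FALSE, n_perm = cfg$n_perm,
          cf_alpha = cfg$cf_alpha, alpha = cfg$cluster_alpha)
      }
    }
    anova_alpha <- if ("alpha" %in% cfg$bands) {
      aa <- compare_groups(band_tab$d_alpha, band_tab$group, reference = ref)
      aa$pairwise$p_fdr <- stats::p.adjust(aa$pairwise$p_raw, "BH")
      aa
    }
    report$tfr <- list(bands = band_tab, within = within, between = between,
                       anova_dalpha = anova_alpha)
  }

  if ("network" %in% cfg$include) {
    say("stats: network")
    rows <- list()
    for (f in feats) {
      for (ses in c("pre", "post")) {
        for (b in cfg$rest_bands) {
          m <- f$network[[ses]][[b]]
          rows[[length(rows) + 1L]] <- data.frame(
            group = f$group, subject = f$subject, session = ses, band = b,
            mean_plv = m$mean_plv, cp = m$cp, lp = m$lp, eglob = m$eglob,
            eloc_mean = m$eloc_mean)
        }
      }
    }
    net <- do.call(rbind, rows)
    tests <- list()
    for (g in sim$groups) {
      for (b in cfg$rest_bands) {
        for (metric in c("mean_plv", "cp", "lp", "eglob", "eloc_mean")) {
          pre <- net[net$group == g & net$band == b & net$session == "pre",
                     metric]
          post <- net[net$group == g & net$band == b & net$session == "post",
                      metric]
          tt <- paired_test(pre, post)
          tests[[length(tests) + 1L]] <- data.frame(
            group = g, band = b, metric = metric, method = tt$method,
            mean_diff = tt$mean_diff, p = tt$p)
        }
      }
    }
    tests <- do.call(rbind, tests)
    tests$p_fdr <- stats::p.adjust(tests$p, "BH")
    report$network <- list(metrics = net, tests = tests)
  }

  if (all(c("behavior", "erp", "tfr") %in% cfg$include)) {
    say("stats: correlations")
    deltas <- merge(report$erp$components[, c("group", "subject", "d_N100",
                                              "d_P150", "d_N200", "d_P300")],
                    report$tfr$bands[, c("group", "subject",
                                         paste0("d_", cfg$bands))],
                    by = c("group", "subject"))
    beh <- report$behavior$subjects
    beh$d_rt <- beh$rt_post - beh$rt_pre
    deltas <- merge(deltas, beh[, c("group", "subject", "d_rt")],
                    by = c("group", "subject"))
    report$correlations <- correlate_outcomes(deltas,
                                              bands = cfg$bands)
  }
  class(report) <- "study_report"
  report
}

#' Correlate electrophysiological and behavioral change
#'
#' Per arm: Pearson r and p between each component-amplitude change and
#' the reaction-time change, between each band-power change and the
#' reaction-time change, and between each (component, band) change pair.
#' Arms with fewer than 3 subjects, or zero-variance pairs, are skipped
#' with a notice row.
#'
#' @param deltas Data frame with columns `group`, `subject`, `d_rt`,
#'   `d_<component>` and `d_<band>` columns.
#' @param components Component labels (default the four standard ones).
#' @param bands Band labels present in `deltas`.
#' @return Data frame `group, var1, var2, r, p, n, note`.
#' @export
correlate_outcomes <- function(deltas,
                               components = c("N100", "P150", "N200", "P300"),
                               bands = c("theta", "alpha", "beta1")) {
  pairs <- rbind(
    data.frame(v1 = paste0("d_", components), v2 = "d_rt"),
    data.frame(v1 = paste0("d_", bands), v2 = "d_rt"),
    expand.grid(v1 = paste0("d_", components), v2 = paste0("d_", bands),
                stringsAsFactors = FALSE))
  out <- list()
  for (g in unique(deltas$group)) {
    d <- deltas[deltas$group == g, ]
    for (i in seq_len(nrow(pairs))) {
      v1 <- pairs$v1[i]; v2 <- pairs$v2[i]
      if (!all(c(v1, v2) %in% names(d))) next
      row <- data.frame(group = g, var1 = v1, var2 = v2, r = NA_real_,
                        p = NA_real_, n = nrow(d), note = "")
      if (nrow(d) < 3) {
        row$note <- "skipped: n < 3"
      } else if (stats::sd(d[[v1]]) == 0 || stats::sd(d[[v2]]) == 0) {
        row$note <- "skipped: zero variance"
      } else {
        pc <- pearson_corr(d[[v1]], d[[v2]])
        row$r <- pc$r; row$p <- pc$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
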