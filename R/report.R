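# Structured report output: JSON tables + human-readable Markdown.

cluster_summary_df <- function(ct) {
  if (!length(ct$clusters)) {
    return(data.frame(sign = integer(0), n_points = integer(0),
                      n_channels = integer(0), mass = numeric(0),
                      p = numeric(0), significant = logical(0)))
  }
  do.call(rbind, lapply(ct$clusters, function(cl)
    data.frame(sign = cl$sign, n_points = nrow(cl$members),
               n_channels = length(unique(cl$members[, 1])),
               mass = cl$mass, p = cl$p, significant = cl$significant)))
}

#' Write a study report to disk
#'
#' Emits `report.json` (behavioral, component, band-power and network
#' tables plus cluster-test summaries with their parameters and seeds) and
#' `report.md`, a short human-readable digest, into `dir`.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  payload <- list(
    parameters = list(seed = cfg$sim$seed, n_perm = cfg$n_perm,
                      cf_alpha = cfg$cf_alpha,
                      cluster_alpha = cfg$cluster_alpha,
                      density = cfg$density, groups = report$groups,
                      n_subjects = report$n_subjects))
  md <- c("# Study report", "")
  if (!is.null(report$behavior)) {
    payload$behavior <- list(
      summary = report$behavior$summary,
      anova = lapply(report$behavior$anova, function(a)
        list(method = a$method, statistic = a$statistic, df = a$df, p = a$p,
             pairwise = a$pairwise)))
    md <- c(md, "## Behavior", "",
            utils::capture.output(print(report$behavior$summary,
                                        row.names = FALSE)), "",
            sprintf("Change-index ANOVA: %s = %.3f, p = %.4g",
                    toupper(substr(report$behavior$anova$x$method, 1, 1)),
                    report$behavior$anova$x$statistic,
                    report$behavior$anova$x$p), "")
  }
  if (!is.null(report$erp)) {
    payload$erp <- list(
      within = lapply(report$erp$within, cluster_summary_df),
      between = lapply(report$erp$between, cluster_summary_df),
      anova_dP150 = report$erp$anova_dP150[c("method", "statistic", "df",
                                             "p", "pairwise")])
    md <- c(md, "## ERP", "",
            sprintf("dP150 ANOVA: statistic = %.3f, p = %.4g",
                    report$erp$anova_dP150$statistic,
                    report$erp$anova_dP150$p), "")
  }
  if (!is.null(report$tfr)) {
    payload$tfr <- list(
      within = lapply(report$tfr$within, function(x)
        lapply(x, cluster_summary_df)),
      between = lapply(report$tfr$between, function(x)
        lapply(x, cluster_summary_df)))
    if (!is.null(report$tfr$anova_dalpha)) {
      payload$tfr$anova_dalpha <-
        report$tfr$anova_dalpha[c("method", "statistic", "df", "p",
                                  "pairwise")]
      md <- c(md, "## Oscillatory power", "",
              sprintf("dAlpha ANOVA: statistic = %.3f, p = %.4g",
                      report$tfr$anova_dalpha$statistic,
                      report$tfr$anova_dalpha$p), "")
    }
  }
  if (!is.null(report$network)) {
    payload$network <- list(tests = report$network$tests)
    sig <- report$network$tests[report$network$tests$p_fdr < 0.05, ]
    md <- c(md, "## Resting networks", "",
            if (nrow(sig)) utils::capture.output(print(sig, row.names = FALSE))
            else "No FDR-significant pre/post network changes.", "")
  }
  if (!is.null(report$correlations)) {
    payload$correlations <- report$correlations
  }
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
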