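# 2-back behavioral scoring: signal-detection d', reaction times, change
# index, and group comparisons.

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`, the difference of
#' inverse-normal-transformed hit and false-alarm rates. Extreme rates are
#' corrected before the transform with the log-linear style rule: 0 becomes
#' `0.5/n`, 1 becomes `(n - 0.5)/n`, where `n` is the number of trials
#' underlying the rate (`n_targets` for hits, `n_nontargets` for false
#' alarms). Without trial counts an extreme rate is an error, since the
#' transform diverges.
#'
#' @param hit_rate,fa_rate Rates in `[0, 1]`.
#' @param n_targets,n_nontargets Trial counts behind each rate, used only
#'   for the extreme-rate correction.
#' @return Unitless sensitivity.
#' @examples
#' dprime(0.84, 0.16)  # ~1.989
#' @export
dprime <- function(hit_rate, fa_rate, n_targets = NULL, n_nontargets = NULL) {
  for (r in c(hit_rate, fa_rate)) {
    if (is.na(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  correct <- function(r, n) {
    if (r > 0 && r < 1) return(r)
    if (is.null(n)) stop("extreme rate ", r, " needs a trial count to correct")
    if (r == 0) 0.5 / n else (n - 0.5) / n
  }
  hit_rate <- correct(hit_rate, n_targets)
  fa_rate <- correct(fa_rate, n_nontargets)
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

is_correct_trial <- function(session) {
  (session$is_target & session$response) |
    (!session$is_target & !session$response)
}

#' Mean reaction time over correct responses
#'
#' @param session A `behavior_session`.
#' @return Mean reaction time in seconds, correct trials only.
#' @export
mean_correct_rt <- function(session) {
  ok <- is_correct_trial(session)
  if (!any(ok)) stop("session has no correct response")
  mean(session$rt_s[ok])
}

#' Score a 2-back session
#'
#' @param session A `behavior_session`.
#' @return List: `n_targets`, `n_nontargets`, `n_hits`, `n_false_alarms`,
#'   `hit_rate`, `fa_rate`, `dprime`, `mean_rt`.
#' @export
score_session <- function(session) {
  n_t <- sum(session$is_target)
  n_nt <- sum(!session$is_target)
  hits <- sum(session$is_target & session$response)
  fas <- sum(!session$is_target & session$response)
  list(n_targets = n_t, n_nontargets = n_nt, n_hits = hits,
       n_false_alarms = fas, hit_rate = hits / n_t, fa_rate = fas / n_nt,
       dprime = dprime(hits / n_t, fas / n_nt, n_t, n_nt),
       mean_rt = mean_correct_rt(session))
}

#' Normalized pre-to-post change index
#'
#' `x = (pre - post) / pre`, so that a reaction-time reduction yields a
#' positive index. Set `literal = TRUE` for the opposite sign convention
#' `(post - pre) / pre`. When averaging over a group, average the
#' per-subject indices (mean of ratios), not the ratio of group means.
#'
#' @param pre,post Positive scalars (e.g. mean reaction times, seconds).
#' @param literal Use the `(post - pre)/pre` sign convention.
#' @return List `x`, `pre`, `post`.
#' @export
change_index <- function(pre, post, literal = FALSE) {
  if (!is.finite(pre) || pre <= 0) stop("pre must be > 0")
  x <- if (literal) (post - pre) / pre else (pre - post) / pre
  list(x = x, pre = pre, post = post)
}

#' Compare a per-subject measure across groups
#'
#' One-way ANOVA (or Kruskal-Wallis) across groups, with pairwise
#' comparisons of each group against a reference group, Bonferroni
#' corrected. With `method = "auto"` the parametric/nonparametric choice
#' follows a Shapiro-Wilk gate at alpha = 0.05 in any group
#' (see [normality_gate()]).
#'
#' @param values Numeric vector of per-subject values.
#' @param groups Factor/character of group labels, same length.
#' @param method `"auto"`, `"anova"` or `"kruskal"`.
#' @param reference Reference group for pairwise comparisons (default: last
#'   level, conventionally the sham arm).
#' @return List: `method`, `statistic` (F or H), `df`, `p`, and `pairwise`
#'   (data frame `group, p_raw, p_adj` vs the reference group,
#'   Bonferroni-adjusted).
#' @export
compare_groups <- function(values, groups, method = c("auto", "anova", "kruskal"),
                           reference = NULL) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (method == "auto") {
    method <- if (normality_gate(split(values, groups)) == "parametric")
      "anova" else "kruskal"
  }
  if (is.null(reference)) reference <- levels(groups)[nlevels(groups)]
  if (!reference %in% levels(groups)) stop("reference group not present")

  if (method == "anova") {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    stat <- tab[["F value"]][1]
    df <- c(tab[["Df"]][1], tab[["Df"]][2])
    p <- tab[["Pr(>F)"]][1]
  } else {
    kt <- stats::kruskal.test(values, groups)
    stat <- unname(kt$statistic)
    df <- c(unname(kt$parameter), NA)
    p <- kt$p.value
  }

  others <- setdiff(levels(groups), reference)
  p_raw <- vapply(others, function(g) {
    a <- values[groups == g]; b <- values[groups == reference]
    if (method == "anova") stats::t.test(a, b, var.equal = TRUE)$p.value
    else stats::wilcox.test(a, b, exact = FALSE)$p.value
  }, numeric(1))
  pairwise <- data.frame(group = others, p_raw = unname(p_raw),
                         p_adj = pmin(1, unname(p_raw) * length(others)),
                         stringsAsFactors = FALSE)
  list(method = method, statistic = unname(stat), df = df, p = unname(p),
       pairwise = pairwise, reference = reference)
}
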