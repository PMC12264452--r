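# Statistics: cluster-based permutation tests over channel x time data and
# the classical layer (FDR, Bonferroni, normality gating, Pearson).

# ---- spatio-temporal clustering -------------------------------------------

# Connected components of a channels x time logical mask. Two suprathreshold
# points are connected if they share a channel and are adjacent in time, or
# share a time bin and are spatially adjacent channels.
# Returns a list of components, each an integer matrix (channel, time).
connected_components <- function(mask, adj_list) {
  nch <- nrow(mask); nt <- ncol(mask)
  cells <- which(mask)
  comps <- list()
  if (length(cells) == 0) return(comps)
  state <- integer(nch * nt)   # 0 = not suprathreshold, 1 = unvisited, 2 = done
  state[cells] <- 1L
  for (start in cells) {
    if (state[start] != 1L) next
    queue <- start
    state[start] <- 2L
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      ch <- ((cur - 1L) %% nch) + 1L
      ti <- ((cur - 1L) %/% nch) + 1L
      nb <- integer(0)
      if (ti > 1L) nb <- c(nb, cur - nch)
      if (ti < nt) nb <- c(nb, cur + nch)
      sp <- adj_list[[ch]]
      if (length(sp)) nb <- c(nb, (ti - 1L) * nch + sp)
      nb <- nb[state[nb] == 1L]
      state[nb] <- 2L
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <-
      cbind(channel = ((members - 1L) %% nch) + 1L,
            time = ((members - 1L) %/% nch) + 1L)
  }
  comps
}

# Max cluster mass (clusters spanning >= min_channels electrodes) for one
# tail of a t map; used inside the permutation loop.
max_cluster_mass <- function(tmat, thr, adj_list, min_channels = 2L) {
  mask <- tmat > thr
  if (!any(mask)) return(0)
  comps <- connected_components(mask, adj_list)
  best <- 0
  for (cm in comps) {
    if (length(unique(cm[, 1])) < min_channels) next
    best <- max(best, sum(tmat[cm]))
  }
  best
}

paired_t_perm <- function(D, signs) {
  # D: subjects x points; signs: n_perm x subjects of +-1
  n <- nrow(D)
  ss <- colSums(D^2)                       # invariant under sign flips
  m <- (signs %*% D) / n                   # n_perm x points
  v <- sweep(-(m^2), 2, ss / n, "+") * n / (n - 1)
  v[v < 0] <- 0
  guard <- 1e-12 * max(mean(ss / n), .Machine$double.xmin)
  m / sqrt(pmax(v, guard) / n)
}

indep_t_perm <- function(X, assign1, n1, n2) {
  # X: (n1+n2) x points; assign1: n_perm x n 0/1 membership of group 1
  S <- colSums(X); Q <- colSums(X^2)
  S1 <- assign1 %*% X
  Q1 <- assign1 %*% X^2
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, S, "+") / n2
  ss1 <- Q1 - S1^2 / n1
  ss2 <- sweep(-Q1, 2, Q, "+") - (m2^2) * n2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  sp2[sp2 < 0] <- 0
  guard <- 1e-12 * max(mean(Q / (n1 + n2)), .Machine$double.xmin)
  (m1 - m2) / sqrt(pmax(sp2, guard) * (1 / n1 + 1 / n2))
}

#' Cluster-based permutation test over channel x time maps
#'
#' Nonparametric family-wise control over electrodes and time. Pointwise
#' t statistics (paired or independent) are thresholded at the two-sided
#' `cf_alpha` quantile; suprathreshold points form spatio-temporal clusters
#' through spatial adjacency (at the same time bin) and temporal contiguity
#' (on the same channel); clusters spanning fewer than two distinct
#' electrodes are discarded; each cluster's mass is the sum of its t
#' values. Positive and negative clusters are tested separately against
#' the permutation null of the maximum cluster mass -- random sign flips of
#' subject difference maps for paired designs, full label reshuffles for
#' independent designs -- and each tail is evaluated at `alpha` (default
#' 0.025, i.e. a two-tailed test at 0.05). Monte Carlo p-values use the
#' add-one correction `p = (1 + #exceedances) / (1 + n_perm)`.
#'
#' Results are reproducible for a fixed RNG seed (`set.seed()` before the
#' call).
#'
#' @param a,b Numeric arrays `subjects x channels x time`. For
#'   `paired = TRUE` the subject dimensions must match.
#' @param adjacency Symmetric logical channel adjacency matrix
#'   (see [channel_adjacency()]).
#' @param paired Paired (within-subject) or independent design.
#' @param n_perm Number of random permutations (the study default is 5000;
#'   at least 100 or a warning is issued).
#' @param cf_alpha Cluster-forming threshold (two-sided pointwise alpha).
#' @param alpha Per-tail cluster significance threshold.
#' @return Object of class `cluster_test`: list with `t` (channels x time),
#'   `clusters` (list of `members` (channel,time) matrices, `mass`, `p`,
#'   `sign`, `significant`), `n_perm`, `cf_alpha`, `alpha`, `tail_null`
#'   (max-mass null distributions per tail).
#' @export
cluster_permutation_test <- function(a, b, adjacency, paired = TRUE,
                                     n_perm = 5000, cf_alpha = 0.05,
                                     alpha = 0.025) {
  stopifnot(length(dim(a)) == 3, length(dim(b)) == 3)
  if (!all(dim(a)[2:3] == dim(b)[2:3])) {
    stop("a and b must share channel and time axes")
  }
  nch <- dim(a)[2]; nt <- dim(a)[3]
  if (nrow(adjacency) != nch) stop("adjacency size does not match channels")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse Monte Carlo p grid")
  adj_list <- lapply(seq_len(nch), function(i) which(adjacency[i, ]))

  if (paired) {
    if (dim(a)[1] != dim(b)[1]) stop("paired design needs equal subject counts")
    n <- dim(a)[1]
    D <- matrix(a - b, nrow = n)           # subjects x (ch*time)
    df <- n - 1
    t_obs <- paired_t_perm(D, matrix(1, 1, n))[1, ]
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    t_perm <- paired_t_perm(D, signs)
  } else {
    n1 <- dim(a)[1]; n2 <- dim(b)[1]
    X <- rbind(matrix(a, nrow = n1), matrix(b, nrow = n2))
    df <- n1 + n2 - 2
    obs_assign <- matrix(c(rep(1, n1), rep(0, n2)), 1)
    t_obs <- indep_t_perm(X, obs_assign, n1, n2)[1, ]
    assigns <- t(vapply(seq_len(n_perm), function(i) {
      z <- numeric(n1 + n2); z[sample(n1 + n2, n1)] <- 1; z
    }, numeric(n1 + n2)))
    t_perm <- indep_t_perm(X, assigns, n1, n2)
  }
  thr <- stats::qt(1 - cf_alpha / 2, df)
  t_mat <- matrix(t_obs, nch, nt)

  null_pos <- null_neg <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tm <- matrix(t_perm[i, ], nch, nt)
    null_pos[i] <- max_cluster_mass(tm, thr, adj_list)
    null_neg[i] <- max_cluster_mass(-tm, thr, adj_list)
  }

  clusters <- list()
  for (sgn in c(1, -1)) {
    comps <- connected_components(sgn * t_mat > thr, adj_list)
    for (cm in comps) {
      if (length(unique(cm[, 1])) < 2) next
      mass <- sum(t_mat[cm])
      nulld <- if (sgn > 0) null_pos else null_neg
      p <- (1 + sum(nulld >= abs(mass))) / (1 + n_perm)
      clusters[[length(clusters) + 1L]] <-
        list(members = cm, mass = mass, p = p, sign = sgn,
             significant = p < alpha)
    }
  }
  if (length(clusters)) {
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "p"))]
  }
  structure(list(t = t_mat, clusters = clusters, n_perm = n_perm,
                 cf_alpha = cf_alpha, alpha = alpha, df = df, paired = paired,
                 tail_null = list(pos = null_pos, neg = null_neg)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s, %d permutations, cluster alpha %g/tail\n",
              if (x$paired) "paired" else "independent", x$n_perm, x$alpha))
  if (!length(x$clusters)) {
    cat("  no clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  %s cluster: %d points, %d channels, mass %.2f, p = %.4g%s\n",
                  if (cl$sign > 0) "positive" else "negative",
                  nrow(cl$members), length(unique(cl$members[, 1])),
                  cl$mass, cl$p, if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up rule: reject the `i` smallest p-values where
#' `i = max{k : p_(k) <= q k / m}` (via `stats::p.adjust`).
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection mask (empty input gives an empty mask).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Bonferroni correction
#'
#' @param pvals P-values in `[0, 1]`.
#' @param alpha Family-wise level.
#' @return Logical rejection mask.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  stats::p.adjust(pvals, method = "bonferroni") <= alpha
}

#' Normality gate for parametric vs nonparametric routing
#'
#' Shapiro-Wilk in every group at `alpha`; if any group rejects, the
#' analysis routes to nonparametric tests (ANOVA to Kruskal-Wallis,
#' paired t to Wilcoxon signed-rank).
#'
#' @param samples List of numeric vectors (one per group), each of length
#'   >= 3.
#' @param alpha Shapiro-Wilk level.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  for (s in samples) {
    if (length(s) < 3) stop("each group needs at least 3 observations")
  }
  for (s in samples) {
    if (stats::sd(s) == 0) return("nonparametric")
    if (stats::shapiro.test(s)$p.value < alpha) return("nonparametric")
  }
  "parametric"
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y Equal-length numeric vectors (n >= 3, nonzero variance).
#' @return List `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired pre/post test with normality gating
#'
#' Paired t-test when both the pre and post samples pass the Shapiro-Wilk
#' gate (on the differences), Wilcoxon signed-rank otherwise.
#'
#' @param pre,post Equal-length numeric vectors.
#' @return List `method`, `statistic`, `p`, `mean_diff` (post - pre).
#' @export
paired_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  d <- post - pre
  gate <- normality_gate(list(d))
  if (gate == "parametric") {
    ht <- stats::t.test(post, pre, paired = TRUE)
    list(method = "paired_t", statistic = unname(ht$statistic),
         p = ht$p.value, mean_diff = mean(d))
  } else {
    ht <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)
    list(method = "wilcoxon_signed_rank", statistic = unname(ht$statistic),
         p = ht$p.value, mean_diff = mean(d))
  }
}
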