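# Shared fixtures: small simulation configs, brute-force graph oracles,
# and array helpers. Everything is generated in code at test time.

small_cfg <- function(..., seed = 1L) {
  args <- list(...)
  defaults <- list(n_channels = 8, fs = 250, n_trials = 12,
                   n_rest_segments = 6, n_subjects = 3, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

zero_cfg <- function(..., seed = 1L) {
  small_cfg(effect_deltas = lapply(default_effect_deltas(),
                                   function(x) zero_deltas()),
            seed = seed, ...)
}

# stack per-subject channel x time matrices into subjects x channels x time
stack_maps <- function(maps) {
  arr <- array(0, dim = c(length(maps), dim(maps[[1]])))
  for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]
  arr
}

# subject-averaged ERP maps for one group/session at a reduced time grid
subject_erp_maps <- function(cfg, montage, group, session, n_sub, seed_base,
                             decimate = 5) {
  dec <- NULL
  maps <- lapply(seq_len(n_sub), function(s) {
    set.seed(seed_base + s)
    e <- average_erp(generate_epochs(cfg, group, session, "task", montage))
    if (is.null(dec)) dec <<- seq(1, length(e$times), by = decimate)
    e$data[, dec]
  })
  list(arr = stack_maps(maps), times = NULL, dec = dec)
}

# ---- brute-force graph oracles --------------------------------------------

floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

brute_graph_metrics <- function(a) {
  n <- nrow(a)
  d <- floyd_warshall(a)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (u in nb) for (v in nb) if (u < v && a[u, v] == 1) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  off <- d[upper.tri(d)]
  lp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else 0
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    ds <- floyd_warshall(sub)
    m <- length(nb)
    sum(ifelse(is.finite(ds) & ds > 0, 1 / ds, 0)) / (m * (m - 1))
  }, numeric(1))
  list(cp = mean(cc), lp = lp, eglob = eglob, eloc = eloc)
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

adjacency_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  a
}
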