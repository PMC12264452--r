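test_that("the analytic-signal phase of a sinusoid advances at 2*pi*f", {
  fs <- 250
  t <- (0:499) / fs
  for (f0 in c(5, 6.5)) {
    z <- analytic_signal(cos(2 * pi * f0 * t))
    ph <- signal::unwrap(Arg(z))
    mid <- 50:450   # away from edges
    slope <- coef(lm(ph[mid] ~ t[mid]))[2] / (2 * pi)
    expect_equal(unname(slope), f0, tolerance = 0.02)
  }
  # imaginary part is the Hilbert transform: cos -> sin
  z <- analytic_signal(cos(2 * pi * 10 * t))
  expect_equal(Im(z)[100:400], sin(2 * pi * 10 * t)[100:400], tolerance = 1e-6)
})

test_that("phase extraction flags edges and warns of empty bands", {
  fs <- 250
  t <- (0:499) / fs
  x <- array(sin(2 * pi * 6 * t), dim = c(1, 500, 1))
  ep <- eeg_epochs(x, fs, 0, "a", kind = "rest")
  ph <- instantaneous_phase(ep, "theta")
  expect_false(any(ph$valid[1:25]))
  expect_true(all(ph$valid[50:450]))
  expect_false(ph$low_snr)
  # content far outside the band -> low SNR flag
  ph2 <- instantaneous_phase(ep, "beta2")
  expect_true(ph2$low_snr)
  expect_error(instantaneous_phase(ep, c(30, 130)), "Nyquist")
})

test_that("identical and constant-lag signals give PLV of one", {
  fs <- 250
  t <- (0:499) / fs
  base <- sin(2 * pi * 6 * t) + 0.2 * sin(2 * pi * 5 * t + 1)
  x <- array(0, dim = c(2, 500, 3))
  for (tr in 1:3) { x[1, , tr] <- base; x[2, , tr] <- base }
  ep <- eeg_epochs(x, fs, 0, c("a", "b"), kind = "rest")
  plv <- plv_matrix(instantaneous_phase(ep, "theta"))
  expect_equal(plv[1, 2], 1, tolerance = 1e-6)

  x2 <- array(0, dim = c(2, 500, 1))
  x2[1, , 1] <- sin(2 * pi * 6 * t)
  x2[2, , 1] <- sin(2 * pi * 6 * t - pi / 2)
  ep2 <- eeg_epochs(x2, fs, 0, c("a", "b"), kind = "rest")
  plv2 <- plv_matrix(instantaneous_phase(ep2, "theta"))
  expect_equal(plv2[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(plv2), c(a = 0, b = 0))
})

test_that("independent-phase PLV decays toward zero with segment length", {
  set.seed(20)
  fs <- 250
  null_plv <- function(n_s) {
    x <- array(rnorm(2 * n_s * 6), dim = c(2, n_s, 6))
    ep <- eeg_epochs(x, fs, 0, c("a", "b"), kind = "rest")
    plv_matrix(instantaneous_phase(ep, "alpha"))[1, 2]
  }
  short <- mean(replicate(6, null_plv(250)))
  long <- mean(replicate(6, null_plv(2000)))
  expect_lt(long, short)
  expect_lt(long, 0.25)
})

test_that("PLV entries stay within bounds on random input", {
  set.seed(21)
  for (i in 1:20) {
    n_ch <- sample(2:6, 1)
    x <- array(rnorm(n_ch * 300 * 2), dim = c(n_ch, 300, 2))
    ep <- eeg_epochs(x, 250, 0, paste0("c", seq_len(n_ch)), kind = "rest")
    plv <- plv_matrix(instantaneous_phase(ep, "alpha"))
    expect_true(all(plv >= 0 & plv <= 1))
    expect_true(isSymmetric(unclass(plv)))
  }
})

test_that("proportional thresholding keeps exactly the strongest edges", {
  # 5 nodes, P = 10, density 0.30 -> 3 edges
  set.seed(22)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- runif(10)
  w <- w + t(w)
  g <- proportional_threshold(w, 0.30)
  expect_equal(sum(g) / 2, 3)
  # matches brute-force top-k selection for strictly ordered weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  top3 <- ut[order(-w[upper.tri(w)])[1:3], , drop = FALSE]
  expect_true(all(g[top3] == 1))
  # full density -> complete graph
  gc <- proportional_threshold(w, 1)
  expect_true(all(gc[upper.tri(gc)] == 1))
  expect_error(proportional_threshold(w, 0), "density")
})

test_that("threshold ties resolve deterministically without error", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  g1 <- proportional_threshold(w, 0.5)
  g2 <- proportional_threshold(w, 0.5)
  expect_identical(g1, g2)
  expect_equal(sum(g1) / 2, 3)   # round(0.5 * 6)
  # lexicographically first pairs win at equal weight
  expect_equal(g1[1, 2], 1L)
  expect_equal(g1[1, 3], 1L)
  expect_equal(g1[1, 4], 1L)
})

test_that("closed-form graphs give the textbook metric values", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  m <- graph_metrics(k3)
  expect_equal(m$cp, 1); expect_equal(m$lp, 1)
  expect_equal(m$eglob, 1); expect_equal(m$eloc_mean, 1)

  path3 <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  mp <- graph_metrics(path3)
  expect_equal(mp$eglob, 5 / 6)
  expect_equal(mp$lp, (1 + 1 + 2) / 3)
  expect_equal(mp$cp, 0)

  k4_minus <- matrix(1, 4, 4); diag(k4_minus) <- 0
  k4_minus[1, 2] <- k4_minus[2, 1] <- 0
  mk <- graph_metrics(k4_minus)
  expect_equal(mk$cp, 5 / 6)
  # degree-2 nodes see a connected pair (Eloc 1); degree-3 nodes see a path
  expect_equal(sort(mk$eloc), sort(c(1, 1, 5 / 6, 5 / 6)))
})

test_that("metrics agree exactly with brute-force enumeration", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.8))
    if (sum(a) == 0) next
    got <- graph_metrics(a)
    want <- brute_graph_metrics(a)
    expect_equal(got$cp, want$cp)
    expect_equal(got$lp, want$lp)
    expect_equal(got$eglob, want$eglob)
    expect_equal(got$eloc, want$eloc)
  }
})

test_that("adding an edge never hurts integration", {
  set.seed(24)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    a <- random_adjacency(n, 0.4)
    absent <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(absent) == 0 || sum(a) == 0) next
    e <- absent[sample(nrow(absent), 1), ]
    b <- a; b[e[1], e[2]] <- b[e[2], e[1]] <- 1L
    ma <- graph_metrics(a); mb <- graph_metrics(b)
    # Lp over reachable pairs is monotone only on connected graphs (a new
    # edge can make distant pairs reachable and lengthen the average)
    if (ma$connected) expect_gte(ma$lp + 1e-12, mb$lp)
    expect_gte(mb$eglob + 1e-12, ma$eglob) # Eglob never decreases
  }
})

test_that("degenerate graphs are handled explicitly", {
  empty <- matrix(0L, 4, 4)
  expect_warning(m <- graph_metrics(empty), "empty graph")
  expect_equal(m$eglob, 0)
  expect_error(graph_metrics(matrix(0L, 2, 2)), "at least 3")
  # isolated node: Eloc 0, Lp over reachable pairs only
  a <- adjacency_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3)))
  m2 <- graph_metrics(a)
  expect_equal(m2$eloc[4], 0)
  expect_false(m2$connected)
  expect_equal(m2$lp, 1)
})

test_that("an injected coupling increase raises set PLV and global efficiency", {
  cfg <- sim_config(n_channels = 32, fs = 250, n_rest_segments = 24,
                    n_subjects = 1)
  m <- generate_montage(32)
  tset <- match(intersect(default_plv_groups()$theta$channels, m$label),
                m$label)
  eval_session <- function(ep) {
    pl <- plv_matrix(instantaneous_phase(ep, "theta"))
    gm <- graph_metrics(proportional_threshold(pl, 0.3))
    c(mean_plv(pl), mean(pl[tset, tset][upper.tri(pl[tset, tset])]), gm$eglob)
  }
  n_rep <- 5; n_sub <- 6
  deltas <- matrix(0, n_rep, 3)
  for (r in seq_len(n_rep)) {
    pre <- post <- matrix(0, n_sub, 3)
    for (s in seq_len(n_sub)) {
      set.seed(r * 1000 + s)
      pre[s, ] <- eval_session(generate_epochs(cfg, "rTMS5", "pre", "rest", m))
      set.seed(r * 1000 + 500 + s)
      post[s, ] <- eval_session(generate_epochs(cfg, "rTMS5", "post", "rest", m))
    }
    deltas[r, ] <- colMeans(post) - colMeans(pre)
  }
  expect_true(all(deltas[, 2] > 0))          # coupled-set PLV up everywhere
  expect_gte(sum(deltas[, 1] > 0), n_rep - 1) # whole-matrix PLV up
  expect_gt(mean(deltas[, 3]), 0)            # efficiency up on average
  expect_gte(sum(deltas[, 3] > 0), n_rep - 1)
})
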