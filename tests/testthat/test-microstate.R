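test_that("GFP follows the spatial-SD definition with the divide-by-n convention", {
  expect_equal(compute_gfp(matrix(c(1, -1), 2, 1)), 1)
  expect_equal(compute_gfp(matrix(7, 5, 3)), c(0, 0, 0))
  # worked column: mean 0, sum of squares 12, /4, sqrt
  expect_equal(compute_gfp(matrix(c(3, -1, -1, -1), 4, 1)), sqrt(3))

  # two-pass mean/variance oracle on random matrices
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rnorm(17 * 40), 17)
    oracle <- vapply(seq_len(ncol(m)), function(t) {
      v <- m[, t]; sqrt(sum((v - mean(v))^2) / length(v))
    }, 0)
    expect_lt(max(abs(compute_gfp(m) - oracle)), 1e-12)
  }
})

test_that("GFP peaks are strict interior local maxima", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_length(find_gfp_peaks(c(1, 2, 3, 4, 5)), 0)
  expect_length(find_gfp_peaks(c(0, 1, 1, 0)), 0)  # plateau: no strict peak
  # minimum separation keeps the larger peak
  g <- c(0, 3, 0, 5, 0, 1, 0)
  expect_identical(find_gfp_peaks(g, min_separation_samples = 3), 4L)
  expect_identical(find_gfp_peaks(g), c(2L, 4L, 6L))
})

test_that("noiseless polarity-flipped template maps are recovered exactly", {
  # orthogonal templates via QR, average-referenced
  set.seed(33)
  q <- qr.Q(qr(matrix(rnorm(19 * 5), 19, 5)))
  maps <- microdyn:::normalize_maps(t(q[, 2:5]))
  idx <- rep(1:4, each = 50)
  signs <- sample(c(-1, 1), 200, replace = TRUE)
  x <- maps[idx, ] * signs * runif(200, 0.5, 2)
  model <- modified_kmeans(x, k = 4, n_restarts = 10, seed = 1)
  al <- microdyn:::best_alignment(maps, model$maps)
  expect_lt(max(abs(al$corrs - 1)), 1e-9)
  expect_lt(abs(model$gev - 1), 1e-9)
})

test_that("k = 1 clustering equals the GFP^2-weighted first principal component", {
  set.seed(44)
  x <- matrix(rnorm(60 * 19), 60, 19)
  model <- modified_kmeans(x, k = 1, n_restarts = 3, seed = 2)
  xc <- x - rowMeans(x)
  w <- rowMeans(xc^2)
  xn <- xc / sqrt(rowSums(xc^2))
  s <- crossprod(xn * sqrt(w))
  ev <- eigen(s, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]; pc1 <- pc1 - mean(pc1)
  pc1 <- pc1 / sqrt(sum(pc1^2))
  expect_lt(min(sum(abs(model$maps[1, ] - pc1)),
                sum(abs(model$maps[1, ] + pc1))), 1e-6)
  expect_equal(model$gev, ev$values[1] / sum(w), tolerance = 1e-9)
})

test_that("clustering is polarity invariant and deterministic", {
  fx <- fixture_synthetic(seed = 6, snr = 4, duration_s = 10)
  eps <- epochs_from_matrix(fx$eeg$data, 500, n = 1, length_s = 10)
  pk <- microdyn:::collect_peak_maps(eps)
  m1 <- modified_kmeans(pk$maps, k = 4, n_restarts = 10, seed = 5)
  set.seed(99)
  flips <- sample(c(-1, 1), nrow(pk$maps), replace = TRUE)
  m2 <- modified_kmeans(pk$maps * flips, k = 4, n_restarts = 10,
                        seed = 5)
  al <- microdyn:::best_alignment(m1$maps, m2$maps)
  expect_lt(max(abs(al$corrs - 1)), 1e-9)
  expect_equal(m1$gev, m2$gev, tolerance = 1e-9)
  m3 <- modified_kmeans(pk$maps, k = 4, n_restarts = 10, seed = 5)
  expect_identical(m1$maps, m3$maps)
  expect_error(modified_kmeans(pk$maps[1:3, ], k = 4), "P >= k")
  expect_error(modified_kmeans(pk$maps[c(1, 1, 1, 1), ], k = 4),
               "distinct")
})

test_that("GEV is 1 for exact fits, 0 for orthogonal fits, and maximal at the best assignment", {
  set.seed(55)
  # orthonormal basis of the zero-mean (average-reference) subspace
  q <- qr.Q(qr(cbind(rep(1, 19), matrix(rnorm(19 * 4), 19, 4))))
  maps <- microdyn:::normalize_maps(t(q[, 2:3]))
  idx <- rep(1:2, each = 10)
  data <- t(maps[idx, ] * runif(20, 0.5, 3))
  expect_equal(compute_gev(maps, data, idx), 1, tolerance = 1e-12)
  # a zero-mean map orthogonal to every data column
  ortho <- microdyn:::normalize_maps(t(q[, 4, drop = FALSE]))
  expect_lt(compute_gev(ortho, data, rep(1, 20)), 1e-20)

  # exhaustive-assignment oracle on a tiny instance
  set.seed(56)
  tiny <- matrix(rnorm(19 * 6), 19, 6)
  grid <- expand.grid(rep(list(1:2), 6))
  gevs <- apply(grid, 1, function(a) {
    compute_gev(maps, tiny, as.integer(a))
  })
  best <- max(gevs)
  for (i in c(1, 17, 33)) expect_lte(gevs[i], best + 1e-12)
  # the per-sample argmax assignment attains the exhaustive maximum
  seg <- backfit(tiny, structure(list(maps = maps, labels = c("M1", "M2"),
                                      gev = NA, k = 2,
                                      channel_labels = NULL),
                                 class = "microstate_model"))
  expect_equal(compute_gev(maps, tiny, unlist(seg$labels)), best,
               tolerance = 1e-12)
})

test_that("group-map aggregation aligns permutations and polarity", {
  tpl <- fixture_templates(seed = 9)
  mk_model <- function(maps) {
    structure(list(maps = maps, labels = paste0("M", 1:4), gev = 0.9,
                   k = 4, channel_labels = tpl$channel_labels),
              class = "microstate_model")
  }
  m1 <- mk_model(tpl$maps)
  m2 <- mk_model(tpl$maps[c(3, 1, 4, 2), ] * c(-1, 1, -1, 1))
  agg <- aggregate_group_maps(list(m1, m2))
  cors <- abs(diag(agg$maps %*% t(tpl$maps)))
  expect_lt(max(abs(cors - 1)), 1e-9)

  # single model: unchanged up to normalization
  one <- aggregate_group_maps(list(m1))
  expect_equal(one$maps, m1$maps, tolerance = 1e-12, ignore_attr = TRUE)

  # averaging noisy perturbations beats the median individual model
  set.seed(77)
  noisy <- lapply(1:10, function(i) {
    mk_model(microdyn:::normalize_maps(
      tpl$maps + matrix(rnorm(4 * 19, sd = 0.25), 4, 19)))
  })
  agg_n <- aggregate_group_maps(noisy)
  align_score <- function(m) {
    min(microdyn:::best_alignment(tpl$maps, m$maps)$corrs)
  }
  expect_gt(align_score(agg_n),
            stats::median(vapply(noisy, align_score, 0)))

  bad <- mk_model(tpl$maps[1:3, ]); bad$k <- 3
  expect_error(aggregate_group_maps(list(m1, bad)), "share k")
})

test_that("canonical labelling restores shuffled canonical maps, ignoring polarity", {
  can <- canonical_maps()
  model <- structure(list(maps = can[c(3, 1, 4, 2), ],
                          labels = paste0("M", 1:4), gev = 1, k = 4,
                          channel_labels = colnames(can)),
                     class = "microstate_model")
  out <- assign_canonical_labels(model)
  expect_identical(out$labels, c("A", "B", "C", "D"))
  expect_lt(max(abs(out$canonical_corr - 1)), 1e-9)
  expect_equal(unname(out$maps), unname(can), tolerance = 1e-12)

  flipped <- model; flipped$maps <- -flipped$maps
  out2 <- assign_canonical_labels(flipped)
  expect_identical(out2$labels, c("A", "B", "C", "D"))
  expect_lt(max(abs(out2$canonical_corr - 1)), 1e-9)

  small <- model; small$maps <- model$maps[1:3, ]; small$k <- 3
  expect_error(assign_canonical_labels(small), "size")
})

test_that("back-fitting is exact in the noiseless limit and scale invariant", {
  fx <- fixture_synthetic(seed = 8, snr = Inf, duration_s = 4)
  eps <- epochs_from_matrix(fx$eeg$data, 500, n = 2, length_s = 2)
  model <- structure(list(maps = fx$templates$maps,
                          labels = paste0("M", 1:4), gev = 1, k = 4,
                          channel_labels = fx$templates$channel_labels),
                     class = "microstate_model")
  seg <- backfit(eps, model)
  expect_identical(unlist(seg$labels), fx$labels)

  # positive per-sample rescaling leaves labels unchanged
  scaled <- fx$eeg$data * rep(runif(ncol(fx$eeg$data), 0.1, 10),
                              each = 19)
  seg2 <- backfit(epochs_from_matrix(scaled, 500, 2, 2), model)
  expect_identical(seg2$labels, seg$labels)

  # single-map model: one segment per epoch
  one <- structure(list(maps = fx$templates$maps[1, , drop = FALSE],
                        labels = "M1", gev = 1, k = 1,
                        channel_labels = fx$templates$channel_labels),
                   class = "microstate_model")
  seg1 <- backfit(eps, one)
  expect_equal(nrow(seg1$segments), 2)
  expect_true(all(seg1$segments$state == 1))
})

test_that("temporal parameters match the hand-enumerated oracle", {
  # one epoch at 500 Hz: A x50, B x25, A x25
  seg <- segmentation_from_labels(c(rep(1L, 50), rep(2L, 25),
                                    rep(1L, 25)), 500, k = 2)
  p <- compute_parameters(seg)
  expect_equal(unname(p$coverage), c(0.75, 0.25))
  expect_equal(unname(p$duration_ms), c(75, 50))  # mean(100, 50), 50
  expect_equal(unname(p$occurrence_per_s), c(10, 5))  # 2 and 1 per 0.2 s
  # transitions condition on leaving the state: zero diagonal, rows sum 1
  expect_equal(unname(p$transition),
               matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(p$transition)), c(1, 1))
  expect_equal(p$n_transitions, 2)
})

test_that("single-state and absent-state segmentations are handled", {
  seg <- segmentation_from_labels(list(rep(1L, 500), rep(1L, 500)),
                                  500, k = 2)
  p <- compute_parameters(seg)
  expect_equal(unname(p$coverage), c(1, 0))
  # two epochs over 2 s total
  expect_equal(unname(p$occurrence_per_s)[1], 2 / 2)
  expect_true(all(is.na(p$transition[1, ])))  # no outgoing transitions
  expect_equal(unname(p$duration_ms[2]), 0)
  expect_equal(unname(p$occurrence_per_s[2]), 0)
})

test_that("coverage equals occurrence x duration within the epoch-edge budget", {
  for (sd in 1:3) {
    run <- fixture_recovery_run(sd, duration_s = 20, n_restarts = 5)
    p <- run$params
    pred <- p$occurrence_per_s * p$duration_ms / 1000
    expect_lt(max(abs(p$coverage - pred) / pmax(p$coverage, 1e-9)), 0.02)
  }
})

test_that("recovered transition structure matches the generative spec", {
  # a single 50-s run; the tighter pooled bound over ten runs is part
  # of the acceptance suite
  run <- fixture_recovery_run(1, duration_s = 50, n_restarts = 10)
  counts <- pooled_transition_counts(run$segmentation,
                                     run$alignment$perm)
  expect_gt(sum(counts), 2000)
  tm <- counts / rowSums(counts)
  expect_lt(max(abs(tm - run$fx$spec$transition_matrix)), 0.1)
})

test_that("minimum-duration merging recovers dwell durations from flickered fits", {
  # without smoothing, noise flicker biases run lengths far below the
  # generative 60 ms dwell; the merge recovers them to the documented
  # accuracy band
  plain <- fixture_recovery_run(2, duration_s = 50, n_restarts = 10)
  expect_lt(mean(plain$params$duration_ms), 0.6 * 60)
  merged <- fixture_recovery_run(2, duration_s = 50, n_restarts = 10,
                                 min_duration_ms = 15)
  dur <- merged$params$duration_ms[merged$alignment$perm]
  expect_lt(max(abs(dur - 60) / 60), 0.35)
  expect_gt(merged$accuracy, plain$accuracy)
})
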