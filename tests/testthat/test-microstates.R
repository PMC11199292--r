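test_that("gfp is the population spatial standard deviation", {
  expect_equal(gfp(c(5, 5, 5)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(2, 0, -1, -1)), sqrt(1.5))
  expect_equal(round(gfp(c(2, 0, -1, -1)), 4), 1.2247)
  # matrix form matches per-column evaluation
  m <- matrix(rnorm(12), 4)
  expect_equal(gfp(m), apply(m, 2, gfp))
  expect_error(gfp(3), ">= 2 channels")
})

test_that("GFP peaks are strict-left, loose-right local maxima", {
  expect_identical(find_gfp_peaks(1:10), integer(0))
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(find_gfp_peaks(c(0, 1, 1, 0)), 2L)  # plateau: first sample
  expect_error(find_gfp_peaks(numeric(0)), "empty")

  # noiseless 10 Hz carrier at 512 Hz: two GFP maxima per cycle
  tm <- tiny_maps(n_ch = 8, K = 2)
  lab <- simulate_state_sequence(duration_law("fixed", 50), 1024, 2, seed = 2)
  rec <- simulate_eeg(tm$maps, lab, snr = Inf, oscillation_hz = 10,
                      sfreq = 512, seed = 3)
  n_pk <- length(find_gfp_peaks(gfp(rec$data)))
  expect_gte(n_pk, 39); expect_lte(n_pk, 41)
})

test_that("spatial correlation is polarity-invariant when asked", {
  set.seed(6)
  m <- rnorm(10)
  expect_equal(spatial_correlation(m, m), 1)
  expect_equal(spatial_correlation(m, -m, polarity_invariant = TRUE), 1)
  expect_equal(spatial_correlation(m, -m, polarity_invariant = FALSE), -1)
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(a, b), 0)
  expect_error(spatial_correlation(rep(1, 4), a), "zero-variance")
})

test_that("AAHC recovers planted clusters under random polarity flips", {
  tm <- tiny_maps(n_ch = 16, K = 2, seed = 13)
  set.seed(14)
  truth <- rep(1:2, each = 6)
  flips <- sample(c(-1, 1), 12, replace = TRUE)
  X <- tm$maps[, truth] * rep(flips * runif(12, 0.5, 2), each = 16)
  model <- aahc(X, 2)
  # centroids match generators up to polarity
  match_corr <- sapply(1:2, function(k)
    max(spatial_correlation(model$maps[, k], tm$maps[, 1]),
        spatial_correlation(model$maps[, k], tm$maps[, 2])))
  expect_true(all(match_corr > 1 - 1e-9))
  # induced partition equals ground truth
  cc <- abs(crossprod(model$maps, sweep(X, 2, sqrt(colSums(X^2)), "/")))
  part <- max.col(t(cc))
  expect_equal(length(unique(paste(part, truth))), 2)
  expect_equal(model$gev_total, 1, tolerance = 1e-9)
})

test_that("AAHC degenerate cases behave as specified", {
  tm <- tiny_maps(n_ch = 8, K = 2)
  # K equal to the number of maps: singleton clusters, total GEV 1
  X <- tm$maps[, c(1, 2, 1, 2)] + matrix(rnorm(32, sd = 0.05), 8)
  X <- sweep(X, 2, colMeans(X), "-")
  model <- aahc(X, 4)
  expect_equal(ncol(model$maps), 4)
  expect_equal(model$gev_total, 1, tolerance = 1e-9)

  # all inputs identical up to sign: fewer effective clusters, flagged
  Xdup <- tm$maps[, 1] %o% c(1, -1, 1, -1, 1)
  expect_warning(mdup <- aahc(Xdup, 2, weights = rep(1, 5)),
                 "effective rank")
  expect_equal(ncol(mdup$maps), 1)

  expect_error(aahc(tm$maps, 3), "fewer peak maps")
})

test_that("AAHC attains the exhaustive max-GEV partition on small instances", {
  # instances with <= 10 maps, K <= 3, sources equally represented (the regime
  # GFP-peak clustering operates in); amplitudes and polarities vary per map
  proto <- make_prototype_maps(make_montage(12), 4)
  for (s in 1:12) {
    set.seed(s)
    K <- sample(2:3, 1)
    n <- K * 3
    src <- rep(seq_len(K), each = 3)
    X <- proto[, src] * rep(sample(c(-1, 1), n, TRUE) * runif(n, 0.8, 1.2),
                            each = 12) +
      matrix(rnorm(12 * n, sd = 0.05), 12)
    X <- sweep(X, 2, colMeans(X), "-")
    got <- sum(aahc(X, K)$gev_per_map)
    best <- exhaustive_gev(X, K)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("grand-mean clustering pools subject maps correctly", {
  montage <- make_montage(16)
  maps <- make_prototype_maps(montage, 4)
  model <- microstate_model(maps)
  # consensus case: identical subjects reproduce the shared maps
  gm <- cluster_grand_mean(list(model, model, model), 4)
  expect_identical(gm$level, "grand_mean")
  agree <- sapply(1:4, function(k)
    max(abs(crossprod(gm$maps[, k], maps))))
  expect_true(all(agree > 1 - 1e-9))
  expect_error(cluster_grand_mean(list(model), 4), ">= 2")
  m8 <- microstate_model(make_prototype_maps(make_montage(8), 4))
  expect_error(cluster_grand_mean(list(model, m8), 4), "mismatched")
})

test_that("map sorting finds the permutation-optimal template match", {
  montage <- make_montage(32)
  templates <- make_prototype_maps(montage, 4)
  model <- microstate_model(templates, labels = as.character(1:4))
  sorted <- sort_maps(model, templates)
  expect_identical(attr(sorted, "permutation"), 1:4)
  expect_identical(sorted$labels, c("A", "B", "C", "D"))

  # shuffle by a known permutation (with sign flips): recovered exactly
  p <- c(3, 1, 4, 2)
  shuffled <- microstate_model(templates[, p] * rep(c(-1, 1, -1, 1), each = 32))
  sorted2 <- sort_maps(shuffled, templates)
  expect_identical(attr(sorted2, "permutation"), order(p))

  # random maps: equals independent exhaustive search over all 24 candidates
  set.seed(17)
  for (i in 1:5) {
    R <- matrix(rnorm(32 * 4), 32)
    R <- sweep(R, 2, colMeans(R), "-")
    got <- sort_maps(microstate_model(R), templates)
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- as.matrix(perms[apply(perms, 1, function(r)
      length(unique(r)) == 4), ])
    vals <- apply(perms, 1, function(pp)
      sum(sapply(1:4, function(j) spatial_correlation(R[, pp[j]],
                                                      templates[, j]))))
    expect_equal(attr(got, "sort_objective"), max(vals), tolerance = 1e-12)
  }
})

test_that("backfitting labels match the generating sequence on clean data", {
  pe <- planted_epochs(seconds = 12, snr = Inf, seed = 31)
  model <- sort_maps(segment_subject(pe$epochs, 4)$model, pe$maps)
  labels <- backfit(pe$epochs, model)
  got <- unlist(labels$labels)
  truth <- pe$labels[seq_along(got)]
  # at GFP peaks the assignment is exact on noiseless data; between peaks the
  # nearest-peak rule quantizes boundaries to the inter-peak spacing
  off <- 0
  peak_hits <- unlist(lapply(seq_along(pe$epochs$epochs), function(i) {
    pk <- find_gfp_peaks(gfp(pe$epochs$epochs[[i]]))
    hits <- labels$labels[[i]][pk] == pe$labels[off + pk]
    off <<- off + ncol(pe$epochs$epochs[[i]])
    hits
  }))
  expect_equal(mean(peak_hits), 1)
  expect_gte(mean(got == truth), 0.8)

  # polarity invariance: negated data gives identical labels
  neg <- pe$epochs; neg$epochs <- lapply(neg$epochs, function(e) -e)
  expect_identical(backfit(neg, model)$labels, labels$labels)

  # single-map model labels everything with that map
  m1 <- microstate_model(pe$maps[, 1, drop = FALSE], labels = "A")
  expect_true(all(unlist(backfit(pe$epochs, m1)$labels) == 1))
})

test_that("durations, occurrences and coverage follow the run rules", {
  # hand-traced example: one epoch at 100 Hz, A x10, B x15, A x10, B x15
  lab <- rep(c(1L, 2L, 1L, 2L), times = c(10, 15, 10, 15))
  ls <- manual_labels(list(lab), sfreq = 100, map_labels = c("A", "B"))
  st <- compute_stats(ls, NULL, exclude_truncated = TRUE)
  expect_equal(unname(st$duration_ms["A"]), 100)  # only the interior A run
  expect_equal(unname(st$duration_ms["B"]), 150)  # only the interior B run
  expect_equal(unname(st$occurrence_hz), c(1, 2) / 0.5)
  expect_equal(unname(st$coverage), c(20, 30) / 50)
  expect_equal(st$mean_duration, 125)

  # all samples one type
  ls1 <- manual_labels(list(rep(1L, 40)), 100, c("A", "B", "C", "D"))
  st1 <- compute_stats(ls1, NULL)
  expect_equal(unname(st1$coverage), c(1, 0, 0, 0))
  expect_identical(st1$flags$absent_types, c("B", "C", "D"))
  expect_identical(st1$flags$truncation_fallback, "A")

  # accounting identity with truncation off (to 1e-6)
  set.seed(18)
  labs <- lapply(1:6, function(i)
    simulate_state_sequence(duration_law("gamma", 12, 5), 400, 4, seed = i))
  lsr <- manual_labels(labs, 250, c("A", "B", "C", "D"))
  sta <- compute_stats(lsr, NULL, exclude_truncated = FALSE)
  expect_equal(sum(sta$duration_ms * sta$occurrence_hz),
               1000 * sum(sta$coverage), tolerance = 1e-6)
})

test_that("planted durations are recovered and metrics are scale-invariant", {
  pe <- planted_epochs(mean_dur_ms = 80, seconds = 120, snr = Inf, seed = 41)
  seg <- segment_subject(pe$epochs, 4, templates = pe$maps)
  expect_gt(seg$stats$mean_duration, 70)
  expect_lt(seg$stats$mean_duration, 90)
  expect_gte(seg$stats$gev_total, 0.9)
  expect_equal(sum(seg$stats$coverage), 1, tolerance = 1e-9)

  # scale invariance: x3.7 leaves labels and stats unchanged
  scaled <- pe$epochs; scaled$epochs <- lapply(scaled$epochs, function(e) 3.7 * e)
  seg_s <- segment_subject(scaled, 4, templates = pe$maps)
  expect_identical(seg_s$labels$labels, seg$labels$labels)
  expect_equal(seg_s$stats$duration_ms, seg$stats$duration_ms)
  expect_equal(seg_s$stats$gev_total, seg$stats$gev_total, tolerance = 1e-12)

  # polarity invariance end to end
  neg <- pe$epochs; neg$epochs <- lapply(neg$epochs, function(e) -e)
  seg_n <- segment_subject(neg, 4, templates = pe$maps)
  expect_identical(seg_n$labels$labels, seg$labels$labels)
  expect_equal(seg_n$stats$duration_ms, seg$stats$duration_ms)

  # determinism: identical subjects give identical stats
  seg2 <- segment_subject(pe$epochs, 4, templates = pe$maps)
  expect_identical(seg2$stats, seg$stats)
})

test_that("recovered duration and occurrence are monotone in the planted mean", {
  res <- lapply(c(40, 80, 120), function(d) {
    pe <- planted_epochs(mean_dur_ms = d, seconds = 40, snr = 10,
                         seed = 50 + d)
    segment_subject(pe$epochs, 4, templates = pe$maps)$stats
  })
  durs <- vapply(res, `[[`, numeric(1), "mean_duration")
  occs <- vapply(res, `[[`, numeric(1), "mean_occurrence")
  expect_true(all(diff(durs) > 0))
  expect_true(all(diff(occs) < 0))
})
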