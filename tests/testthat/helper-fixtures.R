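# Shared fixtures, built in code at test time.

fixture_montage <- function() make_montage(64)

# tiny montage + two well-separated prototype maps for clustering tests
tiny_maps <- function(n_ch = 8, K = 2, seed = 42) {
  set.seed(seed)
  m <- make_montage(n_ch)
  maps <- make_prototype_maps(m, 4)[, seq_len(K), drop = FALSE]
  list(montage = m, maps = maps)
}

# epoch_set wrapping a single channels x samples matrix
one_epoch <- function(mat, sfreq) {
  epoch_set(list(mat), sfreq = sfreq, epoch_length = ncol(mat) / sfreq)
}

# label_sequence built directly from integer label vectors (no backfitting);
# gfp and fit_corr set to 1 so GEV is well defined but uninformative
manual_labels <- function(label_list, sfreq, map_labels) {
  structure(list(labels = label_list,
                 gfp = lapply(label_list, function(l) rep(1, length(l))),
                 fit_corr = lapply(label_list, function(l) rep(1, length(l))),
                 sfreq = sfreq, map_labels = map_labels,
                 flags = list(no_peak_epochs = integer(0))),
            class = "label_sequence")
}

# Exhaustive max-GEV clustering oracle: enumerate every partition of n maps
# into exactly K non-empty clusters, score each with the same GEV objective
# (centroid = first principal direction of weighted members), return the best
# total GEV. Independent of the AAHC code path.
exhaustive_gev <- function(maps, K, weights = NULL) {
  n <- ncol(maps)
  if (is.null(weights)) weights <- microstability::gfp(maps)
  V <- sweep(maps, 2, colMeans(maps), "-")
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  w2 <- weights^2
  score_cluster <- function(idx) {
    M <- sweep(V[, idx, drop = FALSE], 2, weights[idx], "*")
    u <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
    u <- u - mean(u); u <- u / sqrt(sum(u^2))
    sum(w2[idx] * (crossprod(V[, idx, drop = FALSE], u))^2)
  }
  best <- -Inf
  assign <- integer(n)
  recurse <- function(i, used) {
    if (i > n) {
      if (used == K) {
        tot <- sum(vapply(seq_len(K), function(k)
          score_cluster(which(assign == k)), numeric(1)))
        if (tot > best) best <<- tot
      }
      return(invisible())
    }
    for (k in seq_len(min(used + 1L, K))) {
      assign[i] <<- k
      recurse(i + 1L, max(used, k))
    }
  }
  recurse(1L, 0L)
  best / sum(w2)
}

# noiseless single-subject epoch set with a planted label sequence
planted_epochs <- function(mean_dur_ms = 80, seconds = 20, sfreq = 512,
                           snr = Inf, seed = 11, K = 4, montage = NULL) {
  if (is.null(montage)) montage <- fixture_montage()
  maps <- make_prototype_maps(montage, K)
  law <- duration_law("gamma", mean = mean_dur_ms * sfreq / 1000,
                      sd = 15 * sfreq / 1000)
  lab <- simulate_state_sequence(law, as.integer(seconds * sfreq), K, seed = seed)
  rec <- simulate_eeg(maps, lab, snr = snr, sfreq = sfreq, seed = seed + 1)
  eps <- select_condition_and_epoch(rec, "eyes_closed", 2)
  eps <- average_reference(eps)
  list(epochs = eps, maps = maps, labels = lab, sfreq = sfreq, montage = montage)
}
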