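#' Microstate segmentation and temporal stability metrics
#'
#' Implements the standard resting-state microstate chain: topographic maps
#' are extracted at peaks of the global field power (GFP), clustered into K
#' classes with the atomize-agglomerate hierarchical clustering (AAHC),
#' pooled across subjects into grand-mean maps, sorted against canonical
#' templates (A, B, C, D), backfitted to the continuous data by
#' polarity-invariant spatial correlation, and summarized per subject as
#' duration (ms), occurrence (per second), coverage, and global explained
#' variance (GEV).
#'
#' All comparisons between topographies are polarity-invariant: a map and its
#' negation describe the same microstate.
#'
#' @name microstates
NULL

#' Global field power
#'
#' The spatial standard deviation of the potential across channels at one
#' time point (population form: divide by the channel count).
#'
#' @param x A numeric vector (one map) or channels x samples matrix.
#' @return Scalar, or per-sample vector for a matrix.
#' @examples
#' gfp(c(1, -1))        # 1
#' gfp(c(2, 0, -1, -1)) # sqrt(1.5)
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("gfp requires >= 2 channels")
    cm <- colMeans(x)
    sqrt(colMeans(x^2) - cm^2)
  } else {
    if (length(x) < 2) stop("gfp requires >= 2 channels")
    sqrt(mean((x - mean(x))^2))
  }
}

#' Find local maxima of a GFP trace
#'
#' Returns indices i with `g[i-1] < g[i] >= g[i+1]` (interior samples only).
#' Traces from different epochs must be passed separately; no peak can span
#' an epoch boundary.
#'
#' @param g Numeric GFP trace (length >= 3 for any interior peak).
#' @return Integer vector of peak indices (possibly empty).
#' @export
find_gfp_peaks <- function(g) {
  if (length(g) == 0) stop("empty GFP trace")
  if (length(g) < 3) return(integer(0))
  i <- 2:(length(g) - 1)
  i[g[i - 1] < g[i] & g[i] >= g[i + 1]]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels; with `polarity_invariant = TRUE`
#' (the default) the absolute value is returned, since microstate maps are
#' defined up to polarity.
#'
#' @param m1,m2 Numeric vectors of equal length.
#' @param polarity_invariant Return |r| instead of r.
#' @export
spatial_correlation <- function(m1, m2, polarity_invariant = TRUE) {
  stopifnot(length(m1) == length(m2))
  v1 <- m1 - mean(m1); v2 <- m2 - mean(m2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-variance map in spatial_correlation")
  r <- sum(v1 * v2) / (n1 * n2)
  if (polarity_invariant) abs(r) else r
}

# Normalize columns to zero mean, unit norm. Returns list(V, gfp_scale).
.normalize_maps <- function(x) {
  x <- sweep(x, 2, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  bad <- nrm < 1e-12
  nrm[bad] <- 1
  list(V = sweep(x, 2, nrm, "/"), norm = nrm, degenerate = bad)
}

# First principal direction of weighted member maps (columns of V, weights w).
# Sign fixed so correlation with the heaviest member is positive.
.principal_map <- function(V, w) {
  if (ncol(V) == 1) return(V[, 1])
  M <- sweep(V, 2, w, "*")
  if (ncol(M) <= nrow(M)) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    u <- V %*% (sweep(e$vectors[, 1, drop = FALSE], 1, w, "*"))
    u <- u[, 1]
  } else {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    u <- e$vectors[, 1]
  }
  u <- u - mean(u)
  n <- sqrt(sum(u^2))
  if (n < 1e-12) return(V[, which.max(w)])
  u <- u / n
  if (sum(u * V[, which.max(w)]) < 0) u <- -u
  u
}

#' Construct a microstate model
#'
#' @param maps channels x K matrix of zero-mean, unit-norm maps.
#' @param labels Map labels (default colnames or 1..K).
#' @param gev_per_map Fraction of GFP-weighted variance explained per map.
#' @param level "subject" or "grand_mean".
#' @export
microstate_model <- function(maps, labels = colnames(maps),
                             gev_per_map = NULL,
                             level = c("subject", "grand_mean")) {
  level <- match.arg(level)
  stopifnot(is.matrix(maps))
  if (is.null(labels)) labels <- as.character(seq_len(ncol(maps)))
  colnames(maps) <- labels
  if (is.null(gev_per_map)) gev_per_map <- rep(NA_real_, ncol(maps))
  structure(list(maps = maps, labels = labels, gev_per_map = gev_per_map,
                 gev_total = sum(gev_per_map), level = level),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K=%d (%s), %d channels, GEV total = %s\n",
              ncol(x$maps), x$level, nrow(x$maps),
              ifelse(is.na(x$gev_total), "NA", sprintf("%.3f", x$gev_total))))
  invisible(x)
}

#' Atomize-agglomerate hierarchical clustering of topographic maps
#'
#' Starts from singleton clusters and repeatedly dissolves ("atomizes") the
#' cluster contributing least global explained variance, reassigning each of
#' its member maps individually to the cluster whose centroid it correlates
#' with most strongly (squared, polarity-invariant). A cluster centroid is the
#' first principal direction of its (GFP-weighted) member maps, which makes
#' the procedure polarity-invariant. GEV is computed against the input peak
#' maps with their GFP values as weights.
#'
#' If the input has effective rank below K (duplicate centroids), the
#' duplicates are merged, a warning is raised, and fewer than K maps are
#' returned.
#'
#' @param peak_maps channels x N matrix of maps (typically at GFP peaks).
#' @param K Target number of clusters (2 <= K <= N).
#' @param weights Per-map GFP weights; default: GFP of each column.
#' @param refine After agglomeration, iterate full reassignment and centroid
#'   recomputation until the partition is stable (default TRUE). This polish
#'   step removes the path dependence of the greedy atomization.
#' @return A `microstate_model` with `gev_per_map` against the inputs.
#' @export
aahc <- function(peak_maps, K, weights = NULL, refine = TRUE) {
  stopifnot(is.matrix(peak_maps))
  N <- ncol(peak_maps)
  if (N < K) stop("fewer peak maps than clusters requested")
  if (K < 1) stop("K must be >= 1")
  if (is.null(weights)) weights <- gfp(peak_maps)
  stopifnot(length(weights) == N, all(weights >= 0))
  nm <- .normalize_maps(peak_maps)
  V <- nm$V
  w <- weights
  w2 <- w^2
  tot_w2 <- sum(w2)
  if (tot_w2 <= 0) stop("degenerate input: all maps have zero field power")

  member <- as.list(seq_len(N))          # cluster -> member map indices
  centroids <- V                          # one column per cluster
  # contribution of cluster c to GEV: sum_{t in c} w2_t * (v_t . u_c)^2
  contrib <- w2                           # singleton: corr = 1
  alive <- rep(TRUE, N)
  n_alive <- N

  cluster_contrib <- function(c) {
    idx <- member[[c]]
    sum(w2[idx] * (crossprod(V[, idx, drop = FALSE], centroids[, c]))^2)
  }

  while (n_alive > K) {
    worst <- which(alive)[which.min(contrib[alive])]
    freed <- member[[worst]]
    alive[worst] <- FALSE
    n_alive <- n_alive - 1L
    live <- which(alive)
    # assign each freed map to the best remaining centroid
    cc <- crossprod(centroids[, live, drop = FALSE],
                    V[, freed, drop = FALSE])^2   # live x freed
    gain <- live[max.col(t(cc), ties.method = "first")]
    changed <- unique(gain)
    for (i in seq_along(freed)) member[[gain[i]]] <- c(member[[gain[i]]], freed[i])
    for (c in changed) {
      idx <- member[[c]]
      centroids[, c] <- .principal_map(V[, idx, drop = FALSE], w[idx])
      contrib[c] <- cluster_contrib(c)
    }
  }

  live <- which(alive)
  U <- centroids[, live, drop = FALSE]
  if (refine && ncol(U) > 1) {
    # polish: reassign every map to its best centroid and recompute centroids
    # until the partition is stable (local optimum of the GEV objective)
    prev <- integer(N)
    for (it in seq_len(50)) {
      cc <- crossprod(U, V)^2
      assign <- max.col(t(cc), ties.method = "first")
      if (identical(assign, prev)) break
      prev <- assign
      for (k in seq_len(ncol(U))) {
        idx <- which(assign == k)
        if (length(idx) > 0) U[, k] <- .principal_map(V[, idx, drop = FALSE], w[idx])
      }
    }
  }
  # merge effectively identical centroids (input rank < K)
  if (ncol(U) > 1) {
    keep <- rep(TRUE, ncol(U))
    for (i in seq_len(ncol(U) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):ncol(U)) {
        if (keep[j] && abs(sum(U[, i] * U[, j])) > 1 - 1e-9) keep[j] <- FALSE
      }
    }
    if (!all(keep)) {
      warning(sprintf(
        "input has effective rank %d < K = %d; returning %d distinct maps",
        sum(keep), K, sum(keep)))
      U <- U[, keep, drop = FALSE]
    }
  }
  # final hard assignment of every input map, and per-cluster GEV
  cc <- crossprod(U, V)^2                  # K x N
  assign <- max.col(t(cc), ties.method = "first")
  gev_k <- vapply(seq_len(ncol(U)), function(k) {
    idx <- which(assign == k)
    sum(w2[idx] * cc[k, idx]) / tot_w2
  }, numeric(1))
  ord <- order(gev_k, decreasing = TRUE)
  rownames(U) <- rownames(peak_maps)
  microstate_model(U[, ord, drop = FALSE],
                   labels = as.character(seq_len(ncol(U))),
                   gev_per_map = gev_k[ord], level = "subject")
}

#' Extract normalized maps at GFP peaks of an epoch set
#'
#' @param epochs An `epoch_set` (average-referenced).
#' @return List with `maps` (channels x Npeaks, original scale), `gfp`
#'   (peak GFP values) and `epoch` (epoch index of each peak).
#' @export
extract_gfp_peak_maps <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  maps <- list(); gg <- list(); ep <- list()
  for (i in seq_along(epochs$epochs)) {
    e <- epochs$epochs[[i]]
    g <- gfp(e)
    pk <- find_gfp_peaks(g)
    if (length(pk) > 0) {
      maps[[length(maps) + 1]] <- e[, pk, drop = FALSE]
      gg[[length(gg) + 1]] <- g[pk]
      ep[[length(ep) + 1]] <- rep(i, length(pk))
    }
  }
  if (length(maps) == 0) stop("no GFP peaks found in any epoch")
  list(maps = do.call(cbind, maps), gfp = unlist(gg), epoch = unlist(ep))
}

#' Grand-mean clustering across subjects
#'
#' Pools every subject's K maps (unit weight each) and applies the same AAHC
#' to yield K grand-mean maps.
#'
#' @param subject_models List of >= 2 `microstate_model`s with equal K and
#'   channel count.
#' @param K Number of grand-mean clusters (default: the subjects' K).
#' @export
cluster_grand_mean <- function(subject_models, K = NULL) {
  stopifnot(is.list(subject_models), length(subject_models) >= 2)
  stopifnot(all(vapply(subject_models, inherits, logical(1), "microstate_model")))
  nch <- vapply(subject_models, function(m) nrow(m$maps), integer(1))
  if (length(unique(nch)) != 1) stop("subject models have mismatched channel counts")
  if (is.null(K)) K <- ncol(subject_models[[1]]$maps)
  pooled <- do.call(cbind, lapply(subject_models, function(m) m$maps))
  model <- aahc(pooled, K, weights = rep(1, ncol(pooled)))
  model$level <- "grand_mean"
  model
}

# all permutations of 1..n in lexicographic order
.perm_vec <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in .perm_vec(v[-i]))
    out[[length(out) + 1L]] <- c(v[i], p)
  out
}
.permutations <- function(n) .perm_vec(seq_len(n))

#' Sort model maps against template maps
#'
#' Exhaustively searches all K! label permutations for the one maximizing the
#' summed polarity-invariant spatial correlation with the templates; ties are
#' broken by the lexicographically smallest permutation. Maps are relabeled
#' with the template labels; the optimal objective is stored as attribute
#' `sort_objective`.
#'
#' @param model A `microstate_model`.
#' @param templates channels x K matrix (or `microstate_model`) of templates,
#'   same K and channel count as `model`.
#' @export
sort_maps <- function(model, templates) {
  stopifnot(inherits(model, "microstate_model"))
  if (inherits(templates, "microstate_model")) templates <- templates$maps
  K <- ncol(model$maps)
  stopifnot(ncol(templates) == K, nrow(templates) == nrow(model$maps))
  cmat <- matrix(0, K, K)   # cmat[i, j] = |corr(model map i, template j)|
  for (i in seq_len(K)) for (j in seq_len(K))
    cmat[i, j] <- spatial_correlation(model$maps[, i], templates[, j])
  best <- NULL; best_val <- -Inf
  for (p in .permutations(K)) {
    # permutation p: template slot j receives model map p[j]
    val <- sum(cmat[cbind(p, seq_len(K))])
    if (val > best_val + 1e-12) { best_val <- val; best <- p }
  }
  tl <- colnames(templates)
  if (is.null(tl)) tl <- LETTERS[seq_len(K)]
  out <- microstate_model(model$maps[, best, drop = FALSE], labels = tl,
                          gev_per_map = model$gev_per_map[best],
                          level = model$level)
  attr(out, "sort_objective") <- best_val
  attr(out, "permutation") <- best
  out
}

#' Assign subject maps to grand-mean classes
#'
#' Same permutation-optimal matching as [sort_maps()], using the grand-mean
#' maps as templates; the subject's maps are relabeled accordingly.
#'
#' @param subject_model,grand_mean_model `microstate_model`s of equal K and
#'   channel count.
#' @export
assign_subject_maps <- function(subject_model, grand_mean_model) {
  sort_maps(subject_model, grand_mean_model)
}

#' Backfit a microstate model to epoched data
#'
#' Every GFP peak is labeled by the model map with maximal polarity-invariant
#' spatial correlation; every other sample inherits the label of its nearest
#' peak within the same epoch (midpoint rule, ties to the earlier peak). No
#' temporal smoothing is applied. Epochs without any GFP peak are labeled by
#' per-sample best fit and flagged.
#'
#' @param epochs An `epoch_set`.
#' @param model A `microstate_model` with the same channel count.
#' @return A `label_sequence`: list with per-epoch `labels` (integer vectors
#'   indexing the model maps), `gfp` traces, `fit_corr` (per-sample
#'   polarity-invariant correlation with the assigned map), `sfreq`,
#'   `map_labels`, and `flags`.
#' @export
backfit <- function(epochs, model) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(model, "microstate_model"))
  if (nrow(epochs$epochs[[1]]) != nrow(model$maps))
    stop("epochs and model have different channel counts")
  U <- model$maps
  labels <- list(); gtr <- list(); fitc <- list(); flagged <- integer(0)
  for (i in seq_along(epochs$epochs)) {
    e <- epochs$epochs[[i]]
    g <- gfp(e)
    nmV <- .normalize_maps(e)$V
    cc <- abs(crossprod(U, nmV))           # K x L |corr| (maps zero-mean unit)
    pk <- find_gfp_peaks(g)
    L <- ncol(e)
    if (length(pk) == 0) {
      lab <- max.col(t(cc), ties.method = "first")
      flagged <- c(flagged, i)
    } else {
      pklab <- max.col(t(cc[, pk, drop = FALSE]), ties.method = "first")
      if (length(pk) == 1) {
        lab <- rep(pklab, L)
      } else {
        mids <- (pk[-length(pk)] + pk[-1]) / 2
        nearest <- findInterval(seq_len(L), mids + 1e-9) + 1L
        lab <- pklab[nearest]
      }
    }
    labels[[i]] <- lab
    gtr[[i]] <- g
    fitc[[i]] <- cc[cbind(lab, seq_len(L))]
  }
  structure(list(labels = labels, gfp = gtr, fit_corr = fitc,
                 sfreq = epochs$sfreq, map_labels = model$labels,
                 flags = list(no_peak_epochs = flagged)),
            class = "label_sequence")
}

#' Temporal stability metrics from a label sequence
#'
#' A run is a maximal same-label span within one epoch. With
#' `exclude_truncated = TRUE` (default), duration averages use only runs not
#' touching an epoch edge and occurrence counts only runs starting strictly
#' inside an epoch; with FALSE, all runs enter both. If every run of a type
#' is edge-truncated, all its runs are used and the type is flagged. A type
#' never present has missing duration (excluded from the unweighted mean) and
#' zero occurrence.
#'
#' GEV is the GFP-squared-weighted mean squared correlation between each
#' sample and its assigned map: `sum_t (gfp_t * corr_t)^2 / sum_t gfp_t^2`.
#'
#' @param labels A `label_sequence` from [backfit()].
#' @param model The `microstate_model` used (for K and map labels).
#' @param exclude_truncated Exclude edge-truncated runs (see above).
#' @return A `microstate_stats` object: per-type `duration_ms`,
#'   `occurrence_hz`, `coverage`, the unweighted `mean_duration` and
#'   `mean_occurrence`, `gev_total`, and `flags`.
#' @export
compute_stats <- function(labels, model, exclude_truncated = TRUE) {
  stopifnot(inherits(labels, "label_sequence"))
  K <- length(labels$map_labels)
  run_len <- vector("list", K); run_interior <- vector("list", K)
  starts_inside <- numeric(K); n_runs_all <- numeric(K)
  n_samples <- 0L; cover <- numeric(K)
  for (lab in labels$labels) {
    L <- length(lab)
    n_samples <- n_samples + L
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- starts > 1L & ends < L
    for (k in seq_len(K)) {
      sel <- r$values == k
      if (!any(sel)) next
      run_len[[k]] <- c(run_len[[k]], r$lengths[sel])
      run_interior[[k]] <- c(run_interior[[k]], interior[sel])
      starts_inside[k] <- starts_inside[k] + sum(sel & starts > 1L)
      n_runs_all[k] <- n_runs_all[k] + sum(sel)
      cover[k] <- cover[k] + sum(r$lengths[sel])
    }
  }
  total_s <- n_samples / labels$sfreq
  duration <- rep(NA_real_, K)
  fallback <- logical(K)
  for (k in seq_len(K)) {
    if (is.null(run_len[[k]])) next
    use <- if (exclude_truncated) run_interior[[k]] else rep(TRUE, length(run_len[[k]]))
    if (exclude_truncated && !any(use)) { use <- rep(TRUE, length(use)); fallback[k] <- TRUE }
    duration[k] <- mean(run_len[[k]][use]) * 1000 / labels$sfreq
  }
  occurrence <- if (exclude_truncated) starts_inside / total_s else n_runs_all / total_s
  coverage <- cover / n_samples
  g <- unlist(labels$gfp); fc <- unlist(labels$fit_corr)
  gev_total <- sum((g * fc)^2) / sum(g^2)
  names(duration) <- names(occurrence) <- names(coverage) <- labels$map_labels
  structure(list(duration_ms = duration, occurrence_hz = occurrence,
                 coverage = coverage,
                 mean_duration = mean(duration, na.rm = TRUE),
                 mean_occurrence = mean(occurrence),
                 gev_total = gev_total,
                 flags = list(absent_types = labels$map_labels[is.na(duration)],
                              truncation_fallback = labels$map_labels[fallback],
                              no_peak_epochs = labels$flags$no_peak_epochs)),
            class = "microstate_stats")
}

#' @export
print.microstate_stats <- function(x, ...) {
  cat("<microstate_stats>\n")
  print(round(rbind(duration_ms = x$duration_ms,
                    occurrence_hz = x$occurrence_hz,
                    coverage = x$coverage), 3))
  cat(sprintf("mean duration %.1f ms, mean occurrence %.2f /s, GEV %.3f\n",
              x$mean_duration, x$mean_occurrence, x$gev_total))
  invisible(x)
}

#' Segment one subject end to end
#'
#' Composes peak extraction, AAHC, optional relabeling against a grand-mean
#' model or template maps, backfitting with the subject's own (relabeled)
#' maps, and metric computation. Deterministic given its inputs.
#'
#' @param epochs Preprocessed, average-referenced `epoch_set`.
#' @param K Number of microstate classes (default 4).
#' @param grand_mean Optional `microstate_model` used to relabel the
#'   subject's maps (permutation-optimal matching).
#' @param templates Optional template maps used instead when no grand mean is
#'   given.
#' @param exclude_truncated Passed to [compute_stats()].
#' @return List with `model`, `labels` (a `label_sequence`), `stats`.
#' @export
segment_subject <- function(epochs, K = 4, grand_mean = NULL, templates = NULL,
                            exclude_truncated = TRUE) {
  pk <- extract_gfp_peak_maps(epochs)
  model <- aahc(pk$maps, K, weights = pk$gfp)
  if (!is.null(grand_mean)) {
    model <- assign_subject_maps(model, grand_mean)
  } else if (!is.null(templates)) {
    model <- sort_maps(model, templates)
  }
  labels <- backfit(epochs, model)
  stats <- compute_stats(labels, model, exclude_truncated = exclude_truncated)
  list(model = model, labels = labels, stats = stats)
}
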