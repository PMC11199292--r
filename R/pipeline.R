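#' End-to-end pipeline
#'
#' Ties the stages together: preprocessing of every subject's recording,
#' per-subject microstate segmentation, grand-mean clustering, template
#' sorting into the canonical A-D order, backfitting with relabeled subject
#' maps, per-subject stability metrics, and the trait-association analysis.
#'
#' @name pipeline
NULL

#' Run the full microstate stability pipeline
#'
#' @param recordings Named list of `eeg_recording` objects (names =
#'   subject_id), or character vector of `.vhdr` paths.
#' @param subjects Subject table (data.frame or CSV path) with `subject_id`,
#'   `gender`, `aq_item_01`..`aq_item_12`.
#' @param montage A `sensor_montage` (default: packaged 64-channel cap).
#' @param K Number of microstate classes.
#' @param templates channels x K template maps for A-D sorting (default:
#'   canonical prototypes on the montage).
#' @param low,high,notch,threshold,epoch_length,tag Preprocessing settings;
#'   see [preprocess_recording()].
#' @param bad_channels Named list: subject_id -> channels to interpolate.
#' @param exclude_truncated Duration/occurrence truncation policy; see
#'   [compute_stats()].
#' @param analyze Run the trait-association analysis (requires both genders
#'   with n >= 3); set FALSE for EEG-only runs.
#' @param out_dir If given, results and provenance are written there.
#' @return List with `subject_stats` (one row per subject: per-type and mean
#'   metrics, GEV, gender, AQ scores), `grand_mean` (`microstate_model`),
#'   `subject_models`, `analysis` (a `trait_analysis`), and `provenance`.
#' @export
run_pipeline <- function(recordings, subjects, montage = make_montage(64),
                         K = 4, templates = NULL,
                         low = 1.5, high = 20, notch = 60, threshold = 100,
                         epoch_length = 2, tag = "eyes_closed",
                         bad_channels = list(), exclude_truncated = TRUE,
                         analyze = TRUE, out_dir = NULL) {
  if (is.character(recordings)) {
    paths <- recordings
    recordings <- lapply(paths, read_brainvision)
    names(recordings) <- sub("\\.vhdr$", "", basename(paths))
  }
  if (is.character(subjects)) subjects <- read_subject_table(subjects)
  if (is.null(names(recordings)) || !all(names(recordings) %in% subjects$subject_id))
    stop("recordings must be named by subject_id values present in the subject table")
  if (is.null(templates)) templates <- make_prototype_maps(montage, K)

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for subject %s: %s", what, id,
                   conditionMessage(e)), call. = FALSE))
  }
  ids <- names(recordings)
  epochs <- lapply(ids, function(id) stage("preprocess", id,
    preprocess_recording(recordings[[id]], montage = montage, low = low,
                         high = high, notch = notch,
                         bad_channels = if (!is.null(bad_channels[[id]]))
                           bad_channels[[id]] else character(0),
                         tag = tag, epoch_length = epoch_length,
                         threshold = threshold)))
  names(epochs) <- ids
  seg1 <- lapply(ids, function(id) stage("segment", id, {
    pk <- extract_gfp_peak_maps(epochs[[id]])
    list(model = aahc(pk$maps, K, weights = pk$gfp))
  }))
  names(seg1) <- ids
  gm <- cluster_grand_mean(lapply(seg1, `[[`, "model"), K)
  gm <- sort_maps(gm, templates)
  per_subject <- lapply(ids, function(id) stage("backfit", id, {
    model <- assign_subject_maps(seg1[[id]]$model, gm)
    labels <- backfit(epochs[[id]], model)
    stats <- compute_stats(labels, model, exclude_truncated = exclude_truncated)
    list(model = model, stats = stats)
  }))
  names(per_subject) <- ids

  stat_rows <- lapply(ids, function(id) {
    s <- per_subject[[id]]$stats
    row <- data.frame(subject_id = id, mean_duration = s$mean_duration,
                      mean_occurrence = s$mean_occurrence,
                      gev_total = s$gev_total, stringsAsFactors = FALSE)
    for (k in names(s$duration_ms)) {
      row[[paste0("duration_", k)]] <- s$duration_ms[[k]]
      row[[paste0("occurrence_", k)]] <- s$occurrence_hz[[k]]
      row[[paste0("coverage_", k)]] <- s$coverage[[k]]
    }
    row
  })
  subject_stats <- do.call(rbind, stat_rows)
  subject_stats <- merge(score_aq_table(subjects), subject_stats,
                         by = "subject_id", sort = TRUE)
  analysis <- if (analyze) run_full_analysis(subject_stats, types = gm$labels)
              else NULL

  provenance <- list(
    n_subjects = length(ids), K = K,
    filter = list(low_hz = low, high_hz = high, notch_hz = notch),
    artifact_threshold_uV = threshold, epoch_length_s = epoch_length,
    condition_tag = tag, exclude_truncated = exclude_truncated,
    epochs_kept = vapply(epochs, function(e) length(e$epochs), integer(1)),
    epochs_rejected = vapply(epochs, function(e)
      e$provenance$n_rejected %||% 0L, integer(1)),
    interpolated_channels = vapply(epochs, function(e)
      length(e$provenance$interpolated_channels %||% character(0)), integer(1)))
  out <- list(subject_stats = subject_stats, grand_mean = gm,
              subject_models = lapply(per_subject, `[[`, "model"),
              analysis = analysis, provenance = provenance)
  if (!is.null(out_dir)) write_results(out, out_dir, provenance = provenance)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-command synthetic demo
#'
#' Generates a synthetic cohort with planted microstate structure and trait
#' effects, runs the full pipeline, and returns the results bundle together
#' with the ground truth.
#'
#' @param seed RNG seed.
#' @param n_subjects Cohort size.
#' @param record_seconds Recording length per subject.
#' @param snr Signal-to-noise ratio of the simulated EEG.
#' @param ... Further arguments to [cohort_sim_config()].
#' @return The [run_pipeline()] bundle, plus elements `truth` and `config`.
#' @export
demo_cohort_analysis <- function(seed = 1, n_subjects = 10,
                                 record_seconds = 60, snr = 5, ...) {
  cf <- cohort_sim_config(n_subjects = n_subjects,
                          record_seconds = record_seconds, snr = snr,
                          seed = seed, ...)
  sim <- simulate_cohort(cf)
  res <- run_pipeline(sim$recordings, sim$subjects,
                      montage = cf$montage, K = cf$K,
                      templates = cf$true_maps)
  res$truth <- sim$truth
  res$config <- cf
  res
}
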