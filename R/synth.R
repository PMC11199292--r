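#' Synthetic resting-state EEG and cohorts with known ground truth
#'
#' The generator plants a known microstate structure: at every instant the
#' scalp topography is one of K fixed zero-mean maps, driven by a
#' sign-flipping oscillatory activation, with state run lengths drawn from a
#' per-subject duration law. A cohort layer adds a trait score (12-item
#' aggression questionnaire) that depends linearly on each subject's true mean
#' state duration with a gender-dependent slope. Every stage downstream of raw
#' data can therefore be validated against ground truth.
#'
#' @name synth
NULL

# ---- topographic helpers ----------------------------------------------------

.zero_mean_unit <- function(v) {
  v <- as.numeric(v)
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (constant) topography")
  v / n
}

#' Canonical prototype topographies
#'
#' Builds K prototype maps over a montage. The first four follow the canonical
#' resting-state orientations: A, a left-posterior to right-frontal diagonal
#' gradient; B, its left-right mirror; C, a posterior-anterior gradient with an
#' occipito-parietal emphasis; D, a fronto-central focal pattern. Maps beyond
#' four are smooth random topographies. All maps are zero-mean across channels
#' and unit Euclidean norm.
#'
#' @param montage A `sensor_montage`.
#' @param K Number of maps (default 4).
#' @param seed RNG seed, used only when K > 4.
#' @return channels x K matrix; columns named "A", "B", "C", "D", then "E5"...
#' @export
make_prototype_maps <- function(montage, K = 4, seed = 1) {
  stopifnot(inherits(montage, "sensor_montage"))
  p <- montage$positions
  if (nrow(p) < 2) stop("degenerate montage")
  grad <- function(d) .zero_mean_unit(p %*% (d / sqrt(sum(d^2))))
  bump <- function(center, sigma) {
    d <- acos(pmax(-1, pmin(1, p %*% (center / sqrt(sum(center^2))))))
    .zero_mean_unit(exp(-d^2 / (2 * sigma^2)))
  }
  proto <- cbind(
    A = grad(c(cos(55 * pi / 180), -sin(55 * pi / 180), 0)),
    B = grad(c(cos(55 * pi / 180), sin(55 * pi / 180), 0)),
    C = grad(c(-1, 0, 0.6)),
    D = bump(c(0.45, 0, 1), 0.8)
  )
  if (K < 1) stop("K must be >= 1")
  maps <- proto[, seq_len(min(K, 4)), drop = FALSE]
  if (K > 4) {
    set.seed(seed)
    extra <- vapply(seq_len(K - 4), function(i) {
      .zero_mean_unit(grad(stats::rnorm(3)) + bump(stats::rnorm(3), 0.9))
    }, numeric(nrow(p)))
    colnames(extra) <- paste0("E", 5:K)
    maps <- cbind(maps, extra)
  }
  rownames(maps) <- montage$labels
  maps
}

# ---- duration laws ----------------------------------------------------------

#' Run-length (duration) laws
#'
#' A duration law describes the distribution of microstate run lengths in
#' samples. `"gamma"` draws from a gamma distribution parameterized by mean
#' and sd, rounded to the nearest integer with a floor of 1 sample; `"fixed"`
#' always returns `round(mean)`.
#'
#' @param dist "gamma" or "fixed".
#' @param mean Mean run length in samples (> 0).
#' @param sd Standard deviation in samples (gamma only, > 0).
#' @return A `duration_law` object.
#' @export
duration_law <- function(dist = c("gamma", "fixed"), mean, sd = NULL) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(mean), mean > 0)
  if (dist == "gamma") stopifnot(is.numeric(sd), sd > 0)
  structure(list(dist = dist, mean = mean, sd = sd), class = "duration_law")
}

.draw_runs <- function(law, n) {
  if (n == 0) return(integer(0))
  if (law$dist == "fixed") return(rep.int(max(1L, as.integer(round(law$mean))), n))
  shape <- (law$mean / law$sd)^2
  rate <- shape / law$mean
  pmax(1L, as.integer(round(stats::rgamma(n, shape = shape, rate = rate))))
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Run lengths are i.i.d. draws from `law`; each new state is uniform over the
#' other K - 1 states (no self-transitions).
#'
#' @param law A [duration_law()] with run lengths in samples.
#' @param n_samples Sequence length; 0 yields an empty sequence.
#' @param K Number of states (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of labels in 1..K, length `n_samples`.
#' @export
simulate_state_sequence <- function(law, n_samples, K, seed = NULL) {
  stopifnot(inherits(law, "duration_law"), n_samples >= 0)
  if (K < 2) stop("K must be >= 2: no valid non-self transition exists for K = 1")
  if (n_samples == 0) return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  out <- integer(n_samples)
  pos <- 1L
  cur <- sample.int(K, 1L)
  # draw runs in blocks to limit RNG calls
  while (pos <= n_samples) {
    runs <- .draw_runs(law, max(16L, ceiling((n_samples - pos + 1L) / law$mean)))
    for (r in runs) {
      end <- min(n_samples, pos + r - 1L)
      out[pos:end] <- cur
      pos <- end + 1L
      cur <- (cur + sample.int(K - 1L, 1L) - 1L) %% K + 1L
      if (pos > n_samples) break
    }
  }
  out
}

# ---- EEG recording container ------------------------------------------------

#' Construct an EEG recording
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param sfreq Sampling frequency, Hz.
#' @param labels Channel names (defaults to rownames of `data`).
#' @param annotations data.frame with columns onset (s), duration (s), tag.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sfreq, labels = rownames(data),
                          annotations = NULL) {
  stopifnot(is.matrix(data), sfreq > 0)
  if (!all(is.finite(data))) stop("non-finite values in EEG data")
  if (is.null(labels)) labels <- sprintf("E%02d", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data), !anyDuplicated(labels))
  dur <- ncol(data) / sfreq
  if (is.null(annotations)) {
    annotations <- data.frame(onset = 0, duration = dur, tag = "eyes_closed")
  }
  stopifnot(all(c("onset", "duration", "tag") %in% names(annotations)))
  if (any(annotations$onset < 0 | annotations$onset + annotations$duration > dur + 1e-9))
    stop("annotations exceed record bounds")
  rownames(data) <- labels
  structure(list(data = data, sfreq = sfreq, labels = labels,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              nrow(x$annotations)))
  invisible(x)
}

#' Simulate multichannel EEG from a planted microstate sequence
#'
#' Sample t equals `maps[, label(t)] * a(t)` plus spatially white Gaussian
#' noise, where `a(t)` is an amplitude-modulated sinusoid at `oscillation_hz`
#' (so the topography's polarity flips within a state, as in alpha-band EEG).
#' Noise is scaled so that RMS(signal) / RMS(noise) matches `snr`.
#'
#' @param maps channels x K matrix of zero-mean maps.
#' @param labels Integer label vector (values in 1..K).
#' @param snr Signal-to-noise RMS ratio; `Inf` disables noise.
#' @param oscillation_hz Carrier frequency, Hz.
#' @param sfreq Sampling frequency, Hz.
#' @param seed RNG seed.
#' @param amplitude_uV Peak carrier amplitude scale, microvolts.
#' @param channel_labels Channel names for the recording.
#' @return An `eeg_recording`; attributes `true_labels` and `carrier` carry
#'   the ground truth.
#' @export
simulate_eeg <- function(maps, labels, snr = 5, oscillation_hz = 10,
                         sfreq = 512, seed = NULL, amplitude_uV = 60,
                         channel_labels = rownames(maps)) {
  stopifnot(is.matrix(maps), length(labels) > 0)
  if (any(labels < 1 | labels > ncol(maps))) stop("labels out of range for maps")
  if (max(abs(colMeans(maps))) > 1e-8) stop("maps must be zero-mean across channels")
  if (snr <= 0) stop("snr must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  t <- (seq_len(n) - 1) / sfreq
  phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.5 * sin(2 * pi * 0.4 * t + stats::runif(1, 0, 2 * pi))
  a <- amplitude_uV * env * sin(2 * pi * oscillation_hz * t + phase)
  sig <- maps[, labels, drop = FALSE] * rep(a, each = nrow(maps))
  colnames(sig) <- NULL
  rms_sig <- sqrt(mean(sig^2))
  if (is.finite(snr)) {
    noise <- matrix(stats::rnorm(length(sig), sd = rms_sig / snr), nrow(sig))
    data <- sig + noise
  } else {
    data <- sig
  }
  rec <- eeg_recording(data, sfreq, labels = channel_labels)
  attr(rec, "true_labels") <- labels
  attr(rec, "carrier") <- a
  rec
}

#' Inject amplitude spikes (synthetic artifacts)
#'
#' Adds square pulses on one channel, for exercising the +/-100 uV rejection
#' rule. Returns the modified recording; attribute `spike_onsets_s` records
#' where spikes were planted.
#'
#' @param rec An `eeg_recording`.
#' @param onsets_s Spike onset times, seconds.
#' @param amplitude_uV Spike amplitude (added to channel `channel`).
#' @param width_s Spike width, seconds.
#' @param channel Channel index.
#' @export
inject_spikes <- function(rec, onsets_s, amplitude_uV = 150, width_s = 0.02,
                          channel = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  for (on in onsets_s) {
    i0 <- floor(on * rec$sfreq) + 1L
    i1 <- min(n, i0 + max(1L, round(width_s * rec$sfreq)) - 1L)
    if (i0 > n) stop("spike onset beyond record end")
    rec$data[channel, i0:i1] <- rec$data[channel, i0:i1] + amplitude_uV
  }
  attr(rec, "spike_onsets_s") <- onsets_s
  rec
}

# ---- cohort simulation ------------------------------------------------------

#' Cohort simulation configuration
#'
#' Ground-truth parameters for a synthetic cohort: per-subject mean state
#' durations drawn from a normal population law (mean/sd in ms, floored at
#' 20 ms), a within-subject gamma run-length law, an EEG forward model, and a
#' trait model in which the standardized aggression score equals
#' `beta_gender * z(true mean duration) + noise`, mapped affinely onto the
#' 1-6 questionnaire scale and discretized into 12 item responses.
#'
#' When `noise_sd_trait` is NULL, the residual sd defaults to
#' `sqrt(1 - beta^2)` per gender so the planted standardized slope equals
#' `beta` exactly in expectation.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param K Number of microstate classes.
#' @param montage A `sensor_montage` (default: packaged 64-channel cap).
#' @param true_maps channels x K matrix; default [make_prototype_maps()].
#' @param duration_mean_population,duration_sd_population Population law of
#'   per-subject mean durations, ms.
#' @param duration_within_sd Within-subject run-length sd, ms.
#' @param snr Signal-to-noise RMS ratio.
#' @param oscillation_hz Carrier frequency, Hz.
#' @param sfreq Sampling rate, Hz.
#' @param record_seconds Recording length per subject, s.
#' @param beta_male,beta_female Planted standardized slopes of aggression on
#'   mean duration (|beta| <= 1).
#' @param noise_sd_trait Residual sd of the latent trait model, or NULL.
#' @param prop_female Proportion of female subjects (default 58/101).
#' @param aq_center,aq_scale Affine map from the standardized latent trait to
#'   the 1-6 questionnaire scale.
#' @param clip If TRUE, questionnaire targets falling outside 1-6 are
#'   winsorized to the scale bounds; if FALSE (default) they raise an error.
#' @param seed RNG seed (mandatory).
#' @return A `cohort_sim_config` object.
#' @export
cohort_sim_config <- function(n_subjects, K = 4, montage = make_montage(64),
                              true_maps = NULL,
                              duration_mean_population = 80,
                              duration_sd_population = 15,
                              duration_within_sd = 15,
                              snr = 5, oscillation_hz = 10, sfreq = 512,
                              record_seconds = 120,
                              beta_male = -0.471, beta_female = -0.141,
                              noise_sd_trait = NULL,
                              prop_female = 58 / 101,
                              aq_center = 3.5, aq_scale = 0.55,
                              clip = FALSE, seed) {
  stopifnot(n_subjects >= 2, snr > 0, duration_mean_population > 0,
            abs(beta_male) <= 1, abs(beta_female) <= 1,
            prop_female >= 0, prop_female <= 1)
  if (missing(seed)) stop("seed is mandatory in cohort_sim_config")
  if (is.null(true_maps)) true_maps <- make_prototype_maps(montage, K)
  stopifnot(ncol(true_maps) == K, nrow(true_maps) == length(montage$labels))
  structure(as.list(environment()), class = "cohort_sim_config")
}

# Distribute target score s into 12 items in 1..6 whose mean is round(12 s)/12,
# then apply mean-preserving jitter.
.aq_items_from_target <- function(s, n_items = 12L, lo = 1L, hi = 6L) {
  total <- as.integer(round(s * n_items))
  total <- max(lo * n_items, min(hi * n_items, total))
  q <- total %/% n_items
  r <- total %% n_items
  items <- c(rep.int(q + 1L, r), rep.int(q, n_items - r))
  items <- items[sample.int(n_items)]
  for (j in seq_len(2L * n_items)) {       # mean-preserving +/-1 swaps
    ij <- sample.int(n_items, 2L)
    if (items[ij[1]] < hi && items[ij[2]] > lo) {
      items[ij[1]] <- items[ij[1]] + 1L
      items[ij[2]] <- items[ij[2]] - 1L
    }
  }
  items
}

#' Simulate a cohort with planted microstate structure and trait effects
#'
#' @param config A [cohort_sim_config()].
#' @param make_eeg If FALSE, skip the EEG forward model and return only the
#'   subject table and ground truth (fast path for statistical simulations).
#' @return List with `recordings` (list of `eeg_recording` or NULL),
#'   `subjects` (data.frame: subject_id, gender, aq_item_01..aq_item_12), and
#'   `truth` (data.frame: subject_id, gender, true_mean_duration_ms,
#'   latent_trait, aq_target, aq_score).
#' @export
simulate_cohort <- function(config, make_eeg = TRUE) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_subjects
  n_f <- round(cf$prop_female * n)
  gender <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  true_dur <- pmax(20, stats::rnorm(n, cf$duration_mean_population,
                                    cf$duration_sd_population))
  z <- as.numeric(scale(true_dur))
  beta <- ifelse(gender == "male", cf$beta_male, cf$beta_female)
  sd_eps <- if (is.null(cf$noise_sd_trait)) sqrt(1 - beta^2) else
    rep(cf$noise_sd_trait, n)
  latent <- beta * z + stats::rnorm(n, sd = sd_eps)
  target <- cf$aq_center + cf$aq_scale * latent
  if (any(target < 1 | target > 6)) {
    if (cf$clip) target <- pmin(6, pmax(1, target)) else
      stop("aggression target outside the 1-6 scale; reduce aq_scale or set clip = TRUE")
  }
  items <- t(vapply(target, .aq_items_from_target, integer(12)))
  colnames(items) <- sprintf("aq_item_%02d", 1:12)
  subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         gender = gender, items,
                         stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = subjects$subject_id, gender = gender,
                      true_mean_duration_ms = true_dur,
                      latent_trait = latent, aq_target = target,
                      aq_score = rowMeans(items),
                      stringsAsFactors = FALSE)
  recordings <- NULL
  if (make_eeg) {
    n_samp <- as.integer(round(cf$record_seconds * cf$sfreq))
    seeds <- cf$seed + seq_len(n)
    recordings <- lapply(seq_len(n), function(i) {
      law <- duration_law("gamma",
                          mean = true_dur[i] * cf$sfreq / 1000,
                          sd = cf$duration_within_sd * cf$sfreq / 1000)
      lab <- simulate_state_sequence(law, n_samp, cf$K, seed = seeds[i])
      simulate_eeg(cf$true_maps, lab, snr = cf$snr,
                   oscillation_hz = cf$oscillation_hz, sfreq = cf$sfreq,
                   channel_labels = rownames(cf$true_maps))
    })
    names(recordings) <- subjects$subject_id
  }
  list(recordings = recordings, subjects = subjects, truth = truth)
}
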