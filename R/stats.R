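#' Trait-association statistics for microstate stability
#'
#' Scores the 12-item short-form aggression questionnaire, quantifies the
#' within-subject consistency of microstate metrics across the four classes
#' (random-intercept model comparison and intraclass correlation), and relates
#' mean duration / mean occurrence to aggression via standardized regression
#' and gender-moderated regression with simple slopes.
#'
#' @name traitstats
NULL

# item -> subscale map for the 12-item short form: three items per subscale
.aq_subscales <- list(physical = 1:3, verbal = 4:6, hostility = 7:9,
                      anger = 10:12)

#' Score the 12-item aggression questionnaire
#'
#' The total score is the mean of all 12 items; each subscale (physical
#' aggression, verbal aggression, hostility, anger) is the mean of its three
#' items. No reverse scoring. Items must be integers in 1..6; missing or
#' out-of-range items raise an error (no imputation).
#'
#' @param items Numeric vector of exactly 12 item responses in 1..6.
#' @return Named list: `total`, `physical`, `verbal`, `hostility`, `anger`.
#' @examples
#' score_aq(c(2, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5))
#' @export
score_aq <- function(items) {
  if (length(items) != 12) stop("exactly 12 items required")
  if (anyNA(items) || !all(items %in% 1:6))
    stop("all items must be integers in 1..6 (no imputation)")
  c(list(total = mean(items)),
    lapply(.aq_subscales, function(ix) mean(items[ix])))
}

#' Add questionnaire scores to a subject table
#'
#' @param subjects data.frame with columns `aq_item_01` .. `aq_item_12`.
#' @return The table with `aq_total`, `aq_physical`, `aq_verbal`,
#'   `aq_hostility`, `aq_anger` appended.
#' @export
score_aq_table <- function(subjects) {
  cols <- sprintf("aq_item_%02d", 1:12)
  if (!all(cols %in% names(subjects))) stop("missing aq_item_01..aq_item_12 columns")
  items <- as.matrix(subjects[, cols])
  sc <- t(apply(items, 1, function(r) unlist(score_aq(r))))
  colnames(sc) <- paste0("aq_", colnames(sc))
  cbind(subjects, as.data.frame(sc))
}

#' Long-format stability table
#'
#' Reshapes per-subject per-type metrics into one row per subject x
#' microstate type.
#'
#' @param wide data.frame with `subject_id` and columns `duration_<type>` and
#'   `occurrence_<type>` for types A..D (or the model's map labels).
#' @param types Microstate type labels (default A, B, C, D).
#' @return data.frame: subject_id, microstate_type, duration_ms, occurrence_hz.
#' @export
stability_long <- function(wide, types = c("A", "B", "C", "D")) {
  dcols <- paste0("duration_", types)
  ocols <- paste0("occurrence_", types)
  if (!all(c(dcols, ocols, "subject_id") %in% names(wide)))
    stop("wide table must contain subject_id and duration_/occurrence_ columns per type")
  do.call(rbind, lapply(seq_along(types), function(j) {
    data.frame(subject_id = wide$subject_id, microstate_type = types[j],
               duration_ms = wide[[dcols[j]]], occurrence_hz = wide[[ocols[j]]],
               stringsAsFactors = FALSE)
  }))
}

.long_metric <- function(long_table, metric = c("duration", "occurrence")) {
  metric <- match.arg(metric)
  col <- if (metric == "duration") "duration_ms" else "occurrence_hz"
  stopifnot(all(c("subject_id", "microstate_type", col) %in% names(long_table)))
  data.frame(subject = factor(long_table$subject_id),
             type = factor(long_table$microstate_type),
             y = long_table[[col]])
}

#' One-way random-effects intraclass correlation
#'
#' Fits a random-intercept model (subject as random factor over the K
#' microstate types) by REML and returns
#' `ICC = var_between / (var_between + var_within)`. Degenerate input with
#' zero total variance raises an error; a zero within-subject variance gives
#' ICC = 1 directly.
#'
#' @param long_table Long-format table (see [stability_long()]), >= 2
#'   subjects with one row per type.
#' @param metric "duration" or "occurrence".
#' @return An `icc_result`: list(icc, variance_between, variance_within).
#' @export
icc_oneway <- function(long_table, metric = c("duration", "occurrence")) {
  d <- .long_metric(long_table, metric)
  if (nlevels(d$subject) < 2) stop("need >= 2 subjects")
  tot <- stats::var(d$y)
  if (!is.finite(tot) || tot < 1e-24) stop("degenerate input: zero total variance")
  subj_means <- tapply(d$y, d$subject, mean)
  ss_within <- sum((d$y - subj_means[d$subject])^2)
  if (ss_within / (length(d$y) * tot) < 1e-12) {
    out <- list(icc = 1, variance_between = stats::var(subj_means),
                variance_within = 0)
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | subject), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vb <- max(0, vc$vcov[vc$grp == "subject"])
    vw <- vc$vcov[vc$grp == "Residual"]
    out <- list(icc = vb / (vb + vw), variance_between = vb,
                variance_within = vw)
  }
  structure(out, class = "icc_result")
}

#' Compare a fixed-effect model with a random-intercept model
#'
#' Both models include microstate type as a fixed categorical predictor; the
#' mixed model adds a subject random intercept. Both are fit by maximum
#' likelihood; the likelihood-ratio statistic is referred to a chi-square
#' with 1 df (conservative at the variance boundary). With
#' `boundary_mixture = TRUE` the 50:50 mixture of chi-square(0) and
#' chi-square(1) is used instead.
#'
#' @param long_table Long-format table.
#' @param metric "duration" or "occurrence".
#' @param boundary_mixture Use the boundary-corrected null distribution.
#' @return A `model_comparison_result`: loglik_fixed, loglik_mixed,
#'   lrt_statistic, df, p_value.
#' @export
compare_fixed_vs_random_intercept <- function(long_table,
                                              metric = c("duration", "occurrence"),
                                              boundary_mixture = FALSE) {
  d <- .long_metric(long_table, metric)
  fixed <- stats::lm(y ~ type, data = d)
  mixed <- tryCatch(
    lme4::lmer(y ~ type + (1 | subject), data = d, REML = FALSE),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  ll_f <- as.numeric(stats::logLik(fixed))
  ll_m <- as.numeric(stats::logLik(mixed))
  lrt <- max(0, 2 * (ll_m - ll_f))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- if (lrt == 0) 1 else 0.5 * p
  structure(list(loglik_fixed = ll_f, loglik_mixed = max(ll_m, ll_f),
                 lrt_statistic = lrt, df = 1, p_value = p),
            class = "model_comparison_result")
}

#' Standardized simple regression
#'
#' Ordinary least squares of z-scored y on z-scored x; the slope equals the
#' Pearson correlation and R-squared equals its square.
#'
#' @param y,x Numeric vectors, n >= 3, nonzero variance.
#' @return A `regression_result`: beta_standardized, p_value, r_squared, n.
#' @export
regress_standardized <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("constant input: zero variance in x or y")
  fit <- stats::lm(scale(y) ~ scale(x))
  s <- summary(fit)
  structure(list(beta_standardized = unname(stats::coef(fit)[2]),
                 p_value = s$coefficients[2, 4],
                 r_squared = s$r.squared, n = n),
            class = "regression_result")
}

#' Gender-moderated regression (simple moderation)
#'
#' Fits `y = b0 + b1 x + b2 g + b3 (x g)` with y and x z-scored over the
#' whole sample and the moderator coded 0/1 (0 = first factor level). Reports
#' the interaction coefficient with t, df = n - 4, two-sided p and 95% CI,
#' the full-model R-squared, the R-squared change relative to the
#' no-interaction model, and per-group simple slopes (standardized regression
#' of y on x within each moderator level).
#'
#' @param y,x Numeric vectors.
#' @param g Two-level factor or character vector (both levels n >= 3).
#' @return A `moderation_result`.
#' @export
moderation_model1 <- function(y, x, g) {
  g <- factor(g)
  if (nlevels(g) != 2) stop("moderator must have exactly 2 levels, both present")
  if (any(table(g) < 3)) stop("each moderator level needs n >= 3")
  n <- length(y)
  stopifnot(length(x) == n, length(g) == n)
  zy <- as.numeric(scale(y)); zx <- as.numeric(scale(x))
  d01 <- as.numeric(g == levels(g)[2])
  full <- stats::lm(zy ~ zx * d01)
  red <- stats::lm(zy ~ zx + d01)
  s <- summary(full)
  co <- s$coefficients["zx:d01", ]
  ci <- stats::confint(full)["zx:d01", ]
  slopes <- lapply(levels(g), function(l)
    regress_standardized(y[g == l], x[g == l]))
  names(slopes) <- levels(g)
  structure(list(interaction_b = unname(co[1]), t_value = unname(co[2]),
                 df = n - 4, p_value = unname(co[4]),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 r_squared = s$r.squared,
                 r_squared_change = s$r.squared - summary(red)$r.squared,
                 simple_slopes = slopes,
                 coding = stats::setNames(0:1, levels(g)), n = n),
            class = "moderation_result")
}

#' Full trait-association analysis
#'
#' For each outcome (total aggression plus the four subscales) and each
#' predictor (mean duration, mean occurrence): pooled standardized beta and
#' p, per-gender simple slopes, and the gender-moderation model. When
#' per-type columns (`duration_A` .. `occurrence_D`) are present, also the
#' ICCs and fixed-vs-random-intercept comparisons for durations and
#' occurrences.
#'
#' @param subjects data.frame with `gender`, `mean_duration`,
#'   `mean_occurrence`, either `aq_total`..`aq_anger` or raw
#'   `aq_item_01`..`aq_item_12`, and optionally per-type metric columns.
#' @param types Microstate type labels for the long reshape.
#' @return A `trait_analysis` bundle: `grid` (data.frame, one row per
#'   outcome x predictor), `icc`, `model_comparison`, `meta`.
#' @export
run_full_analysis <- function(subjects, types = c("A", "B", "C", "D")) {
  if (!"aq_total" %in% names(subjects)) subjects <- score_aq_table(subjects)
  stopifnot(all(c("gender", "mean_duration", "mean_occurrence") %in% names(subjects)))
  outcomes <- c(total = "aq_total", physical = "aq_physical",
                verbal = "aq_verbal", hostility = "aq_hostility",
                anger = "aq_anger")
  predictors <- c(mean_duration = "mean_duration",
                  mean_occurrence = "mean_occurrence")
  g <- factor(subjects$gender)
  if (!setequal(levels(g), c("female", "male")))
    stop("gender must contain exactly the levels 'female' and 'male'")
  rows <- list()
  for (oc in names(outcomes)) for (pr in names(predictors)) {
    y <- subjects[[outcomes[oc]]]; x <- subjects[[predictors[pr]]]
    pooled <- regress_standardized(y, x)
    mod <- moderation_model1(y, x, g)
    sl <- mod$simple_slopes
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oc, predictor = pr, n = pooled$n,
      beta_pooled = pooled$beta_standardized, p_pooled = pooled$p_value,
      beta_male = sl$male$beta_standardized, p_male = sl$male$p_value,
      beta_female = sl$female$beta_standardized, p_female = sl$female$p_value,
      int_b = mod$interaction_b, int_t = mod$t_value, int_df = mod$df,
      int_p = mod$p_value, ci_low = mod$ci_low, ci_high = mod$ci_high,
      r_squared = mod$r_squared, r_squared_change = mod$r_squared_change,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  icc <- mc <- NULL
  if (all(paste0("duration_", types) %in% names(subjects))) {
    long <- stability_long(subjects, types)
    icc <- list(duration = icc_oneway(long, "duration"),
                occurrence = icc_oneway(long, "occurrence"))
    mc <- list(duration = compare_fixed_vs_random_intercept(long, "duration"),
               occurrence = compare_fixed_vs_random_intercept(long, "occurrence"))
  }
  structure(list(grid = grid, icc = icc, model_comparison = mc,
                 meta = list(alpha = 0.05, multiple_testing = "none",
                             moderator_coding = stats::setNames(0:1, levels(g)))),
            class = "trait_analysis")
}

#' @export
print.trait_analysis <- function(x, ...) {
  cat("<trait_analysis> outcome x predictor grid:\n")
  print(cbind(x$grid[, c("outcome", "predictor", "n")],
              round(x$grid[, c("beta_pooled", "p_pooled", "beta_male",
                               "beta_female", "int_b", "int_p",
                               "r_squared_change")], 3)))
  if (!is.null(x$icc)) {
    cat(sprintf("\nICC duration = %.3f, occurrence = %.3f\n",
                x$icc$duration$icc, x$icc$occurrence$icc))
    cat(sprintf("random-intercept LRT p: duration %.3g, occurrence %.3g\n",
                x$model_comparison$duration$p_value,
                x$model_comparison$occurrence$p_value))
  }
  invisible(x)
}

#' Approximate sample size for a simple correlation test
#'
#' Normal-approximation (Fisher z) sample size for detecting a correlation of
#' size `r` with a two-sided test. Approximate; intended for planning only.
#'
#' @param r Expected correlation magnitude.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @export
required_n_correlation <- function(r, alpha = 0.05, power = 0.85) {
  stopifnot(abs(r) > 0, abs(r) < 1)
  z <- atanh(abs(r))
  ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / z)^2 + 3)
}
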