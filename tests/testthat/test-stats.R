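sim_long <- function(n_subj, sd_b, sd_w, mu = 80, seed = 1) {
  set.seed(seed)
  subj <- rep(sprintf("S%03d", 1:n_subj), each = 4)
  intercept <- rep(rnorm(n_subj, mu, sd_b), each = 4)
  data.frame(subject_id = subj,
             microstate_type = rep(c("A", "B", "C", "D"), n_subj),
             duration_ms = intercept + rnorm(4 * n_subj, 0, sd_w),
             occurrence_hz = 12.5 / pmax(intercept + rnorm(4 * n_subj, 0, sd_w), 1) * 1000 / 80,
             stringsAsFactors = FALSE)
}

test_that("questionnaire scoring follows the mean-of-items rule", {
  all1 <- score_aq(rep(1, 12))
  expect_equal(all1$total, 1)
  expect_equal(unlist(all1[c("physical", "verbal", "hostility", "anger")]),
               c(physical = 1, verbal = 1, hostility = 1, anger = 1))
  expect_equal(score_aq(rep(6, 12))$total, 6)

  sc <- score_aq(c(2, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5))
  expect_equal(sc$physical, 2); expect_equal(sc$verbal, 3)
  expect_equal(sc$hostility, 4); expect_equal(sc$anger, 5)
  expect_equal(sc$total, 3.5)

  expect_error(score_aq(rep(3, 11)), "12 items")
  expect_error(score_aq(c(rep(3, 11), 7)), "1..6")
  expect_error(score_aq(c(rep(3, 11), NA)), "1..6")
})

test_that("ICC limits and recovery behave as a variance ratio should", {
  # zero within-subject variance -> ICC = 1
  lt <- sim_long(20, sd_b = 5, sd_w = 1, seed = 2)
  lt$duration_ms <- rep(tapply(lt$duration_ms, lt$subject_id, mean)[
    factor(lt$subject_id)], 1)
  expect_equal(icc_oneway(lt, "duration")$icc, 1)

  # zero between-subject variance -> ICC ~ 0
  lt0 <- sim_long(60, sd_b = 0, sd_w = 3, seed = 3)
  expect_lt(icc_oneway(lt0, "duration")$icc, 0.1)

  # planted variance ratio 3:1 -> ICC near 0.75
  ltr <- sim_long(100, sd_b = sqrt(3), sd_w = 1, seed = 4)
  r <- icc_oneway(ltr, "duration")
  expect_gt(r$icc, 0.65); expect_lt(r$icc, 0.85)
  expect_equal(r$icc, r$variance_between / (r$variance_between + r$variance_within))

  # affine invariance of the metric scale
  lt2 <- ltr
  lt2$duration_ms <- 3.7 * lt2$duration_ms - 12
  expect_equal(icc_oneway(lt2, "duration")$icc, r$icc, tolerance = 1e-6)

  ltc <- ltr; ltc$duration_ms <- 5
  expect_error(icc_oneway(ltc, "duration"), "zero total variance")
})

test_that("random-intercept model comparison detects subject heterogeneity", {
  # subject intercept SD = 3x residual SD: decisive rejection
  lt <- sim_long(100, sd_b = 9, sd_w = 3, seed = 5)
  r <- compare_fixed_vs_random_intercept(lt, "duration")
  expect_lt(r$p_value, 0.001)
  expect_gte(r$loglik_mixed, r$loglik_fixed)
  expect_gte(r$lrt_statistic, 0)

  # determinism
  r2 <- compare_fixed_vs_random_intercept(lt, "duration")
  expect_identical(r, r2)

  # boundary-conservative null calibration: rejection rate <= nominal 0.05
  rej <- vapply(1:400, function(s) {
    lt0 <- sim_long(40, sd_b = 0, sd_w = 3, seed = 1000 + s)
    compare_fixed_vs_random_intercept(lt0, "duration")$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05)
})

test_that("standardized regression equals the Pearson correlation", {
  x <- rnorm(50, sd = 3)
  r <- suppressWarnings(regress_standardized(x, x))  # exact fit by design
  expect_equal(r$beta_standardized, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  set.seed(7)
  y <- rnorm(10000); xx <- rnorm(10000)
  expect_lt(abs(regress_standardized(y, xx)$beta_standardized), 0.03)

  # beta == cor and R^2 == beta^2 across random inputs (to 1e-9)
  for (i in 1:10) {
    set.seed(20 + i)
    a <- rnorm(30); b <- 0.4 * a + rnorm(30)
    r <- regress_standardized(b, a)
    expect_equal(r$beta_standardized, stats::cor(a, b), tolerance = 1e-9)
    expect_equal(r$r_squared, r$beta_standardized^2, tolerance = 1e-9)
  }

  # unbiased recovery of a planted slope at n = 101
  est <- vapply(1:1000, function(s) {
    set.seed(3000 + s)
    x <- rnorm(101)
    y <- -0.265 * x + rnorm(101, sd = sqrt(1 - 0.265^2))
    regress_standardized(y, x)$beta_standardized
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.265), 0.02)

  expect_error(regress_standardized(rep(1, 10), rnorm(10)), "constant")
  expect_error(regress_standardized(rnorm(2), rnorm(2)), "n >= 3")
})

test_that("moderation model recovers group-specific slopes and is symmetric", {
  # identical slopes, noiseless: zero interaction, zero R^2 change
  set.seed(8)
  x <- rnorm(40); g <- rep(c("female", "male"), 20)
  y <- 2 * x + 3 * (g == "male")
  m0 <- suppressWarnings(moderation_model1(y, x, g))  # exact fit by design
  expect_equal(m0$interaction_b, 0, tolerance = 1e-9)
  expect_equal(m0$r_squared_change, 0, tolerance = 1e-9)
  expect_true(m0$ci_low <= m0$interaction_b && m0$interaction_b <= m0$ci_high)

  # planted per-gender slopes at n = 2000 via the cohort generator
  cf <- cohort_sim_config(n_subjects = 2000, beta_male = -0.47,
                          beta_female = -0.14, clip = TRUE, seed = 9)
  sim <- simulate_cohort(cf, make_eeg = FALSE)
  tab <- score_aq_table(sim$subjects)
  m <- moderation_model1(tab$aq_total, sim$truth$true_mean_duration_ms,
                         tab$gender)
  expect_lt(abs(m$simple_slopes$male$beta_standardized + 0.47), 0.07)
  expect_lt(abs(m$simple_slopes$female$beta_standardized + 0.14), 0.07)
  expect_equal(m$df, 2000 - 4)

  # swapping the coding flips the interaction sign, p unchanged
  g2 <- factor(tab$gender, levels = c("male", "female"))
  m_swap <- moderation_model1(tab$aq_total, sim$truth$true_mean_duration_ms, g2)
  expect_equal(m_swap$interaction_b, -m$interaction_b, tolerance = 1e-9)
  expect_equal(m_swap$p_value, m$p_value, tolerance = 1e-12)
  expect_equal(m_swap$simple_slopes$male$beta_standardized,
               m$simple_slopes$male$beta_standardized)

  expect_error(moderation_model1(y, x, rep("a", 40)), "2 levels")
})

test_that("interaction test keeps its nominal type-I error", {
  # null: same slope in both genders; n = 101 per replicate
  rej <- vapply(1:2000, function(s) {
    set.seed(5000 + s)
    g <- c(rep("female", 58), rep("male", 43))
    x <- rnorm(101)
    y <- -0.3 * x + rnorm(101, sd = sqrt(1 - 0.09))
    moderation_model1(y, x, g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("planted effects at the study's sample size are recovered unbiasedly", {
  # (beta_pooled, beta_men, beta_women) planted via per-gender slopes
  n_rep <- 1000
  est <- matrix(0, n_rep, 3,
                dimnames = list(NULL, c("pooled", "male", "female")))
  for (r in 1:n_rep) {
    cf <- cohort_sim_config(n_subjects = 101, beta_male = -0.47,
                            beta_female = -0.14, clip = TRUE, seed = 7000 + r)
    sim <- simulate_cohort(cf, make_eeg = FALSE)
    tab <- score_aq_table(sim$subjects)
    x <- sim$truth$true_mean_duration_ms
    est[r, "pooled"] <- regress_standardized(tab$aq_total, x)$beta_standardized
    m <- moderation_model1(tab$aq_total, x, tab$gender)
    est[r, "male"] <- m$simple_slopes$male$beta_standardized
    est[r, "female"] <- m$simple_slopes$female$beta_standardized
  }
  p_m <- 1 - 58 / 101
  planted_pooled <- p_m * -0.47 + (1 - p_m) * -0.14
  expect_lt(abs(mean(est[, "pooled"]) - planted_pooled), 0.03)
  expect_lt(abs(mean(est[, "male"]) + 0.47), 0.03)
  expect_lt(abs(mean(est[, "female"]) + 0.14), 0.03)
})

test_that("the full analysis grid is deterministic and matches planted signs", {
  cf <- cohort_sim_config(n_subjects = 300, beta_male = -0.6,
                          beta_female = -0.2, clip = TRUE, seed = 11)
  sim <- simulate_cohort(cf, make_eeg = FALSE)
  tab <- score_aq_table(sim$subjects)
  tab$mean_duration <- sim$truth$true_mean_duration_ms
  tab$mean_occurrence <- 1000 / tab$mean_duration  # reciprocal proxy
  for (ty in c("A", "B", "C", "D")) {
    tab[[paste0("duration_", ty)]] <- tab$mean_duration + rnorm(300, 0, 4)
    tab[[paste0("occurrence_", ty)]] <- tab$mean_occurrence + rnorm(300, 0, 0.4)
  }
  b1 <- run_full_analysis(tab)
  b2 <- run_full_analysis(tab)
  expect_identical(b1$grid, b2$grid)
  expect_equal(nrow(b1$grid), 10)  # 5 outcomes x 2 predictors

  tot_dur <- b1$grid[b1$grid$outcome == "total" &
                     b1$grid$predictor == "mean_duration", ]
  expect_lt(tot_dur$beta_pooled, 0)
  expect_lt(tot_dur$beta_male, tot_dur$beta_female)  # stronger in men
  expect_lt(tot_dur$p_pooled, 0.001)
  tot_occ <- b1$grid[b1$grid$outcome == "total" &
                     b1$grid$predictor == "mean_occurrence", ]
  expect_gt(tot_occ$beta_pooled, 0)  # occurrence associates positively

  expect_gt(b1$icc$duration$icc, 0.8)
  expect_lt(b1$model_comparison$duration$p_value, 0.001)
})

test_that("null cohorts produce the nominal rate of significant cells", {
  hits <- 0; cells <- 0
  for (r in 1:150) {
    cf <- cohort_sim_config(n_subjects = 101, beta_male = 0, beta_female = 0,
                            clip = TRUE, seed = 9000 + r)
    sim <- simulate_cohort(cf, make_eeg = FALSE)
    tab <- score_aq_table(sim$subjects)
    p <- vapply(c("aq_total", "aq_physical", "aq_verbal", "aq_hostility",
                  "aq_anger"), function(oc)
      regress_standardized(tab[[oc]], sim$truth$true_mean_duration_ms)$p_value,
      numeric(1))
    hits <- hits + sum(p < 0.05); cells <- cells + length(p)
  }
  expect_gt(hits / cells, 0.02)
  expect_lt(hits / cells, 0.09)
})
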