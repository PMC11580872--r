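test_that("per-subject summaries reduce to hand-computable statistics", {
  trials <- tibble::tibble(
    subject_id = "S1", task = "linear_bar",
    itd_us = rep(c(0, 240), c(3, 9)),
    response = c(-1, 0, 1, rep(0.5, 9)),
    reaction_time_s = 0.5, confidence = 70
  )
  s <- summarize_subjects(trials)
  r0 <- s[s$itd_us == 0, ]
  expect_equal(r0$mean_estimate, 0)
  expect_equal(r0$sd_estimate, 1) # sd of {-1, 0, 1} with n-1 denominator
  r240 <- s[s$itd_us == 240, ]
  expect_equal(r240$mean_estimate, 0.5)
  expect_equal(r240$sd_estimate, 0)
  expect_equal(r240$n_trials, 9)
})

test_that("single-trial ITD levels flag an undefined SD", {
  trials <- tibble::tibble(
    subject_id = "S1", task = "linear_bar", itd_us = c(0, 240, 240),
    response = c(0.1, 0.5, 0.6), reaction_time_s = 0.4, confidence = 50
  )
  expect_warning(s <- summarize_subjects(trials), "undefined")
  expect_true(is.na(s$sd_estimate[s$itd_us == 0]))
})

test_that("noise-free summaries equal the generator curve", {
  m <- subject_model("azimuth_pointer", sd_front = 0, sd_periphery = 0)
  s <- summarize_subjects(simulate_cohort(m, n_blocks_per_task = 1, seed = 4))
  expect_equal(s$mean_estimate, mean_response(m, s$itd_us), tolerance = 1e-12)
})

test_that("z-scored mean vectors are standardized and affine-invariant", {
  base <- c(-4, -2.5, 0.2, 2.8, 4.1)
  summaries <- dplyr::bind_rows(
    tibble::tibble(
      subject_id = "deg", task = "t", itd_us = seq(-480, 480, 240),
      mean_estimate = 12 * base + 3, sd_estimate = abs(base) + 1,
      mean_rt_s = 0.5, mean_confidence = 60, n_trials = 9
    ),
    tibble::tibble(
      subject_id = "dB", task = "t", itd_us = seq(-480, 480, 240),
      mean_estimate = 0.8 * base - 0.1, sd_estimate = 0.8 * (abs(base) + 1),
      mean_rt_s = 0.5, mean_confidence = 60, n_trials = 9
    )
  )
  z <- zscore_pool(summaries, n_boot = 200, seed = 1)
  per_subj <- split(z$by_subject, z$by_subject$subject_id)
  for (s in per_subj) {
    expect_equal(mean(s$z_mean), 0, tolerance = 1e-12)
    expect_equal(sd(s$z_mean), 1, tolerance = 1e-12)
  }
  # proportional response scales give identical z vectors
  expect_equal(per_subj[["deg"]]$z_mean, per_subj[["dB"]]$z_mean,
    tolerance = 1e-12
  )
  expect_error(
    zscore_pool(dplyr::mutate(summaries, mean_estimate = 1)),
    "zero variance"
  )
})

test_that("bootstrap CI behaves on degenerate and regular input", {
  const <- matrix(5, 10, 1)
  ci <- bootstrap_mean_ci(const, n_boot = 500, seed = 1)
  expect_equal(ci$conf.low, 5)
  expect_equal(ci$conf.high, 5)
  x <- matrix(withr::with_seed(2, rnorm(14 * 3)), 14, 3)
  ci <- bootstrap_mean_ci(x, n_boot = 2000, seed = 2)
  expect_true(all(ci$conf.low <= ci$mean & ci$mean <= ci$conf.high))
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    x <- matrix(withr::with_seed(seed, rnorm(n)), n, 1)
    ci <- bootstrap_mean_ci(x, n_boot = 2000, seed = seed)
    ci$conf.high - ci$conf.low
  }
  ratios <- vapply(1:12, function(s) {
    width_at(10, s) / width_at(40, s + 100)
  }, numeric(1))
  expect_equal(median(ratios), 2, tolerance = 0.35)
})

test_that("paired bootstrap separates clear effects and not null ones", {
  same <- rnorm(10)
  expect_equal(paired_bootstrap_test(same, same, 500, seed = 1)$p.value, 1)
  a <- 1:10
  b <- a - 5 # all differences equal, same sign
  expect_lte(paired_bootstrap_test(a, b, 2000, seed = 1)$p.value, 0.01)
})

test_that("sigmoid fit recovers exact generator parameters", {
  k_true <- 0.0065
  d <- tibble::tibble(itd_us = rep(seq(-480, 480, 240), 3))
  d$estimate <- 50 * (2 / (1 + exp(-k_true * d$itd_us)) - 1)
  f <- fit_sigmoid(d, n_boot = 0)
  expect_equal(f$A, 50, tolerance = 0.01)
  expect_equal(f$k, k_true, tolerance = 0.02)
  # degenerate all-zero data collapses to A = 0
  d0 <- tibble::tibble(itd_us = seq(-480, 480, 240), estimate = 0)
  expect_equal(fit_sigmoid(d0, n_boot = 0)$A, 0)
})

test_that("tidy/glance/predict expose the fit in broom style", {
  d <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 5),
    itd_us = rep(seq(-480, 480, 240), 2)
  )
  d$estimate <- 45 * (2 / (1 + exp(-0.008 * d$itd_us)) - 1) +
    withr::with_seed(3, rnorm(10, 0, 2))
  f <- fit_sigmoid(d, n_boot = 200, seed = 3)
  td <- tidy(f)
  expect_equal(td$term, c("A", "k"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(f)
  expect_equal(g$n, 10L)
  expect_gt(g$n_boot, 0)
  expect_equal(predict(f, 0), 0)
})

test_that("acoustic map inversion matches the closed-form sphere", {
  cm <- default_cue_map()
  inv <- invert_acoustic_map(cm, 500)
  # printed stimulus <-> azimuth correspondences
  expect_equal(inv(480), sphere_azimuth_of_itd(480), tolerance = 0.02)
  expect_equal(inv(240), sphere_azimuth_of_itd(240), tolerance = 0.02)
  expect_lt(abs(inv(0)), 0.5)
  # inversion identity across the measured grid
  s500 <- dplyr::filter(cm$summary, band_hz == 500)
  expect_equal(inv(s500$itd_median), s500$azimuth_deg, tolerance = 0.5)
  # out-of-domain queries fail loudly
  expect_error(inv(900), "outside the acoustic domain")
})

test_that("non-monotone bands cannot be inverted", {
  cm <- default_cue_map()
  expect_error(invert_acoustic_map(cm, 3000), "not monotone")
})

test_that("bias curve vanishes when percept equals acoustics and is odd", {
  cm <- default_cue_map()
  inv <- invert_acoustic_map(cm, 500)
  d <- tibble::tibble(itd_us = seq(-480, 480, 240))
  d$estimate <- 50 * (2 / (1 + exp(-0.008 * d$itd_us)) - 1)
  f <- fit_sigmoid(d, n_boot = 0)
  # perceived == acoustic: zero bias by construction
  self <- f$fitted
  attr(self, "domain") <- c(-700, 700)
  bc0 <- compute_bias_curve(f, self, seq(-700, 700, 100))
  expect_equal(max(abs(bc0$bias_deg)), 0, tolerance = 1e-9)
  # antisymmetric inputs give an odd bias curve
  grid <- seq(-700, 700, 100)
  bc <- compute_bias_curve(f, inv, grid)
  expect_equal(bc$bias_deg, -rev(bc$bias_deg), tolerance = 0.1)
  expect_lt(abs(bc$bias_deg[grid == 0]), 0.2)
  expect_error(compute_bias_curve(f, inv, seq(-900, 900, 100)), "outside")
})

test_that("noise-free bias equals the closed-form psi minus asin difference", {
  cm <- default_cue_map()
  inv <- invert_acoustic_map(cm, 500)
  d <- tibble::tibble(itd_us = rep(seq(-480, 480, 240), 2))
  d$estimate <- 50 * (2 / (1 + exp(-0.008 * d$itd_us)) - 1)
  f <- fit_sigmoid(d, n_boot = 0)
  grid <- seq(-700, 700, 50)
  bc <- compute_bias_curve(f, inv, grid)
  closed <- 50 * (2 / (1 + exp(-0.008 * grid)) - 1) -
    sphere_azimuth_of_itd(grid)
  expect_lt(max(abs(bc$bias_deg - closed)), 0.5)
})

test_that("plot methods return ggplot objects", {
  cm <- coarse_cue_map()
  expect_s3_class(autoplot(cm), "gg")
  expect_s3_class(autoplot(cm, cue = "ild", show_branches = FALSE), "gg")
  m <- cohort_models(4, tasks = "azimuth_pointer", seed = 5)
  s <- summarize_subjects(simulate_cohort(m, n_blocks_per_task = 1, seed = 5))
  z <- zscore_pool(s, n_boot = 100, seed = 5)
  expect_s3_class(autoplot(z), "gg")
  expect_s3_class(autoplot(z, which = "sd"), "gg")
  f <- fit_sigmoid(dplyr::rename(s, estimate = mean_estimate),
    n_boot = 50, seed = 5
  )
  expect_s3_class(autoplot(f), "gg")
  inv <- invert_acoustic_map(default_cue_map(), 500)
  bc <- compute_bias_curve(f, inv, seq(-700, 700, 100))
  expect_s3_class(autoplot(bc), "gg")
  expect_s3_class(autoplot(bc, which = "curves"), "gg")
})
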