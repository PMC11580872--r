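test_that("mean response is odd, zero at the front, saturating at A", {
  m <- subject_model("azimuth_pointer")
  expect_equal(mean_response(m, 0), 0)
  expect_equal(mean_response(m, 1e9), m$A)
  expect_equal(mean_response(m, -1e9), -m$A)
  x <- c(120, 240, 480, 700)
  expect_equal(mean_response(m, -x), -mean_response(m, x))
  # A = 50 with k chosen so psi(480) = 48 implies psi(-480) = -48
  k48 <- atanh(48 / 50) / 240
  m2 <- subject_model("azimuth_pointer", A = 50, k = k48)
  expect_equal(mean_response(m2, 480), 48, tolerance = 1e-9)
  expect_equal(mean_response(m2, -480), -48, tolerance = 1e-9)
})

test_that("trial SD interpolates its anchors and decreases toward the periphery", {
  m <- subject_model("azimuth_pointer")
  expect_equal(trial_sd(m, 0), 36.3)
  expect_equal(trial_sd(m, 480), 14.0)
  expect_equal(trial_sd(m, -480), 14.0)
  x <- seq(0, 480, by = 40)
  expect_equal(trial_sd(m, x), trial_sd(m, -x))
  expect_true(all(diff(trial_sd(m, x)) < 0))
})

test_that("task presets encode the reported response ranges", {
  ap <- task_preset("azimuth_pointer")
  lb <- task_preset("linear_bar")
  im <- task_preset("ild_match")
  expect_equal(c(ap$sd_front, ap$sd_periphery), c(36.3, 14.0))
  expect_equal(im$bounds, c(-7, 7))
  expect_equal(lb$bounds, c(-1, 1))
  # confidence direction: periphery-high for pointer/bar, front-high for
  # ILD match
  expect_gt(ap$conf_periphery, ap$conf_front)
  expect_gt(lb$conf_periphery, lb$conf_front)
  expect_lt(im$conf_periphery, im$conf_front)
})

test_that("simulator bookkeeping matches the block design arithmetic", {
  one <- simulate_cohort(subject_model("azimuth_pointer"),
    n_blocks_per_task = 1, seed = 1
  )
  expect_equal(nrow(one), 45)
  expect_true(all(table(one$itd_us) == 9))

  models <- cohort_models(14, seed = 2)
  trials <- simulate_cohort(models, n_blocks_per_task = 2, seed = 2)
  expect_equal(nrow(trials), 14 * 3 * 2 * 45)
  expect_equal(dplyr::n_distinct(trials$subject_id), 14)
  expect_setequal(
    unique(trials$task),
    c("azimuth_pointer", "linear_bar", "ild_match")
  )
})

test_that("noise-free simulation reproduces the latent curve exactly", {
  m <- subject_model("azimuth_pointer",
    sd_front = 0, sd_periphery = 0,
    bounds = c(-1e6, 1e6)
  )
  trials <- simulate_cohort(m, n_blocks_per_task = 1, seed = 3)
  expect_equal(trials$response, mean_response(m, trials$itd_us),
    tolerance = 1e-12
  )
})

test_that("simulation is reproducible and respects bounds", {
  m <- subject_model("ild_match")
  t1 <- simulate_cohort(m, n_blocks_per_task = 2, seed = 7)
  t2 <- simulate_cohort(m, n_blocks_per_task = 2, seed = 7)
  expect_equal(t1, t2)
  expect_true(all(t1$response >= -7 & t1$response <= 7))
  expect_true(all(t1$confidence >= 0 & t1$confidence <= 100))
  expect_true(all(t1$reaction_time_s > 0))
  expect_true(all(t1$n_iterations >= 1))
})

test_that("ILD-match iterations grow with eccentricity; other tasks stay at 1", {
  m <- subject_model("ild_match")
  trials <- simulate_cohort(m, n_blocks_per_task = 20, seed = 8)
  it <- tapply(trials$n_iterations, abs(trials$itd_us), mean)
  expect_gt(it[["480"]], it[["0"]])
  ap <- simulate_cohort(subject_model("azimuth_pointer"),
    n_blocks_per_task = 1, seed = 8
  )
  expect_true(all(ap$n_iterations == 1))
})

test_that("per-ITD empirical means are statistically consistent with the latent curve", {
  m <- subject_model("azimuth_pointer")
  trials <- simulate_cohort(m, n_blocks_per_task = 25, seed = 9) # 225/ITD
  stats <- trials |>
    dplyr::group_by(itd_us) |>
    dplyr::summarise(
      m = mean(response), sem = sd(response) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  z <- (stats$m - mean_response(m, stats$itd_us)) / stats$sem
  # global calibration check: sum of squared z-scores ~ chi^2 with 5 df if
  # the generator means are unbiased; reject only at the 0.1% level
  expect_lt(sum(z^2), stats::qchisq(0.999, df = nrow(stats)))
})

test_that("frontal variability exceeds peripheral variability across seeds", {
  hits <- vapply(1:10, function(s) {
    m <- subject_model("azimuth_pointer")
    trials <- simulate_cohort(m, n_blocks_per_task = 4, seed = s)
    sds <- tapply(trials$response, trials$itd_us, sd)
    sds[["0"]] > max(sds[["480"]], sds[["-480"]])
  }, logical(1))
  expect_true(all(hits))
})

test_that("trial tables round-trip through CSV with a parameter sidecar", {
  m <- subject_model("linear_bar")
  trials <- simulate_cohort(m, n_blocks_per_task = 1, seed = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(trials, p, params = list(seed = 10, task = "linear_bar"))
  back <- read_trials_csv(p)
  expect_equal(back$response, trials$response)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 10)
})
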