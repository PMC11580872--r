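test_that("gammatone filter passes the centre tone and rejects distant tones", {
  fs <- 16000
  t <- (0:15999) / fs
  band <- cochlear_band(500)
  mid <- 4000:12000
  rms <- function(x) sqrt(mean(x^2))

  tone <- sin(2 * pi * 500 * t)
  y <- gammatone_filter(tone, band, fs)
  gain_db <- 20 * log10(rms(y[mid]) / rms(tone[mid]))
  expect_lt(abs(gain_db), 1)

  far <- sin(2 * pi * 2000 * t) # two octaves up
  y2 <- gammatone_filter(far, band, fs)
  att_db <- 20 * log10(rms(y2[mid]) / rms(far[mid]))
  expect_lt(att_db, -20)

  expect_equal(gammatone_filter(rep(0, 512), band, fs), rep(0, 512))
  expect_error(gammatone_filter(tone, cochlear_band(9000), fs), "Nyquist")
})

test_that("circular mean is a true circular (not arithmetic) average", {
  expect_equal(circular_mean_ipd(rep(1.3, 100), rep(1.3, 100)), 0)
  expect_equal(circular_mean_ipd(rep(0, 100), rep(pi / 2, 100)), pi / 2)
  # offsets straddling the +/-pi branch cut: circular mean ~ pi, not ~ 0
  offs <- rep(c(pi - 0.1, -pi + 0.1), 50)
  got <- circular_mean_ipd(rep(0, 100), offs, discard_edges = 0)
  oracle <- circ_mean_oracle(offs)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(abs(got), pi, tolerance = 0.05)
  # invariance under adding 2*pi to all differences
  base <- runif(200, -1, 1)
  expect_equal(
    circular_mean_ipd(rep(0, 200), base),
    circular_mean_ipd(rep(0, 200), base + 2 * pi),
    tolerance = 1e-10
  )
})

test_that("IPD-to-ITD conversion is the exact linear formula", {
  expect_equal(ipd_to_itd(pi / 2, 500), 500)
  expect_equal(ipd_to_itd(0, 500), 0)
  expect_equal(ipd_to_itd(-pi, 500), -1000)
  x <- runif(10, -pi, pi)
  expect_equal(ipd_to_itd(3 * x, 700), 3 * ipd_to_itd(x, 700))
  expect_error(ipd_to_itd(1, 0), "positive")
})

test_that("instantaneous ILD reduces to the level-ratio formula", {
  a <- rep(1, 100)
  expect_equal(instantaneous_ild(a, a), 0)
  expect_equal(instantaneous_ild(a, 10 * a), 20)
  expect_equal(instantaneous_ild(a, a / 2), 20 * log10(0.5), tolerance = 1e-9)
  expect_error(instantaneous_ild(a, c(rep(1, 50), rep(0, 50))), "amplitude")
})

test_that("pure interchannel delay and gain are recovered end to end", {
  fs <- 44100
  x <- withr::with_seed(5, rnorm(fs))
  for (d_us in c(-300, 120, 480)) {
    rec <- list(
      left = x, right = fractional_delay(x, -d_us * 1e-6 * fs),
      sample_rate = fs
    )
    got <- extract_cues(rec, bands = 500)$itd_us
    expect_lt(abs(got - d_us), 10)
  }
  g <- 1.7
  rec <- list(left = x, right = g * x, sample_rate = fs)
  expect_lt(abs(extract_cues(rec, bands = 500)$ild_db - 20 * log10(g)), 0.1)
})

test_that("spherical cue map matches the closed-form delay and is odd", {
  cm <- default_cue_map()
  s500 <- dplyr::filter(cm$summary, band_hz == 500)
  # saturation at 90 deg: model 765 us
  expect_equal(
    s500$itd_median[s500$azimuth_deg == 90],
    spherical_itd_us(head_geometry(), 90),
    tolerance = 0.02
  )
  # symmetry at the front
  expect_lt(abs(s500$itd_median[s500$azimuth_deg == 0]), 5)
  expect_lt(abs(s500$ild_median[s500$azimuth_deg == 0]), 0.1)
  # odd in azimuth; IQR non-negative
  pos <- s500$itd_median[s500$azimuth_deg > 0]
  neg <- s500$itd_median[s500$azimuth_deg < 0]
  expect_equal(pos, -rev(neg), tolerance = 0.02)
  expect_true(all(cm$summary$itd_iqr >= 0))
  # strictly increasing on the unambiguous band
  expect_true(all(diff(s500$itd_median) > 0))
})

test_that("ambiguity branches sit at integer multiples of the band period", {
  cm <- default_cue_map()
  b500 <- dplyr::filter(cm$branches, band_hz == 500, k == 1)
  base <- dplyr::filter(cm$summary, band_hz == 500)
  expect_equal(b500$itd_us - base$itd_median, rep(2000, nrow(base)))
  ks <- sort(unique(cm$branches$k))
  expect_equal(ks, c(-2, -1, 1, 2))
})

test_that("cue map export writes readable CSV and JSON", {
  cm <- coarse_cue_map()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_cue_map(cm, csv, js)
  back <- utils::read.csv(csv)
  expect_setequal(
    names(back),
    c("subject_id", "azimuth_deg", "band_hz", "itd_us", "ild_db")
  )
  expect_equal(nrow(back), nrow(cm$cues))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$bands_hz, 500)
  expect_equal(j$summary$itd_median, cm$summary$itd_median)
})

test_that("across-subject IQR is nonzero for a jittered cohort", {
  cohort <- spherical_cohort(
    n_subjects = 5, azimuths = c(-60, 0, 60),
    sample_rate = 16000, seed = 4
  )
  cm <- build_cue_map(cohort, bands = 500, noise_duration = 0.5, seed = 4)
  iqr60 <- dplyr::filter(cm$summary, azimuth_deg == 60)$itd_iqr
  expect_gt(iqr60, 5)
})
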