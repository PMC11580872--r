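# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default single-subject spherical cue map (both bands), as used by the
# acceptance checks; ~2 s to build, so cached across test files.
default_cue_map <- function() {
  if (is.null(.fixtures$cue_map)) {
    .fixtures$cue_map <- build_cue_map(
      spherical_hrir(azimuths = seq(-90, 90, by = 10)),
      bands = c(500, 3000), noise_duration = 1, seed = 1
    )
  }
  .fixtures$cue_map
}

# Coarse, fast map for tests that only need shape, not precision.
coarse_cue_map <- function() {
  if (is.null(.fixtures$coarse_map)) {
    .fixtures$coarse_map <- build_cue_map(
      spherical_hrir(azimuths = seq(-90, 90, by = 15), sample_rate = 16000),
      bands = 500, noise_duration = 0.5, seed = 2
    )
  }
  .fixtures$coarse_map
}

# Closed-form spherical azimuth-of-ITD, the independent oracle for the
# inverted acoustic map.
sphere_azimuth_of_itd <- function(itd_us, geometry = head_geometry()) {
  asin(itd_us / spherical_itd_us(geometry, 90)) * 180 / pi
}

# Unwrap a phase series (cumulative sum of wrapped increments).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- atan2(sin(d), cos(d))
  p[1] + c(0, cumsum(d))
}

# Brute-force circular mean: angle of the summed unit vectors.
circ_mean_oracle <- function(a) atan2(sum(sin(a)), sum(cos(a)))

# Brute-force interaural lag: cross-correlation argmax over integer lags.
xcorr_lag <- function(left, right, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      sum(right[(1 + l):length(right)] * left[1:(length(left) - l)])
    } else {
      sum(right[1:(length(right) + l)] * left[(1 - l):length(left)])
    }
  }, numeric(1))
  lags[which.max(cc)]
}
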