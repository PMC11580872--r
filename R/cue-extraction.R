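#' Equivalent rectangular bandwidth (ERB) of a cochlear filter
#'
#' Glasberg & Moore ERB scale: `ERB(f) = 24.7 * (4.37 * f / 1000 + 1)` Hz.
#'
#' @param f centre frequency in Hz.
#' @return bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Define a cochlear band
#'
#' A band of the gammatone filterbank used for cue extraction: a 4th-order
#' gammatone centred at `f` with ERB-derived bandwidth.
#'
#' @param f centre frequency in Hz, > 0.
#' @param order gammatone order (default 4).
#' @param bandwidth bandwidth parameter in Hz; defaults to
#'   `1.019 * erb_bandwidth(f)`, the standard 4th-order gammatone calibration.
#' @return an object of class `cochlear_band`.
#' @export
#' @examples
#' cochlear_band(500)
cochlear_band <- function(f, order = 4, bandwidth = 1.019 * erb_bandwidth(f)) {
  stopifnot(f > 0, bandwidth > 0, order >= 1)
  structure(list(f = f, order = order, bandwidth = bandwidth),
    class = "cochlear_band"
  )
}

#' @export
print.cochlear_band <- function(x, ...) {
  cat(
    "<cochlear_band>", x$f, "Hz, order", x$order, ", bandwidth",
    round(x$bandwidth, 1), "Hz\n"
  )
  invisible(x)
}

as_band_list <- function(bands) {
  if (inherits(bands, "cochlear_band")) {
    return(list(bands))
  }
  lapply(bands, function(b) {
    if (inherits(b, "cochlear_band")) b else cochlear_band(b)
  })
}

#' Gammatone impulse response, unit gain at the centre frequency
#' @noRd
gammatone_ir <- function(band, sample_rate) {
  b <- band$bandwidth
  # envelope t^(n-1) exp(-2 pi b t): keep taps until it decays to 1e-5 of peak
  t_peak <- (band$order - 1) / (2 * pi * b)
  t_max <- t_peak + log(1e5) / (2 * pi * b)
  n <- max(32L, ceiling(t_max * sample_rate))
  t <- (0:(n - 1)) / sample_rate
  g <- t^(band$order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * band$f * t)
  resp <- sum(g * exp(-2i * pi * band$f * t))
  g / Mod(resp)
}

#' Apply a gammatone cochlear filter
#'
#' Band-pass filters a signal with a 4th-order gammatone (FIR realization via
#' FFT convolution), normalized to unit magnitude response at the band's
#' centre frequency. Output has the same length as the input.
#'
#' @param x numeric signal.
#' @param band a [cochlear_band()] (or a centre frequency in Hz).
#' @param sample_rate in Hz; the band centre must be below Nyquist.
#' @return filtered signal, `length(x)`.
#' @export
#' @examples
#' fs <- 16000
#' x <- sin(2 * pi * 500 * seq(0, 0.2, by = 1 / fs))
#' y <- gammatone_filter(x, cochlear_band(500), fs)
gammatone_filter <- function(x, band, sample_rate) {
  if (!inherits(band, "cochlear_band")) band <- cochlear_band(band)
  if (band$f >= sample_rate / 2) {
    stop("band centre ", band$f, " Hz is at or above Nyquist")
  }
  g <- gammatone_ir(band, sample_rate)
  fft_convolve(x, g)[seq_along(x)]
}

#' Circular mean of the interaural phase difference
#'
#' Computes the per-sample phase difference (right minus left), wraps it to
#' the principal interval (-pi, pi], trims a fraction of samples at both ends
#' (to discard filter and Hilbert-transform transients), and returns the
#' circular mean: the angle of the summed unit phasors.
#'
#' @param phase_left,phase_right instantaneous phase, radians, equal length.
#' @param discard_edges fraction trimmed at each end, in \[0, 0.4\]
#'   (default 0.1).
#' @return the circular-mean IPD in radians, in (-pi, pi].
#' @export
circular_mean_ipd <- function(phase_left, phase_right, discard_edges = 0.1) {
  stopifnot(length(phase_left) == length(phase_right))
  d <- wrap_angle(phase_right - phase_left)
  d <- d[trim_edges(length(d), discard_edges)]
  z <- sum(exp(1i * d))
  if (Mod(z) < .Machine$double.eps * length(d)) {
    stop("circular mean undefined: zero resultant length")
  }
  Arg(z)
}

#' Convert an interaural phase difference to a time difference
#'
#' `ITD = 1e6 * IPD / (2 * pi * f)` microseconds: the delay of a narrowband
#' carrier at frequency `f` whose phase lags by `IPD` radians.
#'
#' @param ipd phase difference in radians (right minus left).
#' @param f band centre frequency in Hz, > 0.
#' @return ITD in microseconds (positive = right leading).
#' @export
#' @examples
#' ipd_to_itd(pi / 2, 500) # 500 us
ipd_to_itd <- function(ipd, f) {
  if (any(f <= 0)) stop("frequency must be positive")
  1e6 * ipd / (2 * pi * f)
}

#' Mean instantaneous interaural level difference
#'
#' Trims the edge fraction from both envelope series and averages the
#' per-sample level difference `20 * log10(A_right / A_left)` dB.
#'
#' @param amp_left,amp_right instantaneous amplitude envelopes, equal length.
#' @param discard_edges fraction trimmed at each end (default 0.1).
#' @return mean ILD in dB (positive = right louder).
#' @export
instantaneous_ild <- function(amp_left, amp_right, discard_edges = 0.1) {
  stopifnot(length(amp_left) == length(amp_right))
  keep <- trim_edges(length(amp_left), discard_edges)
  al <- amp_left[keep]
  ar <- amp_right[keep]
  if (any(al <= 0) || any(ar <= 0)) {
    stop("non-positive amplitude in trimmed region: ILD undefined")
  }
  mean(20 * log10(ar / al))
}

#' Extract ITD and ILD from one binaural recording
#'
#' For each cochlear band: filter both channels with the gammatone filter,
#' take the analytic-signal phase and amplitude, and reduce to a single
#' circular-mean IPD (converted to ITD) and mean ILD.
#'
#' @param recording a `binaural_recording` (see [binaural_render()]), or any
#'   list with `left`, `right`, `sample_rate`.
#' @param bands a list of [cochlear_band()]s or centre frequencies
#'   (default 500 and 3000 Hz).
#' @param discard_edges edge fraction trimmed before averaging (default 0.1).
#' @return a tibble with one row per band: `band_hz`, `itd_us`, `ild_db`.
#' @export
extract_cues <- function(recording, bands = c(500, 3000),
                         discard_edges = 0.1) {
  bands <- as_band_list(bands)
  purrr::map_dfr(bands, function(b) {
    l <- gammatone_filter(recording$left, b, recording$sample_rate)
    r <- gammatone_filter(recording$right, b, recording$sample_rate)
    pal <- instantaneous_phase_amplitude(l)
    par <- instantaneous_phase_amplitude(r)
    ipd <- circular_mean_ipd(pal$phase, par$phase, discard_edges)
    tibble::tibble(
      band_hz = b$f,
      itd_us = ipd_to_itd(ipd, b$f),
      ild_db = instantaneous_ild(pal$amplitude, par$amplitude, discard_edges)
    )
  })
}

#' Build the acoustic ITD/ILD-versus-azimuth cue map
#'
#' The acoustic front end of the analysis: for every subject and azimuth a
#' white-noise probe is rendered through the subject's HRIR pair, passed
#' through the gammatone filterbank, and reduced to one ITD (via circular-
#' mean IPD) and one ILD per band. Across subjects the map reports the median
#' and interquartile range per azimuth and band. Because IPD is only defined
#' modulo 2 pi, each band also carries phase-ambiguity branches: copies of
#' the median ITD curve offset by +/- k * 1e6 / f microseconds (k = 1, 2),
#' the ITDs acoustically indistinguishable from the principal curve at that
#' frequency.
#'
#' @param hrir_sets an `hrir_set` or list of them (one per subject).
#' @param bands band centre frequencies or [cochlear_band()]s
#'   (default 500 and 3000 Hz).
#' @param noise_duration white-noise probe duration in seconds (>= 0.5,
#'   default 1).
#' @param discard_edges edge fraction trimmed before averaging (default 0.1).
#' @param max_branch largest ambiguity multiple k attached per band
#'   (default 2).
#' @param seed RNG seed for the noise probes.
#' @return an object of class `cue_map`: list with tibbles `cues`
#'   (subject_id, azimuth_deg, band_hz, itd_us, ild_db), `summary`
#'   (azimuth_deg, band_hz, itd_median, itd_iqr, ild_median, ild_iqr),
#'   `branches` (band_hz, k, azimuth_deg, itd_us), plus `sample_rate`.
#' @export
#' @examples
#' \donttest{
#' cm <- build_cue_map(spherical_hrir(azimuths = seq(-90, 90, 30)),
#'   bands = 500, noise_duration = 0.5
#' )
#' }
build_cue_map <- function(hrir_sets, bands = c(500, 3000),
                          noise_duration = 1, discard_edges = 0.1,
                          max_branch = 2, seed = 1) {
  if (inherits(hrir_sets, "hrir_set")) hrir_sets <- list(hrir_sets)
  stopifnot(length(hrir_sets) >= 1, noise_duration >= 0.5)
  bands <- as_band_list(bands)
  fs <- hrir_sets[[1]]$sample_rate
  n <- round(noise_duration * fs)
  cues <- purrr::imap_dfr(hrir_sets, function(h, i) {
    noise <- white_noise(n, seed = seed + 7919L * (i - 1L))
    purrr::map_dfr(h$azimuths, function(az) {
      rec <- binaural_render(noise, h, az)
      dplyr::mutate(
        extract_cues(rec, bands, discard_edges),
        subject_id = h$subject_id, azimuth_deg = az,
        .before = 1
      )
    })
  })
  summary <- cues |>
    dplyr::group_by(.data$azimuth_deg, .data$band_hz) |>
    dplyr::summarise(
      itd_median = median(.data$itd_us), itd_iqr = IQR(.data$itd_us),
      ild_median = median(.data$ild_db), ild_iqr = IQR(.data$ild_db),
      .groups = "drop"
    )
  branches <- purrr::map_dfr(bands, function(b) {
    base <- dplyr::filter(summary, .data$band_hz == b$f)
    purrr::map_dfr(setdiff(-max_branch:max_branch, 0), function(k) {
      tibble::tibble(
        band_hz = b$f, k = k, azimuth_deg = base$azimuth_deg,
        itd_us = base$itd_median + k * 1e6 / b$f
      )
    })
  })
  structure(
    list(
      cues = cues, summary = summary, branches = branches,
      bands = vapply(bands, `[[`, numeric(1), "f"), sample_rate = fs
    ),
    class = "cue_map"
  )
}

#' @export
print.cue_map <- function(x, ...) {
  cat(
    "<cue_map>", dplyr::n_distinct(x$cues$subject_id), "subject(s),",
    dplyr::n_distinct(x$cues$azimuth_deg), "azimuths, bands:",
    paste(x$bands, collapse = ", "), "Hz\n"
  )
  invisible(x)
}

#' Export a cue map
#'
#' Writes the per-subject cues as long-format CSV and (optionally) the
#' median/IQR summaries plus ambiguity branches as JSON.
#'
#' @param x a `cue_map`.
#' @param csv_path path for the long CSV (subject, azimuth, band, itd, ild);
#'   `NULL` to skip.
#' @param json_path path for the JSON summary; `NULL` to skip.
#' @return `x`, invisibly.
#' @export
export_cue_map <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "cue_map"))
  if (!is.null(csv_path)) {
    write.csv(x$cues, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        bands_hz = x$bands, sample_rate = x$sample_rate,
        summary = x$summary, branches = x$branches
      ),
      json_path,
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }
  invisible(x)
}
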