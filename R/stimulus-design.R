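#' Specify a dichotic tone-burst stimulus
#'
#' Defaults describe the standard probe: a 500-Hz tone presented as ten
#' consecutive 50-ms elements, each gated with a 25-ms raised-cosine rise and
#' 25-ms fall (500 ms total), lateralized by a whole-waveform interaural
#' time difference.
#'
#' @param carrier_f carrier frequency in Hz (default 500).
#' @param n_elements number of consecutive gated elements (default 10).
#' @param element_ms element duration in ms (default 50).
#' @param rise_ms,fall_ms raised-cosine ramp durations in ms (default 25/25;
#'   their sum must not exceed `element_ms`).
#' @param itd_us interaural time difference in microseconds (positive =
#'   right ear leads); practically bounded by +/-1000.
#' @param sample_rate in Hz (default 44100).
#' @return an object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec(itd_us = 480)
stimulus_spec <- function(carrier_f = 500, n_elements = 10, element_ms = 50,
                          rise_ms = 25, fall_ms = 25, itd_us = 0,
                          sample_rate = 44100) {
  if (rise_ms + fall_ms > element_ms) {
    stop("rise + fall ramps exceed the element duration")
  }
  if (carrier_f >= sample_rate / 2) stop("carrier at or above Nyquist")
  if (abs(itd_us) > 1000) stop("|itd_us| must be <= 1000")
  structure(
    list(
      carrier_f = carrier_f, n_elements = n_elements,
      element_ms = element_ms, rise_ms = rise_ms, fall_ms = fall_ms,
      itd_us = itd_us, sample_rate = sample_rate
    ),
    class = "stimulus_spec"
  )
}

#' Raised-cosine on/off gate for one element
#' @noRd
element_envelope <- function(spec) {
  fs <- spec$sample_rate
  n <- round(spec$element_ms / 1000 * fs)
  nr <- round(spec$rise_ms / 1000 * fs)
  nf <- round(spec$fall_ms / 1000 * fs)
  env <- rep(1, n)
  if (nr > 0) env[1:nr] <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  if (nf > 0) env[(n - nf + 1):n] <- 0.5 * (1 + cos(pi * (1:nf) / nf))
  env
}

#' Synthesize a dichotic tone-burst stimulus
#'
#' Builds the two-channel waveform for a [stimulus_spec()]: a continuous
#' carrier multiplied by the concatenated element gates, duplicated to both
#' channels, then delayed by +itd/2 samples on one channel and -itd/2 on the
#' other (whole-waveform delay, sub-sample precision via a windowed-sinc
#' kernel). Positive ITD makes the right channel lead.
#'
#' @param spec a [stimulus_spec()].
#' @return an object of class `dichotic_stimulus`: list with `left`, `right`
#'   (numeric, equal length = total duration), `sample_rate`, and the `spec`.
#' @export
#' @examples
#' s <- synthesize_stimulus(stimulus_spec(itd_us = 240))
synthesize_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$sample_rate
  env <- rep(element_envelope(spec), spec$n_elements)
  n <- length(env)
  t <- (0:(n - 1)) / fs
  mono <- env * sin(2 * pi * spec$carrier_f * t)
  d_half <- spec$itd_us * 1e-6 * fs / 2
  structure(
    list(
      left = fractional_delay(mono, +d_half),
      right = fractional_delay(mono, -d_half),
      sample_rate = fs, spec = spec
    ),
    class = "dichotic_stimulus"
  )
}

#' @export
print.dichotic_stimulus <- function(x, ...) {
  cat(
    "<dichotic_stimulus>", length(x$left), "frames @", x$sample_rate,
    "Hz,", x$spec$carrier_f, "Hz carrier, ITD", x$spec$itd_us, "us\n"
  )
  invisible(x)
}

#' Specify a trial block
#'
#' A block presents each ITD level a fixed number of times in a randomized
#' order whose first-order transitions (ordered level pairs, including
#' repeats) are balanced: across the block, no ordered pair occurs more than
#' one time oftener than any other. Defaults give the standard design: five
#' ITDs from -480 to 480 microseconds in 240-microsecond steps, nine
#' repetitions each, 45 trials.
#'
#' @param itd_levels_us ITD levels in microseconds (>= 2 distinct values).
#' @param reps_per_level repetitions of each level (>= 1, default 9).
#' @param seed RNG seed for the order search.
#' @return an object of class `block_design` with `order` unset; pass to
#'   [build_block()] to fill it.
#' @export
block_design <- function(itd_levels_us = seq(-480, 480, by = 240),
                         reps_per_level = 9, seed = 1) {
  stopifnot(length(itd_levels_us) >= 2, reps_per_level >= 1)
  structure(
    list(
      itd_levels_us = as.numeric(itd_levels_us),
      reps_per_level = as.integer(reps_per_level),
      order = NULL, seed = as.integer(seed)
    ),
    class = "block_design"
  )
}

#' Tabulate ordered first-order transition counts of a level sequence
#'
#' @param order integer sequence of level indices.
#' @param n_levels number of levels.
#' @return an `n_levels` x `n_levels` matrix; entry (i, j) counts
#'   transitions i -> j.
#' @export
transition_counts <- function(order, n_levels) {
  m <- matrix(0L, n_levels, n_levels)
  for (t in seq_len(length(order) - 1)) {
    m[order[t], order[t + 1]] <- m[order[t], order[t + 1]] + 1L
  }
  m
}

#' Fill a block design with a transition-balanced random order
#'
#' Seeded randomized search with backtracking: trials are appended one at a
#' time, always drawing the next level from those with repetitions left whose
#' transition from the current level has been used least, breaking ties at
#' random; dead ends trigger a restart. The search stops at the first order
#' whose ordered transition counts differ by at most one (with 5 levels and
#' 9 repetitions, 44 transitions over 25 ordered pairs make exact equality
#' impossible, so max - min <= 1 is the balance criterion).
#'
#' @param design a [block_design()].
#' @param max_restarts restarts before giving up (default 1000).
#' @return the design with `order` (level indices), `itd_sequence_us`, and
#'   `transition_counts` filled in. Deterministic given the design's seed.
#' @export
#' @examples
#' b <- build_block(block_design(seed = 7))
#' table(b$itd_sequence_us)
build_block <- function(design, max_restarts = 1000) {
  stopifnot(inherits(design, "block_design"))
  nl <- length(design$itd_levels_us)
  reps <- design$reps_per_level
  n <- nl * reps
  order <- withr_seed(design$seed, {
    found <- NULL
    for (attempt in seq_len(max_restarts)) {
      remaining <- rep(reps, nl)
      trans <- matrix(0L, nl, nl)
      seq_out <- integer(n)
      seq_out[1] <- sample.int(nl, 1)
      remaining[seq_out[1]] <- remaining[seq_out[1]] - 1L
      ok <- TRUE
      for (t in 2:n) {
        cur <- seq_out[t - 1]
        avail <- which(remaining > 0)
        if (length(avail) == 0) {
          ok <- FALSE
          break
        }
        cost <- trans[cur, avail]
        best <- avail[cost == min(cost)]
        nxt <- if (length(best) == 1) best else sample(best, 1)
        seq_out[t] <- nxt
        remaining[nxt] <- remaining[nxt] - 1L
        trans[cur, nxt] <- trans[cur, nxt] + 1L
      }
      if (ok && diff(range(trans)) <= 1L) {
        found <- seq_out
        break
      }
    }
    found
  })
  if (is.null(order)) {
    stop(
      "no transition-balanced order found after ", max_restarts,
      " restarts; adjust levels or repetitions"
    )
  }
  design$order <- order
  design$itd_sequence_us <- design$itd_levels_us[order]
  design$transition_counts <- transition_counts(order, nl)
  design
}

#' @export
print.block_design <- function(x, ...) {
  cat(
    "<block_design>", length(x$itd_levels_us), "levels x",
    x$reps_per_level, "reps",
    if (is.null(x$order)) "(order not built)" else "(order built)", "\n"
  )
  invisible(x)
}

#' Export / import a built block as CSV
#'
#' One row per trial: `trial_index`, `itd_us`.
#'
#' @param design a built [block_design()].
#' @param path CSV path.
#' @return `write_block_csv()` returns `path` invisibly; `read_block_csv()`
#'   a tibble.
#' @export
write_block_csv <- function(design, path) {
  if (is.null(design$order)) stop("block order not built; call build_block()")
  write.csv(
    data.frame(
      trial_index = seq_along(design$order),
      itd_us = design$itd_sequence_us
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_block_csv
#' @export
read_block_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
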