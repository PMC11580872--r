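#' Calibration presets for the three lateralization tasks
#'
#' One latent percept model drives all three tasks: a symmetric saturating
#' response curve `psi(itd) = A * (2 / (1 + exp(-k * itd)) - 1)` rescaled
#' into each task's native range, with trial-to-trial variability that is
#' largest for frontal (ITD 0) stimuli and smallest at the periphery.
#' Defaults reproduce the reported ranges of human cohorts on 500-Hz tone
#' bursts:
#'
#' * `azimuth_pointer` — degrees; saturation 50, SD 36.3 (front) to 14.0
#'   (periphery), responses clipped to \[-90, 90\], confidence higher at the
#'   periphery.
#' * `linear_bar` — bar position in \[-1, 1\]; saturation 0.85, SD 0.5 to
#'   0.2, confidence higher at the periphery, mean reaction time ~50 ms
#'   above the pointer task.
#' * `ild_match` — dB in \[-7, 7\]; saturation 4.2, SD 1.9 to 1.2,
#'   confidence higher at the front, more matching iterations for
#'   peripheral stimuli, first-response time ~75 ms above the pointer task.
#'
#' The shared slope default `k = 0.008` per microsecond puts the response at
#' +/-480 microseconds at 96% of saturation, i.e. visibly saturated at the
#' extreme design ITDs.
#'
#' @param task one of `"azimuth_pointer"`, `"linear_bar"`, `"ild_match"`.
#' @return a named list of calibration values.
#' @export
task_preset <- function(task = c("azimuth_pointer", "linear_bar",
                                 "ild_match")) {
  task <- match.arg(task)
  base <- list(
    k = 0.008, design_itd_us = 480, sd_tau_us = 300,
    rt_sd = 0.15, conf_sd = 10, iter_base = 0, iter_slope = 0
  )
  cal <- switch(task,
    azimuth_pointer = list(
      A = 50, sd_front = 36.3, sd_periphery = 14.0,
      bounds = c(-90, 90), rt_mean = 0.600,
      conf_front = 65, conf_periphery = 85
    ),
    linear_bar = list(
      A = 0.85, sd_front = 0.5, sd_periphery = 0.2,
      bounds = c(-1, 1), rt_mean = 0.650,
      conf_front = 65, conf_periphery = 85
    ),
    ild_match = list(
      A = 4.2, sd_front = 1.9, sd_periphery = 1.2,
      bounds = c(-7, 7), rt_mean = 0.675,
      conf_front = 85, conf_periphery = 65,
      iter_base = 0.5, iter_slope = 2
    )
  )
  c(list(task = task), utils::modifyList(base, cal))
}

#' Define a simulated subject
#'
#' @param task task name (see [task_preset()]).
#' @param subject_id identifier.
#' @param ... calibration overrides (any field of [task_preset()]): `A`
#'   (saturation, task-native units), `k` (1/us), `sd_front`/`sd_periphery`
#'   (trial SD at ITD 0 / at the extreme design ITD), `sd_tau_us` (width of
#'   the frontal variability bump), `bounds` (response clip range),
#'   `rt_mean`/`rt_sd` (log-normal reaction time, s), `conf_front`/
#'   `conf_periphery`/`conf_sd` (confidence %, 0-100), `iter_base`/
#'   `iter_slope` (ILD-match iteration count model).
#' @return an object of class `subject_model`.
#' @export
#' @examples
#' m <- subject_model("azimuth_pointer")
#' mean_response(m, c(-480, 0, 480))
subject_model <- function(task = "azimuth_pointer", subject_id = "S001",
                          ...) {
  m <- utils::modifyList(task_preset(task), list(...))
  m$subject_id <- subject_id
  stopifnot(
    m$A >= 0, m$sd_front >= m$sd_periphery, m$sd_periphery >= 0,
    m$conf_front >= 0, m$conf_front <= 100,
    m$conf_periphery >= 0, m$conf_periphery <= 100,
    m$rt_mean > 0, length(m$bounds) == 2, m$bounds[1] < m$bounds[2]
  )
  structure(m, class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(
    "<subject_model>", x$subject_id, "-", x$task, ": A =", x$A,
    ", k =", x$k, "/us, sd", x$sd_front, "->", x$sd_periphery, "\n"
  )
  invisible(x)
}

#' Mean response curve of a simulated subject
#'
#' `psi(itd) = A * (2 / (1 + exp(-k * itd)) - 1)`: odd, sigmoidal,
#' saturating at +/-A.
#'
#' @param model a [subject_model()].
#' @param itd_us ITD values in microseconds (vectorized).
#' @return mean response in task-native units.
#' @export
mean_response <- function(model, itd_us) {
  model$A * (2 / (1 + exp(-model$k * itd_us)) - 1)
}

#' Trial-to-trial response SD of a simulated subject
#'
#' An even Gaussian bump in ITD, pinned to `sd_front` at 0 and
#' `sd_periphery` at the extreme design ITD, strictly decreasing in |itd|
#' over the design range: frontal stimuli are judged with the largest
#' trial-to-trial spread.
#'
#' @inheritParams mean_response
#' @return SD in task-native units.
#' @export
trial_sd <- function(model, itd_us) {
  e <- exp(-(itd_us / model$sd_tau_us)^2)
  e_max <- exp(-(model$design_itd_us / model$sd_tau_us)^2)
  model$sd_periphery +
    (model$sd_front - model$sd_periphery) * (e - e_max) / (1 - e_max)
}

#' Mean confidence profile (linear in |itd| between the two anchors)
#' @noRd
confidence_mean <- function(model, itd_us) {
  w <- pmin(abs(itd_us) / model$design_itd_us, 1)
  model$conf_front + (model$conf_periphery - model$conf_front) * w
}

#' Generate a cohort of simulated subjects
#'
#' Per-subject heterogeneity (invented, since only cohort-level ranges are
#' reported for human listeners): saturation and variability scales jitter
#' log-normally, reaction-time means jitter normally with a large
#' between-subject spread, and the latent slope k is shared across tasks
#' within a subject so the three tasks express one underlying percept.
#'
#' @param n_subjects cohort size (default 14).
#' @param tasks character vector of tasks to calibrate per subject.
#' @param seed RNG seed.
#' @param a_cv coefficient of variation of the saturation A (default 0.1).
#' @param sd_cv coefficient of variation of the SD anchors (default 0.1).
#' @param rt_between_sd between-subject SD of mean reaction time in seconds
#'   (default 0.2).
#' @param k_cv coefficient of variation of the latent slope (default 0.1).
#' @param ... further overrides applied to every subject.
#' @return a list of [subject_model()]s, one per subject x task.
#' @export
cohort_models <- function(n_subjects = 14,
                          tasks = c("azimuth_pointer", "linear_bar",
                                    "ild_match"),
                          seed = 1, a_cv = 0.1, sd_cv = 0.1,
                          rt_between_sd = 0.2, k_cv = 0.1, ...) {
  stopifnot(n_subjects >= 1)
  draws <- withr_seed(seed, list(
    a = exp(rnorm(n_subjects, 0, a_cv)),
    s = exp(rnorm(n_subjects, 0, sd_cv)),
    # RT jitter is per subject x task: a subject who is slow with one
    # response interface need not be slow with another, and a shared
    # subject offset would cancel out of paired task comparisons entirely
    rt = matrix(rnorm(n_subjects * length(tasks), 0, rt_between_sd),
      n_subjects, length(tasks)
    ),
    k = exp(rnorm(n_subjects, 0, k_cv))
  ))
  out <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(tasks)) {
      p <- task_preset(tasks[j])
      out[[length(out) + 1]] <- subject_model(
        task = tasks[j], subject_id = sprintf("S%03d", i),
        A = p$A * draws$a[i], k = p$k * draws$k[i],
        sd_front = p$sd_front * draws$s[i],
        sd_periphery = p$sd_periphery * draws$s[i],
        rt_mean = max(p$rt_mean + draws$rt[i, j], 0.15),
        ...
      )
    }
  }
  out
}

#' Simulate per-trial responses of a cohort
#'
#' For every subject-model x block, a fresh transition-balanced trial order
#' is drawn and each trial yields: response = clip(psi(itd) + noise *
#' sd(itd), bounds); a log-normal reaction time (moment-matched to the
#' subject's `rt_mean`/`rt_sd`); a confidence score from the task's profile
#' (periphery-high for pointer/bar, front-high for ILD match) with trial
#' noise, clipped to \[0, 100\]; and, for the ILD-match task, a matching
#' iteration count `1 + Poisson(iter_base + iter_slope * |itd| / itd_max)`
#' that grows with eccentricity. Fully reproducible from `seed`.
#'
#' @param models a [subject_model()] or list of them (e.g.
#'   [cohort_models()]).
#' @param design a [block_design()] (order need not be built; each block
#'   draws its own).
#' @param n_blocks_per_task blocks per subject-model (default 2, giving the
#'   standard 2 x 45 = 90 trials per subject and task).
#' @param seed master RNG seed.
#' @return a tibble with one row per trial: `subject_id`, `task`, `block`,
#'   `trial`, `itd_us`, `response`, `reaction_time_s`, `confidence`,
#'   `n_iterations`.
#' @export
#' @examples
#' trials <- simulate_cohort(subject_model("azimuth_pointer"),
#'   n_blocks_per_task = 1
#' )
#' nrow(trials) # 45
simulate_cohort <- function(models, design = block_design(),
                            n_blocks_per_task = 2, seed = 1) {
  if (inherits(models, "subject_model")) models <- list(models)
  stopifnot(length(models) >= 1, inherits(design, "block_design"),
            n_blocks_per_task >= 1)
  rows <- list()
  for (im in seq_along(models)) {
    m <- models[[im]]
    for (blk in seq_len(n_blocks_per_task)) {
      sub_seed <- (seed + 131L * im + 17L * blk) %% .Machine$integer.max
      d <- design
      d$seed <- sub_seed
      d <- build_block(d)
      itd <- d$itd_sequence_us
      nt <- length(itd)
      mu <- mean_response(m, itd)
      sdv <- trial_sd(m, itd)
      sim <- withr_seed(sub_seed + 1L, {
        resp <- pmin(pmax(mu + rnorm(nt) * sdv, m$bounds[1]), m$bounds[2])
        mlog <- log(m$rt_mean^2 / sqrt(m$rt_sd^2 + m$rt_mean^2))
        slog <- sqrt(log(1 + m$rt_sd^2 / m$rt_mean^2))
        rt <- rlnorm(nt, mlog, slog)
        conf <- pmin(pmax(
          confidence_mean(m, itd) + rnorm(nt) * m$conf_sd, 0
        ), 100)
        iters <- if (m$task == "ild_match") {
          1L + rpois(nt, m$iter_base +
                       m$iter_slope * pmin(abs(itd) / m$design_itd_us, 1))
        } else {
          rep(1L, nt)
        }
        list(resp = resp, rt = rt, conf = conf, iters = iters)
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = m$subject_id, task = m$task, block = blk,
        trial = seq_len(nt), itd_us = itd, response = sim$resp,
        reaction_time_s = sim$rt, confidence = sim$conf,
        n_iterations = sim$iters
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a trial table as CSV (the interchange format of the
#' analysis stage), with an optional JSON sidecar of generator settings
#'
#' @param trials tibble from [simulate_cohort()].
#' @param path CSV path.
#' @param params optional named list written as `<path>.json`.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` a tibble.
#' @export
write_trials_csv <- function(trials, path, params = NULL) {
  write.csv(trials, path, row.names = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
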