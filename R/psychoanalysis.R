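#' Per-subject summary statistics
#'
#' Reduces a trial table to the four per-subject, per-ITD summaries the
#' analysis works with: mean estimate, SD of estimates (n - 1 denominator),
#' mean reaction time, mean confidence. For the ILD-match task the recorded
#' reaction time is already the first-response interval, so no special
#' handling is needed here.
#'
#' @param trials tibble with columns `subject_id`, `task`, `itd_us`,
#'   `response`, `reaction_time_s`, `confidence` (see [simulate_cohort()]).
#' @return a tibble with one row per subject x task x ITD: `mean_estimate`,
#'   `sd_estimate`, `mean_rt_s`, `mean_confidence`, `n_trials`. ITD levels
#'   with fewer than two trials get `NA` SD with a warning.
#' @export
summarize_subjects <- function(trials) {
  stopifnot(nrow(trials) > 0)
  out <- trials |>
    dplyr::group_by(.data$subject_id, .data$task, .data$itd_us) |>
    dplyr::summarise(
      mean_estimate = mean(.data$response),
      sd_estimate = if (dplyr::n() >= 2) sd(.data$response) else NA_real_,
      mean_rt_s = mean(.data$reaction_time_s),
      mean_confidence = mean(.data$confidence),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  if (anyNA(out$sd_estimate)) {
    warning("some ITD levels have < 2 trials; their SD is undefined (NA)")
  }
  out
}

#' Percentile-bootstrap mean and confidence interval
#'
#' Resamples rows (subjects) with replacement and returns, per column, the
#' observed mean and the percentile interval of the bootstrap distribution
#' of the mean. Deterministic given `seed`.
#'
#' @param values matrix-like, rows = subjects, columns = conditions (a
#'   vector is treated as one column).
#' @param n_boot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return a tibble with one row per column: `column`, `mean`, `conf.low`,
#'   `conf.high`.
#' @export
#' @examples
#' m <- matrix(rnorm(14 * 5), 14, 5)
#' bootstrap_mean_ci(m, n_boot = 1000, seed = 1)
bootstrap_mean_ci <- function(values, n_boot = 10000, level = 0.95,
                              seed = 1) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(n >= 2, n_boot >= 1)
  boot <- withr_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    t(apply(idx, 1, function(i) colMeans(values[i, , drop = FALSE])))
  })
  if (ncol(values) == 1) boot <- matrix(boot, ncol = 1)
  a <- (1 - level) / 2
  tibble::tibble(
    column = colnames(values) %||% as.character(seq_len(ncol(values))),
    mean = colMeans(values),
    conf.low = apply(boot, 2, quantile, probs = a, names = FALSE),
    conf.high = apply(boot, 2, quantile, probs = 1 - a, names = FALSE)
  )
}

#' Paired bootstrap comparison (analogous to a paired t-test)
#'
#' Resamples the per-subject paired differences with replacement; the
#' two-sided p-value is twice the smaller tail fraction of bootstrap mean
#' differences at or beyond zero (percentile convention), capped at 1.
#'
#' @param a,b paired per-subject values, equal length >= 2.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return a one-row tibble: `estimate` (mean of a - b), `p.value`,
#'   `n`, `n_boot`.
#' @export
paired_bootstrap_test <- function(a, b, n_boot = 10000, seed = 1) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  bm <- withr_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    rowMeans(matrix(d[idx], n_boot, n))
  })
  p <- 2 * min(mean(bm <= 0), mean(bm >= 0))
  tibble::tibble(
    estimate = mean(d), p.value = min(p, 1), n = n, n_boot = n_boot
  )
}

#' Pool estimates across subjects on the z scale
#'
#' Each subject's vector of per-ITD mean estimates (in the task's native
#' scale — dB, bar position, or degrees) is transformed to the z scale:
#' centred on its own mean and divided by its own SD across the design ITDs.
#' This makes subjects and tasks with different response scales directly
#' comparable. The subject's SD-of-estimates vector is divided by the same
#' per-subject scale factor (preserving its shape across ITD); set
#' `sd_scaling = "independent"` to z-transform the SD vector on its own
#' mean/SD instead. Pooled curves are across-subject means per ITD with
#' percentile-bootstrap confidence intervals (subjects as the resampling
#' unit).
#'
#' @param summaries tibble from [summarize_subjects()] (a single task).
#' @param sd_scaling `"mean"` (default; scale SDs by the mean-vector SD) or
#'   `"independent"`.
#' @param n_boot bootstrap resamples for the pooled CIs (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return an object of class `normalized_summary`: list with tibbles
#'   `by_subject` (`subject_id`, `itd_us`, `z_mean`, `z_sd`) and `pooled`
#'   (`itd_us`, `mean_z`, `mean_conf.low`, `mean_conf.high`, `sd_z`,
#'   `sd_conf.low`, `sd_conf.high`), plus `task`.
#' @export
zscore_pool <- function(summaries, sd_scaling = c("mean", "independent"),
                        n_boot = 10000, level = 0.95, seed = 1) {
  sd_scaling <- match.arg(sd_scaling)
  if (dplyr::n_distinct(summaries$task) != 1) {
    stop("zscore_pool() expects summaries from a single task")
  }
  if (dplyr::n_distinct(summaries$subject_id) < 2) {
    stop("need at least 2 subjects to pool")
  }
  by_subject <- summaries |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      .scale = sd(.data$mean_estimate),
      z_mean = (.data$mean_estimate - mean(.data$mean_estimate)) / .data$.scale,
      z_sd = if (sd_scaling == "mean") {
        .data$sd_estimate / .data$.scale
      } else {
        (.data$sd_estimate - mean(.data$sd_estimate)) / sd(.data$sd_estimate)
      }
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(by_subject$z_mean))) {
    stop("a subject has zero variance across ITDs; cannot z-score")
  }
  zm <- by_subject |>
    dplyr::select("subject_id", "itd_us", "z_mean") |>
    tidyr::pivot_wider(names_from = "itd_us", values_from = "z_mean")
  zs <- by_subject |>
    dplyr::select("subject_id", "itd_us", "z_sd") |>
    tidyr::pivot_wider(names_from = "itd_us", values_from = "z_sd")
  mat_m <- as.matrix(zm[-1])
  mat_s <- as.matrix(zs[-1])
  ci_m <- bootstrap_mean_ci(mat_m, n_boot, level, seed)
  ci_s <- bootstrap_mean_ci(mat_s, n_boot, level, seed + 1L)
  pooled <- tibble::tibble(
    itd_us = as.numeric(ci_m$column),
    mean_z = ci_m$mean, mean_conf.low = ci_m$conf.low,
    mean_conf.high = ci_m$conf.high,
    sd_z = ci_s$mean, sd_conf.low = ci_s$conf.low,
    sd_conf.high = ci_s$conf.high
  )
  structure(
    list(
      by_subject = dplyr::select(
        by_subject, "subject_id", "itd_us", "z_mean", "z_sd"
      ),
      pooled = pooled, task = summaries$task[1]
    ),
    class = "normalized_summary"
  )
}

#' @export
print.normalized_summary <- function(x, ...) {
  cat(
    "<normalized_summary>", x$task, "-",
    dplyr::n_distinct(x$by_subject$subject_id), "subjects,",
    nrow(x$pooled), "ITD levels\n"
  )
  print(x$pooled)
  invisible(x)
}

psi_fun <- function(A, k) function(itd_us) A * (2 / (1 + exp(-k * itd_us)) - 1)

fit_psi_once <- function(x, y, start_k = 0.005) {
  if (sd(y) < 1e-12) {
    return(list(A = 0, k = NA_real_))
  }
  fit <- minpack.lm::nlsLM(
    y ~ A * (2 / (1 + exp(-k * x)) - 1),
    start = list(A = max(abs(y)), k = start_k),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  as.list(coef(fit))
}

#' Fit the saturating response sigmoid
#'
#' Least-squares fit (Levenberg-Marquardt) of the two-parameter symmetric
#' logistic through the origin, `psi(itd) = A * (2 / (1 + exp(-k * itd)) -
#' 1)`, to azimuth estimates as a function of stimulus ITD. `A` is the
#' saturation asymptote (degrees), `k` the slope (1/us). Confidence
#' intervals come from refitting under resampling of subjects (if a
#' `subject_id` column is present) or of rows otherwise.
#'
#' @param data tibble with columns `itd_us` and `estimate` (e.g. per-subject
#'   mean estimates from [summarize_subjects()], renamed), optionally
#'   `subject_id`.
#' @param n_boot bootstrap refits for the CI (default 1000; 0 disables).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @param start_k initial slope for the optimizer (default 0.005 /us).
#' @return an object of class `sigmoid_fit`: list with `A`, `k`, `data`,
#'   `boot` (tibble of resampled A, k), `level`, and `fitted` (the fitted
#'   function of ITD in us). Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(itd_us = seq(-480, 480, 240))
#' d$estimate <- 50 * (2 / (1 + exp(-0.008 * d$itd_us)) - 1)
#' f <- fit_sigmoid(d, n_boot = 0)
#' glance(f)
fit_sigmoid <- function(data, n_boot = 1000, level = 0.95, seed = 1,
                        start_k = 0.005) {
  stopifnot(all(c("itd_us", "estimate") %in% names(data)))
  if (dplyr::n_distinct(data$itd_us) < 3) {
    stop("need at least 3 distinct ITDs to fit the sigmoid")
  }
  est <- fit_psi_once(data$itd_us, data$estimate, start_k)
  boot <- NULL
  if (n_boot > 0) {
    units <- if ("subject_id" %in% names(data)) {
      split(seq_len(nrow(data)), data$subject_id)
    } else {
      as.list(seq_len(nrow(data)))
    }
    boot <- withr_seed(seed, {
      draws <- purrr::map(seq_len(n_boot), function(b) {
        rows <- unlist(units[sample.int(length(units), replace = TRUE)])
        d <- data[rows, ]
        out <- tryCatch(
          fit_psi_once(d$itd_us, d$estimate, start_k),
          error = function(e) NULL
        )
        if (is.null(out)) NULL else tibble::tibble(A = out$A, k = out$k)
      })
      dplyr::bind_rows(draws)
    })
  }
  structure(
    list(
      A = est$A, k = est$k, data = data, boot = boot, level = level,
      fitted = psi_fun(est$A, est$k)
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(
    "<sigmoid_fit> A =", signif(x$A, 4), ", k =", signif(x$k, 4),
    "/us", if (!is.null(x$boot)) {
      paste0("(", nrow(x$boot), " bootstrap refits)")
    } else {
      ""
    }, "\n"
  )
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, itd_us, ...) object$fitted(itd_us)

#' @rdname fit_sigmoid
#' @param x a `sigmoid_fit`.
#' @param ... unused.
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("A", "k"), estimate = c(x$A, x$k),
    conf.low = NA_real_, conf.high = NA_real_
  )
  if (!is.null(x$boot) && nrow(x$boot) > 0) {
    a <- (1 - x$level) / 2
    out$conf.low <- c(
      quantile(x$boot$A, a, names = FALSE),
      quantile(x$boot$k, a, names = FALSE, na.rm = TRUE)
    )
    out$conf.high <- c(
      quantile(x$boot$A, 1 - a, names = FALSE),
      quantile(x$boot$k, 1 - a, names = FALSE, na.rm = TRUE)
    )
  }
  out
}

#' @rdname fit_sigmoid
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  res <- x$data$estimate - x$fitted(x$data$itd_us)
  tibble::tibble(
    A = x$A, k = x$k, sigma = sqrt(mean(res^2)), n = nrow(x$data),
    n_boot = if (is.null(x$boot)) 0L else nrow(x$boot)
  )
}

#' Invert the acoustic ITD-azimuth map
#'
#' Interpolates the across-subject median ITD of one cochlear band as a
#' cubic spline in azimuth, checks it is strictly monotone, and returns the
#' numerically inverted function: azimuth (degrees) as a function of ITD
#' (microseconds), defined on the span of the median curve.
#'
#' @param cue_map a `cue_map` from [build_cue_map()].
#' @param band_f band to invert (default 500 Hz, the band of the stimuli).
#' @return a vectorized function `f(itd_us) -> azimuth_deg` with attributes
#'   `domain` (ITD range, us) and `band_hz`.
#' @export
invert_acoustic_map <- function(cue_map, band_f = 500) {
  s <- dplyr::filter(cue_map$summary, .data$band_hz == band_f) |>
    dplyr::arrange(.data$azimuth_deg)
  if (nrow(s) < 4) stop("need >= 4 azimuths in band ", band_f, " Hz")
  d <- diff(s$itd_median)
  if (!(all(d > 0) || all(d < 0))) {
    bad <- which(sign(d) != sign(d[1]))[1]
    stop(
      "median ITD is not monotone in azimuth between ",
      s$azimuth_deg[bad], " and ", s$azimuth_deg[bad + 1],
      " deg; cannot invert (is the band above the ambiguity limit?)"
    )
  }
  fwd <- splinefun(s$azimuth_deg, s$itd_median, method = "natural")
  lo <- min(s$azimuth_deg)
  hi <- max(s$azimuth_deg)
  rng <- range(s$itd_median)
  inv1 <- function(itd) {
    if (itd < rng[1] || itd > rng[2]) {
      stop("ITD ", itd, " us outside the acoustic domain [",
        round(rng[1]), ", ", round(rng[2]), "] us",
        call. = FALSE
      )
    }
    uniroot(function(a) fwd(a) - itd, c(lo, hi), tol = 1e-10)$root
  }
  out <- function(itd_us) vapply(itd_us, inv1, numeric(1))
  attr(out, "domain") <- rng
  attr(out, "band_hz") <- band_f
  out
}

#' Azimuth-estimation bias curve
#'
#' The central comparison of the pipeline: perceived azimuth (the fitted
#' response sigmoid) minus acoustic azimuth (the inverted cue map),
#' evaluated on an ITD grid. Positive bias = the percept lies further
#' toward the periphery than the acoustics warrant. The confidence band
#' propagates only the sigmoid-fit uncertainty (bootstrap refits); the
#' acoustic curve is treated as fixed.
#'
#' @param fit a [fit_sigmoid()] result.
#' @param acoustic an [invert_acoustic_map()] function.
#' @param itd_grid_us evaluation grid in microseconds; defaults to 97 points
#'   spanning the acoustic domain.
#' @param level confidence level for the band (default the fit's).
#' @return a tibble of class `bias_curve`: `itd_us`, `acoustic_deg`,
#'   `perceived_deg`, `perceived_conf.low/high`, `bias_deg`,
#'   `bias_conf.low/high`; attributes `A`, `k`.
#' @export
compute_bias_curve <- function(fit, acoustic, itd_grid_us = NULL,
                               level = NULL) {
  stopifnot(inherits(fit, "sigmoid_fit"), is.function(acoustic))
  dom <- attr(acoustic, "domain")
  if (is.null(itd_grid_us)) {
    itd_grid_us <- seq(dom[1], dom[2], length.out = 97)
  }
  if (any(itd_grid_us < dom[1] | itd_grid_us > dom[2])) {
    stop("itd_grid_us extends outside the acoustic domain")
  }
  level <- level %||% fit$level
  ac <- acoustic(itd_grid_us)
  pc <- fit$fitted(itd_grid_us)
  out <- tibble::tibble(
    itd_us = itd_grid_us, acoustic_deg = ac, perceived_deg = pc,
    perceived_conf.low = NA_real_, perceived_conf.high = NA_real_,
    bias_deg = pc - ac, bias_conf.low = NA_real_, bias_conf.high = NA_real_
  )
  if (!is.null(fit$boot) && nrow(fit$boot) > 0) {
    a <- (1 - level) / 2
    draws <- purrr::pmap(fit$boot, function(A, k) psi_fun(A, k)(itd_grid_us))
    pm <- do.call(rbind, draws)
    out$perceived_conf.low <- apply(pm, 2, quantile, a, names = FALSE)
    out$perceived_conf.high <- apply(pm, 2, quantile, 1 - a, names = FALSE)
    out$bias_conf.low <- out$perceived_conf.low - ac
    out$bias_conf.high <- out$perceived_conf.high - ac
  }
  attr(out, "A") <- fit$A
  attr(out, "k") <- fit$k
  class(out) <- c("bias_curve", class(out))
  out
}
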