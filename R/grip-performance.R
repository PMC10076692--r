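#' Construct a digit-force grip trial
#'
#' Bundles one grip trial: time-stamped three-axis force series for the
#' thumb and index finger, the cue times, and trial annotations. Forces
#' follow the sensor convention of a normal component `fn_N` (toward the
#' grip surface) and two tangential (shear) components `ft1_N`, `ft2_N`,
#' all in newtons; time is seconds from recording start.
#'
#' @param forces Long tibble/data frame with columns `time_s`, `digit`
#'   (`"thumb"` or `"index"`), `fn_N`, `ft1_N`, `ft2_N`. Both digits must
#'   be sampled on the same uniform time grid.
#' @param sampling_rate Sampling rate in Hz (500 in the reference setup).
#' @param cue_grip,cue_rest Cue times (s) in the recording frame. Target
#'   trials need both with `cue_grip < cue_rest`; maximum-grip trials may
#'   leave them `NA`.
#' @param trial_kind `"target_grip"` (grip to a 4 N target) or
#'   `"max_grip"` (maximum voluntary grip).
#' @param hand `"paretic"` or `"nonparetic"`.
#' @return A `grip_trial` object: the force tibble with trial metadata
#'   stored as attributes.
#' @export
grip_trial <- function(forces, sampling_rate = 500,
                       cue_grip = NA_real_, cue_rest = NA_real_,
                       trial_kind = c("target_grip", "max_grip"),
                       hand = c("paretic", "nonparetic")) {
  trial_kind <- match.arg(trial_kind)
  hand <- match.arg(hand)
  forces <- tibble::as_tibble(forces)
  required <- c("time_s", "digit", "fn_N", "ft1_N", "ft2_N")
  missing_cols <- setdiff(required, names(forces))
  if (length(missing_cols) > 0) {
    stop_input("trial forces lack column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  digits <- sort(unique(forces$digit))
  for (d in c("index", "thumb")) {
    if (!d %in% digits) stop_input("trial is missing digit '%s'", d)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_input("sampling_rate must be positive")
  }
  times <- sort(unique(forces$time_s))
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE)) {
    stop_input("trial needs at least two strictly increasing time points")
  }
  n_per_digit <- table(forces$digit)
  if (length(unique(n_per_digit)) != 1 ||
      n_per_digit[[1]] != length(times)) {
    stop_input("thumb and index must share one time grid")
  }
  span <- range(times)
  if (trial_kind == "target_grip") {
    if (is.na(cue_grip) || is.na(cue_rest)) {
      stop_input("target_grip trials require cue_grip and cue_rest")
    }
    if (cue_grip >= cue_rest) stop_input("cue_grip must precede cue_rest")
    if (cue_grip < span[1] || cue_rest > span[2]) {
      stop_input("cue times fall outside the recorded span")
    }
  }
  structure(
    forces,
    class = c("grip_trial", class(forces)),
    sampling_rate = sampling_rate,
    cue_grip = cue_grip,
    cue_rest = cue_rest,
    trial_kind = trial_kind,
    hand = hand
  )
}

#' Grip-analysis configuration
#'
#' All tunable parameters of the grip-performance stage with their
#' defaults. `combine` chooses how the two digits' normal forces define
#' the scalar "grip force" (mean keeps the units of one digit's force,
#' which is natural for parallel grip surfaces whose opposing normal
#' forces are ideally equal; `"sum"` is available).
#'
#' @param baseline_window_s Length (s) of the pre-cue window used for the
#'   baseline mean/SD.
#' @param threshold_sd Threshold multiplier: onset/offset are crossings of
#'   baseline mean +/- `threshold_sd` * SD (3 by convention).
#' @param sustain_s Time (s) the threshold condition must hold to count,
#'   rejecting single-sample spikes.
#' @param sd_floor_N Lower bound (N) on the baseline SD so noiseless
#'   traces still have a finite-width threshold.
#' @param transient_s Rise transient (s) excluded from the hold window
#'   after onset; 0 reproduces a literal onset-to-rest-cue window.
#' @param max_latency_s Search horizon (s) after a cue; no crossing
#'   within it marks the metric invalid for that trial.
#' @param target_N Target grip force (N) for target trials.
#' @param angle_floor_N Minimum digit force magnitude (N) for a sample to
#'   define a force-direction angle.
#' @param combine `"mean"` or `"sum"` of the two digits' normal forces.
#' @return A named list of class `grip_config`.
#' @export
grip_config <- function(baseline_window_s = 0.5,
                        threshold_sd = 3,
                        sustain_s = 0.02,
                        sd_floor_N = 1e-3,
                        transient_s = 0.5,
                        max_latency_s = 5,
                        target_N = 4,
                        angle_floor_N = 0.1,
                        combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  stopifnot(baseline_window_s > 0, threshold_sd > 0, sustain_s >= 0,
            sd_floor_N > 0, transient_s >= 0, max_latency_s > 0,
            target_N > 0, angle_floor_N > 0)
  structure(
    list(
      baseline_window_s = baseline_window_s, threshold_sd = threshold_sd,
      sustain_s = sustain_s, sd_floor_N = sd_floor_N,
      transient_s = transient_s, max_latency_s = max_latency_s,
      target_N = target_N, angle_floor_N = angle_floor_N, combine = combine
    ),
    class = "grip_config"
  )
}

#' Scalar grip-force series of a trial
#'
#' Combines the thumb and index normal-force components into one scalar
#' series per time point (arithmetic mean by default, sum optionally).
#'
#' @param trial A [grip_trial()].
#' @param combine `"mean"` or `"sum"`.
#' @return Tibble with columns `time_s`, `force_N`, one row per sample.
#' @export
grip_force_series <- function(trial, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(trial)[, c("time_s", "digit", "fn_N")],
    names_from = "digit", values_from = "fn_N"
  )
  wide <- dplyr::arrange(wide, .data$time_s)
  f <- if (combine == "mean") {
    (wide$thumb + wide$index) / 2
  } else {
    wide$thumb + wide$index
  }
  tibble::tibble(time_s = wide$time_s, force_N = f)
}

#' Baseline force statistics before the grip cue
#'
#' Sample mean and SD (denominator n - 1) of the grip-force series over
#' the window `[cue_grip - window_s, cue_grip)`.
#'
#' @param series Tibble from [grip_force_series()].
#' @param cue_grip Grip cue time (s).
#' @param window_s Window length (s).
#' @return List with `mean` and `sd` (newtons).
#' @export
baseline_stats <- function(series, cue_grip, window_s = 0.5) {
  idx <- series$time_s >= cue_grip - window_s & series$time_s < cue_grip
  if (sum(idx) < 10) {
    stop_input("baseline window holds %d samples; need at least 10",
               sum(idx))
  }
  x <- series$force_N[idx]
  list(mean = mean(x), sd = stats::sd(x))
}

# first index at/after the cue where `above` is TRUE for >= sustain_n
# consecutive samples, restricted to crossings starting within
# max_latency; returns NA_integer_ if none
first_sustained <- function(above, time_s, cue, sustain_n, max_latency_s) {
  start <- which(time_s >= cue)[1]
  if (is.na(start)) {
    return(NA_integer_)
  }
  ok <- above[start:length(above)]
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= sustain_n)
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  idx <- start + begins[hit[1]] - 1
  if (time_s[idx] - cue > max_latency_s) {
    return(NA_integer_)
  }
  idx
}

#' Detect grip onset (reaction time)
#'
#' Grip initiation is the first sample at or after the grip cue where the
#' grip force exceeds the baseline mean by `threshold_sd` baseline SDs
#' and stays above for `sustain_s`. The returned reaction time is that
#' sample's time minus the cue time.
#'
#' @inheritParams baseline_stats
#' @param baseline_mean,baseline_sd Baseline statistics (N), typically
#'   from [baseline_stats()].
#' @param config A [grip_config()].
#' @return Reaction time in seconds, or `NA` if no sustained crossing
#'   occurs within `max_latency_s`.
#' @export
detect_onset <- function(series, cue_grip, baseline_mean, baseline_sd,
                         config = grip_config()) {
  if (is.unsorted(series$time_s, strictly = TRUE)) {
    stop_input("time must be strictly increasing")
  }
  dt <- stats::median(diff(series$time_s))
  thr <- baseline_mean +
    config$threshold_sd * max(baseline_sd, config$sd_floor_N)
  sustain_n <- max(1L, as.integer(round(config$sustain_s / dt)))
  idx <- first_sustained(series$force_N > thr, series$time_s, cue_grip,
                         sustain_n, config$max_latency_s)
  if (is.na(idx)) {
    return(NA_real_)
  }
  series$time_s[idx] - cue_grip
}

#' Detect grip offset (relaxation time)
#'
#' Grip termination is the first sample at or after the rest cue where
#' the grip force has returned to within `threshold_sd` baseline SDs of
#' the baseline mean and stays there for `sustain_s`.
#'
#' @inheritParams detect_onset
#' @param cue_rest Rest cue time (s).
#' @return Relaxation time in seconds, or `NA` if the force never
#'   returns within `max_latency_s`.
#' @export
detect_offset <- function(series, cue_rest, baseline_mean, baseline_sd,
                          config = grip_config()) {
  if (is.unsorted(series$time_s, strictly = TRUE)) {
    stop_input("time must be strictly increasing")
  }
  dt <- stats::median(diff(series$time_s))
  thr <- baseline_mean +
    config$threshold_sd * max(baseline_sd, config$sd_floor_N)
  sustain_n <- max(1L, as.integer(round(config$sustain_s / dt)))
  idx <- first_sustained(series$force_N <= thr, series$time_s, cue_rest,
                         sustain_n, config$max_latency_s)
  if (is.na(idx)) {
    return(NA_real_)
  }
  series$time_s[idx] - cue_rest
}

#' Peak grip strength of a maximum-grip trial
#'
#' @param trial A [grip_trial()] with `trial_kind = "max_grip"`.
#' @param config A [grip_config()].
#' @return Peak of the scalar grip-force series (N).
#' @export
peak_strength <- function(trial, config = grip_config()) {
  if (attr(trial, "trial_kind") != "max_grip") {
    stop_input("peak_strength expects a max_grip trial")
  }
  series <- grip_force_series(trial, config$combine)
  if (nrow(series) == 0) stop_input("empty force trace")
  max(series$force_N)
}

# hold window of a target trial: [cue_grip + onset + transient, cue_rest]
hold_window <- function(series, cue_grip, cue_rest, onset_s, transient_s) {
  lo <- cue_grip + onset_s + transient_s
  series$time_s >= lo & series$time_s <= cue_rest
}

#' Force-magnitude control error
#'
#' Absolute difference (N) between the target force and the mean grip
#' force over the hold window, which starts `transient_s` after the
#' detected onset (excluding the rise transient) and ends at the rest
#' cue.
#'
#' @inheritParams detect_onset
#' @param cue_rest Rest cue time (s).
#' @param onset_s Detected reaction time (s) for this trial.
#' @param config A [grip_config()]; supplies `target_N` and
#'   `transient_s`.
#' @return Magnitude error in newtons, or `NA` if the hold window is
#'   empty.
#' @export
magnitude_error <- function(series, cue_grip, cue_rest, onset_s,
                            config = grip_config()) {
  if (is.na(onset_s)) {
    return(NA_real_)
  }
  idx <- hold_window(series, cue_grip, cue_rest, onset_s,
                     config$transient_s)
  if (!any(idx)) {
    return(NA_real_)
  }
  abs(config$target_N - mean(series$force_N[idx]))
}

#' Force-direction control error
#'
#' Mean angular deviation (degrees) of each digit's force vector from
#' the direction normal to the grip surface, over the hold window:
#' per sample `theta = atan2(sqrt(ft1^2 + ft2^2), fn)`, averaged over
#' in-window samples whose force magnitude exceeds `angle_floor_N`, then
#' averaged (unweighted) over the two digits.
#'
#' @param trial A target-grip [grip_trial()].
#' @param onset_s Detected reaction time (s) for this trial.
#' @param config A [grip_config()].
#' @return Direction error in degrees (0 to 180), or `NA` if no sample
#'   defines an angle.
#' @export
direction_error <- function(trial, onset_s, config = grip_config()) {
  if (is.na(onset_s)) {
    return(NA_real_)
  }
  cue_grip <- attr(trial, "cue_grip")
  cue_rest <- attr(trial, "cue_rest")
  tb <- tibble::as_tibble(trial)
  per_digit <- vapply(c("thumb", "index"), function(d) {
    sub <- tb[tb$digit == d, ]
    sub <- sub[order(sub$time_s), ]
    idx <- sub$time_s >= cue_grip + onset_s + config$transient_s &
      sub$time_s <= cue_rest
    sub <- sub[idx, ]
    mag <- sqrt(sub$fn_N^2 + sub$ft1_N^2 + sub$ft2_N^2)
    sub <- sub[mag > config$angle_floor_N, ]
    if (nrow(sub) == 0) {
      return(NA_real_)
    }
    shear <- sqrt(sub$ft1_N^2 + sub$ft2_N^2)
    mean(atan2(shear, sub$fn_N)) * 180 / pi
  }, numeric(1))
  if (all(is.na(per_digit))) {
    return(NA_real_)
  }
  mean(per_digit, na.rm = TRUE)
}

#' All metrics of one trial
#'
#' Runs the full per-trial extraction: strength for maximum-grip trials;
#' reaction time, relaxation time, magnitude error and direction error
#' for target trials. Metrics that cannot be computed (no sustained
#' crossing within the search horizon, empty hold window) come back `NA`
#' and are excluded from repetition averages downstream.
#'
#' @param trial A [grip_trial()].
#' @param config A [grip_config()].
#' @return One-row tibble: `hand`, `trial_kind`, `strength_N`,
#'   `reaction_s`, `relaxation_s`, `magnitude_N`, `direction_deg`.
#' @export
trial_metrics <- function(trial, config = grip_config()) {
  kind <- attr(trial, "trial_kind")
  hand <- attr(trial, "hand")
  out <- tibble::tibble(
    hand = hand, trial_kind = kind,
    strength_N = NA_real_, reaction_s = NA_real_, relaxation_s = NA_real_,
    magnitude_N = NA_real_, direction_deg = NA_real_
  )
  if (kind == "max_grip") {
    out$strength_N <- peak_strength(trial, config)
    return(out)
  }
  series <- grip_force_series(trial, config$combine)
  cue_grip <- attr(trial, "cue_grip")
  cue_rest <- attr(trial, "cue_rest")
  bl <- baseline_stats(series, cue_grip, config$baseline_window_s)
  out$reaction_s <- detect_onset(series, cue_grip, bl$mean, bl$sd, config)
  out$relaxation_s <- detect_offset(series, cue_rest, bl$mean, bl$sd, config)
  out$magnitude_N <- magnitude_error(series, cue_grip, cue_rest,
                                     out$reaction_s, config)
  out$direction_deg <- direction_error(trial, out$reaction_s, config)
  out
}

#' Per-hand repetition averages
#'
#' Averages each metric over its valid repetitions, separately per hand.
#'
#' @param metrics Tibble of per-trial rows from [trial_metrics()].
#' @return Tibble with one row per hand: mean of each metric over valid
#'   repetitions plus `n_<metric>` counts.
#' @export
summarize_trials <- function(metrics) {
  cols <- c("strength_N", "reaction_s", "relaxation_s",
            "magnitude_N", "direction_deg")
  metrics |>
    dplyr::group_by(.data$hand) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         n = ~ sum(!is.na(.x))),
                    .names = "{.fn}_{.col}"),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("mean_"),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
}

#' Paretic-to-sum performance ratios
#'
#' For each of the five measures, the normalization
#' `paretic / (paretic + nonparetic)` of the per-hand repetition means.
#' A both-hands-zero denominator yields `NA` with a warning.
#'
#' @param hand_summary Output of [summarize_trials()] containing one
#'   `paretic` and one `nonparetic` row.
#' @return One-row tibble with `ratio_strength`, `ratio_reaction`,
#'   `ratio_relaxation`, `ratio_magnitude`, `ratio_direction`.
#' @export
performance_ratios <- function(hand_summary) {
  for (h in c("paretic", "nonparetic")) {
    if (!h %in% hand_summary$hand) {
      stop_input("hand summary lacks the %s hand", h)
    }
  }
  p <- hand_summary[hand_summary$hand == "paretic", ]
  q <- hand_summary[hand_summary$hand == "nonparetic", ]
  one <- function(col, label) {
    a <- p[[paste0("mean_", col)]]
    b <- q[[paste0("mean_", col)]]
    if (is.na(a) || is.na(b)) {
      return(NA_real_)
    }
    if (a + b == 0) {
      rlang::warn(sprintf("both-hand %s values are zero; ratio undefined",
                          label))
      return(NA_real_)
    }
    a / (a + b)
  }
  tibble::tibble(
    ratio_strength = one("strength_N", "strength"),
    ratio_reaction = one("reaction_s", "reaction"),
    ratio_relaxation = one("relaxation_s", "relaxation"),
    ratio_magnitude = one("magnitude_N", "magnitude"),
    ratio_direction = one("direction_deg", "direction")
  )
}

#' Grip performance of one participant
#'
#' Convenience wrapper: per-trial metrics for a list of trials from both
#' hands, repetition averages per hand, and the five paretic ratios.
#'
#' @param trials List of [grip_trial()] objects (both hands, both trial
#'   kinds).
#' @param config A [grip_config()].
#' @return List with `metrics` (per-trial tibble), `summary` (per-hand
#'   tibble) and `ratios` (one-row tibble).
#' @export
grip_performance <- function(trials, config = grip_config()) {
  metrics <- purrr::map_dfr(trials, trial_metrics, config = config)
  hand_summary <- summarize_trials(metrics)
  list(
    metrics = metrics,
    summary = hand_summary,
    ratios = performance_ratios(hand_summary)
  )
}

#' @describeIn grip_trial Annotated force-trace plot of a trial (grip
#'   force with cue markers), mainly for visual quality checks.
#' @param object A `grip_trial`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.grip_trial <- function(object, ...) {
  series <- grip_force_series(object)
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_s, y = .data$force_N)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "grip force (N)",
                  title = sprintf("%s / %s", attr(object, "hand"),
                                  attr(object, "trial_kind")))
  cues <- c(attr(object, "cue_grip"), attr(object, "cue_rest"))
  cues <- cues[!is.na(cues)]
  if (length(cues) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = cues, linetype = "dashed")
  }
  p
}
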