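#' Specification of a synthetic cohort
#'
#' Defines every parameter of the synthetic data generator. The
#' defaults emulate the clinical situation the pipeline is designed
#' for: a 22-participant chronic hemiparetic cohort, 500 Hz digit-force
#' recordings with a 4 N target and three repetitions per condition per
#' hand, skewed nonnegative streamline counts over the 20-region
#' sensorimotor set with a planted latent network structure, per-region
#' lesion fractions that confound both connectivity and performance,
#' and five performance ratios centred and scaled like those observed
#' in such cohorts (means 0.39-0.54, SDs 0.11-0.35).
#'
#' @param n_participants Cohort size.
#' @param regions Region tibble ([default_regions()]).
#' @param k_networks Number of planted latent networks.
#' @param network_groups Integer vector (length = number of regions)
#'   assigning each region to a planted network `1..K` (0 = none).
#'   Default: contiguous near-equal partition of the region list.
#' @param edge_weight_range Range the planted in-network edge weights
#'   are drawn from (uniform), default `c(0.4, 0.9)`.
#' @param base_log_count Baseline natural-log streamline count shared by
#'   all edges (default 5, i.e. ~150 streamlines).
#' @param count_noise_sd SD of the log-count noise.
#' @param count_jitter_sd SD of the directed-count jitter added to one
#'   direction and subtracted from the other (counts, not log).
#' @param effects 5 x K matrix of standardized effects of each network
#'   score on each performance ratio. Default: ratio `m` loads 0.35 on
#'   network `((m - 1) mod K) + 1`.
#' @param measure_means,measure_sds Location and scale of the five
#'   ratios (order: strength, reaction, relaxation, magnitude,
#'   direction).
#' @param ratio_clamp Bounds the generated ratios are clamped to.
#' @param lesion_intercept Logit-scale intercept of the per-region
#'   lesion fraction model (default `qlogis(0.05)`).
#' @param lesion_noise_sd Logit-scale lesion noise SD.
#' @param lesion_score_coupling Coupling `b >= 0`: each region's lesion
#'   fraction rises as its network's latent score falls (0 =
#'   unconfounded).
#' @param lesion_measure_effect Direct standardized effect of network
#'   lesion load on the ratios (performance worsens with lesion load).
#' @param sampling_rate,cue_grip,cue_rest,trial_duration Trial timing
#'   (Hz, s): grip cue, rest cue 2 s later, total recording length.
#' @param n_reps Repetitions per condition per hand.
#' @param target_N Target force of the target-grip condition.
#' @param trial_noise_sd Per-digit force sensor noise SD (N); 0 gives
#'   noiseless traces.
#' @param baseline_force_N Resting contact force before the grip cue.
#' @param nonparetic Named list of normative nonparetic-hand metric
#'   values (`strength_N`, `reaction_s`, `relaxation_s`, `magnitude_N`,
#'   `direction_deg`).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 22,
                        regions = default_regions(),
                        k_networks = 3,
                        network_groups = NULL,
                        edge_weight_range = c(0.4, 0.9),
                        base_log_count = 5,
                        count_noise_sd = 0.3,
                        count_jitter_sd = 2,
                        effects = NULL,
                        measure_means = c(0.39, 0.52, 0.54, 0.50, 0.54),
                        measure_sds = c(0.20, 0.11, 0.16, 0.35, 0.11),
                        ratio_clamp = c(0.05, 0.95),
                        lesion_intercept = stats::qlogis(0.05),
                        lesion_noise_sd = 0.5,
                        lesion_score_coupling = 0.5,
                        lesion_measure_effect = 0.2,
                        sampling_rate = 500,
                        cue_grip = 2,
                        cue_rest = 4,
                        trial_duration = 7,
                        n_reps = 3,
                        target_N = 4,
                        trial_noise_sd = 0.02,
                        baseline_force_N = 0.2,
                        nonparetic = list(strength_N = 30,
                                          reaction_s = 0.35,
                                          relaxation_s = 0.45,
                                          magnitude_N = 0.3,
                                          direction_deg = 8),
                        seed) {
  if (missing(seed) || is.null(seed)) stop_input("cohort_spec requires a seed")
  r <- nrow(regions)
  if (is.null(network_groups)) {
    network_groups <- sort(rep_len(seq_len(k_networks), r))
  }
  if (length(network_groups) != r) {
    stop_input("network_groups must have one entry per region")
  }
  if (is.null(effects)) {
    effects <- matrix(0, 5, k_networks)
    for (m in 1:5) effects[m, ((m - 1) %% k_networks) + 1] <- 0.35
  }
  effects <- as.matrix(effects)
  if (nrow(effects) != 5 || ncol(effects) != k_networks) {
    stop_input("effects must be a 5 x k_networks matrix")
  }
  if (any(abs(effects) > 1)) stop_input("|effects| must be <= 1")
  stopifnot(count_noise_sd > 0, lesion_noise_sd > 0,
            all(measure_sds > 0), trial_noise_sd >= 0,
            lesion_score_coupling >= 0,
            cue_grip < cue_rest, cue_rest < trial_duration)
  structure(
    list(
      n_participants = n_participants, regions = regions,
      k_networks = k_networks, network_groups = network_groups,
      edge_weight_range = edge_weight_range,
      base_log_count = base_log_count, count_noise_sd = count_noise_sd,
      count_jitter_sd = count_jitter_sd, effects = effects,
      measure_means = measure_means, measure_sds = measure_sds,
      ratio_clamp = ratio_clamp,
      lesion_intercept = lesion_intercept,
      lesion_noise_sd = lesion_noise_sd,
      lesion_score_coupling = lesion_score_coupling,
      lesion_measure_effect = lesion_measure_effect,
      sampling_rate = sampling_rate, cue_grip = cue_grip,
      cue_rest = cue_rest, trial_duration = trial_duration,
      n_reps = n_reps, target_N = target_N,
      trial_noise_sd = trial_noise_sd,
      baseline_force_N = baseline_force_N,
      nonparetic = nonparetic,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

participant_ids <- function(spec) {
  sprintf("p%02d", seq_len(spec$n_participants))
}

measure_cols <- c("ratio_strength", "ratio_reaction", "ratio_relaxation",
                  "ratio_magnitude", "ratio_direction")
metric_cols <- c("strength_N", "reaction_s", "relaxation_s",
                 "magnitude_N", "direction_deg")

#' Planted network edge-weight patterns
#'
#' The ground-truth analog of [network_definitions()]: for each planted
#' network, edges joining two regions of its group carry a weight drawn
#' uniformly from `edge_weight_range` (seeded, fixed per spec); all
#' other edges are 0.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble `network`, `edge`, `region_a`, `region_b`, `weight`,
#'   `reported` (same shape as [network_definitions()] output).
#' @export
planted_networks <- function(spec) {
  ei <- edge_index(spec$regions)
  g <- spec$network_groups
  set.seed(child_seed(spec$seed, 23))
  out <- purrr::map_dfr(seq_len(spec$k_networks), function(k) {
    in_net <- g[ei$idx_a] == k & g[ei$idx_b] == k
    w <- numeric(nrow(ei))
    w[in_net] <- stats::runif(sum(in_net), spec$edge_weight_range[1],
                              spec$edge_weight_range[2])
    tibble::tibble(network = paste0("N", k), edge = ei$edge,
                   region_a = ei$region_a, region_b = ei$region_b,
                   weight = w)
  })
  out |>
    dplyr::group_by(.data$network) |>
    dplyr::mutate(reported = rank(-abs(.data$weight),
                                  ties.method = "first") <= 6 &
                    abs(.data$weight) >= 0.4) |>
    dplyr::ungroup()
}

#' Sample latent network scores
#'
#' Independent standard-normal scores, one column per planted network.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble `participant` + `N1..NK`.
#' @export
sample_latents <- function(spec) {
  set.seed(child_seed(spec$seed, 11))
  s <- matrix(stats::rnorm(spec$n_participants * spec$k_networks),
              spec$n_participants, spec$k_networks)
  colnames(s) <- paste0("N", seq_len(spec$k_networks))
  dplyr::bind_cols(tibble::tibble(participant = participant_ids(spec)),
                   tibble::as_tibble(s))
}

#' Generate directed streamline-count matrices
#'
#' Log-normal count model with planted factor structure: for edge `e`
#' and participant `i`,
#' `log count = base + sum_g pattern_g(e) * score_ig + eps`,
#' `eps ~ N(0, count_noise_sd)`. Counts are the rounded exponential; the
#' two directions are the symmetric count plus/minus a small seeded
#' jitter (so [symmetrize_counts()] is exercised), floored at 0.
#'
#' @param latents Tibble from [sample_latents()].
#' @param spec A [cohort_spec()].
#' @return Named list of directed count matrices, one per participant.
#' @export
generate_counts <- function(latents, spec) {
  ei <- edge_index(spec$regions)
  pattern <- planted_networks(spec) |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  lam <- as.matrix(pattern[match(ei$edge, pattern$edge), -1, drop = FALSE])
  s <- as.matrix(latents[, paste0("N", seq_len(spec$k_networks)),
                         drop = FALSE])
  set.seed(child_seed(spec$seed, 37))
  n <- nrow(s)
  ne <- nrow(ei)
  logc <- spec$base_log_count + s %*% t(lam) +
    matrix(stats::rnorm(n * ne, 0, spec$count_noise_sd), n, ne)
  counts <- round(exp(logc))
  jitter <- matrix(stats::rnorm(n * ne, 0, spec$count_jitter_sd), n, ne)
  r <- nrow(spec$regions)
  out <- lapply(seq_len(n), function(i) {
    m <- matrix(0, r, r,
                dimnames = list(spec$regions$region, spec$regions$region))
    fwd <- pmax(0, round(counts[i, ] + jitter[i, ]))
    bwd <- pmax(0, round(counts[i, ] - jitter[i, ]))
    m[cbind(ei$idx_a, ei$idx_b)] <- fwd
    m[cbind(ei$idx_b, ei$idx_a)] <- bwd
    m
  })
  stats::setNames(out, latents$participant)
}

#' Generate per-region lesion fractions
#'
#' Each region's lesioned volume fraction follows a logistic-normal
#' model whose logit falls with the latent score of the region's
#' planted network (coupling `b = lesion_score_coupling`; `b = 0` gives
#' lesions independent of connectivity):
#' `fraction = plogis(intercept - b * score + noise)`.
#'
#' @inheritParams generate_counts
#' @return Tibble `participant`, `region`, `lesion_fraction`.
#' @export
generate_lesions <- function(latents, spec) {
  set.seed(child_seed(spec$seed, 53))
  g <- spec$network_groups
  s <- as.matrix(latents[, paste0("N", seq_len(spec$k_networks)),
                         drop = FALSE])
  n <- nrow(s)
  r <- nrow(spec$regions)
  score_term <- matrix(0, n, r)
  grouped <- g > 0
  score_term[, grouped] <- s[, g[grouped], drop = FALSE]
  logit <- spec$lesion_intercept -
    spec$lesion_score_coupling * score_term +
    matrix(stats::rnorm(n * r, 0, spec$lesion_noise_sd), n, r)
  frac <- stats::plogis(logit)
  tibble::tibble(
    participant = rep(latents$participant, each = r),
    region = rep(spec$regions$region, times = n),
    lesion_fraction = as.numeric(t(frac))
  )
}

# planted network lesion percents (uses the ground-truth edge pattern)
planted_lesion_percents <- function(lesions, spec) {
  defs <- planted_networks(spec)
  purrr::map_dfr(unique(defs$network), function(g) {
    network_lesion_percent(lesions, defs[defs$network == g, ],
                           spec$regions)
  })
}

#' Generate the five performance ratios
#'
#' Each ratio is an affine transform of a standardized signal combining
#' the planted network effects, a direct lesion-load effect on the
#' measure's primary network, and independent noise scaled so the
#' signal has unit variance when lesions are unconfounded:
#' `ratio_m = mean_m + sd_m * (sum_g E[m,g] score_g - gamma * lesion_z +
#' resid * eps)`, clamped to `ratio_clamp`.
#'
#' @inheritParams generate_counts
#' @param lesions Tibble from [generate_lesions()] (used for the direct
#'   lesion effect; may be omitted when `lesion_measure_effect = 0`).
#' @return Tibble `participant` + the five `ratio_*` columns.
#' @export
generate_measures <- function(latents, spec, lesions = NULL) {
  s <- as.matrix(latents[, paste0("N", seq_len(spec$k_networks)),
                         drop = FALSE])
  n <- nrow(s)
  gamma <- spec$lesion_measure_effect
  lesion_z <- matrix(0, n, spec$k_networks)
  if (gamma != 0) {
    if (is.null(lesions)) {
      stop_input("lesion_measure_effect != 0 requires lesion profiles")
    }
    lp <- planted_lesion_percents(lesions, spec) |>
      tidyr::pivot_wider(names_from = "network",
                         values_from = "lesion_percent")
    lp <- lp[match(latents$participant, lp$participant), ]
    lesion_z <- scale(as.matrix(
      lp[, paste0("N", seq_len(spec$k_networks)), drop = FALSE]
    ))
  }
  set.seed(child_seed(spec$seed, 67))
  out <- tibble::tibble(participant = latents$participant)
  for (m in 1:5) {
    e_m <- spec$effects[m, ]
    primary <- if (all(e_m == 0)) 1L else which.max(abs(e_m))
    resid_sd <- sqrt(max(0, 1 - sum(e_m^2) - gamma^2))
    u <- as.numeric(s %*% e_m) - gamma * lesion_z[, primary] +
      resid_sd * stats::rnorm(n)
    ratio <- spec$measure_means[m] + spec$measure_sds[m] * u
    out[[measure_cols[m]]] <- pmin(spec$ratio_clamp[2],
                                   pmax(spec$ratio_clamp[1], ratio))
  }
  out
}

# invert the paretic/(paretic + nonparetic) normalization to per-hand
# true metric values, clamped to ranges the trace synthesizer supports
true_hand_metrics <- function(measures, spec) {
  np <- spec$nonparetic
  np_vals <- c(np$strength_N, np$reaction_s, np$relaxation_s,
               np$magnitude_N, np$direction_deg)
  lo <- c(2, 0.08, 0.25, 0.02, 0.5)
  hi <- c(80, 1.2, 1.5, 2.5, 60)
  rows <- purrr::map_dfr(seq_len(nrow(measures)), function(i) {
    ratios <- as.numeric(measures[i, measure_cols])
    paretic <- np_vals * ratios / (1 - ratios)
    paretic <- pmin(hi, pmax(lo, paretic))
    tibble::tibble(
      participant = measures$participant[i],
      hand = c("paretic", "nonparetic"),
      strength_N = c(paretic[1], np_vals[1]),
      reaction_s = c(paretic[2], np_vals[2]),
      relaxation_s = c(paretic[3], np_vals[3]),
      magnitude_N = c(paretic[4], np_vals[4]),
      direction_deg = c(paretic[5], np_vals[5])
    )
  })
  rows
}

# quarter-sine rise/fall trace through (baseline, hold) levels with
# exact threshold crossings at the planted latencies: the rise is
# advanced by the instant the sine needs to clear the floored 3-SD
# detection band, so at zero trace noise the band crossing falls
# exactly on cue + reaction_s (and within one sample once discretized)
target_trace <- function(t, spec, reaction_s, relaxation_s, hold_N) {
  b0 <- spec$baseline_force_N
  rise_s <- 0.15
  fall_s <- 0.2
  band <- 3 * 1e-3 # detection threshold offset at the SD floor
  lead <- (2 * rise_s / pi) * asin(min(1, band / max(hold_N - b0, band)))
  t_on <- spec$cue_grip + reaction_s - lead
  t_fs <- spec$cue_rest + relaxation_s - fall_s
  f <- rep(b0, length(t))
  rising <- t >= t_on & t < t_on + rise_s
  f[rising] <- b0 + (hold_N - b0) *
    sin(pi / 2 * (t[rising] - t_on) / rise_s)
  holding <- t >= t_on + rise_s & t < t_fs
  f[holding] <- hold_N
  falling <- t >= t_fs & t < t_fs + fall_s
  f[falling] <- b0 + (hold_N - b0) *
    cos(pi / 2 * (t[falling] - t_fs) / fall_s)
  f
}

max_trace <- function(t, spec, peak_N) {
  b0 <- spec$baseline_force_N
  t_on <- 1.5
  rise_s <- 1
  hold_s <- 1
  f <- rep(b0, length(t))
  rising <- t >= t_on & t < t_on + rise_s
  f[rising] <- b0 + (peak_N - b0) *
    sin(pi / 2 * (t[rising] - t_on) / rise_s)
  holding <- t >= t_on + rise_s & t < t_on + rise_s + hold_s
  f[holding] <- peak_N
  falling <- t >= t_on + rise_s + hold_s &
    t < t_on + rise_s + hold_s + rise_s
  f[falling] <- b0 + (peak_N - b0) *
    cos(pi / 2 * (t[falling] - (t_on + rise_s + hold_s)) / rise_s)
  f
}

#' Synthesize one grip trial with planted metric values
#'
#' Builds a [grip_trial()] whose extracted metrics equal the planted
#' values (up to one sample period for the latencies) when
#' `trial_noise_sd = 0`: baseline contact force, quarter-sine rise
#' starting `reaction_s` after the grip cue, constant hold at
#' `target_N + magnitude_N`, quarter-sine fall timed so the force
#' re-enters the baseline band exactly `relaxation_s` after the rest
#' cue, and tangential components set so each digit's force angle is
#' `direction_deg` throughout.
#'
#' @param spec A [cohort_spec()] (supplies timing, target and noise).
#' @param reaction_s,relaxation_s,magnitude_N,direction_deg,strength_N
#'   Planted metric values; `strength_N` only used for max-grip trials.
#' @param trial_kind `"target_grip"` or `"max_grip"`.
#' @param hand Hand label.
#' @return A [grip_trial()].
#' @export
synthesize_trial <- function(spec, reaction_s = 0.3, relaxation_s = 0.4,
                             magnitude_N = 0, direction_deg = 5,
                             strength_N = 30,
                             trial_kind = c("target_grip", "max_grip"),
                             hand = c("paretic", "nonparetic")) {
  trial_kind <- match.arg(trial_kind)
  hand <- match.arg(hand)
  t <- seq(0, spec$trial_duration, by = 1 / spec$sampling_rate)
  f <- if (trial_kind == "target_grip") {
    target_trace(t, spec, reaction_s, relaxation_s,
                 spec$target_N + magnitude_N)
  } else {
    max_trace(t, spec, strength_N)
  }
  tan_theta <- tan(direction_deg * pi / 180)
  phis <- c(thumb = 0.6, index = 3.6) # arbitrary fixed shear azimuths
  forces <- purrr::imap_dfr(phis, function(phi, d) {
    noise <- function() {
      if (spec$trial_noise_sd > 0) {
        stats::rnorm(length(t), 0, spec$trial_noise_sd)
      } else {
        0
      }
    }
    tibble::tibble(
      time_s = t, digit = d,
      fn_N = f + noise(),
      ft1_N = f * tan_theta * cos(phi) + noise(),
      ft2_N = f * tan_theta * sin(phi) + noise()
    )
  })
  grip_trial(forces, sampling_rate = spec$sampling_rate,
             cue_grip = if (trial_kind == "target_grip") spec$cue_grip
             else NA_real_,
             cue_rest = if (trial_kind == "target_grip") spec$cue_rest
             else NA_real_,
             trial_kind = trial_kind, hand = hand)
}

#' Generate all grip trials of a cohort
#'
#' For every participant and hand, synthesizes `n_reps` maximum-grip
#' and `n_reps` target-grip trials whose planted metric values come
#' from inverting the generated performance ratios against normative
#' nonparetic values ([generate_measures()]), so that running the
#' extraction stage on these traces recovers the planted metrics.
#'
#' @inheritParams generate_counts
#' @param measures Tibble from [generate_measures()].
#' @return Tibble with one row per trial: `participant`, `hand`,
#'   `trial_kind`, `repetition`, the planted metric values and a
#'   `trial` list-column of [grip_trial()] objects.
#' @export
generate_trials <- function(latents, spec,
                            measures = generate_measures(latents, spec)) {
  truth <- true_hand_metrics(measures, spec)
  set.seed(child_seed(spec$seed, 79))
  grid <- tidyr::expand_grid(
    truth,
    trial_kind = c("max_grip", "target_grip"),
    repetition = seq_len(spec$n_reps)
  )
  grid$trial <- purrr::pmap(grid, function(participant, hand, strength_N,
                                           reaction_s, relaxation_s,
                                           magnitude_N, direction_deg,
                                           trial_kind, repetition) {
    synthesize_trial(spec, reaction_s = reaction_s,
                     relaxation_s = relaxation_s,
                     magnitude_N = magnitude_N,
                     direction_deg = direction_deg,
                     strength_N = strength_N,
                     trial_kind = trial_kind, hand = hand)
  })
  grid
}

#' Generate a complete synthetic cohort
#'
#' Draws every component of a cohort with planted ground truth and,
#' optionally, writes the full input bundle the pipeline stages consume
#' (trial CSVs plus metadata, per-participant count TSVs, region and
#' distance tables, lesion profiles) together with a ground-truth JSON.
#' Bit-identical across runs with the same spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @param trials Set `FALSE` to skip force-trace synthesis (the slowest
#'   component) when only counts/lesions/measures are needed.
#' @return List: `spec`, `latents`, `pattern` (planted network
#'   definitions), `counts`, `lesions`, `measures`, `trials` (or
#'   `NULL`), `distances`, and `dir` when written.
#' @export
generate_cohort <- function(spec, dir = NULL, trials = TRUE) {
  latents <- sample_latents(spec)
  pattern <- planted_networks(spec)
  counts <- generate_counts(latents, spec)
  lesions <- generate_lesions(latents, spec)
  measures <- generate_measures(latents, spec, lesions)
  trial_tbl <- if (trials) generate_trials(latents, spec, measures)
  else NULL
  distances <- default_distances(spec$regions)
  out <- list(spec = spec, latents = latents, pattern = pattern,
              counts = counts, lesions = lesions, measures = measures,
              trials = trial_tbl, distances = distances, dir = dir)
  if (!is.null(dir)) {
    write_cohort(out, dir)
  }
  out
}
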