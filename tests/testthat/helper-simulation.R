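# simulation harnesses used by the acceptance-style tests

# one two-level recovery run: planted K disjoint networks, returns the
# number of Kaiser-retained second-level factors and the matched
# congruences between recovered and planted composite edge weights
recovery_run <- function(seed, n, k = 3, weight_range = c(0.6, 0.9),
                         count_noise_sd = 0.3) {
  spec <- cohort_spec(n_participants = n, k_networks = k,
                      edge_weight_range = weight_range,
                      count_noise_sd = count_noise_sd, seed = seed)
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  model <- two_level_model(tab, spec$regions)
  recovered <- network_definitions(model) |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  planted <- co$pattern |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  stopifnot(identical(recovered$edge, planted$edge))
  matched <- match_factors(as.matrix(planted[, -1]),
                           as.matrix(recovered[, -1]))
  list(k2 = model$second$k, model = model, cohort = co,
       congruence = abs(matched$congruence), matched = matched)
}

# one association-calibration replicate: planted effect of network 1 on
# the strength ratio, unconfounded lesions; returns the fitted cell
calibration_run <- function(seed, n, effect = 0.5) {
  e <- matrix(0, 5, 3)
  e[1, 1] <- effect
  spec <- cohort_spec(n_participants = n, seed = seed, effects = e,
                      lesion_score_coupling = 0,
                      lesion_measure_effect = 0)
  lat <- sample_latents(spec)
  les <- generate_lesions(lat, spec)
  meas <- generate_measures(lat, spec, les)
  lp <- connectogrip:::planted_lesion_percents(les, spec)
  lp1 <- lp[lp$network == "N1", ]
  lp1 <- lp1[match(lat$participant, lp1$participant), ]
  fit_association(meas$ratio_strength, lat$N1, lp1$lesion_percent)
}

# one confounded replicate: lesions depress both the latent-linked
# connectivity score and the measure, so the simple correlation
# overstates the planted direct effect
confounding_run <- function(seed, n, effect = 0.4, gamma = 0.45,
                            b = 0.8) {
  e <- matrix(0, 5, 3)
  e[1, 1] <- effect
  spec <- cohort_spec(n_participants = n, seed = seed, effects = e,
                      lesion_score_coupling = b,
                      lesion_measure_effect = gamma)
  lat <- sample_latents(spec)
  les <- generate_lesions(lat, spec)
  meas <- generate_measures(lat, spec, les)
  lp <- connectogrip:::planted_lesion_percents(les, spec)
  lp1 <- lp[lp$network == "N1", ]
  lp1 <- lp1[match(lat$participant, lp1$participant), ]
  fit_association(meas$ratio_strength, lat$N1, lp1$lesion_percent)
}

# one full end-to-end run: 5 measures driven by 5 distinct planted
# networks; returns whether the best-network call matches the planted
# pairing for every measure, with and without lesion adjustment
table1_run <- function(seed, n, effect = 0.6) {
  spec <- cohort_spec(n_participants = n, k_networks = 5,
                      effects = diag(effect, 5),
                      edge_weight_range = c(0.6, 0.9),
                      lesion_score_coupling = 0,
                      lesion_measure_effect = 0, seed = seed)
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  model <- two_level_model(tab, spec$regions)
  netdefs <- network_definitions(model)
  recovered <- netdefs |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  planted <- co$pattern |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  matched <- match_factors(as.matrix(planted[, -1]),
                           as.matrix(recovered[, -1]))
  twin <- stats::setNames(colnames(recovered[, -1])[matched$matched],
                          colnames(planted[, -1]))
  scores <- network_scores(model)
  lesion_percents <- purrr::map_dfr(model$networks, function(g) {
    network_lesion_percent(co$lesions, netdefs[netdefs$network == g, ],
                           spec$regions)
  })
  suppressMessages(
    tabl <- association_table(scores, co$measures, lesion_percents)
  )
  measure_names <- c("ratio_strength", "ratio_reaction",
                     "ratio_relaxation", "ratio_magnitude",
                     "ratio_direction")
  planted_pairs <- stats::setNames(paste0("N", 1:5), measure_names)
  ok_adj <- all(vapply(measure_names, function(m) {
    tabl$best$network_adjusted[tabl$best$measure == m] ==
      twin[[planted_pairs[[m]]]]
  }, logical(1)))
  ok_unadj <- all(vapply(measure_names, function(m) {
    tabl$best$network_unadjusted[tabl$best$measure == m] ==
      twin[[planted_pairs[[m]]]]
  }, logical(1)))
  list(ok_adj = ok_adj, ok_unadj = ok_unadj, k2 = model$second$k)
}
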