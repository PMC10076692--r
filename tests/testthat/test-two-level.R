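# builds a hand-specified two-level model object for the composite-edge
# arithmetic tests (3 regions, 3 edges, controlled loadings)
fake_two_level <- function(first_loadings, second_loadings) {
  regions <- toy_regions(3)
  models <- lapply(stats::setNames(regions$region, regions$region),
                   function(r) {
    l <- first_loadings[[r]]
    structure(list(loadings = l, k = ncol(l)), class = "factor_model")
  })
  structure(
    list(
      first = list(models = models),
      second = list(loadings = second_loadings,
                    k = ncol(second_loadings)),
      regions = regions,
      edge_info = edge_index(regions),
      participants = c("p1", "p2", "p3"),
      networks = colnames(second_loadings)
    ),
    class = "two_level_model"
  )
}

test_that("composite edge weights keep the dominant loading product", {
  # R1's single factor loads 0.8 on edge R1--R2; that factor loads 0.6
  # on the network; R2 and R3 carry an alternative weaker path
  l1 <- matrix(c(0.8, 0.1), 2, 1,
               dimnames = list(c("R1--R2", "R1--R3"), "F1"))
  l2 <- matrix(c(0.5, 0.2), 2, 1,
               dimnames = list(c("R1--R2", "R2--R3"), "F1"))
  l3 <- matrix(c(0.1, -0.9), 2, 1,
               dimnames = list(c("R1--R3", "R2--R3"), "F1"))
  second <- matrix(c(0.6, 0.5, 0.8), 3, 1,
                   dimnames = list(c("R1::F1", "R2::F1", "R3::F1"), "N1"))
  m <- fake_two_level(list(R1 = l1, R2 = l2, R3 = l3), second)
  w <- composite_edge_weights(m, "N1")
  # R1--R2: max(|0.8*0.6|, |0.5*0.5|) -> 0.48
  expect_equal(w$weight[w$edge == "R1--R2"], 0.48)
  # R2--R3: candidates 0.2*0.5 = 0.1 and -0.9*0.8 = -0.72; keep -0.72
  expect_equal(w$weight[w$edge == "R2--R3"], -0.72)
  expect_true(w$reported[w$edge == "R2--R3"])
  # |0.1*0.6| vs |0.1*0.8| -> 0.08, below threshold
  expect_false(w$reported[w$edge == "R1--R3"])
  expect_error(composite_edge_weights(m, "N9"), "unknown network")

  # sum rule adds the two paths
  ws <- composite_edge_weights(m, "N1", combine = "sum")
  expect_equal(ws$weight[ws$edge == "R1--R2"], 0.48 + 0.25)
})

test_that("reporting keeps at most top_n edges at |weight| >= threshold", {
  set.seed(91)
  l <- function(e, v) matrix(v, length(v), 1,
                             dimnames = list(e, "F1"))
  l1 <- l(c("R1--R2", "R1--R3"), c(0.9, 0.85))
  l2 <- l(c("R1--R2", "R2--R3"), c(0.88, 0.8))
  l3 <- l(c("R1--R3", "R2--R3"), c(0.7, 0.75))
  second <- matrix(c(1, 1, 1), 3, 1,
                   dimnames = list(c("R1::F1", "R2::F1", "R3::F1"), "N1"))
  m <- fake_two_level(list(R1 = l1, R2 = l2, R3 = l3), second)
  w1 <- composite_edge_weights(m, "N1", top_n = 2)
  expect_equal(sum(w1$reported), 2)
  expect_equal(sort(w1$edge[w1$reported]), c("R1--R2", "R1--R3"))
  # a high threshold empties the reported set without error
  w2 <- composite_edge_weights(m, "N1", threshold = 0.95)
  expect_equal(sum(w2$reported), 0)
})

test_that("first level fits one model per region over its incident edges", {
  spec <- cohort_spec(n_participants = 40, seed = 101)
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  first <- first_level_factors(tab, spec$regions)
  expect_length(first$models, 20)
  expect_true(all(vapply(first$models, function(m) m$p, numeric(1)) == 19))
  k1 <- vapply(first$models, function(m) m$k, numeric(1))
  expect_equal(ncol(first$pooled_scores), 1 + sum(k1))
  expect_true(all(grepl("::F", setdiff(names(first$pooled_scores),
                                       "participant"))))
})

test_that("two-level pipeline is deterministic and recovers planted networks", {
  spec <- cohort_spec(n_participants = 150, seed = 111,
                      edge_weight_range = c(0.6, 0.9))
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  model <- two_level_model(tab, spec$regions)
  model2 <- two_level_model(tab, spec$regions)
  expect_identical(model$second$loadings, model2$second$loadings)

  recovered <- network_definitions(model) |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  planted <- co$pattern |>
    dplyr::select("network", "edge", "weight") |>
    tidyr::pivot_wider(names_from = "network", values_from = "weight")
  stopifnot(identical(recovered$edge, planted$edge))
  matched <- match_factors(as.matrix(planted[, -1]),
                           as.matrix(recovered[, -1]))
  expect_true(all(abs(matched$congruence) > 0.85))
})

test_that("network scores are standardized and participants retrievable", {
  spec <- cohort_spec(n_participants = 30, seed = 121)
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  model <- two_level_model(tab, spec$regions)
  sc <- network_scores(model)
  vals <- as.matrix(sc[, -1])
  expect_equal(unname(colMeans(vals)), rep(0, ncol(vals)),
               tolerance = 1e-10)
  expect_equal(unname(apply(vals, 2, sd)), rep(1, ncol(vals)),
               tolerance = 1e-10)
  one <- network_scores(model, "p03")
  expect_equal(one$participant, "p03")
  expect_error(network_scores(model, "p99"), "p99")
})

test_that("destroying edge structure leaves no signal-scale second factor", {
  # permuting each edge column independently across participants breaks
  # all latent structure; what survives at the second level is sampling
  # noise (plus the overlap correlation from edges shared between the
  # two endpoint views), which must stay below every planted network's
  # eigenvalue in the intact fit
  spec <- cohort_spec(n_participants = 200, seed = 131,
                      edge_weight_range = c(0.6, 0.9))
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  signal_model <- two_level_model(tab, spec$regions)
  set.seed(132)
  shuffled <- tab
  for (cc in setdiff(names(tab), "participant")) {
    shuffled[[cc]] <- sample(tab[[cc]])
  }
  null_model <- two_level_model(shuffled, spec$regions)
  p_pooled <- nrow(null_model$second$loadings)
  n <- spec$n_participants
  mp_edge <- (1 + sqrt(p_pooled / n))^2
  # loose sanity bound: the null bulk cannot wander far above the
  # independent-column Marchenko-Pastur edge
  expect_lt(null_model$second$eigenvalues[1], 1.5 * mp_edge)
  # all three planted networks stand above the strongest null factor
  expect_gt(signal_model$second$eigenvalues[3],
            null_model$second$eigenvalues[1])
})

test_that("tidy and glance expose both levels", {
  spec <- cohort_spec(n_participants = 25, seed = 141)
  co <- generate_cohort(spec, trials = FALSE)
  mats <- lapply(co$counts, build_connectome, distances = co$distances,
                 regions = spec$regions)
  tab <- assemble_edge_table(mats, spec$regions)
  model <- two_level_model(tab, spec$regions)
  t2 <- tidy(model, "second")
  expect_true(all(c("region", "region_factor", "network", "loading") %in%
                    names(t2)))
  t1 <- tidy(model, "first")
  expect_true(all(c("region", "edge", "factor", "loading") %in% names(t1)))
  te <- tidy(model, "edges")
  expect_equal(nrow(te), 190 * model$second$k)
  gl <- glance(model)
  expect_equal(gl$n_participants, 25)
  expect_equal(gl$n_regions, 20)
})
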