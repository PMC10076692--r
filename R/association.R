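#' Percent lesion volume within a network
#'
#' Aggregates per-region lesion fractions into one lesion-load covariate
#' per network. Each region's network membership is the largest
#' magnitude of the composite weights of its incident edges
#' (unthresholded, so every network has a nonzero denominator); the
#' network lesion percent is the membership- and volume-weighted mean
#' lesioned fraction, times 100.
#'
#' @param lesions Tibble `participant`, `region`, `lesion_fraction`
#'   (fractions in `[0, 1]`, one row per participant x region).
#' @param netdef Composite edge weights of one network
#'   ([composite_edge_weights()]).
#' @param regions Region tibble (for volumes).
#' @return Tibble `participant`, `network`, `lesion_percent` in
#'   `[0, 100]`.
#' @export
network_lesion_percent <- function(lesions, netdef, regions) {
  bad <- lesions$lesion_fraction < 0 | lesions$lesion_fraction > 1
  if (any(bad)) stop_input("lesion fractions must lie in [0, 1]")
  membership <- vapply(regions$region, function(r) {
    inc <- netdef$region_a == r | netdef$region_b == r
    if (!any(inc)) {
      return(0)
    }
    max(abs(netdef$weight[inc]))
  }, numeric(1))
  if (all(membership == 0)) {
    stop_input("network '%s' has all-zero edge weights",
               unique(netdef$network)[1])
  }
  missing_regions <- setdiff(regions$region, unique(lesions$region))
  if (length(missing_regions) > 0) {
    stop_input("lesion profile lacks region(s): %s",
               paste(utils::head(missing_regions, 3), collapse = ", "))
  }
  wts <- tibble::tibble(
    region = regions$region,
    m = membership,
    v = regions$volume_mm3
  )
  lesions |>
    dplyr::inner_join(wts, by = "region") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      network = unique(netdef$network)[1],
      lesion_percent = 100 * sum(.data$m * .data$v * .data$lesion_fraction) /
        sum(.data$m * .data$v),
      .groups = "drop"
    )
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing predictor `k` on the
#' remaining predictors. Perfect collinearity is reported as `Inf` with
#' a warning rather than an error; values above `warn_above` trigger a
#' multicollinearity warning.
#'
#' @param design Numeric matrix or data frame of at least two predictor
#'   columns.
#' @param warn_above Warning threshold (default 10).
#' @return Named numeric vector of VIFs (each `>= 1`).
#' @export
vif <- function(design, warn_above = 10) {
  x <- as.matrix(design)
  if (ncol(x) < 2) stop_input("vif needs at least 2 predictors")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    res <- fit$residuals
    tot <- sum((x[, j] - mean(x[, j]))^2)
    if (tot == 0) {
      return(Inf)
    }
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  if (any(!is.finite(out))) {
    rlang::warn("perfectly collinear predictor(s); VIF infinite")
  } else if (any(out > warn_above)) {
    rlang::warn(sprintf("VIF above %g suggests multicollinearity",
                        warn_above))
  }
  out
}

#' Lesion-adjusted association of one network with one measure
#'
#' Ordinary least squares of a grip performance measure on one network
#' score with the network lesion percent as covariate. All three
#' variables are standardized first, so the network slope `beta` is on
#' the correlation scale. `partial_r` is the partial correlation of
#' measure and score given lesion load, computed as the correlation of
#' the two lesion-residualized variables; `simple_r` is the plain
#' (uncontrolled) correlation. VIFs cover both predictors.
#'
#' @param measure,score,lesion Aligned numeric vectors (one value per
#'   participant).
#' @return One-row tibble: `partial_r`, `beta`, `se`, `p_value`,
#'   `simple_r`, `vif_score`, `vif_lesion`, `n`.
#' @export
fit_association <- function(measure, score, lesion) {
  n <- length(measure)
  if (length(score) != n || length(lesion) != n) {
    stop_input("measure, score and lesion must have equal length")
  }
  if (n < 4) stop_input("need at least 4 participants")
  if (anyNA(measure) || anyNA(score) || anyNA(lesion)) {
    stop_input("missing values in association inputs")
  }
  for (nm in c("measure", "score", "lesion")) {
    if (stats::sd(get(nm)) == 0) {
      stop_input("constant %s vector", nm)
    }
  }
  zy <- as.numeric(scale(measure))
  zs <- as.numeric(scale(score))
  zl <- as.numeric(scale(lesion))
  fit <- stats::lm(zy ~ zs + zl)
  sm <- summary(fit)$coefficients
  ry <- stats::residuals(stats::lm(zy ~ zl))
  rs <- stats::residuals(stats::lm(zs ~ zl))
  tibble::tibble(
    partial_r = stats::cor(ry, rs),
    beta = unname(coef(fit)["zs"]),
    se = sm["zs", "Std. Error"],
    p_value = sm["zs", "Pr(>|t|)"],
    simple_r = stats::cor(zy, zs),
    vif_score = suppressWarnings(vif(cbind(score = zs, lesion = zl)))[[1]],
    vif_lesion = suppressWarnings(vif(cbind(score = zs, lesion = zl)))[[2]],
    n = n
  )
}

#' Networks x measures association grid
#'
#' Fits [fit_association()] for every (network, measure) cell, flags the
#' best network per measure by the largest `|partial_r|` (ties broken by
#' lowest network index with a warning), and repeats the call on the
#' uncontrolled grid (`|simple_r|`) to record whether the best-network
#' calls agree with and without the lesion covariate.
#'
#' @param scores Tibble `participant` + one column per network
#'   ([network_scores()]).
#' @param measures Tibble `participant` + one column per performance
#'   measure.
#' @param lesion_percents Tibble `participant`, `network`,
#'   `lesion_percent` covering every network in `scores`.
#' @return Object of class `association_table`: list with `grid` (one
#'   row per cell incl. `best` flag), `best` (per-measure winners,
#'   adjusted and unadjusted), and `consistent` (logical).
#' @export
association_table <- function(scores, measures, lesion_percents) {
  networks <- setdiff(names(scores), "participant")
  measure_names <- setdiff(names(measures), "participant")
  joined <- dplyr::inner_join(scores, measures, by = "participant")
  if (nrow(joined) != nrow(scores) || nrow(joined) != nrow(measures)) {
    stop_input("participants in scores and measures do not align")
  }
  grid <- purrr::map_dfr(networks, function(g) {
    lp <- lesion_percents[lesion_percents$network == g, ]
    sub <- dplyr::inner_join(joined, lp, by = "participant")
    if (nrow(sub) != nrow(joined)) {
      stop_input("lesion percents missing for network %s", g)
    }
    purrr::map_dfr(measure_names, function(m) {
      dplyr::bind_cols(
        tibble::tibble(network = g, measure = m),
        fit_association(sub[[m]], sub[[g]], sub$lesion_percent)
      )
    })
  })
  pick_best <- function(stat) {
    grid |>
      dplyr::group_by(.data$measure) |>
      dplyr::group_map(function(df, key) {
        a <- abs(df[[stat]])
        winners <- which(a == max(a))
        if (length(winners) > 1) {
          rlang::warn(sprintf(
            "tie for best network on %s; keeping lowest index",
            key$measure
          ))
        }
        tibble::tibble(measure = key$measure,
                       network = df$network[winners[1]])
      }) |>
      dplyr::bind_rows()
  }
  best_adj <- pick_best("partial_r")
  best_unadj <- pick_best("simple_r")
  best <- dplyr::full_join(best_adj, best_unadj, by = "measure",
                           suffix = c("_adjusted", "_unadjusted"))
  grid$best <- paste(grid$network, grid$measure) %in%
    paste(best_adj$network, best_adj$measure)
  consistent <- all(best$network_adjusted == best$network_unadjusted)
  if (!consistent) {
    rlang::inform("best-network calls differ with vs. without lesion adjustment")
  }
  structure(
    list(grid = grid, best = best, consistent = consistent),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf(
    "<association_table> %d networks x %d measures\n",
    dplyr::n_distinct(x$grid$network), dplyr::n_distinct(x$grid$measure)
  ))
  cat(sprintf("  best calls consistent with/without lesion adjustment: %s\n",
              x$consistent))
  print(x$best)
  invisible(x)
}

#' @describeIn association_table Long tibble of the grid (one row per
#'   cell).
#' @param x An `association_table`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.association_table <- function(x, ...) {
  x$grid
}

#' @describeIn association_table One-row summary.
#' @export
#' @exportS3Method generics::glance
glance.association_table <- function(x, ...) {
  tibble::tibble(
    n_networks = dplyr::n_distinct(x$grid$network),
    n_measures = dplyr::n_distinct(x$grid$measure),
    n = x$grid$n[1],
    max_abs_partial_r = max(abs(x$grid$partial_r)),
    consistent = x$consistent
  )
}

#' @describeIn association_table Heatmap of lesion-adjusted partial
#'   correlations with best-network cells outlined.
#' @param object An `association_table`.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.association_table <- function(object, ...) {
  df <- object$grid
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$network,
                                   fill = .data$partial_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$best, ], fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r")
}
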