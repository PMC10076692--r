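#' First-level (region-wise) factor models
#'
#' Separately for each region, fits a factor model to the weights of the
#' edges incident to that region across participants. Pooling the
#' resulting factor scores over all regions yields the input for the
#' second level. Pooled column labels carry the region and factor index
#' as `region::F<j>`.
#'
#' @param edge_table Cohort edge table from [assemble_edge_table()].
#' @param regions Region tibble.
#' @param ... Passed to [fit_factor_model()] (extraction, retention,
#'   rotation, k).
#' @return List with `models` (named list of `factor_model`, one per
#'   region) and `pooled_scores` (tibble: `participant` plus one column
#'   per retained first-level factor).
#' @export
first_level_factors <- function(edge_table, regions, ...) {
  if (nrow(edge_table) < 3) {
    stop_input("first-level factoring needs at least 3 participants")
  }
  models <- purrr::map(
    stats::setNames(regions$region, regions$region),
    function(r) {
      view <- region_edge_view(edge_table, r, regions)
      withCallingHandlers(
        fit_factor_model(dplyr::select(view, -"participant"), ...),
        error = function(e) {
          stop_input("region %s: %s", r, conditionMessage(e))
        }
      )
    }
  )
  pooled <- purrr::imap(models, function(m, r) {
    s <- m$scores
    colnames(s) <- paste(r, colnames(s), sep = "::")
    tibble::as_tibble(s)
  })
  pooled_scores <- dplyr::bind_cols(
    tibble::tibble(participant = edge_table$participant),
    pooled
  )
  list(models = models, pooled_scores = pooled_scores)
}

#' Second-level factor model over pooled region factors
#'
#' Fits one factor model to the pooled first-level factor scores; the
#' retained factors are the latent networks, ordered by descending
#' explained variance.
#'
#' @param first Output of [first_level_factors()].
#' @param ... Passed to [fit_factor_model()].
#' @return A `factor_model` whose variables are the pooled first-level
#'   factors and whose factors are networks.
#' @export
second_level_factors <- function(first, ...) {
  pooled <- dplyr::select(first$pooled_scores, -"participant")
  if (ncol(pooled) < 2) {
    stop_input("second level needs at least 2 pooled first-level factors")
  }
  fit_factor_model(pooled, ...)
}

#' Two-level network factorization
#'
#' Runs both levels on a cohort edge table and returns one fitted
#' object. Network ids are `N1 ... NK` in order of explained variance.
#'
#' @inheritParams first_level_factors
#' @param first_args,second_args Named lists of arguments forwarded to
#'   [fit_factor_model()] at each level (e.g.
#'   `list(retention = "fixed_k", k = 1)`).
#' @return Object of class `two_level_model`: `first`, `second`,
#'   `regions`, `edge_info`, `participants`, `networks`.
#' @export
two_level_model <- function(edge_table, regions,
                            first_args = list(), second_args = list()) {
  first <- do.call(first_level_factors,
                   c(list(edge_table = edge_table, regions = regions),
                     first_args))
  second <- do.call(second_level_factors,
                    c(list(first = first), second_args))
  networks <- paste0("N", seq_len(second$k))
  structure(
    list(
      first = first,
      second = second,
      regions = regions,
      edge_info = edge_index(regions),
      participants = edge_table$participant,
      networks = networks
    ),
    class = "two_level_model"
  )
}

#' @export
print.two_level_model <- function(x, ...) {
  k1 <- vapply(x$first$models, function(m) m$k, numeric(1))
  cat(sprintf(
    "<two_level_model> %d networks from %d pooled region factors\n",
    x$second$k, sum(k1)
  ))
  cat(sprintf("  %d regions, %d participants, first-level k: %d-%d\n",
              nrow(x$regions), length(x$participants),
              min(k1), max(k1)))
  invisible(x)
}

#' Per-participant network scores
#'
#' Standardized second-level factor scores: one column per network.
#'
#' @param model A [two_level_model()].
#' @param participant Optional participant id(s) to subset to.
#' @return Tibble `participant` x networks.
#' @export
network_scores <- function(model, participant = NULL) {
  s <- model$second$scores
  colnames(s) <- model$networks
  out <- dplyr::bind_cols(
    tibble::tibble(participant = model$participants),
    tibble::as_tibble(s)
  )
  if (!is.null(participant)) {
    missing_ids <- setdiff(participant, out$participant)
    if (length(missing_ids) > 0) {
      stop_input("participant(s) not in cohort: %s",
                 paste(missing_ids, collapse = ", "))
    }
    out <- out[match(participant, out$participant), ]
  }
  out
}

#' Composite edge weights of a network
#'
#' Projects a second-level network back onto the original edges. Every
#' edge appears in the incident-edge views of its two endpoint regions
#' and may load on several first-level factors; each (region, factor)
#' pair gives a candidate contribution
#' `loading(edge -> factor) * loading(factor -> network)`. The
#' composite weight keeps the candidate of largest magnitude (sign
#' preserved; `combine = "sum"` adds all candidates instead). Edges
#' reported for a network are those with `|weight| >= threshold`,
#' capped at the `top_n` largest by magnitude (ties broken by edge label
#' order).
#'
#' @param model A [two_level_model()].
#' @param network Network id (e.g. `"N1"`).
#' @param threshold Reporting threshold on `|weight|` (default 0.4).
#' @param top_n Maximum number of reported edges (default 6).
#' @param combine `"max"` (dominant path) or `"sum"` (all paths).
#' @return Tibble with one row per edge: `network`, `edge`, `region_a`,
#'   `region_b`, `weight`, `reported`.
#' @export
composite_edge_weights <- function(model, network, threshold = 0.4,
                                   top_n = 6, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (!network %in% model$networks) {
    stop_input("unknown network '%s'", network)
  }
  ei <- model$edge_info
  second_load <- model$second$loadings[, network == model$networks]
  w <- stats::setNames(numeric(nrow(ei)), ei$edge)
  for (r in model$regions$region) {
    fm <- model$first$models[[r]]
    for (j in seq_len(fm$k)) {
      pooled_name <- paste0(r, "::F", j)
      if (!pooled_name %in% names(second_load)) next
      b <- second_load[[pooled_name]]
      if (is.na(b)) next
      cand <- fm$loadings[, j] * b
      edges <- rownames(fm$loadings)
      if (combine == "max") {
        take <- abs(cand) > abs(w[edges])
        w[edges[take]] <- cand[take]
      } else {
        w[edges] <- w[edges] + cand
      }
    }
  }
  out <- tibble::tibble(
    network = network,
    edge = ei$edge,
    region_a = ei$region_a,
    region_b = ei$region_b,
    weight = unname(w[ei$edge])
  )
  ord <- order(-abs(out$weight), out$edge)
  eligible <- which(abs(out$weight) >= threshold)
  keep <- utils::head(ord[ord %in% eligible], top_n)
  out$reported <- seq_len(nrow(out)) %in% keep
  out
}

#' Composite weights for every network
#'
#' @inheritParams composite_edge_weights
#' @return Row-bound tibble of [composite_edge_weights()] over all
#'   networks.
#' @export
network_definitions <- function(model, threshold = 0.4, top_n = 6,
                                combine = c("max", "sum")) {
  combine <- match.arg(combine)
  purrr::map_dfr(model$networks, composite_edge_weights, model = model,
                 threshold = threshold, top_n = top_n, combine = combine)
}

#' Tidy a two-level model
#'
#' @param x A `two_level_model`.
#' @param level `"second"` (pooled-factor loadings on networks),
#'   `"first"` (edge loadings on region factors) or `"edges"` (composite
#'   edge weights per network).
#' @param ... Passed to [network_definitions()] when `level = "edges"`.
#' @return A long tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.two_level_model <- function(x, level = c("second", "first", "edges"),
                                 ...) {
  level <- match.arg(level)
  if (level == "second") {
    out <- tidy(x$second)
    names(out)[names(out) == "factor"] <- "network"
    tidyr::separate_wider_delim(out, "variable", delim = "::",
                                names = c("region", "region_factor"))
  } else if (level == "first") {
    purrr::imap_dfr(x$first$models, function(m, r) {
      out <- tidy(m)
      names(out)[names(out) == "variable"] <- "edge"
      dplyr::bind_cols(tibble::tibble(region = r), out)
    })
  } else {
    network_definitions(x, ...)
  }
}

#' One-row summary of a two-level model
#'
#' @param x A `two_level_model`.
#' @param ... Unused.
#' @return Tibble with participant/region counts, pooled factor count,
#'   number of networks and second-level variance explained.
#' @export
#' @exportS3Method generics::glance
glance.two_level_model <- function(x, ...) {
  k1 <- vapply(x$first$models, function(m) m$k, numeric(1))
  tibble::tibble(
    n_participants = length(x$participants),
    n_regions = nrow(x$regions),
    n_pooled_factors = sum(k1),
    n_networks = x$second$k,
    prop_variance_second = sum(colSums(x$second$loadings^2)) / x$second$p
  )
}

#' @describeIn composite_edge_weights Bar chart of a network's largest
#'   composite edge weights.
#' @param netdef Tibble from [composite_edge_weights()].
#' @param n_edges Number of edges to display.
#' @export
plot_network_edges <- function(netdef, n_edges = 15) {
  df <- dplyr::slice_max(netdef, abs(.data$weight), n = n_edges)
  df$edge <- stats::reorder(df$edge, abs(df$weight))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$edge,
                                   fill = .data$reported)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "composite edge weight", y = NULL,
                  title = unique(df$network))
}
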