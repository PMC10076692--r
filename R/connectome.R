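#' Symmetrize directed streamline counts
#'
#' Probabilistic tractography yields directed counts `n(i -> j)` that
#' depend on the seeding direction; the undirected connection strength
#' is taken as the average of the two directions. The diagonal is set to
#' zero (self-connections are not meaningful here).
#'
#' @param raw Square numeric matrix of nonnegative directed counts with
#'   matching row/column region names.
#' @return Symmetric matrix `(raw + t(raw)) / 2` with zero diagonal.
#' @export
symmetrize_counts <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop_input("count matrix must be square")
  if (any(!is.finite(raw))) stop_input("count matrix has non-finite entries")
  if (any(raw < 0)) {
    bad <- which(raw < 0, arr.ind = TRUE)[1, ]
    stop_input("negative streamline count at (%d, %d)", bad[1], bad[2])
  }
  s <- (raw + t(raw)) / 2
  diag(s) <- 0
  s
}

#' Distance- and volume-correct symmetric streamline counts
#'
#' Streamline counts fall off with inter-region distance (probabilistic
#' tracking attenuates with path length) and scale with the seeded gray
#' matter volume. The corrected weight is
#' `w(i, j) = s(i, j) * d(i, j)^alpha / (v_i + v_j)^beta`
#' with defaults `alpha = beta = 1`; `alpha = beta = 0` disables the
#' correction. The formula is isolated here so alternatives are a
#' one-line swap.
#'
#' @param s Symmetric count matrix (from [symmetrize_counts()]).
#' @param distances Symmetric positive matrix of inter-region distances
#'   (mm), same region order as `s`.
#' @param regions Region tibble with `region` and `volume_mm3`.
#' @param alpha,beta Exponents of the distance and summed-volume terms.
#' @return Symmetric corrected connectivity matrix, zero diagonal,
#'   region names attached as dimnames.
#' @export
correct_connectivity <- function(s, distances, regions,
                                 alpha = 1, beta = 1) {
  s <- as.matrix(s)
  distances <- as.matrix(distances)
  r <- nrow(s)
  if (!all(dim(distances) == c(r, r)) || nrow(regions) != r) {
    stop_input("counts, distances and regions disagree in size")
  }
  v <- regions$volume_mm3
  if (any(v <= 0)) stop_input("region volumes must be positive")
  off <- row(distances) != col(distances)
  if (any(distances[off] <= 0)) {
    stop_input("off-diagonal distances must be positive")
  }
  if (max(abs(distances - t(distances))) > 1e-8) {
    stop_input("distance matrix must be symmetric")
  }
  vsum <- outer(v, v, `+`)
  d <- distances
  diag(d) <- 1 # diagonal never used; avoids 0^alpha artifacts
  w <- s * d^alpha / vsum^beta
  diag(w) <- 0
  dimnames(w) <- list(regions$region, regions$region)
  w
}

#' Build a corrected connectivity matrix from raw counts
#'
#' One-call wrapper: [symmetrize_counts()] then
#' [correct_connectivity()].
#'
#' @inheritParams correct_connectivity
#' @param raw Directed streamline-count matrix.
#' @export
build_connectome <- function(raw, distances, regions,
                             alpha = 1, beta = 1) {
  correct_connectivity(symmetrize_counts(raw), distances, regions,
                       alpha = alpha, beta = beta)
}

#' Canonical undirected edge labels
#'
#' Edges are ordered lexicographically by region index (`i < j` in the
#' order of the region table), fixed so factor loadings are comparable
#' across runs; labels join the two region names with `"--"`.
#'
#' @param regions Region tibble.
#' @return Tibble with `edge`, `region_a`, `region_b`, `idx_a`, `idx_b`.
#' @export
edge_index <- function(regions) {
  r <- nrow(regions)
  pairs <- utils::combn(r, 2)
  tibble::tibble(
    idx_a = pairs[1, ], idx_b = pairs[2, ],
    region_a = regions$region[pairs[1, ]],
    region_b = regions$region[pairs[2, ]],
    edge = paste(regions$region[pairs[1, ]],
                 regions$region[pairs[2, ]], sep = "--")
  )
}

#' Assemble per-participant matrices into a cohort edge table
#'
#' Flattens each participant's corrected connectivity matrix into one
#' row over the canonical undirected edges (190 for 20 regions).
#'
#' @param matrices Named list of corrected connectivity matrices, one
#'   per participant, all over the same region set.
#' @param regions Region tibble giving the canonical region order.
#' @return Tibble: `participant` column plus one numeric column per
#'   edge.
#' @export
assemble_edge_table <- function(matrices, regions) {
  ei <- edge_index(regions)
  ids <- names(matrices) %||% as.character(seq_along(matrices))
  rows <- purrr::imap(matrices, function(m, id) {
    m <- as.matrix(m)
    if (!all(dim(m) == nrow(regions))) {
      stop_input("participant %s: matrix size differs from region set", id)
    }
    if (!is.null(rownames(m)) &&
        !identical(rownames(m), regions$region)) {
      stop_input("participant %s: region names differ from the region set",
                 id)
    }
    vals <- m[cbind(ei$idx_a, ei$idx_b)]
    tibble::as_tibble(as.list(stats::setNames(vals, ei$edge)))
  })
  dplyr::bind_cols(tibble::tibble(participant = ids),
                   dplyr::bind_rows(rows))
}

#' Rebuild matrices from an edge table
#'
#' Exact inverse of [assemble_edge_table()].
#'
#' @param edge_table Tibble from [assemble_edge_table()].
#' @param regions Region tibble.
#' @return Named list of symmetric matrices.
#' @export
edge_table_to_matrices <- function(edge_table, regions) {
  ei <- edge_index(regions)
  missing_cols <- setdiff(ei$edge, names(edge_table))
  if (length(missing_cols) > 0) {
    stop_input("edge table lacks %d edge column(s), e.g. %s",
               length(missing_cols), missing_cols[1])
  }
  r <- nrow(regions)
  out <- lapply(seq_len(nrow(edge_table)), function(i) {
    m <- matrix(0, r, r, dimnames = list(regions$region, regions$region))
    vals <- as.numeric(edge_table[i, ei$edge])
    m[cbind(ei$idx_a, ei$idx_b)] <- vals
    m[cbind(ei$idx_b, ei$idx_a)] <- vals
    m
  })
  stats::setNames(out, edge_table$participant)
}

#' Edges incident to one region
#'
#' The per-region view the first-level factor analysis operates on: the
#' `R - 1` edge columns touching `region`, ordered by partner region
#' index.
#'
#' @param edge_table Cohort edge table.
#' @param region Region name.
#' @param regions Region tibble.
#' @return Tibble with `participant` plus the incident edge columns.
#' @export
region_edge_view <- function(edge_table, region, regions) {
  if (!region %in% regions$region) {
    stop_input("unknown region '%s'", region)
  }
  ei <- edge_index(regions)
  inc <- ei[ei$region_a == region | ei$region_b == region, ]
  partner_idx <- ifelse(inc$region_a == region, inc$idx_b, inc$idx_a)
  inc <- inc[order(partner_idx), ]
  dplyr::select(edge_table, "participant", dplyr::all_of(inc$edge))
}
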