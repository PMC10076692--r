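#' Column standardization for correlation-based factoring
#'
#' Centers and scales every numeric column to mean 0, sample SD 1.
#' Zero-variance columns cannot enter a correlation matrix; they are
#' dropped with a warning and recorded so downstream loading tables can
#' map back to the full variable set.
#'
#' @param x Data frame or matrix of numeric columns (rows =
#'   observations).
#' @return Numeric matrix of standardized retained columns with a
#'   `dropped` attribute naming removed columns.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_input("standardize_columns needs numeric data")
  if (nrow(x) < 2) stop_input("need at least 2 rows to standardize")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping %d zero-variance column(s): %s",
                        length(dropped),
                        paste(utils::head(dropped, 5), collapse = ", ")))
  }
  keep <- sds > 0
  z <- scale(x[, keep, drop = FALSE])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "dropped") <- dropped
  z
}

# principal-axis extraction: iterate communalities on the reduced
# correlation matrix (squared multiple correlations as start values)
principal_axis_loadings <- function(r_mat, k, max_iter = 100, tol = 1e-6) {
  p <- ncol(r_mat)
  rinv <- MASS::ginv(r_mat)
  h2 <- 1 - 1 / pmax(diag(rinv), 1)
  for (it in seq_len(max_iter)) {
    rr <- r_mat
    diag(rr) <- h2
    e <- eigen(rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    load <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev), k)
    h2_new <- rowSums(load^2)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  load
}

#' Fit an exploratory factor model
#'
#' The workhorse behind both levels of the network factorization.
#' Principal-component extraction (the default) takes the
#' eigendecomposition of the sample correlation matrix and scales the
#' retained eigenvectors by the square root of their eigenvalues;
#' principal-axis extraction iterates communalities on the reduced
#' correlation matrix. Retention is by the Kaiser criterion (eigenvalue
#' of the correlation matrix > 1) or a fixed factor count. Varimax
#' rotation (orthogonal) is applied when more than one factor is
#' retained. Factor scores use the regression method,
#' `S = Z R^+ Lambda`, with the Moore-Penrose pseudoinverse so singular
#' correlation matrices (fewer observations than variables) are handled;
#' score columns are re-standardized to unit sample SD.
#'
#' Two conventions are fixed for reproducibility: factors are ordered by
#' descending explained variance, and within each factor the loading of
#' largest magnitude is made positive (scores flipped accordingly).
#'
#' @param x Observations x variables data (data frame or matrix); it is
#'   standardized internally, zero-variance columns dropped with a
#'   warning.
#' @param extraction `"principal_component"` or `"principal_axis"`.
#' @param retention `"kaiser"` or `"fixed_k"`.
#' @param k Number of factors when `retention = "fixed_k"`.
#' @param rotation `"varimax"` or `"none"`.
#' @return An object of class `factor_model`: list with `loadings`
#'   (variables x factors), `scores` (observations x factors,
#'   standardized), `score_weights` (`R^+ Lambda`), `eigenvalues` (all
#'   eigenvalues of the correlation matrix), `communalities`, `dropped`
#'   (zero-variance variables), `k`, `n`, and the configuration used.
#' @export
fit_factor_model <- function(x,
                             extraction = c("principal_component",
                                            "principal_axis"),
                             retention = c("kaiser", "fixed_k"),
                             k = NULL,
                             rotation = c("varimax", "none")) {
  extraction <- match.arg(extraction)
  retention <- match.arg(retention)
  rotation <- match.arg(rotation)
  z <- standardize_columns(x)
  if (anyNA(z)) stop_input("factor analysis input contains missing values")
  p <- ncol(z)
  if (p < 2) stop_input("need at least 2 non-constant variables")
  n <- nrow(z)
  r_mat <- stats::cor(z)
  e <- eigen(r_mat, symmetric = TRUE)
  ev <- e$values
  k_used <- if (retention == "kaiser") {
    sum(ev > 1)
  } else {
    if (is.null(k) || k < 1) stop_input("fixed_k retention requires k >= 1")
    as.integer(k)
  }
  if (k_used < 1) {
    stop_input(paste0("no eigenvalue exceeds 1; Kaiser retention keeps ",
                      "nothing - consider retention = 'fixed_k'"))
  }
  if (k_used > p) stop_input("cannot retain more factors than variables")
  load <- if (extraction == "principal_component") {
    e$vectors[, seq_len(k_used), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k_used)]), k_used)
  } else {
    principal_axis_loadings(r_mat, k_used)
  }
  if (rotation == "varimax" && k_used > 1) {
    rot <- stats::varimax(load)
    load <- load %*% rot$rotmat
  }
  # order by explained variance, then fix signs
  ord <- order(colSums(load^2), decreasing = TRUE)
  load <- load[, ord, drop = FALSE]
  flip <- vapply(seq_len(k_used), function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  rownames(load) <- colnames(z)
  colnames(load) <- paste0("F", seq_len(k_used))
  weights <- MASS::ginv(r_mat) %*% load
  scores_raw <- z %*% weights
  score_sd <- apply(scores_raw, 2, function(s) floored_sd(s, 1e-12))
  scores <- sweep(scores_raw, 2, score_sd, `/`)
  colnames(scores) <- colnames(load)
  dimnames(weights) <- dimnames(load)
  structure(
    list(
      loadings = load,
      scores = scores,
      score_weights = weights,
      eigenvalues = ev,
      communalities = rowSums(load^2),
      dropped = attr(z, "dropped"),
      k = k_used,
      n = n,
      p = p,
      extraction = extraction,
      retention = retention,
      rotation = rotation
    ),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> %d factor(s) over %d variable(s), n = %d\n",
    x$k, x$p, x$n
  ))
  cat(sprintf("  extraction: %s | retention: %s | rotation: %s\n",
              x$extraction, x$retention, x$rotation))
  cat(sprintf("  variance explained: %.1f%%\n",
              100 * sum(colSums(x$loadings^2)) / x$p))
  invisible(x)
}

#' Tidy a factor model into a long loading table
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with `variable`, `factor`, `loading`, `communality`.
#' @export
#' @exportS3Method generics::tidy
tidy.factor_model <- function(x, ...) {
  long <- tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "factor",
                        values_to = "loading")
  long$communality <- x$communalities[long$variable]
  long
}

#' One-row summary of a factor model
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble: `n`, `p`, `k`, `prop_variance`, `n_dropped`.
#' @export
#' @exportS3Method generics::glance
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, k = x$k,
    prop_variance = sum(colSums(x$loadings^2)) / x$p,
    n_dropped = length(x$dropped)
  )
}

#' @describeIn fit_factor_model Scree plot (eigenvalues of the
#'   correlation matrix with the Kaiser line).
#' @param object A `factor_model`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.factor_model <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "eigenvalue")
}
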