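# internal helpers shared across modules

# sample SD floored at `floor`; used wherever a zero-variance baseline or
# score column would otherwise produce a degenerate threshold or division
floored_sd <- function(x, floor = 0) {
  max(stats::sd(x), floor)
}

#' Tucker congruence coefficient
#'
#' Cosine-type similarity between two loading (or composite edge-weight)
#' vectors; scale invariant and sign sensitive. Values of 0.9 and above
#' conventionally indicate factor equivalence.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar in `[-1, 1]` (`NA` if either vector is all zero).
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(length(a) == length(b))
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) {
    return(NA_real_)
  }
  sum(a * b) / den
}

#' Match factors between two loading matrices
#'
#' Greedy one-to-one assignment of candidate factors (columns of
#' `cand`) to reference factors (columns of `ref`) by maximal absolute
#' [tucker_congruence()]: used to align recovered networks with planted
#' (or previously published) ones before comparing them.
#'
#' @param ref,cand Matrices with one column per factor over the same
#'   variables.
#' @return Tibble with `reference`, `matched` (candidate column index)
#'   and the signed `congruence` of each pair.
#' @export
match_factors <- function(ref, cand) {
  ref <- as.matrix(ref)
  cand <- as.matrix(cand)
  kr <- ncol(ref)
  cc <- matrix(NA_real_, kr, ncol(cand))
  for (i in seq_len(kr)) {
    for (j in seq_len(ncol(cand))) {
      cc[i, j] <- tucker_congruence(ref[, i], cand[, j])
    }
  }
  used <- integer(0)
  out <- tibble::tibble(
    reference = seq_len(kr), matched = NA_integer_, congruence = NA_real_
  )
  for (step in seq_len(min(kr, ncol(cand)))) {
    abs_cc <- abs(cc)
    abs_cc[, used] <- -Inf
    abs_cc[out$reference[!is.na(out$matched)], ] <- -Inf
    pick <- arrayInd(which.max(abs_cc), dim(abs_cc))
    out$matched[pick[1]] <- pick[2]
    out$congruence[pick[1]] <- cc[pick[1], pick[2]]
    used <- c(used, pick[2])
  }
  out
}

# derive a reproducible child seed from a top-level seed; offsets are fixed
# per component so parts of a cohort can be regenerated independently
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "connectogrip_input_error")
}
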