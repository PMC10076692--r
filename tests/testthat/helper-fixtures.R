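# fixtures built in code; no data files

# constant-force trial: both digits at fn (optionally distinct), shear 0
flat_trial <- function(fn_thumb = 4, fn_index = fn_thumb,
                       duration = 6, rate = 500,
                       cue_grip = 2, cue_rest = 4,
                       trial_kind = "target_grip", hand = "paretic") {
  t <- seq(0, duration, by = 1 / rate)
  forces <- dplyr::bind_rows(
    tibble::tibble(time_s = t, digit = "thumb", fn_N = fn_thumb,
                   ft1_N = 0, ft2_N = 0),
    tibble::tibble(time_s = t, digit = "index", fn_N = fn_index,
                   ft1_N = 0, ft2_N = 0)
  )
  grip_trial(forces, sampling_rate = rate, cue_grip = cue_grip,
             cue_rest = cue_rest, trial_kind = trial_kind, hand = hand)
}

# trial with per-sample force function f(t) applied to both digits'
# normal components and a fixed shear-to-normal ratio
shaped_trial <- function(f, shear_ratio = 0, duration = 6, rate = 500,
                         cue_grip = 2, cue_rest = 4,
                         trial_kind = "target_grip", hand = "paretic") {
  t <- seq(0, duration, by = 1 / rate)
  fn <- f(t)
  forces <- dplyr::bind_rows(
    tibble::tibble(time_s = t, digit = "thumb", fn_N = fn,
                   ft1_N = fn * shear_ratio, ft2_N = 0),
    tibble::tibble(time_s = t, digit = "index", fn_N = fn,
                   ft1_N = 0, ft2_N = fn * shear_ratio)
  )
  grip_trial(forces, sampling_rate = rate, cue_grip = cue_grip,
             cue_rest = cue_rest, trial_kind = trial_kind, hand = hand)
}

# naive linear-scan oracle for sustained threshold crossings
scan_crossing <- function(force, time_s, cue, thr, above, sustain_n,
                          max_latency_s) {
  idx <- which(time_s >= cue)
  for (i in idx) {
    if (time_s[i] - cue > max_latency_s) {
      return(NA_real_)
    }
    seg <- i:min(i + sustain_n - 1, length(force))
    if (length(seg) < sustain_n) {
      return(NA_real_)
    }
    cond <- if (above) all(force[seg] > thr) else all(force[seg] <= thr)
    if (cond) {
      return(time_s[i] - cue)
    }
  }
  NA_real_
}

# tiny region set for connectome unit tests
toy_regions <- function(r = 4) {
  tibble::tibble(
    region = paste0("R", seq_len(r)),
    structure = paste0("s", seq_len(r)),
    hemisphere = "ipsilesional",
    class = "cortical",
    volume_mm3 = seq(1000, by = 500, length.out = r)
  )
}

toy_distances <- function(regions) {
  r <- nrow(regions)
  d <- abs(outer(seq_len(r), seq_len(r), `-`)) * 10 + 5
  diag(d) <- 0
  dimnames(d) <- list(regions$region, regions$region)
  d
}

# random symmetric toy connectivity matrix
toy_matrix <- function(regions, seed) {
  set.seed(seed)
  r <- nrow(regions)
  m <- matrix(runif(r * r, 0, 50), r, r)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(regions$region, regions$region)
  m
}

# data with exact single-factor structure x_j = lambda_j * s + sd_j * e_j
one_factor_data <- function(n, lambdas, seed, noise_sd = NULL) {
  set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - lambdas^2)
  s <- rnorm(n)
  x <- sapply(seq_along(lambdas), function(j) {
    lambdas[j] * s + noise_sd[j] * rnorm(n)
  })
  colnames(x) <- paste0("x", seq_along(lambdas))
  list(x = x, s = s)
}
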