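# Readers and writers for every file dialect the pipeline consumes or
# produces. All files are UTF-8, '.' decimal, header row; readers
# validate the schema and name the offending file/column in errors.

read_checked <- function(path, reader, required, what) {
  if (!file.exists(path)) stop_input("%s: file not found (%s)", what, path)
  df <- reader(path)
  if (nrow(df) == 0) stop_input("%s: %s is empty", what, path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_input("%s: %s lacks column(s) %s", what, path,
               paste(missing_cols, collapse = ", "))
  }
  df
}

csv_in <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
tsv_in <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
# base-R parsers for files whose numbers must round-trip to the exact
# double (strtod is correctly rounded; the fast readr parser can be one
# ulp off)
csv_in_exact <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
tsv_in_exact <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Read / write a single-trial force CSV
#'
#' Long-form per-sample file: `time_s, digit, fn_N, ft1_N, ft2_N`.
#'
#' @param path File path.
#' @return Tibble of force samples.
#' @export
read_trial_csv <- function(path) {
  df <- read_checked(path, csv_in,
                     c("time_s", "digit", "fn_N", "ft1_N", "ft2_N"),
                     "trial CSV")
  num <- c("time_s", "fn_N", "ft1_N", "ft2_N")
  for (cc in num) {
    if (!is.numeric(df[[cc]])) {
      stop_input("trial CSV: %s column '%s' is not numeric", path, cc)
    }
  }
  df
}

#' @rdname read_trial_csv
#' @param trial A [grip_trial()] or plain force tibble.
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(tibble::as_tibble(trial), path, progress = FALSE)
  invisible(path)
}

#' Read / write a square region-by-region TSV
#'
#' Dialect shared by streamline-count and distance matrices: a `region`
#' name column followed by one numeric column per region.
#'
#' @param path File path.
#' @param regions Optional region tibble to check names/order against.
#' @param nonnegative Require all entries `>= 0` (counts).
#' @return Numeric matrix with region dimnames.
#' @export
read_matrix_tsv <- function(path, regions = NULL, nonnegative = FALSE) {
  df <- read_checked(path, tsv_in_exact, "region", "matrix TSV")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$region
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop_input("matrix TSV: %s is not square with matching names", path)
  }
  if (!is.numeric(m) || anyNA(m)) {
    stop_input("matrix TSV: %s has non-numeric or missing cells", path)
  }
  if (nonnegative && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_input("matrix TSV: %s has a negative entry at row '%s', column '%s'",
               path, rownames(m)[bad[1]], colnames(m)[bad[2]])
  }
  if (!is.null(regions) && !identical(rownames(m), regions$region)) {
    stop_input("matrix TSV: %s region set differs from the region table",
               path)
  }
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix to write.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- dplyr::bind_cols(tibble::tibble(region = rownames(m)),
                         tibble::as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a region metadata CSV
#'
#' Columns `region, structure, hemisphere, class, volume_mm3`, or the
#' anatomical variant with `left_right` instead of `hemisphere` (then
#' `lesion_side` must be given to relabel).
#'
#' @param path File path.
#' @param lesion_side `"left"`/`"right"` when the file uses anatomical
#'   labels.
#' @return Region tibble.
#' @export
read_regions_csv <- function(path, lesion_side = NULL) {
  df <- read_checked(path, csv_in, c("region", "volume_mm3"),
                     "regions CSV")
  if (!is.numeric(df$volume_mm3) || any(df$volume_mm3 <= 0)) {
    stop_input("regions CSV: %s has non-positive volumes", path)
  }
  if (!"hemisphere" %in% names(df)) {
    if (is.null(lesion_side)) {
      stop_input("regions CSV: %s uses left/right labels; pass lesion_side",
                 path)
    }
    df <- relabel_hemispheres(df, lesion_side)
  }
  df
}

#' Read a lesion-profile CSV
#'
#' Columns `participant, region, lesion_fraction` with fractions in
#' `[0, 1]`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_lesions_csv <- function(path) {
  df <- read_checked(path, csv_in,
                     c("participant", "region", "lesion_fraction"),
                     "lesions CSV")
  bad <- which(df$lesion_fraction < 0 | df$lesion_fraction > 1 |
                 is.na(df$lesion_fraction))
  if (length(bad) > 0) {
    stop_input("lesions CSV: %s row %d has lesion_fraction outside [0, 1]",
               path, bad[1])
  }
  df
}

#' Read / write a generic participant-keyed table CSV
#'
#' Used for the edge table, network scores and performance-ratio
#' tables: a `participant` column plus numeric value columns.
#'
#' @param path File path.
#' @param what Label used in error messages.
#' @return Tibble.
#' @export
read_participant_csv <- function(path, what = "table CSV") {
  df <- read_checked(path, csv_in_exact, "participant", what)
  value_cols <- setdiff(names(df), "participant")
  for (cc in value_cols) {
    if (!is.numeric(df[[cc]])) {
      stop_input("%s: %s column '%s' is not numeric", what, path, cc)
    }
  }
  df
}

#' @rdname read_participant_csv
#' @param df Tibble to write.
#' @export
write_participant_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a full synthetic-cohort input bundle
#'
#' Materializes a [generate_cohort()] result as the file layout the
#' pipeline stages read: `regions.csv`, `distances.tsv`,
#' `participants.csv`, `counts/<id>.tsv`, `lesions.csv`,
#' `trials_meta.csv` with per-trial CSVs under `trials/`, and
#' `ground_truth.json`.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  spec <- cohort$spec
  readr::write_csv(spec$regions, file.path(dir, "regions.csv"),
                   progress = FALSE)
  write_matrix_tsv(cohort$distances, file.path(dir, "distances.tsv"))
  readr::write_csv(tibble::tibble(participant = cohort$latents$participant),
                   file.path(dir, "participants.csv"), progress = FALSE)
  for (id in names(cohort$counts)) {
    write_matrix_tsv(cohort$counts[[id]],
                     file.path(dir, "counts", paste0(id, ".tsv")))
  }
  readr::write_csv(cohort$lesions, file.path(dir, "lesions.csv"),
                   progress = FALSE)
  if (!is.null(cohort$trials)) {
    dir.create(file.path(dir, "trials"), showWarnings = FALSE)
    meta <- cohort$trials |>
      dplyr::mutate(
        file = sprintf("trials/%s_%s_%s_%d.csv", .data$participant,
                       .data$hand, .data$trial_kind, .data$repetition),
        cue_grip_s = ifelse(.data$trial_kind == "target_grip",
                            spec$cue_grip, NA_real_),
        cue_rest_s = ifelse(.data$trial_kind == "target_grip",
                            spec$cue_rest, NA_real_),
        sampling_rate_hz = spec$sampling_rate
      )
    purrr::walk2(meta$trial, meta$file, function(tr, f) {
      write_trial_csv(tr, file.path(dir, f))
    })
    readr::write_csv(
      dplyr::select(meta, "participant", "hand", "trial_kind",
                    "repetition", "cue_grip_s", "cue_rest_s",
                    "sampling_rate_hz", "file"),
      file.path(dir, "trials_meta.csv"), progress = FALSE
    )
  }
  truth <- list(
    seed = spec$seed,
    n_participants = spec$n_participants,
    k_networks = spec$k_networks,
    network_groups = spec$network_groups,
    effects = unclass(spec$effects),
    latents = cohort$latents,
    planted_edges = cohort$pattern,
    measures = cohort$measures
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the staged pipeline in one
#' object that can be written to / read from YAML. Unknown keys in a
#' config file are rejected.
#'
#' @param grip Named list of [grip_config()] arguments.
#' @param alpha,beta Connectivity-correction exponents.
#' @param first_args,second_args Factor-model arguments per level (see
#'   [two_level_model()]).
#' @param edge_threshold,top_n Composite-edge reporting rule.
#' @param vif_warn VIF warning threshold.
#' @param seed Seed recorded with the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(grip = list(), alpha = 1, beta = 1,
                            first_args = list(), second_args = list(),
                            edge_threshold = 0.4, top_n = 6,
                            vif_warn = 10, seed = 1L) {
  structure(
    list(grip = grip, alpha = alpha, beta = beta,
         first_args = first_args, second_args = second_args,
         edge_threshold = edge_threshold, top_n = top_n,
         vif_warn = vif_warn, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_input("config %s has unknown key(s): %s", path,
               paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stage 1: trials on disk -> per-participant performance ratios
stage_grip_metrics <- function(dir, config) {
  meta <- read_checked(file.path(dir, "trials_meta.csv"), csv_in,
                       c("participant", "hand", "trial_kind",
                         "repetition", "file"),
                       "trial metadata CSV")
  gconf <- do.call(grip_config, config$grip)
  per_part <- meta |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(function(rows, key) {
      trials <- purrr::pmap(rows, function(hand, trial_kind, file,
                                           cue_grip_s = NA,
                                           cue_rest_s = NA,
                                           sampling_rate_hz = 500, ...) {
        grip_trial(read_trial_csv(file.path(dir, file)),
                   sampling_rate = sampling_rate_hz,
                   cue_grip = cue_grip_s, cue_rest = cue_rest_s,
                   trial_kind = trial_kind, hand = hand)
      })
      perf <- grip_performance(trials, gconf)
      dplyr::bind_cols(tibble::tibble(participant = key$participant),
                       perf$ratios)
    }) |>
    dplyr::bind_rows()
  per_part
}

# stage 2: counts on disk -> cohort edge table (+ matrices)
stage_build_connectome <- function(dir, config) {
  regions <- read_regions_csv(file.path(dir, "regions.csv"))
  distances <- read_matrix_tsv(file.path(dir, "distances.tsv"), regions)
  parts <- read_checked(file.path(dir, "participants.csv"), csv_in,
                        "participant", "participants CSV")
  mats <- lapply(stats::setNames(parts$participant, parts$participant),
                 function(id) {
    raw <- read_matrix_tsv(file.path(dir, "counts", paste0(id, ".tsv")),
                           regions, nonnegative = TRUE)
    build_connectome(raw, distances, regions,
                     alpha = config$alpha, beta = config$beta)
  })
  list(regions = regions,
       matrices = mats,
       edge_table = assemble_edge_table(mats, regions))
}

#' Run the full staged pipeline on a cohort directory
#'
#' Executes grip-metrics, build-connectome, factorize and associate on
#' an input bundle (as written by [write_cohort()] or assembled from
#' real recordings in the same layout), writing every intermediate and
#' final table under `out_dir` plus a JSON run report (version, config
#' echo, per-stage timings, warnings). Inputs are never modified.
#'
#' @param dir Input bundle directory.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return List with `measures`, `edge_table`, `model`
#'   (`two_level_model`), `netdefs`, `scores`, `lesion_percents` and
#'   `association` (an [association_table()]), invisibly.
#' @export
run_pipeline <- function(dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen,
                          paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  measures <- timed("grip_metrics", stage_grip_metrics(dir, config))
  write_participant_csv(measures, file.path(out_dir, "measures.csv"))
  conn <- timed("build_connectome", stage_build_connectome(dir, config))
  write_participant_csv(conn$edge_table,
                        file.path(out_dir, "edge_table.csv"))
  model <- timed("factorize", two_level_model(
    conn$edge_table, conn$regions,
    first_args = config$first_args, second_args = config$second_args
  ))
  scores <- network_scores(model)
  netdefs <- network_definitions(model, threshold = config$edge_threshold,
                                 top_n = config$top_n)
  write_participant_csv(scores, file.path(out_dir, "network_scores.csv"))
  readr::write_csv(netdefs, file.path(out_dir, "network_edges.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(model, "second"),
                   file.path(out_dir, "second_level_loadings.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(model, "first"),
                   file.path(out_dir, "first_level_loadings.csv"),
                   progress = FALSE)
  lesions <- read_lesions_csv(file.path(dir, "lesions.csv"))
  assoc <- timed("associate", {
    lesion_percents <- purrr::map_dfr(model$networks, function(g) {
      network_lesion_percent(lesions, netdefs[netdefs$network == g, ],
                             conn$regions)
    })
    list(lp = lesion_percents,
         tab = association_table(scores, measures, lesion_percents))
  })
  readr::write_csv(assoc$lp, file.path(out_dir, "lesion_percents.csv"),
                   progress = FALSE)
  readr::write_csv(assoc$tab$grid, file.path(out_dir, "association.csv"),
                   progress = FALSE)
  report <- list(
    tool = "connectogrip",
    version = as.character(utils::packageVersion("connectogrip")),
    config = unclass(config),
    stages = timings,
    n_participants = nrow(measures),
    n_networks = model$second$k,
    warnings = warnings_seen
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(eigenvalues_second = model$second$eigenvalues,
         k_first = vapply(model$first$models, function(m) m$k, numeric(1)),
         k_second = model$second$k),
    file.path(out_dir, "model_summary.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(list(measures = measures, edge_table = conn$edge_table,
                 model = model, netdefs = netdefs, scores = scores,
                 lesion_percents = assoc$lp, association = assoc$tab))
}
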