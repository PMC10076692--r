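#' The default 20-region sensorimotor set
#'
#' Returns the region table the pipeline operates on by default: eight
#' sensorimotor gray-matter regions taken bilaterally (precentral,
#' Rolandic operculum, postcentral, supplementary motor area, putamen,
#' caudate, pallidum, thalamus) plus four brainstem tract cross-sections —
#' the corticospinal tract (CST) at the medulla (pyramid) and midbrain
#' (cerebral peduncle) and the corticoreticular pathway (CRP) at the
#' medulla and midbrain.
#'
#' Hemispheres are labelled relative to the lesioned side
#' (`ipsilesional` / `contralesional`); brainstem tract regions are
#' labelled `midline`. Volumes are typical adult gray-matter /
#' cross-section volumes in mm^3 and can be replaced by per-cohort
#' estimates via [read_regions_csv()].
#'
#' @param volumes Optional named numeric vector overriding the default
#'   per-structure volumes (names as in the `structure` column).
#' @return A tibble with columns `region`, `structure`, `hemisphere`,
#'   `class`, `volume_mm3`; exactly 20 rows in the pipeline's canonical
#'   region order.
#' @export
#' @examples
#' default_regions()
default_regions <- function(volumes = NULL) {
  base <- tibble::tribble(
    ~structure,    ~class,           ~volume_mm3,
    "precentral",  "cortical",       14000,
    "rolandic",    "cortical",       9000,
    "postcentral", "cortical",       12000,
    "sma",         "cortical",       10000,
    "putamen",     "subcortical",    5500,
    "caudate",     "subcortical",    4800,
    "pallidum",    "subcortical",    1800,
    "thalamus",    "subcortical",    8000
  )
  if (!is.null(volumes)) {
    idx <- match(names(volumes), base$structure)
    if (anyNA(idx)) {
      stop_input("unknown structure in volume override: %s",
                 paste(names(volumes)[is.na(idx)], collapse = ", "))
    }
    base$volume_mm3[idx] <- unname(volumes)
  }
  bilateral <- tidyr::expand_grid(
    base,
    hemisphere = c("ipsilesional", "contralesional")
  )
  bilateral$region <- paste(
    bilateral$structure,
    ifelse(bilateral$hemisphere == "ipsilesional", "ipsi", "contra"),
    sep = "_"
  )
  brainstem <- tibble::tribble(
    ~region,        ~structure, ~hemisphere, ~class,           ~volume_mm3,
    "cst_medulla",  "cst",      "midline",   "brainstem_CST",  350,
    "cst_midbrain", "cst",      "midline",   "brainstem_CST",  520,
    "crp_medulla",  "crp",      "midline",   "brainstem_CRP",  300,
    "crp_midbrain", "crp",      "midline",   "brainstem_CRP",  460
  )
  dplyr::bind_rows(
    dplyr::select(bilateral, "region", "structure", "hemisphere",
                  "class", "volume_mm3"),
    brainstem
  )
}

# nominal region centroids (mm, MNI-flavoured coordinates) used to derive
# the default inter-region distance matrix; approximate anatomy is enough
# because distances only enter as a per-edge scale factor
region_coordinates <- function(regions = default_regions()) {
  coords <- tibble::tribble(
    ~structure,    ~x,  ~y,   ~z,
    "precentral",  38, -8,    50,
    "rolandic",    48, -2,    12,
    "postcentral", 42, -26,   50,
    "sma",         6,  -2,    58,
    "putamen",     26, 2,     0,
    "caudate",     14, 10,    10,
    "pallidum",    20, -2,    -2,
    "thalamus",    11, -19,   7,
    "cst_medulla", 4,  -30,   -46,
    "cst_midbrain", 8, -18,   -16,
    "crp_medulla", 6,  -34,   -44,
    "crp_midbrain", 5, -24,   -14
  )
  out <- regions
  key <- ifelse(out$hemisphere == "midline", out$region, out$structure)
  idx <- match(key, coords$structure)
  out$x <- coords$x[idx] * ifelse(out$hemisphere == "contralesional", -1, 1)
  out$y <- coords$y[idx]
  out$z <- coords$z[idx]
  out
}

#' Default inter-region centroid distances
#'
#' Pairwise Euclidean distances (mm) between nominal region centroids of
#' the default sensorimotor set. Serves as the distance input to the
#' streamline-count correction when no subject-specific distances are
#' supplied.
#'
#' @param regions A region tibble as returned by [default_regions()].
#' @return A symmetric numeric matrix (mm) with region names as
#'   dimnames and zero diagonal.
#' @export
default_distances <- function(regions = default_regions()) {
  rc <- region_coordinates(regions)
  xyz <- as.matrix(rc[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(regions$region, regions$region)
  d
}

#' Relabel anatomical hemispheres relative to the lesioned side
#'
#' Input region tables recorded with anatomical `left` / `right` labels
#' are converted to the reporting convention used throughout the
#' pipeline: the hemisphere containing the lesion becomes
#' `ipsilesional`, the other `contralesional`; `midline` rows pass
#' through.
#'
#' @param regions Tibble with columns `region`, `left_right` (one of
#'   `left`, `right`, `midline`) and any others.
#' @param lesion_side `"left"` or `"right"`.
#' @return The tibble with a `hemisphere` column added.
#' @export
relabel_hemispheres <- function(regions, lesion_side) {
  lesion_side <- match.arg(lesion_side, c("left", "right"))
  if (!"left_right" %in% names(regions)) {
    stop_input("regions table lacks a 'left_right' column")
  }
  bad <- setdiff(unique(regions$left_right), c("left", "right", "midline"))
  if (length(bad) > 0) {
    stop_input("invalid left_right value(s): %s", paste(bad, collapse = ", "))
  }
  regions$hemisphere <- dplyr::case_when(
    regions$left_right == "midline" ~ "midline",
    regions$left_right == lesion_side ~ "ipsilesional",
    TRUE ~ "contralesional"
  )
  regions
}
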