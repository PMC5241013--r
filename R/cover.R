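# Point-intercept cover metrics.
#
# All functions take the long point-intercept table (one row per hit,
# substrate-only points as one row with species_code NA) for a single
# plot-visit unless noted. The denominator of every cover metric is the
# number of intercept points laid out in the plot — recovered as the
# number of distinct (transect, position) pairs, since every point
# carries at least a substrate row — never reduced by empty points.

check_single_visit <- function(hits) {
  if (!is.data.frame(hits) || nrow(hits) == 0)
    stop("`hits` must be a non-empty point-intercept data.frame", call. = FALSE)
  if (length(unique(visit_key(hits))) != 1)
    stop("`hits` must contain exactly one plot-visit", call. = FALSE)
  invisible(hits)
}

n_layout_points <- function(hits) length(unique(point_key(hits)))

#' Foliage Projective Cover of one species
#'
#' FPC is the percentage of intercept points at which the species'
#' foliage is directly intercepted: the number of points with at least
#' one hit on the species, excluding `IN_CANOPY_SKY` hits, divided by
#' the plot's total point count and multiplied by 100. A species
#' intercepted by several vegetation layers at the same point counts
#' once there, so FPC is a proportion bounded by 100; summed over
#' species FPC may still exceed 100 because layers of different species
#' overlap.
#'
#' @param hits point-intercept records of one plot-visit.
#' @param species a species code.
#' @param n_points total intercept points in the layout; by default the
#'   number of distinct (transect, position) pairs present in `hits`
#'   (1010 in the standard design).
#' @return Percent cover in \[0, 100\].
#' @examples
#' com <- simulate_community(3, 1, 50, seed = 1)
#' h <- simulate_point_intercepts(com, generate_plot_layout(), seed = 1)
#' foliage_projective_cover(h, com$species_codes[1])
#' @seealso [opaque_canopy_cover()] which counts canopy gaps toward the
#'   species; [build_cover_matrix()] for all species x plots at once.
#' @export
foliage_projective_cover <- function(hits, species, n_points = NULL) {
  check_single_visit(hits)
  if (is.null(n_points)) n_points <- n_layout_points(hits)
  direct <- !is.na(hits$species_code) & hits$species_code == species
  100 * length(unique(point_key(hits)[direct])) / n_points
}

#' Opaque Canopy Cover of one species
#'
#' Alternative cover metric in which the canopy is treated as a solid
#' convex polygon: points where the line passed through a within-canopy
#' gap (`IN_CANOPY_SKY` records attributed to the species via
#' `canopy_species`) count toward the species in addition to direct
#' foliage hits, so OCC >= FPC always. Sky hits with no species
#' attribution contribute to no species and raise a warning.
#'
#' @inheritParams foliage_projective_cover
#' @return Percent cover in \[0, 100\].
#' @export
opaque_canopy_cover <- function(hits, species, n_points = NULL) {
  check_single_visit(hits)
  if (is.null(n_points)) n_points <- n_layout_points(hits)
  sky <- !is.na(hits$species_code) & hits$species_code == IN_CANOPY_SKY
  if (any(sky & is.na(hits$canopy_species)))
    warning("in-canopy sky hits without canopy species attribution ",
            "contribute to no species")
  counted <- (!is.na(hits$species_code) & hits$species_code == species) |
    (sky & !is.na(hits$canopy_species) & hits$canopy_species == species)
  100 * length(unique(point_key(hits)[counted])) / n_points
}

#' Fractional cover of a plot
#'
#' Partitions intercept points into photosynthetic (green) vegetation,
#' non-photosynthetic (dead) vegetation, and bare substrate, by each
#' point's uppermost interception: the highest hit's `green_flag`
#' decides green versus dead; points with no vegetation hit are
#' classified by substrate (`litter` and `coarse woody debris` count as
#' dead vegetation, everything else as bare). The three percentages sum
#' to 100.
#'
#' When `green_flag` is absent from the vegetated points the green/dead
#' split is indeterminate: `photosynthetic` then reports all vegetated
#' cover, `non_photosynthetic` is `NA`, and a warning is raised — the
#' vegetated/bare split is still valid.
#'
#' @inheritParams foliage_projective_cover
#' @return Named numeric: `photosynthetic`, `non_photosynthetic`,
#'   `bare`, in percent.
#' @export
fractional_cover <- function(hits, n_points = NULL) {
  check_single_visit(hits)
  if (is.null(n_points)) n_points <- n_layout_points(hits)
  veg <- hits[!is.na(hits$species_code) & hits$species_code != IN_CANOPY_SKY, ]
  dead_substrates <- c("litter", "coarse woody debris")

  if (nrow(veg)) {
    # uppermost vegetation hit per point
    ord <- order(point_key(veg), -ifelse(is.na(veg$height_m), 0, veg$height_m))
    veg <- veg[ord, ]
    top <- veg[!duplicated(point_key(veg)), ]
  } else {
    top <- veg
  }
  veg_pts <- unique(point_key(top))

  all_pts <- unique(point_key(hits))
  bare_keys <- setdiff(all_pts, veg_pts)
  substrate_of <- hits$substrate[match(bare_keys, point_key(hits))]
  n_dead_sub <- sum(substrate_of %in% dead_substrates)
  n_bare <- length(bare_keys) - n_dead_sub

  if (nrow(top) && all(is.na(top$green_flag))) {
    warning("green/brown flags missing; non-photosynthetic split of the ",
            "vegetated fraction is indeterminate")
    return(c(photosynthetic = 100 * nrow(top) / n_points,
             non_photosynthetic = NA_real_,
             bare = 100 * n_bare / n_points))
  }
  n_green <- sum(top$green_flag %in% TRUE)
  n_dead_veg <- nrow(top) - n_green
  c(photosynthetic = 100 * n_green / n_points,
    non_photosynthetic = 100 * (n_dead_veg + n_dead_sub) / n_points,
    bare = 100 * n_bare / n_points)
}

#' Build a plot-visit x species percent-cover matrix
#'
#' The "site by species" flat file of the pipeline: one row per
#' plot-visit (input order), one column per species code in the union
#' over all visits (lexicographic order), cells holding percent cover
#' under the chosen metric. Absences are explicit zeros, never missing
#' — a species unrecorded in a plot has cover exactly 0 there.
#'
#' @param hits point-intercept records of one or more plot-visits.
#' @param metric `"FPC"` (default, [foliage_projective_cover()]) or
#'   `"OCC"` ([opaque_canopy_cover()]).
#' @param n_points layout point count per plot; default as in
#'   [foliage_projective_cover()], evaluated per plot-visit.
#' @return A numeric matrix with plot-visit keys (`plot:visit`) as row
#'   names, species codes as column names, and attribute
#'   `metric`. Bare plots contribute rows; a dataset with no species
#'   yields a 0-column matrix with row names preserved.
#' @export
build_cover_matrix <- function(hits, metric = c("FPC", "OCC"),
                               n_points = NULL) {
  metric <- match.arg(metric)
  if (!is.data.frame(hits) || nrow(hits) == 0)
    stop("`hits` must be a non-empty point-intercept data.frame", call. = FALSE)
  keys <- visit_key(hits)
  visits <- unique(keys)
  species <- sort(unique(hits$species_code[
    !is.na(hits$species_code) & hits$species_code != IN_CANOPY_SKY]))
  if (metric == "OCC") {
    attributed <- hits$canopy_species[
      !is.na(hits$species_code) & hits$species_code == IN_CANOPY_SKY]
    species <- sort(unique(c(species, attributed[!is.na(attributed)])))
  }

  mat <- matrix(0, nrow = length(visits), ncol = length(species),
                dimnames = list(visits, species))
  fun <- if (metric == "FPC") foliage_projective_cover else opaque_canopy_cover
  for (v in visits) {
    sub <- hits[keys == v, , drop = FALSE]
    np <- if (is.null(n_points)) n_layout_points(sub) else n_points
    present <- unique(sub$species_code[!is.na(sub$species_code)])
    if (metric == "OCC")
      present <- unique(c(present, sub$canopy_species[!is.na(sub$canopy_species)]))
    for (sp in intersect(present, species))
      mat[v, sp] <- fun(sub, sp, n_points = np)
  }
  attr(mat, "metric") <- metric
  mat
}
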