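# Sampling-sufficiency diagnostics: field-order cumulative cover and
# rarefied species-accumulation curves.

# Parse transect labels of the form E1-W1 / W2-E2 into their field
# sequence number; errors on anything else, naming the label.
transect_sequence <- function(labels) {
  m <- regmatches(labels, regexec("^([EW])([0-9]+)-([EW])([0-9]+)$", labels))
  # valid when the two directions differ and the two numbers agree
  ok <- vapply(m, function(p) {
    length(p) == 5 && p[2] != p[4] && p[3] == p[5]
  }, logical(1))
  if (any(!ok))
    stop("unknown transect label(s): ",
         paste(unique(labels[!ok]), collapse = ", "), call. = FALSE)
  as.integer(vapply(m, `[`, character(1), 3L))
}

#' Order point-intercept records in field collection order
#'
#' Reconstructs the order in which intercepts are taken in the field:
#' transects are walked in a zigzag across the plot (East1-West1 points
#' 0 to 100, then West2-East2 points 0 to 100, and so on), so records
#' are sorted by transect sequence number, then metre position
#' ascending. The ordering is deterministic and idempotent.
#'
#' @param hits point-intercept records (one or more plot-visits;
#'   ordering applies within plot-visit, visits kept in input order).
#' @return `hits` reordered, row names reset.
#' @export
field_order <- function(hits) {
  if (!is.data.frame(hits)) stop("`hits` must be a data.frame", call. = FALSE)
  if (nrow(hits) == 0) return(hits)
  seqno <- transect_sequence(hits$transect)
  visit <- match(visit_key(hits), unique(visit_key(hits)))
  out <- hits[order(visit, seqno, hits$position_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# point x species incidence matrix (rows in field order), sentinel and
# substrate-only rows contribute empty sample rows.
point_species_incidence <- function(hits) {
  hits <- field_order(check_single_visit(hits))
  pts <- unique(point_key(hits))
  species <- sort(unique(hits$species_code[
    !is.na(hits$species_code) & hits$species_code != IN_CANOPY_SKY]))
  inc <- matrix(0L, nrow = length(pts), ncol = length(species),
                dimnames = list(pts, species))
  keep <- !is.na(hits$species_code) & hits$species_code != IN_CANOPY_SKY
  if (any(keep))
    inc[cbind(match(point_key(hits)[keep], pts),
              match(hits$species_code[keep], species))] <- 1L
  inc
}

#' Rarefied species-accumulation curve for one plot
#'
#' Intercept points are the sampling units; each may record zero
#' (substrate only), one, or multiple species. For each of
#' `n_replicates` random permutations of the point set, species
#' richness is recorded after every point added; the returned curve
#' holds the mean and standard deviation of richness across replicates
#' at each sample size. Points are permuted without replacement, so the
#' curve ends exactly at the plot's observed point-intercept richness
#' with zero spread.
#'
#' @param hits point-intercept records of one plot-visit.
#' @param n_replicates number of random permutations (default 1000).
#' @param seed optional integer for reproducible permutations.
#' @return A data.frame of class `accumulation_curve`: `n_points`,
#'   `mean_richness`, `sd_richness`; attribute `n_replicates`.
#' @export
species_accumulation <- function(hits, n_replicates = 1000, seed = NULL) {
  stopifnot_scalar_count(n_replicates, "n_replicates")
  inc <- point_species_incidence(hits)
  n <- nrow(inc)
  if (ncol(inc) == 0) {
    out <- data.frame(n_points = seq_len(n), mean_richness = 0,
                      sd_richness = 0)
  } else {
    sac <- with_seed(seed,
      vegan::specaccum(inc, method = "random", permutations = n_replicates))
    out <- data.frame(n_points = sac$sites,
                      mean_richness = sac$richness,
                      sd_richness = ifelse(is.na(sac$sd), 0, sac$sd))
  }
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Field-order cumulative cover trajectories
#'
#' Adds intercept points to a data pool one at a time in field
#' collection order ([field_order()]) and recomputes every species' FPC
#' after each addition: the value after k points is
#' `100 * points-with-the-species-so-far / k`. Field order is used
#' rather than a random order because consecutive intercepts are taken
#' at adjacent field locations, which is what the stabilisation of a
#' real survey's estimates looks like. The final value of each
#' trajectory equals the whole-plot [foliage_projective_cover()]
#' exactly.
#'
#' @param hits point-intercept records of one plot-visit.
#' @param species optional character vector restricting the output
#'   (default: all species observed in the plot).
#' @return A long data.frame: `species_code`, `n_points`,
#'   `cumulative_fpc`.
#' @export
cumulative_cover <- function(hits, species = NULL) {
  inc <- point_species_incidence(hits)
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(inc))
    if (length(missing))
      stop("species not present in records: ",
           paste(missing, collapse = ", "), call. = FALSE)
    inc <- inc[, species, drop = FALSE]
  }
  n <- nrow(inc)
  if (ncol(inc) == 0)
    return(data.frame(species_code = character(), n_points = integer(),
                      cumulative_fpc = numeric()))
  cum <- apply(inc, 2, cumsum)
  traj <- 100 * cum / seq_len(n)
  data.frame(
    species_code = rep(colnames(inc), each = n),
    n_points = rep(seq_len(n), times = ncol(inc)),
    cumulative_fpc = as.vector(traj),
    stringsAsFactors = FALSE
  )
}
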