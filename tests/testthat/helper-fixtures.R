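# Fixture builders shared across test files. All data are generated in
# code; nothing is read from disk.

# Hand-built point-intercept rows for a tiny plot: `points` is a
# data.frame with transect / position_m and a list-column free spec of
# hits, but for most tests the flat constructor below is simpler.
make_hits <- function(transect, position_m, species_code = NA_character_,
                      canopy_species = NA_character_,
                      growth_form = NA_character_, height_m = NA_real_,
                      green_flag = NA, substrate = "bare",
                      plot_id = "P1", visit_id = "V1") {
  data.frame(
    plot_id = plot_id, visit_id = visit_id,
    transect = transect, position_m = position_m,
    species_code = species_code, canopy_species = canopy_species,
    growth_form = growth_form, height_m = height_m,
    green_flag = green_flag, substrate = substrate,
    stringsAsFactors = FALSE
  )
}

# A complete one-transect plot of `n` points (positions 0..n-1), with
# hits at the named positions; remaining points are substrate-only.
small_plot <- function(n = 10, hit_positions = integer(),
                       species = "SPA", transect = "E1-W1", ...) {
  pts <- make_hits(transect, 0:(n - 1), ...)
  if (length(hit_positions)) {
    extra <- make_hits(transect, hit_positions, species_code = species,
                       green_flag = TRUE, height_m = 1, ...)
    pts <- rbind(pts[!pts$position_m %in% hit_positions, ], extra)
  }
  pts[order(pts$position_m), ]
}

# A standard-layout simulated plot used by several modules.
standard_sim_plot <- function(seed = 101, n_species = 12, alpha = 0.8,
                              target = 60) {
  com <- simulate_community(n_species, alpha, target, seed = seed)
  simulate_point_intercepts(com, generate_plot_layout(), seed = seed + 1)
}
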