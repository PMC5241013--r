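#' Generate a point-intercept plot layout
#'
#' Describes the sampling grid of a survey plot: `n_transects` parallel
#' transects walked in alternating directions (a zigzag across the
#' plot), with intercept points every `spacing_m` metres from 0 to
#' `transect_length_m` inclusive. The standard design — 10 transects of
#' 100 m at 1 m spacing — yields 10 x 101 = 1010 intercept points per
#' 1 ha plot.
#'
#' Transect identifiers carry their walking direction in field order:
#' `"E1-W1"`, `"W2-E2"`, `"E3-W3"`, ... (odd transects walked
#' east-to-west of the grid, even ones back).
#'
#' @param n_transects number of transects (positive integer).
#' @param transect_length_m transect length in metres; must be divisible
#'   by `spacing_m`.
#' @param spacing_m distance between successive intercept points (m).
#' @return An object of class `plot_layout`: a list with `transects`
#'   (ids in field order), `positions` (metre marks along one transect),
#'   `points_per_transect` and `total_points`.
#' @examples
#' layout <- generate_plot_layout()
#' layout$total_points  # 1010
#' @export
generate_plot_layout <- function(n_transects = 10, transect_length_m = 100,
                                 spacing_m = 1) {
  stopifnot_scalar_count(n_transects, "n_transects")
  stopifnot_scalar_count(transect_length_m, "transect_length_m")
  stopifnot_scalar_count(spacing_m, "spacing_m")
  if (transect_length_m %% spacing_m != 0)
    stop("`transect_length_m` must be divisible by `spacing_m`", call. = FALSE)

  i <- seq_len(n_transects)
  ids <- ifelse(i %% 2 == 1,
                sprintf("E%d-W%d", i, i),
                sprintf("W%d-E%d", i, i))
  positions <- seq(0L, as.integer(transect_length_m), by = as.integer(spacing_m))
  structure(
    list(
      transects = ids,
      positions = positions,
      points_per_transect = length(positions),
      total_points = as.integer(n_transects) * length(positions)
    ),
    class = "plot_layout"
  )
}

#' @export
print.plot_layout <- function(x, ...) {
  cat(sprintf(
    "Point-intercept layout: %d transects x %d points = %d intercepts\n",
    length(x$transects), x$points_per_transect, x$total_points
  ))
  invisible(x)
}
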