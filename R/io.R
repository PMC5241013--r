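# Delimited-text readers and writers for the survey data dialects.
# Every writer drops a JSON sidecar (<file>.schema.json) declaring the
# column schema, so downstream consumers can validate files
# independently of this package.

write_schema_sidecar <- function(df, path) {
  schema <- list(
    file = basename(path),
    columns = lapply(names(df), function(nm) {
      list(name = nm, type = class(df[[nm]])[1])
    })
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

pi_mandatory <- c("plot_id", "visit_id", "transect", "position_m",
                  "species_code", "substrate")

#' Write / read point-intercept tables
#'
#' The point-intercept CSV dialect has one row per hit with columns
#' `plot_id`, `visit_id`, `transect`, `position_m`, `species_code`
#' (empty for substrate-only points, `IN_CANOPY_SKY` for within-canopy
#' sky hits), `canopy_species`, `growth_form`, `height_m`, `green_flag`
#' and `substrate`. Percent and metre values are serialised at full
#' precision; rounding happens only in reports.
#'
#' `read_point_intercepts` validates the file: mandatory columns must
#' be present (extra columns are tolerated and carried through),
#' positions must be integral (a schema error names the offending
#' lines), transect labels must parse as zigzag pairs, and fully
#' duplicated hit rows are dropped with a warning.
#'
#' @param hits point-intercept data.frame to serialise.
#' @param path file path.
#' @return `read_point_intercepts` returns the validated data.frame;
#'   `write_point_intercepts` invisibly returns `path`.
#' @export
write_point_intercepts <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  missing <- setdiff(pi_mandatory, names(hits))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  write.csv(hits, path, row.names = FALSE, na = "")
  write_schema_sidecar(hits, path)
  invisible(path)
}

#' @rdname write_point_intercepts
#' @export
read_point_intercepts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(position_m = "character"),
                  na.strings = "")
  missing <- setdiff(pi_mandatory, names(raw))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  pos_num <- suppressWarnings(as.numeric(raw$position_m))
  bad <- which(is.na(pos_num) | pos_num != round(pos_num))
  if (length(bad))
    stop("schema error: non-integral position_m at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  raw$position_m <- as.integer(pos_num)
  transect_sequence(raw$transect)  # errors on malformed labels

  if ("green_flag" %in% names(raw)) raw$green_flag <- as.logical(raw$green_flag)
  if ("height_m" %in% names(raw)) raw$height_m <- as.numeric(raw$height_m)

  dup <- duplicated(raw) & !is.na(raw$species_code)
  if (any(dup)) {
    warning(sum(dup), " duplicate hit row(s) removed")
    raw <- raw[!dup, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write / read site tables
#'
#' One row per plot-visit: `plot_id`, `visit_id`, `latitude`,
#' `longitude`, `vegetation_group`, `map_mm` (mean annual
#' precipitation, mm), plus any extra covariate columns. `map_mm` must
#' be positive when present.
#'
#' @param sites site data.frame.
#' @param path file path.
#' @export
write_sites <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  write.csv(sites, path, row.names = FALSE, na = "")
  write_schema_sidecar(sites, path)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sites <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("plot_id", "visit_id", "vegetation_group", "map_mm")
  missing <- setdiff(need, names(sites))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(duplicated(visit_key(sites))))
    stop("duplicate plot-visit rows in site table", call. = FALSE)
  if (any(!is.na(sites$map_mm) & sites$map_mm <= 0))
    stop("map_mm must be positive", call. = FALSE)
  sites
}

#' Write a cover matrix as the site-by-species flat file
#'
#' Wide CSV with the plot-visit id as first column, species codes as
#' remaining columns and percent cover values at full precision.
#'
#' @param cover_matrix matrix from [build_cover_matrix()].
#' @param path file path.
#' @export
write_cover_matrix <- function(cover_matrix, path) {
  stopifnot(is.matrix(cover_matrix))
  df <- data.frame(plot_visit = rownames(cover_matrix),
                   cover_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  write_schema_sidecar(df, path)
  invisible(path)
}

#' Write the gradient analysis table
#'
#' Table-shaped CSV of [run_gradient_analysis()] results with display
#' columns reporting the slope and CI bounds multiplied by 1e4 (the
#' conventional per-10,000-mm scale of shape-vs-MAP coefficients)
#' alongside the raw machine-precision columns.
#'
#' @param gradient data.frame from [run_gradient_analysis()].
#' @param path file path.
#' @export
write_gradient_table <- function(gradient, path) {
  stopifnot(is.data.frame(gradient))
  out <- gradient
  out$coefficient_x1e4 <- round(out$slope * 1e4, 2)
  out$ci_lower_x1e4 <- round(out$ci_lower * 1e4, 2)
  out$ci_upper_x1e4 <- round(out$ci_upper * 1e4, 2)
  write.csv(out, path, row.names = FALSE)
  write_schema_sidecar(out, path)
  invisible(path)
}
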