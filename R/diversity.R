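# Per-plot diversity metrics computed from FPC cover vectors.

check_cover_vector <- function(covers) {
  if (!is.numeric(covers) || length(covers) == 0 || any(is.na(covers)) ||
      any(covers < 0))
    stop("`covers` must be a non-empty non-negative numeric vector",
         call. = FALSE)
  if (all(covers == 0))
    stop("diversity is undefined for an all-zero cover vector", call. = FALSE)
  covers[covers > 0]
}

#' Shannon diversity of a cover vector
#'
#' H' = -sum p_i log p_i in natural-log units (nats), with p_i the
#' species' share of summed cover. Zero covers are dropped before
#' normalisation; the result lies in \[0, log S\] and is invariant to
#' rescaling all covers by a constant. A monoculture scores 0.
#'
#' @param covers per-species percent cover (FPC) vector, at least one
#'   positive entry.
#' @return Shannon diversity in nats.
#' @examples
#' shannon_diversity(c(25, 25, 25, 25))  # log(4)
#' @export
shannon_diversity <- function(covers) {
  x <- check_cover_vector(covers)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Simpson index (Gini-Simpson complement) of a cover vector
#'
#' Returns 1 - sum p_i^2: the probability that two cover units drawn at
#' random belong to different species. It is 0 for a monoculture and
#' bounded above by (S-1)/S, so observed values over a survey span
#' \[0, ~1). The raw concentration sum p_i^2 and its reciprocal are
#' available as [simpson_dominance()] and [inverse_simpson()].
#'
#' @inheritParams shannon_diversity
#' @return Value in \[0, 1).
#' @examples
#' simpson_index(c(50, 50))  # 0.5
#' @export
simpson_index <- function(covers) {
  x <- check_cover_vector(covers)
  unname(vegan::diversity(x, index = "simpson"))
}

#' @rdname simpson_index
#' @export
simpson_dominance <- function(covers) {
  x <- check_cover_vector(covers)
  p <- x / sum(x)
  sum(p^2)
}

#' @rdname simpson_index
#' @export
inverse_simpson <- function(covers) {
  x <- check_cover_vector(covers)
  unname(vegan::diversity(x, index = "invsimpson"))
}

#' Species richness of a plot-visit
#'
#' Point-intercept richness counts distinct species with at least one
#' direct (non-sky) hit; voucher richness counts distinct taxa on the
#' plot's voucher list from exhaustive visual search. Vouchering
#' normally detects more species than the intercept lines, but real
#' data can violate that, so `richness_voucher >= richness_pi` is not
#' enforced — a violation only raises a warning.
#'
#' @param hits point-intercept records of one plot-visit.
#' @param vouchers optional data.frame with a `species_code` column for
#'   the same plot-visit (may be empty or `NULL`).
#' @return Named integer vector `c(richness_pi, richness_voucher)`.
#' @export
species_richness <- function(hits, vouchers = NULL) {
  check_single_visit(hits)
  sp <- hits$species_code
  r_pi <- length(unique(sp[!is.na(sp) & sp != IN_CANOPY_SKY]))
  r_v <- if (is.null(vouchers) || nrow(vouchers) == 0) 0L else
    length(unique(vouchers$species_code))
  if (r_v > 0 && r_v < r_pi)
    warning("voucher richness below point-intercept richness for ",
            unique(visit_key(hits)))
  c(richness_pi = r_pi, richness_voucher = r_v)
}

#' Per-plot diversity table
#'
#' Computes point-intercept and voucher richness, Shannon diversity and
#' the Simpson index for every plot-visit, from the FPC cover matrix.
#' Plots with no intercepted species get richness 0 and `NA` diversity
#' values (diversity is undefined on an empty community).
#'
#' @param hits point-intercept records, any number of plot-visits.
#' @param vouchers optional voucher table (`plot_id`, `visit_id`,
#'   `species_code`).
#' @return A data.frame: `plot_id`, `visit_id`, `richness_pi`,
#'   `richness_voucher`, `shannon`, `simpson`.
#' @export
diversity_table <- function(hits, vouchers = NULL) {
  cov <- build_cover_matrix(hits, metric = "FPC")
  keys <- rownames(cov)
  ids <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  vkeys <- if (is.null(vouchers)) character() else visit_key(vouchers)
  res <- data.frame(
    plot_id = ids[, 1], visit_id = ids[, 2],
    richness_pi = NA_integer_, richness_voucher = NA_integer_,
    shannon = NA_real_, simpson = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(keys)) {
    covers <- cov[i, ]
    covers <- covers[covers > 0]
    res$richness_pi[i] <- length(covers)
    res$richness_voucher[i] <-
      length(unique(vouchers$species_code[vkeys == keys[i]]))
    if (length(covers) > 0) {
      res$shannon[i] <- shannon_diversity(covers)
      res$simpson[i] <- simpson_index(covers)
    }
  }
  if (any(res$richness_voucher > 0 & res$richness_voucher < res$richness_pi))
    warning("some plot-visits have voucher richness below point-intercept ",
            "richness")
  res
}
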