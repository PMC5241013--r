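# Robust regression of SAD shape on mean annual precipitation:
# Huber M-estimation by IRLS, weighted R^2, percentile bootstrap CIs,
# and the per-vegetation-group analysis table.

#' Robust simple linear regression (Huber M-estimator)
#'
#' Fits `y = intercept + slope * x` by iteratively reweighted least
#' squares with the Huber weight function: observations whose scaled
#' residual exceeds the tuning constant `k` are downweighted by
#' `k / |r/s|`, others get weight 1. The residual scale `s` is
#' re-estimated at every iteration as `median(|r|) / 0.6745` (the MAD
#' normalised to the Gaussian SD). Iteration stops when no coefficient
#' moves by more than `tol`, or after `max_iter` iterations (then the
#' last iterate is returned with `converged = FALSE` and a warning).
#' An exactly collinear sample has zero residual scale and returns the
#' interpolating line with all weights 1.
#'
#' With `k = Inf` (or any constant exceeding every scaled residual) no
#' observation is downweighted and the fit reduces exactly to ordinary
#' least squares.
#'
#' @param x predictor (e.g. MAP in mm), length >= 3, no missing values,
#'   not constant.
#' @param y response (e.g. Pareto alpha), same length as `x`.
#' @param k Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param tol convergence tolerance on the coefficients.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `robust_fit`: list with `coefficients`
#'   (`intercept`, `slope`), `weights` (in (0, 1\]), `scale`,
#'   `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- runif(60, 129, 1437)
#' y <- 1 - 4e-4 * x + rnorm(60, 0, 0.05)
#' robust_fit(x, y)$coefficients
#' @export
robust_fit <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50) {
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (var(x) == 0)
    stop("`x` is constant: slope is unidentifiable", call. = FALSE)
  stopifnot(k > 0, tol > 0, max_iter >= 1)

  n <- length(x)
  wls <- function(w) {
    sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
    sxx <- sum(w * x * x); sxy <- sum(w * x * y)
    d <- sw * sxx - swx^2
    slope <- (sw * sxy - swx * swy) / d
    c(intercept = (swy - slope * swx) / sw, slope = slope)
  }

  b <- wls(rep(1, n))
  w <- rep(1, n)
  scale <- NA_real_
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- y - b["intercept"] - b["slope"] * x
    scale <- median(abs(r)) / 0.6745
    if (scale < .Machine$double.eps^0.75 * max(1, median(abs(y)))) {
      w <- rep(1, n)       # (near-)perfect fit: nothing to downweight
      converged <- TRUE
      break
    }
    u <- abs(r / scale)
    w <- ifelse(u <= k, 1, k / u)
    b_new <- wls(w)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("robust_fit did not converge in %d iterations", max_iter))
  structure(
    list(coefficients = b, weights = w, scale = scale,
         iterations = iter, converged = converged, k = k),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "Huber robust fit (k = %.4g): intercept = %.6g, slope = %.6g%s\n",
    x$k, x$coefficients["intercept"], x$coefficients["slope"],
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Weighted coefficient of determination (R^2_WLS)
#'
#' R^2 computed with the robust fit's final observation weights:
#' `1 - sum(w e^2) / sum(w (y - ybar_w)^2)` with `e` the fit residuals
#' and `ybar_w` the weighted mean of `y`, so outliers influence the fit
#' statistic only to the extent the M-estimator trusted them. Equals
#' the ordinary R^2 when all weights are 1. Values marginally outside
#' \[0, 1\] (possible because the robust line is not the weighted
#' least-squares optimum) are clipped with a message.
#'
#' @param fit a [robust_fit()] result.
#' @param x,y the data the fit was computed on.
#' @return R^2_WLS in \[0, 1\].
#' @export
r2_weighted <- function(fit, x, y) {
  stopifnot(inherits(fit, "robust_fit"))
  w <- fit$weights
  e <- y - fit$coefficients["intercept"] - fit$coefficients["slope"] * x
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  if (tss == 0)
    stop("weighted variance of `y` is zero: R^2 undefined", call. = FALSE)
  r2 <- 1 - sum(w * e^2) / tss
  if (r2 < 0 || r2 > 1) {
    message(sprintf("R^2_WLS = %.4g outside [0, 1]; clipped", r2))
    r2 <- min(max(r2, 0), 1)
  }
  unname(r2)
}

#' Percentile bootstrap confidence interval for the robust slope
#'
#' Case (pairs) resampling: `n_replicates` resamples of (x, y) pairs
#' with replacement, a [robust_fit()] on each, and the empirical
#' quantiles of the replicate slopes at (1-level)/2 and 1-(1-level)/2.
#' Degenerate resamples (constant x) are redrawn. Deterministic given
#' `seed`.
#'
#' @inheritParams robust_fit
#' @param n_replicates bootstrap replicates (default 1000, >= 100).
#' @param level confidence level in (0, 1); default 0.90.
#' @param seed optional integer seed.
#' @return Named numeric `c(lower, upper)` with attribute `slopes`
#'   holding the replicate slopes.
#' @export
bootstrap_slope_ci <- function(x, y, n_replicates = 1000, level = 0.90,
                               seed = NULL, k = 1.345) {
  stopifnot(n_replicates >= 100, level > 0, level < 1)
  n <- length(x)
  with_seed(seed, {
    slopes <- numeric(n_replicates)
    for (b in seq_len(n_replicates)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (var(x[idx]) > 0) break
      }
      fit <- suppressWarnings(robust_fit(x[idx], y[idx], k = k))
      slopes[b] <- fit$coefficients[["slope"]]
    }
    ci <- quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    structure(c(lower = ci[1], upper = ci[2]), slopes = slopes,
              level = level)
  })
}

#' Robust shape-vs-MAP regressions per vegetation group
#'
#' The gradient analysis table: for each vegetation group — and for the
#' pooled `"Combined"` set — and each SAD shape response, regresses the
#' per-plot shape coefficient on mean annual precipitation with
#' [robust_fit()], computes [r2_weighted()], and bootstraps the slope's
#' 90% percentile CI. A slope is flagged as robust when its CI does not
#' overlap zero. Groups with fewer than `min_n` fitted plots are
#' skipped with a warning.
#'
#' @param sad_fits per-plot fit table from [fit_sad_table()].
#' @param sites site table with `plot_id`, `visit_id`,
#'   `vegetation_group`, `map_mm`.
#' @param responses columns of `sad_fits` to regress; default Pareto
#'   alpha and lognormal sigma.
#' @param groups vegetation groups to analyse (default: all in
#'   `sites`); the pooled `"Combined"` row is always added.
#' @param n_boot,level bootstrap replicates and CI level.
#' @param seed optional integer; makes the whole table deterministic.
#' @param min_n minimum observations per group (default 3).
#' @param k Huber tuning constant.
#' @return A data.frame with one row per group x response: `group`,
#'   `response`, `n_obs`, `slope`, `intercept`, `r2_wls`, `ci_lower`,
#'   `ci_upper`, `ci_excludes_zero`, `converged`.
#' @export
run_gradient_analysis <- function(sad_fits, sites,
                                  responses = c("pareto_alpha",
                                                "lognormal_sigma"),
                                  groups = NULL, n_boot = 1000,
                                  level = 0.90, seed = NULL, min_n = 3,
                                  k = 1.345) {
  stopifnot(is.data.frame(sad_fits), is.data.frame(sites))
  if (!all(responses %in% names(sad_fits)))
    stop("`responses` must be columns of `sad_fits`", call. = FALSE)
  dat <- merge(sad_fits, sites, by = c("plot_id", "visit_id"))
  if (is.null(groups)) groups <- sort(unique(sites$vegetation_group))

  with_seed(seed, {
    rows <- list()
    for (g in c(groups, "Combined")) {
      sub <- if (g == "Combined") dat else
        dat[dat$vegetation_group == g, , drop = FALSE]
      if (nrow(sub) < min_n) {
        warning(sprintf("group '%s' has %d observations (< %d): skipped",
                        g, nrow(sub), min_n))
        next
      }
      for (resp in responses) {
        x <- sub$map_mm
        y <- sub[[resp]]
        fit <- robust_fit(x, y, k = k)
        ci <- bootstrap_slope_ci(x, y, n_replicates = n_boot,
                                 level = level, k = k)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, response = resp, n_obs = nrow(sub),
          slope = fit$coefficients[["slope"]],
          intercept = fit$coefficients[["intercept"]],
          r2_wls = r2_weighted(fit, x, y),
          ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
          ci_excludes_zero = ci[["lower"]] > 0 || ci[["upper"]] < 0,
          converged = fit$converged,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(), response = character(),
                 n_obs = integer(), slope = numeric(), intercept = numeric(),
                 r2_wls = numeric(), ci_lower = numeric(),
                 ci_upper = numeric(), ci_excludes_zero = logical(),
                 converged = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
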