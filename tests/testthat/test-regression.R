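test_that("exactly collinear data return the interpolating line, weights 1", {
  x <- seq(129, 1437, length.out = 20)
  fit <- robust_fit(x, 0.9 - 4e-4 * x)
  expect_equal(unname(fit$coefficients), c(0.9, -4e-4))
  expect_true(all(fit$weights == 1))
  expect_true(fit$converged)
})

test_that("robust slope recovers a known truth over repeated simulation", {
  set.seed(61)
  slopes <- replicate(200, {
    x <- runif(60, 129, 1437)
    y <- 1 - 4e-4 * x + rnorm(60, 0, 0.05)
    robust_fit(x, y)$coefficients[["slope"]]
  })
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 4e-4), 3 * mc_se)
})

test_that("a gross outlier is downweighted and pulls the fit less than OLS", {
  x <- seq(1, 60)
  y <- 2 + 0.5 * x
  y[30] <- y[30] + 200
  fit <- robust_fit(x, y)
  ols <- coef(lm(y ~ x))
  expect_lt(fit$weights[30], 0.05)
  expect_lt(abs(fit$coefficients[["slope"]] - 0.5),
            abs(ols[["x"]] - 0.5))
  expect_lt(abs(fit$coefficients[["slope"]] - 0.5), 1e-3)
})

test_that("IRLS agrees with the MASS M-estimator on noisy data", {
  set.seed(62)
  for (i in 1:5) {
    x <- runif(60, 129, 1437)
    y <- 1 - 4e-4 * x + rnorm(60, 0, 0.1)
    y[sample(60, 2)] <- y[sample(60, 2)] + 1
    ours <- robust_fit(x, y)
    mass <- MASS::rlm(cbind(1, x), y, psi = MASS::psi.huber, k = 1.345,
                      maxit = 50, acc = 1e-10, scale.est = "MAD")
    expect_equal(unname(ours$coefficients), unname(coef(mass)),
                 tolerance = 1e-6)
  }
})

test_that("robust fit validates its inputs", {
  expect_error(robust_fit(1:2, 1:2), "length")
  expect_error(robust_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(robust_fit(c(1, 2, NA), 1:3), "missing")
})

test_that("with an infinite tuning constant the fit reduces to OLS", {
  set.seed(63)
  x <- runif(40)
  y <- 2 - x + rnorm(40, 0, 0.5)
  fit <- robust_fit(x, y, k = 1e12)
  expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-8)
  expect_true(all(fit$weights == 1))
})

test_that("R2_WLS is 1 for perfect fits, equals ordinary R2 at unit weights", {
  x <- seq(129, 1437, length.out = 30)
  y0 <- 1 - 4e-4 * x
  fit0 <- robust_fit(x, y0)
  expect_equal(r2_weighted(fit0, x, y0), 1)

  set.seed(64)
  y <- y0 + rnorm(30, 0, 0.2)
  fit <- robust_fit(x, y, k = 1e12)  # all weights 1
  expect_equal(r2_weighted(fit, x, y), summary(lm(y ~ x))$r.squared,
               tolerance = 1e-8)

  expect_error(r2_weighted(fit0, x, rep(1, 30) * 0 + y0 * 0 + 2), "undefined")
})

test_that("slope forced to zero on centred data scores R2 of zero", {
  set.seed(65)
  x <- runif(30)
  y <- rnorm(30)
  fit <- robust_fit(x, y, k = 1e12)
  fit$coefficients[] <- c(mean(y), 0)
  fit$weights[] <- 1
  expect_equal(r2_weighted(fit, x, y), 0, tolerance = 1e-8)
})

test_that("bootstrap CI is deterministic, degenerate on noiseless lines", {
  x <- seq(129, 1437, length.out = 30)
  set.seed(66)
  y <- 1 - 4e-4 * x + rnorm(30, 0, 0.05)
  ci1 <- bootstrap_slope_ci(x, y, n_replicates = 200, seed = 5)
  ci2 <- bootstrap_slope_ci(x, y, n_replicates = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], ci1[["upper"]])

  y0 <- 1 - 4e-4 * x
  ci0 <- bootstrap_slope_ci(x, y0, n_replicates = 100, seed = 6)
  expect_equal(c(ci0[["lower"]], ci0[["upper"]]), c(-4e-4, -4e-4))
})

test_that("bootstrap intervals narrow as the sample grows", {
  width <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 129, 1437)
    y <- 1 - 4e-4 * x + rnorm(n, 0, 0.1)
    ci <- bootstrap_slope_ci(x, y, n_replicates = 300, seed = seed)
    ci[["upper"]] - ci[["lower"]]
  }
  w30 <- mean(vapply(1:5, function(s) width(30, s), numeric(1)))
  w120 <- mean(vapply(1:5, function(s) width(120, s), numeric(1)))
  expect_lt(w120, w30)
})

test_that("gradient analysis emits per-group and combined rows with flags", {
  set.seed(67)
  n <- 40
  mk <- function(group, slope) {
    map <- runif(n, 129, 1437)
    data.frame(
      plot_id = paste0(group, seq_len(n)), visit_id = "V1",
      vegetation_group = group, map_mm = map,
      pareto_alpha = 1 + slope * map + rnorm(n, 0, 0.05),
      lognormal_sigma = 1.5 - slope * map + rnorm(n, 0, 0.05),
      stringsAsFactors = FALSE
    )
  }
  dat <- rbind(mk("Grass", -4e-4), mk("Wood", 0))
  sites <- dat[, c("plot_id", "visit_id", "vegetation_group", "map_mm")]
  fits <- dat[, c("plot_id", "visit_id", "pareto_alpha", "lognormal_sigma")]
  res <- run_gradient_analysis(fits, sites, n_boot = 200, seed = 8)

  expect_setequal(unique(res$group), c("Grass", "Wood", "Combined"))
  expect_equal(nrow(res), 6)
  grass_a <- res[res$group == "Grass" & res$response == "pareto_alpha", ]
  expect_true(grass_a$ci_excludes_zero)
  expect_lt(abs(grass_a$slope + 4e-4), 5e-5)
  wood_a <- res[res$group == "Wood" & res$response == "pareto_alpha", ]
  expect_false(wood_a$ci_excludes_zero)
  expect_true(all(res$r2_wls >= 0 & res$r2_wls <= 1))

  # combined row equals an analysis of the concatenated data
  comb <- res[res$group == "Combined" & res$response == "pareto_alpha", ]
  refit <- robust_fit(dat$map_mm, dat$pareto_alpha)
  expect_equal(comb$slope, refit$coefficients[["slope"]])
  expect_equal(comb$n_obs, 80)
})

test_that("gradient analysis skips tiny groups with a warning", {
  fits <- data.frame(plot_id = c("a", "b"), visit_id = "V1",
                     pareto_alpha = c(1, 2), lognormal_sigma = c(1, 2))
  sites <- data.frame(plot_id = c("a", "b"), visit_id = "V1",
                      vegetation_group = "Tiny", map_mm = c(100, 900))
  w <- capture_warnings(res <- run_gradient_analysis(fits, sites,
                                                     n_boot = 100))
  expect_length(w, 2)  # the group itself and the combined set
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(res), 0)
})

test_that("gradient determinism: same seed gives identical tables", {
  set.seed(68)
  n <- 20
  map <- runif(n, 129, 1437)
  fits <- data.frame(plot_id = as.character(1:n), visit_id = "V1",
                     pareto_alpha = 1 - 4e-4 * map + rnorm(n, 0, 0.1),
                     lognormal_sigma = rnorm(n, 1.5, 0.1))
  sites <- data.frame(plot_id = as.character(1:n), visit_id = "V1",
                      vegetation_group = "G", map_mm = map)
  r1 <- run_gradient_analysis(fits, sites, n_boot = 150, seed = 3)
  r2 <- run_gradient_analysis(fits, sites, n_boot = 150, seed = 3)
  expect_identical(r1, r2)
})
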