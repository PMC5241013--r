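# independent numeric oracles ------------------------------------------------

pareto_loglik_fn <- function(covers, xmin) {
  n <- length(covers)
  slx <- sum(log(covers))
  function(a) n * log(a) + n * a * log(xmin) - (a + 1) * slx
}

numeric_pareto_mle <- function(covers, xmin) {
  optimise(pareto_loglik_fn(covers, xmin), c(1e-6, 1e3), maximum = TRUE,
           tol = 1e-12)$maximum
}

rpareto <- function(n, alpha, xmin) xmin * (1 - runif(n))^(-1 / alpha)

# ----------------------------------------------------------------------------

test_that("eligibility requires six or more recorded species", {
  expect_false(eligible_for_sad(rep(1, 5)))
  expect_true(eligible_for_sad(rep(1, 6)))
  expect_false(eligible_for_sad(numeric(0)))
  expect_false(eligible_for_sad(c(1, 1, 1, 1, 1, 0)))  # zeros don't count
})

test_that("Pareto MLE matches the hand-computed closed form", {
  fit <- fit_pareto(c(1, 2, 4, 8), xmin = 1)
  expect_equal(fit$shape[["alpha"]], 4 / (6 * log(2)))
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
  expect_equal(fit$n_species, 4)
})

test_that("closed-form Pareto MLE equals numeric likelihood maximisation", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    xmin <- runif(1, 0.05, 2)
    covers <- rpareto(n, runif(1, 0.3, 3), xmin)
    fit <- fit_pareto(covers, xmin)
    expect_equal(fit$shape[["alpha"]], numeric_pareto_mle(covers, xmin),
                 tolerance = 1e-6)
  }
})

test_that("Pareto shape is scale equivariant", {
  set.seed(52)
  covers <- rpareto(30, 1.2, 0.099)
  a1 <- fit_pareto(covers, 0.099)$shape[["alpha"]]
  for (c in c(0.01, 10, 1234)) {
    a2 <- fit_pareto(covers * c, 0.099 * c)$shape[["alpha"]]
    expect_equal(a2, a1)
  }
})

test_that("Pareto MLE is consistent under repeated sampling", {
  set.seed(53)
  est <- replicate(100, fit_pareto(rpareto(1000, 2, 0.099),
                                   0.099)$shape[["alpha"]])
  expect_lt(abs(mean(est) - 2), 0.1)  # within 5% of truth
})

test_that("Pareto fit rejects invalid inputs", {
  expect_error(fit_pareto(c(1, 2), xmin = 1.5), "xmin")
  expect_error(fit_pareto(c(1, 1, 1), xmin = 1), "diverges")
  expect_error(fit_pareto(2), ">= 2")
  expect_error(fit_pareto(c(1, -2, 3)), "positive")
})

test_that("lognormal MLE matches logs by hand and the fitdistrplus oracle", {
  fit <- fit_lognormal(c(1, exp(2), 1, exp(2)))
  expect_equal(fit$shape[["mu"]], 1)
  expect_equal(fit$shape[["sigma"]], 1)
  expect_equal(fit$aic, 4 - 2 * fit$loglik)

  skip_if_not_installed("fitdistrplus")
  set.seed(54)
  covers <- rlnorm(40, meanlog = 0.5, sdlog = 1.3)
  fit2 <- fit_lognormal(covers)
  oracle <- fitdistrplus::fitdist(covers, "lnorm")
  expect_equal(fit2$shape[["mu"]], unname(oracle$estimate["meanlog"]),
               tolerance = 1e-6)
  expect_equal(fit2$shape[["sigma"]], unname(oracle$estimate["sdlog"]),
               tolerance = 1e-6)
  expect_equal(fit2$loglik, oracle$loglik, tolerance = 1e-8)
})

test_that("equal covers flag a degenerate lognormal fit", {
  expect_warning(fit <- fit_lognormal(rep(3, 6)), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$shape[["sigma"]], 0)
  expect_equal(fit$shape[["mu"]], log(3))
})

test_that("AIC comparison picks the lowest, breaking ties toward Pareto", {
  set.seed(55)
  covers <- rpareto(30, 1, 0.099)
  fp <- fit_pareto(covers, 0.099)
  fl <- fit_lognormal(covers)
  expect_true(compare_models(list(fp, fl)) %in% c("pareto", "lognormal"))
  # forced tie: fewer parameters wins
  fl2 <- fl; fl2$aic <- fp$aic
  expect_equal(compare_models(list(fp, fl2)), "pareto")
  # mismatched data sizes are an error
  fl3 <- fit_lognormal(covers[1:10])
  expect_error(compare_models(list(fp, fl3)), "n_species")
  expect_error(compare_models(list(fp)), ">= 2")
})

test_that("predicted RADs follow the closed-form quantiles, non-increasing", {
  set.seed(56)
  covers <- rpareto(20, 0.9, 0.099)
  fit <- fit_pareto(covers, 0.099)

  # single species: the median
  expect_equal(predict_rad(fit, 1),
               0.099 * (1 - 0.5)^(-1 / fit$shape[["alpha"]]))

  # numeric inversion oracle for several ranks
  pred <- predict_rad(fit, 15)
  for (i in c(1, 7, 15)) {
    p <- (15 - i + 0.5) / 15
    q <- uniroot(function(x) 1 - (0.099 / x)^fit$shape[["alpha"]] - p,
                 c(0.099, 1e8), tol = 1e-12)$root
    expect_equal(pred[i], q, tolerance = 1e-6)
  }
  expect_true(all(diff(pred) <= 0))

  fl <- fit_lognormal(covers)
  predl <- predict_rad(fl, 10)
  expect_true(all(diff(predl) <= 0))
  expect_equal(predl[5], qlnorm((10 - 5 + 0.5) / 10, fl$shape[["mu"]],
                                fl$shape[["sigma"]]))
})

test_that("alpha orders the evenness of predicted rank-abundance profiles", {
  # Higher alpha means the species density falls off faster with
  # increasing cover: predicted covers pile up just above xmin, so
  # relative shares become MORE similar and the Gini-Simpson evenness
  # of the predicted RAD rises; low alpha gives strong single-species
  # dominance. (Monotone in alpha; checked over a wide span.)
  evenness <- function(alpha) {
    fit <- fit_pareto(rpareto(50, alpha, 0.099), 0.099)
    fit$shape[["alpha"]] <- alpha  # evaluate at exact alpha
    simpson_index(predict_rad(fit, 30))
  }
  set.seed(57)
  ev <- vapply(c(0.3, 0.6, 1, 2, 5), evenness, numeric(1))
  expect_true(all(diff(ev) > 0))
  expect_lt(ev[1], 0.5)          # dominance regime
  expect_gt(ev[5], 29 / 30 - 0.1)  # near-equal shares
})

test_that("fit table applies eligibility and reports exclusions", {
  set.seed(58)
  m <- rbind(
    ok = c(rpareto(10, 1, 0.099), rep(0, 2)),
    few = c(rpareto(5, 1, 0.099), rep(0, 7)),
    flat = c(rep(2, 8), rep(0, 4))
  )
  colnames(m) <- sprintf("SP%02d", 1:12)
  rownames(m) <- c("A:V1", "B:V1", "C:V1")
  fits <- fit_sad_table(m)
  expect_equal(fits$plot_id, "A")
  expect_equal(fits$n_species, 10)
  excl <- attr(fits, "exclusions")
  expect_setequal(excl$plot_id, c("B", "C"))
  expect_match(excl$reason[excl$plot_id == "B"], "fewer than 6")
  expect_match(excl$reason[excl$plot_id == "C"], "degenerate")
  expect_true(fits$best_model %in% c("pareto", "lognormal"))
  # per-plot scale convention: alpha reproducible from the row itself
  covers <- m[1, ]; covers <- covers[covers > 0]
  expect_equal(fits$pareto_alpha,
               fit_pareto(covers, min(covers))$shape[["alpha"]])
})

test_that("a fixed xmin drops covers below it before fitting", {
  m <- matrix(c(0.05, 1, 2, 3, 4, 5, 6, 7), nrow = 1,
              dimnames = list("A:V1", sprintf("S%d", 1:8)))
  fits <- fit_sad_table(m, xmin = 0.099)
  expect_equal(fits$n_species, 7)
  expect_equal(fits$pareto_alpha,
               fit_pareto(c(1, 2, 3, 4, 5, 6, 7), 0.099)$shape[["alpha"]])
})
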