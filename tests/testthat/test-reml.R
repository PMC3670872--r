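# independent oracle: dense grid search on the restricted likelihood
grid_reml <- function(y, v, upper = 2, n_grid = 40001L) {
  grid <- seq(0, upper, length.out = n_grid)
  ll <- vapply(grid, reml_loglik, 0, y = y, v = v)
  grid[which.max(ll)]
}

test_that("2x2 tables convert to hand-computed log odds ratios", {
  e <- table_to_effect(10, 20, 10, 20)
  expect_equal(e$y, 0)
  expect_equal(e$v, 0.4)
  e2 <- table_to_effect(20, 40, 10, 40)
  expect_equal(e2$y, log(3))
  expect_equal(e2$v, 1 / 20 + 1 / 20 + 1 / 10 + 1 / 30)
  # zero cell: 0.5 added to every cell of that study only
  e3 <- table_to_effect(0, 10, 5, 10)
  expect_equal(e3$y, log((0.5 * 5.5) / (10.5 * 5.5)))
  expect_equal(e3$v, 1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5)
  # vectorized: a clean study is left uncorrected alongside a corrected one
  e4 <- table_to_effect(c(10, 0), c(20, 10), c(10, 5), c(20, 10))
  expect_equal(e4$y[1], 0)
  expect_equal(e4$v[2], e3$v)
})

test_that("double-zero studies are excluded with a warning", {
  expect_warning(e <- table_to_effect(c(0, 10), c(10, 20), c(0, 12), c(10, 20)),
                 "non-informative")
  expect_equal(nrow(e), 1L)
  expect_error(table_to_effect(5, 4, 1, 10), "0 <= r <= n")
})

test_that("degenerate pools: single study and perfectly homogeneous sets", {
  one <- reml_pool(data.frame(y = 0.3, v = 0.04))
  expect_equal(one$theta, 0.3)
  expect_equal(one$se, 0.2)
  expect_equal(one$tau2, 0)

  hom <- reml_pool(data.frame(y = rep(0.5, 6), v = c(0.02, 0.05, 0.1, 0.03, 0.08, 0.04)))
  expect_equal(hom$tau2, 0)
  expect_equal(hom$theta, 0.5)
})

test_that("REML matches a dense grid-search oracle on random small instances", {
  set.seed(2024)
  for (case in 1:20) {
    k <- sample(3:10, 1)
    tau2_true <- runif(1, 0, 0.3)
    v <- runif(k, 0.02, 0.3)
    y <- rnorm(k, 0.2, sqrt(v + tau2_true))
    fit <- reml_pool(data.frame(y = y, v = v))
    oracle <- grid_reml(y, v)
    expect_lt(abs(fit$tau2 - oracle), 1e-4)
  }
})

test_that("REML agrees with metafor on the same effects", {
  set.seed(7)
  v <- runif(8, 0.02, 0.2)
  y <- rnorm(8, -0.2, sqrt(v + 0.05))
  fit <- reml_pool(data.frame(y = y, v = v))
  mf <- metafor::rma(yi = y, vi = v, method = "REML")
  # the two implementations iterate to different internal stopping rules,
  # so agreement is to roughly the square root of the convergence tolerance
  expect_equal(fit$tau2, unname(mf$tau2), tolerance = 1e-3)
  expect_equal(fit$theta, unname(as.numeric(mf$beta)), tolerance = 1e-4)
  expect_equal(fit$se, unname(mf$se), tolerance = 1e-4)
})

test_that("parameters are recovered from simulated heterogeneous effects", {
  set.seed(11)
  k <- 400
  v <- runif(k, 0.02, 0.1)
  y <- rnorm(k, 0.3, sqrt(v + 0.04))
  fit <- reml_pool(data.frame(y = y, v = v))
  expect_lt(abs(fit$theta - 0.3), 3 * fit$se)
  expect_lt(abs(fit$tau2 - 0.04), 0.02)
  # pooled estimate is a weighted mean, so it lies inside the effect range
  expect_gte(fit$theta, min(y))
  expect_lte(fit$theta, max(y))
})

test_that("the pooled result carries coherent Wald inference", {
  set.seed(3)
  v <- runif(6, 0.02, 0.2)
  y <- rnorm(6, 0.4, sqrt(v))
  fit <- reml_pool(data.frame(y = y, v = v))
  expect_equal(fit$or, exp(fit$theta))
  expect_equal(fit$ci, exp(fit$theta + c(-1, 1) * qnorm(0.975) * fit$se))
  expect_equal(fit$p, 2 * pnorm(-abs(fit$theta / fit$se)))
  ci_log <- confint(fit)
  expect_equal(exp(unname(ci_log[1, ])), fit$ci)
})

test_that("arm-level two-arm networks convert to per-study effects", {
  d <- data.frame(study = rep(c("s1", "s2"), each = 2),
                  treatment = rep(c("R", "O"), 2),
                  responders = c(10L, 15L, 8L, 9L),
                  sampleSize = c(30L, 30L, 25L, 25L))
  eff <- effects_from_network(trial_network(d))
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$y[eff$study == "s1"],
               table_to_effect(10, 30, 15, 30)$y)
  pooled <- reml_pool(eff)
  expect_equal(pooled$k_studies, 2L)
})
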