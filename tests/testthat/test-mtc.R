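# Oracle values for the single-trial checks, computed in closed form from
# the 2x2 tables (Wald log-OR and variance); with sigma fixed at 0 and vague
# priors the posterior is likelihood-dominated and must match them.
wald_logor <- function(r1, n1, r2, n2) log((r2 / (n2 - r2)) / (r1 / (n1 - r1)))
wald_sd <- function(r1, n1, r2, n2) {
  sqrt(1 / r1 + 1 / (n1 - r1) + 1 / r2 + 1 / (n2 - r2))
}

test_that("single-trial posteriors match the Wald oracle under sigma = 0", {
  cases <- list(c(57L, 100L, 57L, 100L),
                c(20L, 100L, 40L, 100L),
                c(150L, 400L, 180L, 400L))
  for (cs in cases) {
    net <- single_trial(r = cs[c(1, 3)], n = cs[c(2, 4)])
    fit <- mtc_fit(net, sigma = 0, chains = 2, adapt = 1000, iter = 4000,
                   seed = 11)
    m <- coef(fit)[["d[B]"]]
    s <- summary(fit)$sd[1L]
    expect_lt(abs(m - wald_logor(cs[1], cs[2], cs[3], cs[4])), 0.05)
    expect_lt(abs(s / wald_sd(cs[1], cs[2], cs[3], cs[4]) - 1), 0.15)
  }
})

test_that("indirect contrasts equal the sum of direct contrasts on a consistent chain", {
  net <- chain_network(per_arm = 2000, d_ab = 0.4, d_bc = 0.3)
  fit <- mtc_fit(net, chains = 2, adapt = 1500, iter = 4000, seed = 5)
  cc <- contrast_estimates(fit)
  get <- function(t1, t2) cc$logOR_mean[cc$t1 == t1 & cc$t2 == t2]
  # A-C has no direct trials; its estimate must be the A-B + B-C sum
  expect_lt(abs(get("A", "C") - (get("A", "B") + get("B", "C"))), 1e-9)
  expect_lt(abs(get("A", "B") - 0.4), 0.1)
  expect_lt(abs(get("B", "C") - 0.3), 0.1)
})

test_that("sampler agrees with an independent JAGS fit of the same model", {
  sk <- generate_skeleton(n_treatments = 3, n_trials = 8, n_arms = 17,
                          n_participants = 3000, seed = 5)
  net <- simulate_responses(sk, response_model(0.5, c(T02 = 0.3, T03 = -0.2)),
                            seed = 9)
  fit <- mtc_fit(net, seed = 3)
  s <- summary(fit)

  library(rjags)
  trts <- treatments(net)
  dat <- as.data.frame(net)
  dat$t <- match(dat$treatment, trts)
  studies <- unique(dat$study)
  ns <- length(studies)
  na <- vapply(split(dat, dat$study)[studies], nrow, 0L)
  mx <- max(na)
  tm <- rm <- nm <- matrix(NA_integer_, ns, mx)
  for (i in seq_len(ns)) {
    sdat <- dat[dat$study == studies[i], ]
    tm[i, seq_len(nrow(sdat))] <- sdat$t
    rm[i, seq_len(nrow(sdat))] <- sdat$responders
    nm[i, seq_len(nrow(sdat))] <- sdat$sampleSize
  }
  model <- "
  model {
    for (i in 1:ns) {
      w[i,1] <- 0; delta[i,1] <- 0
      mu[i] ~ dnorm(0, 1/225)
      for (j in 1:na[i]) {
        r[i,j] ~ dbin(p[i,j], n[i,j])
        logit(p[i,j]) <- mu[i] + delta[i,j]
      }
      for (j in 2:na[i]) {
        delta[i,j] ~ dnorm(md[i,j], taud[i,j])
        md[i,j] <- d[t[i,j]] - d[t[i,1]] + sw[i,j]
        taud[i,j] <- (1/(sigma*sigma)) * 2*(j-1)/j
        w[i,j] <- delta[i,j] - d[t[i,j]] + d[t[i,1]]
        sw[i,j] <- sum(w[i,1:(j-1)])/(j-1)
      }
    }
    d[1] <- 0
    for (tt in 2:nt) { d[tt] ~ dnorm(0, 1/225) }
    sigma ~ dunif(0, 5)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(ns = ns, na = na, t = tm, r = rm,
                                      n = nm, nt = 3),
                          n.chains = 2, n.adapt = 2000, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("d", "sigma"), n.iter = 10000)
  jstat <- summary(samp)$statistics
  expect_lt(abs(s$mean[s$parameter == "d[T02]"] - jstat["d[2]", "Mean"]), 0.03)
  expect_lt(abs(s$mean[s$parameter == "d[T03]"] - jstat["d[3]", "Mean"]), 0.03)
  expect_lt(abs(s$sd[s$parameter == "d[T02]"] / jstat["d[2]", "SD"] - 1), 0.15)
  expect_lt(abs(s$sd[s$parameter == "d[T03]"] / jstat["d[3]", "SD"] - 1), 0.15)
})

test_that("contrast tables enumerate all unordered pairs with antisymmetry", {
  sk <- generate_skeleton(n_treatments = 4, n_trials = 8, n_arms = 17,
                          n_participants = 2000, seed = 6)
  net <- simulate_responses(sk, seed = 2)
  fit <- do.call(mtc_fit, c(list(net, seed = 4), fast_mcmc))
  cc <- contrast_estimates(fit)
  expect_equal(nrow(cc), 6L)  # 4 * 3 / 2
  expect_equal(cc$OR, exp(cc$logOR_mean))
  expect_equal(cc$significant, cc$lo95 > 1 | cc$hi95 < 1)
  # reversing a pair negates the log-OR: rebuild with reversed treatment order
  pooled_ab <- cc$logOR_mean[cc$t1 == "T01" & cc$t2 == "T02"]
  draws <- fit$draws[, "d[T02]", ]
  expect_equal(pooled_ab, mean(draws), tolerance = 1e-10)
  expect_error(contrast_estimates(fit, alpha = 1.2), "alpha")
})

test_that("credible-interval rule matches draw quantiles", {
  net <- single_trial(r = c(30L, 45L), n = c(80L, 80L))
  fit <- mtc_fit(net, sigma = 0, chains = 2, adapt = 1000, iter = 4000,
                 seed = 2)
  cc <- contrast_estimates(fit, rule = "credible")
  dd <- c(fit$draws[, "d[B]", ])
  expect_equal(cc$lo95, exp(unname(quantile(dd, 0.025))), tolerance = 1e-10)
  expect_equal(cc$hi95, exp(unname(quantile(dd, 0.975))), tolerance = 1e-10)
})

test_that("rank probabilities are doubly stochastic and symmetric under the null", {
  sk <- generate_skeleton(n_treatments = 4, n_trials = 12, n_arms = 24,
                          n_participants = 4000, seed = 3)
  net <- simulate_responses(sk, seed = 8)
  fit <- do.call(mtc_fit, c(list(net, seed = 1), fast_mcmc))
  rp <- rank_probabilities(fit)
  expect_equal(rowSums(rp), rep(1, 4), ignore_attr = TRUE)
  expect_equal(colSums(rp), rep(1, 4), ignore_attr = TRUE)
})

test_that("a strongly dominant treatment takes first rank with near certainty", {
  sk <- generate_skeleton(n_treatments = 3, n_trials = 9, n_arms = 18,
                          n_participants = 9000, seed = 4)
  net <- simulate_responses(sk, response_model(0.4, c(T03 = 1.5)), seed = 5)
  fit <- do.call(mtc_fit, c(list(net, seed = 2), fast_mcmc))
  rp <- rank_probabilities(fit)
  expect_gt(rp["T03", "1"], 0.99)
})

test_that("diagnostics require two chains and flag degenerate identical chains", {
  net <- single_trial()
  fit1 <- mtc_fit(net, sigma = 0, chains = 1, adapt = 500, iter = 500, seed = 1)
  expect_error(convergence_diagnostics(fit1), "at least 2 chains")
  fit2 <- mtc_fit(net, sigma = 0, chains = 2, adapt = 500, iter = 1000, seed = 1)
  dg <- convergence_diagnostics(fit2)
  expect_true(all(is.finite(dg$psrf)))
  expect_true(all(dg$ess > 0))
  # identical-seed chains: PSRF degenerates to exactly the within-chain value
  fit_same <- fit2
  fit_same$draws[, , 2] <- fit_same$draws[, , 1]
  dg_same <- convergence_diagnostics(fit_same)
  expect_equal(dg_same$psrf[dg_same$parameter == "d[B]"],
               sqrt((nrow(fit_same$draws) - 1) / nrow(fit_same$draws)),
               tolerance = 1e-6)
})

test_that("fitting refuses skeletons and disconnected networks", {
  sk <- two_treatment_skeleton(3, 30)
  expect_error(mtc_fit(sk), "unset responders")
})
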