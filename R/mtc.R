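#' Fit a Bayesian random-effects mixed-treatment-comparison model
#'
#' Fits the standard arm-based binomial-logit consistency model to a
#' connected network of trials by Markov chain Monte Carlo.  For arm `k` of
#' trial `i`, `r_ik ~ Binomial(n_ik, p_ik)` with
#' `logit(p_ik) = mu_i + delta_ik`; `delta` is 0 for the trial's baseline
#' arm (its first listed arm), and the non-baseline `delta` vector of a
#' trial is multivariate normal around the basic-parameter contrasts with
#' variance `sigma^2` and pairwise covariance `sigma^2 / 2` (the
#' homogeneous-variance multi-arm assumption).  All contrasts are expressed
#' through basic parameters `d_t` relative to the first treatment in
#' `treatments(net)`.
#'
#' Priors are deliberately vague on the log-odds scale: trial baselines and
#' basic parameters are `N(0, prior_sd^2)` with `prior_sd = 15`, and the
#' between-trial SD has a `Uniform(0, sigma_max)` prior with
#' `sigma_max = 5`.  The sampler is Metropolis-within-Gibbs with
#' per-parameter step sizes adapted during burn-in; it uses a non-centered
#' parameterization of the random effects so that mixing does not degrade
#' when the heterogeneity posterior concentrates near zero.
#'
#' @param net a connected `trial_network` with responders set.
#' @param prior_sd prior SD of trial baselines and basic parameters
#'   (log-odds scale).
#' @param sigma_max upper bound of the uniform prior on the between-trial SD.
#' @param sigma if non-`NULL`, fix the between-trial SD at this value
#'   instead of sampling it (e.g. `sigma = 0` for a fixed-effect fit; used
#'   by the likelihood-domination oracle checks).
#' @param chains number of chains.
#' @param adapt burn-in/adaptation sweeps per chain (discarded).
#' @param iter sampling sweeps per chain.
#' @param thin thinning interval.
#' @param seed integer seed; each chain runs on its own derived substream.
#' @return An object of class `mtc_fit` with components `draws` (array
#'   `iterations x parameters x chains`; parameters are the basic log-odds
#'   ratios `d[treatment]` versus the reference, then `sigma`),
#'   `treatments`, `accept` (acceptance rates per block and chain), and the
#'   settings used.
#' @seealso [contrast_estimates()], [rank_probabilities()],
#'   [convergence_diagnostics()]
#' @examples
#' net <- simulate_responses(generate_skeleton(n_treatments = 3, n_trials = 6,
#'                                             n_arms = 12,
#'                                             n_participants = 1200,
#'                                             seed = 7),
#'                           seed = 7)
#' fit <- mtc_fit(net, chains = 2, adapt = 500, iter = 1000, seed = 1)
#' coef(fit)
#' @export
mtc_fit <- function(net, prior_sd = 15, sigma_max = 5, sigma = NULL,
                    chains = 2L, adapt = 5000L, iter = 10000L, thin = 1L,
                    seed = 1L) {
  stopifnot(inherits(net, "trial_network"))
  if (any(is.na(net$responders))) {
    stop("network has unset responders; fill the skeleton first (simulate_responses)")
  }
  if (!igraph::is_connected(comparison_graph(net))) {
    stop("comparison graph is disconnected; the model is not identified")
  }
  if (chains < 1L || adapt < 1L || iter < 1L || thin < 1L) {
    stop("chains, adapt, iter and thin must all be positive")
  }
  trts <- treatments(net)
  k <- length(trts)

  # arms grouped by trial in order of first appearance; first arm = baseline
  study_order <- unique(net$study)
  ord <- order(match(net$study, study_order))
  dat <- as.data.frame(net)[ord, ]
  trial_id <- match(dat$study, study_order)
  trial_first <- match(seq_along(study_order), trial_id)
  trial_size <- tabulate(trial_id)

  fix_sigma <- !is.null(sigma)
  if (fix_sigma && sigma < 0) stop("fixed sigma must be non-negative")

  n_save <- iter %/% thin
  draws <- array(NA_real_, dim = c(n_save, k, chains))
  accept <- matrix(NA_real_, nrow = 4L, ncol = chains,
                   dimnames = list(c("mu", "z", "d", "sigma"), NULL))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  for (ch in seq_len(chains)) {
    set.seed(rep_seed(seed, ch))
    res <- .mtc_run_chain(
      arm_trial = trial_id - 1L,
      arm_treat = match(dat$treatment, trts) - 1L,
      arm_r = dat$responders, arm_n = dat$sampleSize,
      trial_first = trial_first - 1L, trial_size = trial_size,
      k = k, prior_sd = prior_sd, sigma_max = sigma_max,
      fix_sigma = fix_sigma, sigma_value = if (fix_sigma) sigma else 0,
      n_adapt = as.integer(adapt), n_iter = as.integer(iter),
      thin = as.integer(thin))
    draws[, , ch] <- res$draws
    accept[, ch] <- res$accept
  }
  dimnames(draws) <- list(NULL,
                          c(sprintf("d[%s]", trts[-1L]), "sigma"),
                          paste0("chain", seq_len(chains)))
  structure(list(draws = draws, treatments = trts,
                 reference = trts[1L], accept = accept,
                 prior = list(prior_sd = prior_sd, sigma_max = sigma_max,
                              sigma_fixed = sigma),
                 mcmc = list(chains = chains, adapt = adapt, iter = iter,
                             thin = thin, seed = seed),
                 network = c(trials = n_trials(net), arms = n_arms(net),
                             treatments = k,
                             participants = n_participants(net)),
                 call = match.call()),
            class = "mtc_fit")
}

# pooled (all-chain) draw matrix of basic parameters, reference column
# included as zero, in treatment order
basic_draws <- function(fit, include_reference = TRUE) {
  k <- length(fit$treatments)
  dm <- fit$draws[, seq_len(k - 1L), , drop = FALSE]
  # flatten iterations and chains, keeping parameters as columns
  pooled <- matrix(aperm(dm, c(1L, 3L, 2L)),
                   nrow = dim(dm)[1L] * dim(dm)[3L], ncol = k - 1L)
  colnames(pooled) <- fit$treatments[-1L]
  if (include_reference) {
    pooled <- cbind(matrix(0, nrow(pooled), 1L,
                           dimnames = list(NULL, fit$treatments[1L])), pooled)
  }
  pooled
}

#' @export
print.mtc_fit <- function(x, ...) {
  cat(sprintf("Bayesian MTC model (binomial-logit, random effects)\n"))
  cat(sprintf("Network: %d trials, %d arms, %d treatments, %d participants\n",
              x$network["trials"], x$network["arms"], x$network["treatments"],
              x$network["participants"]))
  cat(sprintf("Reference treatment: %s\n", x$reference))
  cat(sprintf("MCMC: %d chain(s) x %d sampling sweeps (burn-in %d, thin %d)\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$adapt, x$mcmc$thin))
  cat("Posterior means of basic parameters (log-OR vs reference):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.mtc_fit <- function(object, ...) {
  k <- length(object$treatments)
  pooled <- basic_draws(object, include_reference = FALSE)
  est <- colMeans(pooled)
  names(est) <- sprintf("d[%s]", object$treatments[-1L])
  est
}

#' Summarize an MTC fit
#'
#' @param object an `mtc_fit`.
#' @param ... ignored.
#' @return data frame of posterior mean, SD, central 95% interval, potential
#'   scale reduction factor and effective sample size for each basic
#'   parameter and the heterogeneity SD.
#' @export
summary.mtc_fit <- function(object, ...) {
  pars <- dimnames(object$draws)[[2L]]
  pooled <- apply(object$draws, 2L, identity)  # draws*chains x params
  qs <- t(apply(pooled, 2L, stats::quantile, probs = c(0.025, 0.975)))
  diag <- convergence_diagnostics(object, error_on_single_chain = FALSE)
  out <- data.frame(parameter = pars, mean = colMeans(pooled),
                    sd = apply(pooled, 2L, stats::sd),
                    lo95 = qs[, 1L], hi95 = qs[, 2L],
                    psrf = diag$psrf, ess = diag$ess,
                    row.names = NULL)
  class(out) <- c("summary.mtc_fit", "data.frame")
  out
}

#' @export
print.summary.mtc_fit <- function(x, ...) {
  cat("Posterior summary (pooled over chains):\n")
  y <- x
  class(y) <- "data.frame"
  y[-1L] <- lapply(y[-1L], function(v) round(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Trace plots of an MTC fit
#'
#' @param x an `mtc_fit`.
#' @param parameters which parameters to plot (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mtc_fit <- function(x, parameters = dimnames(x$draws)[[2L]], ...) {
  pars <- match.arg(parameters, dimnames(x$draws)[[2L]], several.ok = TRUE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (p in pars) {
    graphics::matplot(x$draws[, p, ], type = "l", lty = 1,
                      xlab = "iteration", ylab = p, main = p, ...)
  }
  invisible(x)
}

#' Pairwise contrast estimates from a fitted MTC model
#'
#' Computes all `k(k-1)/2` pairwise log odds-ratio contrasts from the
#' posterior draws of the basic parameters.  Each contrast is reported as
#' the second-named treatment relative to the first (log-OR
#' `d[t2] - d[t1]`), with posterior mean and SD, the odds ratio, interval
#' bounds on the OR scale, and a significance flag set when the interval
#' excludes 1 — the criterion under which a contrast counts as a (false)
#' positive in the null simulations.
#'
#' Two interval rules are available: `"normal"` (default) builds
#' `exp(mean +/- z * SD)` from the posterior mean and standard error of the
#' log-OR, the usual OR-and-standard-error route; `"credible"` uses
#' equal-tailed sample quantiles of the draws.
#'
#' @param fit an `mtc_fit`.
#' @param alpha two-sided significance level in (0, 1); the interval has
#'   coverage `1 - alpha`.
#' @param rule `"normal"` or `"credible"`.
#' @return data frame of class `mtc_contrasts` with columns `pair`, `t1`,
#'   `t2`, `logOR_mean`, `logOR_sd`, `OR`, `lo95`, `hi95`, `significant`
#'   (interval bounds are at the requested level even when `alpha != 0.05`;
#'   the column names follow the conventional 95% layout).
#' @export
contrast_estimates <- function(fit, alpha = 0.05,
                               rule = c("normal", "credible")) {
  stopifnot(inherits(fit, "mtc_fit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  rule <- match.arg(rule)
  pooled <- basic_draws(fit)
  trts <- fit$treatments
  pairs <- utils::combn(length(trts), 2L)
  m <- ncol(pairs)
  mean_l <- sd_l <- lo <- hi <- numeric(m)
  for (j in seq_len(m)) {
    dd <- pooled[, pairs[2L, j]] - pooled[, pairs[1L, j]]
    mean_l[j] <- mean(dd)
    sd_l[j] <- stats::sd(dd)
    if (rule == "normal") {
      zq <- stats::qnorm(1 - alpha / 2)
      lo[j] <- exp(mean_l[j] - zq * sd_l[j])
      hi[j] <- exp(mean_l[j] + zq * sd_l[j])
    } else {
      q <- stats::quantile(dd, probs = c(alpha / 2, 1 - alpha / 2),
                           names = FALSE)
      lo[j] <- exp(q[1L]); hi[j] <- exp(q[2L])
    }
  }
  out <- data.frame(
    pair = sprintf("%s vs %s", trts[pairs[2L, ]], trts[pairs[1L, ]]),
    t1 = trts[pairs[1L, ]], t2 = trts[pairs[2L, ]],
    logOR_mean = mean_l, logOR_sd = sd_l, OR = exp(mean_l),
    lo95 = lo, hi95 = hi,
    significant = lo > 1 | hi < 1,
    stringsAsFactors = FALSE)
  structure(out, alpha = alpha, rule = rule,
            class = c("mtc_contrasts", "data.frame"))
}

#' Write a contrast table as CSV
#'
#' @param contrasts an `mtc_contrasts` table.
#' @param path file path.
#' @export
write_contrasts <- function(contrasts, path) {
  utils::write.csv(as.data.frame(contrasts), path, row.names = FALSE)
  invisible(path)
}

#' Dump posterior draws to a columnar CSV
#'
#' One column per monitored parameter plus a `chain` column; useful for
#' external diagnostics tooling.
#'
#' @param fit an `mtc_fit`.
#' @param path file path.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "mtc_fit"))
  pars <- dimnames(fit$draws)[[2L]]
  nchain <- dim(fit$draws)[3L]
  out <- do.call(rbind, lapply(seq_len(nchain), function(ch) {
    data.frame(chain = ch, fit$draws[, , ch], check.names = FALSE)
  }))
  names(out) <- c("chain", pars)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Treatment rank probabilities
#'
#' For each posterior draw, treatments are ranked by their basic parameter
#' (rank 1 = best); entry `(t, j)` of the result is the fraction of draws in
#' which treatment `t` holds rank `j`.  Rows and columns each sum to 1.
#'
#' @param fit an `mtc_fit`.
#' @param higher_is_better sign convention: if `TRUE` (default) a larger
#'   log-odds of response means a better treatment.
#' @return `k x k` matrix of rank probabilities (rows = treatments,
#'   columns = ranks).
#' @export
rank_probabilities <- function(fit, higher_is_better = TRUE) {
  pooled <- basic_draws(fit)
  if (!higher_is_better) pooled <- -pooled
  k <- ncol(pooled)
  counts <- matrix(0, k, k, dimnames = list(fit$treatments, seq_len(k)))
  for (s in seq_len(nrow(pooled))) {
    rk <- rank(-pooled[s, ], ties.method = "random")
    counts[cbind(seq_len(k), rk)] <- counts[cbind(seq_len(k), rk)] + 1
  }
  counts / nrow(pooled)
}

#' Convergence diagnostics for an MTC fit
#'
#' Potential scale reduction factor (between/within-chain variance ratio)
#' and effective sample size per monitored parameter.  The PSRF needs at
#' least two chains.
#'
#' @param fit an `mtc_fit`.
#' @param error_on_single_chain internal; if `FALSE`, return `NA` PSRF for a
#'   single chain instead of erroring.
#' @return data frame with columns `parameter`, `psrf`, `ess`.
#' @export
convergence_diagnostics <- function(fit, error_on_single_chain = TRUE) {
  nchain <- dim(fit$draws)[3L]
  pars <- dimnames(fit$draws)[[2L]]
  if (nchain < 2L && error_on_single_chain) {
    stop("convergence diagnostics require at least 2 chains")
  }
  psrf <- vapply(pars, function(p) {
    if (nchain < 2L) return(NA_real_)
    gelman_rubin(fit$draws[, p, ])
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    sum(apply(fit$draws[, p, , drop = FALSE], 3L, ess_one_chain))
  }, numeric(1))
  data.frame(parameter = pars, psrf = psrf, ess = ess, row.names = NULL)
}

# classic Gelman-Rubin statistic from an iterations x chains matrix
gelman_rubin <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W <= 0) return(1)  # degenerate (e.g. identical chains or fixed value)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size of one chain: n / (1 + 2 * sum of positive-lag
# autocorrelations, truncated at the first non-positive one)
ess_one_chain <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  cut <- which(rho <= 0)
  if (length(cut) > 0L) rho <- rho[seq_len(cut[1L] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}
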