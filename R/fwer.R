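#' Count significant contrasts in a contrast table
#'
#' @param contrasts an `mtc_contrasts` table (or any data frame with a
#'   logical `significant` column).
#' @return integer number of contrasts flagged significant.
#' @export
count_significant <- function(contrasts) {
  sum(contrasts$significant)
}

#' Independent-comparisons binomial reference
#'
#' If the `m` pairwise comparisons were independent tests each at level `p`,
#' the number of false positives would be Binomial(`m`, `p`): expectation
#' `m * p` and probability of at least one `1 - (1 - p)^m`.  Used as the
#' no-protection yardstick against which the simulated network
#' meta-analysis error rates are judged.
#'
#' @param m number of comparisons.
#' @param p per-comparison significance level in (0, 1).
#' @return list with `expected` (= `m * p`) and `p_any`
#'   (= `1 - (1 - p)^m`).
#' @export
binomial_reference <- function(m, p = 0.05) {
  if (m < 1) stop("m must be at least 1")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  list(expected = m * p, p_any = 1 - (1 - p)^m)
}

#' Bonferroni-corrected per-comparison level
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Run the null-simulation family-wise error experiment
#'
#' The full Monte Carlo pipeline: one network skeleton is generated once
#' (the design is fixed; only responses vary across replications, mirroring
#' a study that re-randomizes outcomes over a fixed evidence base), each
#' replication fills the skeleton with null responses, fits the MTC model,
#' flags the pairwise contrasts whose interval excludes an odds ratio of 1,
#' and records the count of significant contrasts.  The summary holds the
#' frequency distribution of that count, the family-wise positive rate
#' `P(X >= 1)`, its expectation `E[X]`, the independent-binomial reference,
#' and per-contrast significance frequencies.
#'
#' A replication whose fit shows a potential scale reduction factor above
#' `psrf_limit` is re-fitted once with doubled iterations; if it still fails
#' it is excluded from the denominators and reported in `excluded` (never
#' silently kept or dropped).
#'
#' Per-contrast posterior means and SDs are cached in the summary, so
#' significance can be recounted at other alpha levels without re-fitting
#' (see [recount_significant()]).
#'
#' @param skeleton a `trial_network` skeleton; defaults to the emulated
#'   12-treatment antidepressant network from [generate_skeleton()] with
#'   `skeleton_seed`.
#' @param model a [response_model()]; default null at 0.57.
#' @param n_reps number of replications.
#' @param alpha per-comparison significance level.
#' @param rule interval rule passed to [contrast_estimates()].
#' @param chains,adapt,iter,thin MCMC settings per replication (see
#'   [mtc_fit()]).
#' @param seed master seed; replication `i` uses substream `(seed, i)` for
#'   both its responses and its sampler.
#' @param skeleton_seed seed for the default skeleton when `skeleton` is
#'   missing.
#' @param psrf_limit convergence threshold triggering the one retry.
#' @param checkpoint_dir if non-`NULL`, per-replication results are written
#'   there as they complete (`rep_<i>.csv`) and already-present replications
#'   are reloaded instead of re-fitted, so interrupted runs resume.
#' @param regenerate_skeleton if `TRUE`, a fresh skeleton is drawn per
#'   replication (topology sensitivity analysis) instead of the fixed-design
#'   default.
#' @param verbose print per-replication progress.
#' @return object of class `fwer_summary`; see [distribution_table()],
#'   [recount_significant()] and the `print`/`summary`/`plot` methods.
#' @export
fwer_experiment <- function(skeleton = NULL, model = response_model(),
                            n_reps = 1000L, alpha = 0.05,
                            rule = c("normal", "credible"),
                            chains = 2L, adapt = 5000L, iter = 10000L,
                            thin = 1L, seed = 1L, skeleton_seed = 117L,
                            psrf_limit = 1.05, checkpoint_dir = NULL,
                            regenerate_skeleton = FALSE, verbose = FALSE) {
  rule <- match.arg(rule)
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(skeleton)) skeleton <- generate_skeleton(seed = skeleton_seed)
  stopifnot(inherits(skeleton, "trial_network"))
  if (!is_skeleton(skeleton)) {
    stop("skeleton must have responders unset")
  }
  k <- length(treatments(skeleton))
  m <- k * (k - 1L) / 2L
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }

  mean_mat <- sd_mat <- matrix(NA_real_, nrow = n_reps, ncol = m)
  sig_mat <- matrix(NA, nrow = n_reps, ncol = m)
  excluded <- integer(0)
  pair_names <- NULL

  for (i in seq_len(n_reps)) {
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("rep_%04d.csv", i)) else NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      cc <- utils::read.csv(ckpt, stringsAsFactors = FALSE)
    } else {
      sk <- if (regenerate_skeleton)
        generate_skeleton(n_treatments = k,
                          n_trials = n_trials(skeleton),
                          n_arms = n_arms(skeleton),
                          n_participants = n_participants(skeleton),
                          seed = rep_seed(seed, n_reps + i))
      else skeleton
      net <- simulate_responses(sk, model, seed = rep_seed(seed, i))
      fit <- mtc_fit(net, chains = chains, adapt = adapt, iter = iter,
                     thin = thin, seed = rep_seed(seed, i))
      diag <- convergence_diagnostics(fit, error_on_single_chain = FALSE)
      if (chains >= 2L && any(diag$psrf > psrf_limit, na.rm = TRUE)) {
        fit <- mtc_fit(net, chains = chains, adapt = 2L * adapt,
                       iter = 2L * iter, thin = thin,
                       seed = rep_seed(seed, i) + 1L)
        diag <- convergence_diagnostics(fit, error_on_single_chain = FALSE)
        if (any(diag$psrf > psrf_limit, na.rm = TRUE)) {
          excluded <- c(excluded, i)
          if (verbose) message(sprintf("rep %d: excluded (PSRF > %.2f after retry)",
                                       i, psrf_limit))
          next
        }
      }
      cc <- as.data.frame(contrast_estimates(fit, alpha = alpha, rule = rule))
      if (!is.null(ckpt)) utils::write.csv(cc, ckpt, row.names = FALSE)
    }
    if (is.null(pair_names)) pair_names <- cc$pair
    mean_mat[i, ] <- cc$logOR_mean
    sd_mat[i, ] <- cc$logOR_sd
    sig_mat[i, ] <- cc$significant
    if (verbose) message(sprintf("rep %d/%d: %d significant contrast(s)",
                                 i, n_reps, sum(cc$significant)))
  }

  kept <- setdiff(seq_len(n_reps), excluded)
  if (length(excluded) > 0L) {
    warning(sprintf("%d replication(s) excluded for non-convergence: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  counts <- rowSums(sig_mat[kept, , drop = FALSE])
  build_fwer_summary(counts, kept, excluded, n_reps, m, alpha, rule,
                     pair_names, mean_mat, sd_mat, sig_mat)
}

build_fwer_summary <- function(counts, kept, excluded, n_reps, m, alpha,
                               rule, pair_names, mean_mat, sd_mat, sig_mat) {
  n_eff <- length(kept)
  f <- tabulate(counts + 1L, nbins = m + 1L)
  names(f) <- 0:m
  ref <- binomial_reference(m, alpha)
  structure(list(
    counts = counts, f = f, prob = f / n_eff,
    p_any = mean(counts >= 1L), expectation = mean(counts),
    binomial_expected = ref$expected, binomial_p_any = ref$p_any,
    m = m, alpha = alpha, rule = rule, n_reps = n_reps,
    n_used = n_eff, excluded = excluded,
    per_contrast_rate = colMeans(sig_mat[kept, , drop = FALSE]),
    pair = pair_names,
    contrast_mean = mean_mat, contrast_sd = sd_mat),
    class = "fwer_summary")
}

#' Recount significant contrasts at a different alpha
#'
#' Re-applies the normal-approximation significance rule to the per-contrast
#' posterior means and SDs cached in a completed experiment, so alpha
#' sensitivity analyses (including a Bonferroni re-analysis via
#' `alpha = bonferroni_threshold(0.05, summary$m)`) require no further MCMC.
#'
#' @param x a `fwer_summary`.
#' @param alpha per-comparison level to recount at.
#' @return a new `fwer_summary` at the requested alpha (normal rule).
#' @export
recount_significant <- function(x, alpha) {
  stopifnot(inherits(x, "fwer_summary"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  kept <- setdiff(seq_len(x$n_reps), x$excluded)
  zq <- stats::qnorm(1 - alpha / 2)
  sig <- abs(x$contrast_mean) > zq * x$contrast_sd
  counts <- rowSums(sig[kept, , drop = FALSE])
  build_fwer_summary(counts, kept, x$excluded, x$n_reps, x$m, alpha,
                     "normal", x$pair, x$contrast_mean, x$contrast_sd, sig)
}

#' Frequency table of the significant-contrast count
#'
#' Rows `(x, f, p)` for `x = 0` up to the largest observed count (or
#' `truncate`): `f` is the number of replications with exactly `x`
#' significant contrasts and `p = f / n` the estimated probability
#' `P(X = x)`.  Suitable for plotting the simulation's probability
#' histogram.
#'
#' @param x a `fwer_summary`.
#' @param truncate optional upper `x` cutoff for display.
#' @return data frame with columns `x`, `f`, `p`.
#' @export
distribution_table <- function(x, truncate = NULL) {
  stopifnot(inherits(x, "fwer_summary"))
  xmax <- max(c(0L, x$counts))
  if (!is.null(truncate)) xmax <- min(xmax, truncate)
  idx <- 0:xmax
  data.frame(x = idx, f = unname(x$f[idx + 1L]), p = unname(x$prob[idx + 1L]))
}

#' @export
print.fwer_summary <- function(x, ...) {
  cat(sprintf("Null-simulation FWER experiment: %d of %d replications used (%d excluded)\n",
              x$n_used, x$n_reps, length(x$excluded)))
  cat(sprintf("%d pairwise contrasts per replication, alpha = %g, rule = %s\n",
              x$m, x$alpha, x$rule))
  cat(sprintf("P(at least one significant contrast) = %.3f\n", x$p_any))
  cat(sprintf("E[significant contrasts]            = %.3f\n", x$expectation))
  cat(sprintf("Independent binomial reference: E = %.2f, P(>=1) = %.4f\n",
              x$binomial_expected, x$binomial_p_any))
  invisible(x)
}

#' @export
summary.fwer_summary <- function(object, truncate = NULL, ...) {
  print(object)
  cat("\nDistribution of the significant-contrast count:\n")
  print(distribution_table(object, truncate = truncate), row.names = FALSE)
  invisible(object)
}

#' Histogram of the significant-contrast count distribution
#'
#' @param x a `fwer_summary`.
#' @param truncate optional upper cutoff on the x axis.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fwer_summary <- function(x, truncate = NULL, ...) {
  tab <- distribution_table(x, truncate = truncate)
  graphics::barplot(tab$p, names.arg = tab$x,
                    xlab = "number of significant contrasts",
                    ylab = "probability", ...)
  invisible(x)
}
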