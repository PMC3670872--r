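# small fixture networks built in code

# one trial, two arms
single_trial <- function(r = c(57L, 57L), n = c(100L, 100L),
                         treatments = c("A", "B")) {
  trial_network(data.frame(study = "s1", treatment = treatments,
                           responders = r, sampleSize = n,
                           stringsAsFactors = FALSE))
}

# two-treatment null network: n_trials trials of A vs B, per_arm each
two_treatment_skeleton <- function(n_trials = 20L, per_arm = 100L) {
  trial_network(data.frame(
    study = rep(sprintf("s%02d", seq_len(n_trials)), each = 2L),
    treatment = rep(c("A", "B"), n_trials),
    responders = NA_integer_,
    sampleSize = per_arm, stringsAsFactors = FALSE))
}

# A-B and B-C chain with balanced arms and planted effects; responders are
# the binomial expectations rounded, so the data are near-noise-free
chain_network <- function(per_arm = 2000L, p_base = 0.5,
                          d_ab = 0.4, d_bc = 0.3, n_each = 4L) {
  rows <- list()
  p <- function(shift) plogis(qlogis(p_base) + shift)
  for (i in seq_len(n_each)) {
    rows[[length(rows) + 1L]] <- data.frame(
      study = sprintf("ab%d", i), treatment = c("A", "B"),
      responders = as.integer(round(per_arm * c(p(0), p(d_ab)))),
      sampleSize = per_arm)
    rows[[length(rows) + 1L]] <- data.frame(
      study = sprintf("bc%d", i), treatment = c("B", "C"),
      responders = as.integer(round(per_arm * c(p(d_ab), p(d_ab + d_bc)))),
      sampleSize = per_arm)
  }
  trial_network(do.call(rbind, rows))
}

# quick MCMC settings for small, well-identified fits
fast_mcmc <- list(chains = 2L, adapt = 600L, iter = 1500L)
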