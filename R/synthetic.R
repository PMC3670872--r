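#' Generate a synthetic trial-network skeleton
#'
#' Builds a connected arm-level network skeleton with a prescribed number of
#' trials, arms, treatments and total participants.  The defaults emulate the
#' summary structure of the antidepressant evidence base analysed by the
#' large 2009 multiple-treatments meta-analysis of new-generation
#' antidepressants: 117 randomized trials with 236 treatment arms over 12
#' drugs and 25,928 participants in total.  The trial-level table of that
#' dataset is not public, so only these summary counts are matched; the
#' topology is sampled (see Details).
#'
#' @details
#' Connectivity is guaranteed by construction: the first `n_treatments - 1`
#' trials lay a random spanning tree over the treatments (each new treatment
#' is compared against a uniformly chosen earlier one); every remaining trial
#' compares a pair of treatments drawn either uniformly (`attachment = 0`,
#' the default) or with probability proportional to
#' `(degree + 1)^attachment`, a preferential-attachment option for denser
#' hub-like topologies.  The surplus `n_arms - 2 * n_trials` arms are
#' realized as third arms added to that many distinct randomly chosen trials
#' (three-arm trials being the common multi-arm case in antidepressant
#' trials); with the defaults this yields 115 two-arm and 2 three-arm trials.
#'
#' Sample sizes are allocated by [allocate_sample_sizes()] so they sum
#' exactly to `n_participants`; `dispersion` sets how unequal arm sizes are
#' around the mean (about 110 participants per arm with the defaults).
#'
#' Responders are left unset; fill them with [simulate_responses()].
#'
#' @param n_treatments number of treatments (labelled `T01`, `T02`, ...).
#' @param n_trials number of trials.
#' @param n_arms total number of arms; must be at least `2 * n_trials` and
#'   at most `3 * n_trials`.
#' @param n_participants total participants across all arms.
#' @param dispersion non-negative spread of arm sizes (coefficient of
#'   variation of the allocation weights); `0` gives the most even split.
#' @param attachment preferential-attachment exponent for edge assignment;
#'   `0` (default) draws treatment pairs uniformly.
#' @param seed integer seed; the skeleton is deterministic given the seed.
#' @return A `trial_network` skeleton.
#' @examples
#' net <- generate_skeleton(seed = 1)
#' c(trials = n_trials(net), arms = n_arms(net),
#'   participants = n_participants(net))
#' @export
generate_skeleton <- function(n_treatments = 12L, n_trials = 117L,
                              n_arms = 236L, n_participants = 25928L,
                              dispersion = 0.25, attachment = 0,
                              seed = 1L) {
  n_treatments <- as.integer(n_treatments)
  n_trials <- as.integer(n_trials)
  n_arms <- as.integer(n_arms)
  n_participants <- as.integer(n_participants)
  if (n_treatments < 2L) stop("need at least 2 treatments")
  if (n_trials < n_treatments - 1L) {
    stop("need at least n_treatments - 1 trials to connect the network")
  }
  if (n_arms < 2L * n_trials) stop("n_arms must be at least 2 * n_trials")
  if (n_arms > 3L * n_trials) {
    stop("n_arms must be at most 3 * n_trials (arms beyond two per trial are realized as third arms)")
  }
  if (n_participants < n_arms) stop("need at least one participant per arm")
  if (dispersion < 0) stop("dispersion must be non-negative")

  trts <- sprintf("T%02d", seq_len(n_treatments))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  # spanning tree: treatment j+1 compared against a uniform earlier treatment
  perm <- sample.int(n_treatments)
  pairs <- matrix(0L, nrow = n_trials, ncol = 2L)
  for (j in 2L:n_treatments) {
    pairs[j - 1L, ] <- c(perm[sample.int(j - 1L, 1L)], perm[j])
  }
  # remaining trials: uniform (or degree-weighted) random treatment pairs
  deg <- tabulate(pairs[seq_len(n_treatments - 1L), ], nbins = n_treatments)
  for (i in seq_len(n_trials - n_treatments + 1L) + n_treatments - 1L) {
    w <- (deg + 1)^attachment
    a <- sample.int(n_treatments, 1L, prob = w)
    repeat {
      b <- sample.int(n_treatments, 1L, prob = w)
      if (b != a) break
    }
    pairs[i, ] <- c(a, b)
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
  }

  # surplus arms become third arms of distinct random trials
  n_extra <- n_arms - 2L * n_trials
  arms <- lapply(seq_len(n_trials), function(i) pairs[i, ])
  if (n_extra > 0L) {
    extra_trials <- sample.int(n_trials, n_extra)
    for (i in extra_trials) {
      third <- sample(setdiff(seq_len(n_treatments), arms[[i]]), 1L)
      arms[[i]] <- c(arms[[i]], third)
    }
  }

  study_ids <- sprintf("S%03d", seq_len(n_trials))
  dat <- data.frame(
    study = rep(study_ids, lengths(arms)),
    treatment = trts[unlist(arms)],
    responders = NA_integer_,
    sampleSize = allocate_sample_sizes(n_arms, n_participants,
                                       dispersion = dispersion),
    stringsAsFactors = FALSE
  )
  trial_network(dat, treatments = trts)
}

#' Allocate arm sample sizes that sum exactly to a total
#'
#' Splits `total` participants over `n_arms` arms as positive integers with
#' an exact sum.  With `dispersion = 0` the split is as even as possible
#' (sizes differ by at most 1).  With `dispersion > 0`, sizes are drawn
#' proportional to gamma weights with coefficient of variation `dispersion`
#' and rounded by largest remainders so the total is conserved exactly.
#'
#' @param n_arms number of arms.
#' @param total total participants; must be at least `n_arms`.
#' @param dispersion non-negative weight spread; `0` = even split.
#' @param seed optional integer seed (only used when `dispersion > 0`); when
#'   `NULL` the current RNG stream is used.
#' @return integer vector of length `n_arms`, all entries `>= 1`, summing to
#'   `total`.
#' @export
allocate_sample_sizes <- function(n_arms, total, dispersion = 0, seed = NULL) {
  n_arms <- as.integer(n_arms)
  total <- as.integer(total)
  if (total < n_arms) stop("total must be at least n_arms")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (dispersion == 0) {
    base <- total %/% n_arms
    rem <- total %% n_arms
    return(rep(c(base + 1L, base), times = c(rem, n_arms - rem)))
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  shape <- 1 / dispersion^2
  w <- stats::rgamma(n_arms, shape = shape, rate = shape)
  raw <- total * w / sum(w)
  sizes <- floor(raw)
  short <- total - sum(sizes)
  if (short > 0L) {
    top_up <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[top_up] <- sizes[top_up] + 1
  }
  # repair any zero arms by borrowing from the largest
  while (any(sizes < 1)) {
    i <- which.min(sizes)
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1
    sizes[j] <- sizes[j] - 1
  }
  as.integer(sizes)
}

#' Read a generator configuration from YAML or JSON
#'
#' Accepts a file with any subset of the keys `n_treatments`, `n_trials`,
#' `n_arms`, `n_participants`, `dispersion`, `attachment`, `seed`; missing
#' keys take the [generate_skeleton()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list of generator arguments, suitable for
#'   `do.call(generate_skeleton, ...)`.
#' @export
read_generator_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("n_treatments", "n_trials", "n_arms", "n_participants",
               "dispersion", "attachment", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L) {
    stop("unknown generator config key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}

# restore (or clear) the global RNG state after a seeded section
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
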