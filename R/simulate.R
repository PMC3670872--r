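#' Response model for binary trial outcomes
#'
#' Describes how responders are generated in each arm: every participant
#' responds with probability `plogis(qlogis(baseline_p) + effect[treatment])`.
#' Under the null model (all effects zero, the default) each participant
#' responds with probability `baseline_p` regardless of which arm of which
#' trial they were randomized to.  The default `baseline_p = 0.57` is the
#' overall response rate of the antidepressant evidence base the default
#' skeleton emulates.
#'
#' @param baseline_p response probability under no treatment effect, in
#'   `[0, 1]`.
#' @param effects named numeric vector of log-odds shifts per treatment;
#'   treatments not named get effect 0.
#' @return an object of class `response_model`.
#' @export
response_model <- function(baseline_p = 0.57, effects = numeric()) {
  if (baseline_p < 0 || baseline_p > 1) stop("baseline_p must be in [0, 1]")
  if (length(effects) > 0L && is.null(names(effects))) {
    stop("effects must be a named vector (names are treatment ids)")
  }
  structure(list(baseline_p = baseline_p, effects = effects),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Response model: baseline P(response) = %.3f\n", x$baseline_p))
  if (length(x$effects) == 0L || all(x$effects == 0)) {
    cat("Treatment effects: none (null model)\n")
  } else {
    cat("Log-odds shifts:\n")
    print(x$effects)
  }
  invisible(x)
}

#' Fill a network skeleton with simulated responses
#'
#' Draws each arm's responder count as a binomial with the arm's sample size
#' and the response probability implied by the model — distributionally
#' identical to assigning every participant an independent Bernoulli
#' response, but far cheaper than 25,928 individual draws.
#'
#' @param skeleton a `trial_network` with responders unset.
#' @param model a [response_model()]; defaults to the null model at 0.57.
#' @param seed integer seed; output is deterministic given the seed.
#' @return the network with `responders` filled in.
#' @export
simulate_responses <- function(skeleton, model = response_model(), seed = NULL) {
  stopifnot(inherits(skeleton, "trial_network"))
  if (!is_skeleton(skeleton)) {
    stop("skeleton already has responders set; refusing to overwrite")
  }
  unknown <- setdiff(names(model$effects), treatments(skeleton))
  if (length(unknown) > 0L) {
    stop("effects name treatment(s) not in the network: ",
         paste(unknown, collapse = ", "))
  }
  shift <- rep(0, nrow(skeleton))
  if (length(model$effects) > 0L) {
    m <- match(skeleton$treatment, names(model$effects))
    shift[!is.na(m)] <- model$effects[m[!is.na(m)]]
  }
  p <- stats::plogis(stats::qlogis(model$baseline_p) + shift)
  # qlogis(0/1) are +-Inf; an all-or-nothing baseline stays all-or-nothing
  p[is.nan(p)] <- model$baseline_p
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  filled <- skeleton
  filled$responders <- stats::rbinom(nrow(skeleton), skeleton$sampleSize, p)
  filled
}

# Deterministic per-replication substream seed: an affine map of the master
# seed and replication index mod 2^31 - 1.  Coefficients are coprime to the
# modulus; all intermediates stay below 2^53 so the arithmetic is exact in
# doubles.  Replications are order-independent and reproducible in isolation.
rep_seed <- function(master_seed, i) {
  m <- 2147483647
  s <- (69069 * (as.numeric(master_seed) %% m)) %% m
  as.integer((s + 12345 + 104729 * as.numeric(i)) %% m)
}

#' Generate independent null (or alternative) replications of a skeleton
#'
#' Produces `n_reps` independently filled copies of the skeleton.  Each
#' replication uses its own seed derived from `(master_seed, i)`, so
#' replication `i` can be regenerated in isolation and the set of
#' replications does not depend on the order they are produced in.
#'
#' @param skeleton a `trial_network` skeleton.
#' @param model a [response_model()].
#' @param n_reps number of replications.
#' @param master_seed integer master seed.
#' @param indices which replications to generate (default all of
#'   `1:n_reps`); useful for regenerating a subset.
#' @param out_dir if non-`NULL`, each replication is also written there as
#'   arm-level CSV (`rep_<i>.csv`).
#' @return list of filled `trial_network` objects.
#' @export
replicate_null <- function(skeleton, model = response_model(), n_reps,
                           master_seed = 1L, indices = seq_len(n_reps),
                           out_dir = NULL) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  lapply(indices, function(i) {
    net <- simulate_responses(skeleton, model, seed = rep_seed(master_seed, i))
    if (!is.null(out_dir)) {
      write_network(net, file.path(out_dir, sprintf("rep_%04d.csv", i)))
    }
    net
  })
}
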