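#' Arm-level trial networks
#'
#' A `trial_network` holds arm-level data from a collection of randomized
#' trials over a common set of treatments: one row per arm, with the number
#' randomized and (optionally) the number of responders.  It is the unit of
#' data fed to [mtc_fit()].  A network whose responders are all missing is a
#' *skeleton*: the design (trials, treatments, sample sizes) is fixed but
#' outcomes have not yet been observed or simulated.
#'
#' Validity requires: every trial has at least two arms, no treatment is
#' duplicated within a trial, `0 <= responders <= sampleSize` wherever
#' responders are set, and the comparison graph (treatments as nodes, an edge
#' whenever two treatments are co-randomized in some trial) is connected.
#'
#' @param data data frame with columns `study`, `treatment`, `responders`,
#'   `sampleSize`; one row per arm.  `responders` may be `NA` (skeleton).
#'   Row order within a study is kept as arm order; the first listed arm of
#'   each trial is its baseline for model parameterization.
#' @param treatments optional character vector fixing the treatment order
#'   (the first element is the global reference for basic parameters).
#'   Defaults to the sorted unique treatments in `data`.
#' @param validate if `FALSE`, skip validation (internal use).
#' @return An object of class `trial_network`: the arm-level data frame with
#'   a `treatments` attribute.
#' @seealso [read_network()], [write_network()], [validate_network()],
#'   [generate_skeleton()]
#' @examples
#' d <- data.frame(study = c("s1", "s1", "s2", "s2"),
#'                 treatment = c("A", "B", "B", "C"),
#'                 responders = c(10L, 12L, 7L, 9L),
#'                 sampleSize = c(20L, 20L, 15L, 15L))
#' net <- trial_network(d)
#' n_trials(net)
#' @export
trial_network <- function(data, treatments = NULL, validate = TRUE) {
  required <- c("study", "treatment", "responders", "sampleSize")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[, required]
  data$study <- as.character(data$study)
  data$treatment <- as.character(data$treatment)
  data$responders <- suppressWarnings(as.integer(data$responders))
  data$sampleSize <- as.integer(data$sampleSize)
  if (is.null(treatments)) {
    treatments <- sort(unique(data$treatment))
  } else {
    treatments <- as.character(treatments)
    extra <- setdiff(unique(data$treatment), treatments)
    if (length(extra) > 0L) {
      stop("arm treatment(s) not in the treatment list: ",
           paste(extra, collapse = ", "))
    }
  }
  net <- structure(data, treatments = treatments,
                   class = c("trial_network", "data.frame"))
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0L) {
      stop("invalid trial network:\n  ",
           paste(report$message, collapse = "\n  "))
    }
  }
  net
}

#' @rdname trial_network
#' @param x,net a `trial_network`
#' @export
treatments <- function(net) attr(net, "treatments")

#' @rdname trial_network
#' @export
n_trials <- function(net) length(unique(net$study))

#' @rdname trial_network
#' @export
n_arms <- function(net) nrow(net)

#' @rdname trial_network
#' @export
n_participants <- function(net) sum(net$sampleSize)

#' @rdname trial_network
#' @export
is_skeleton <- function(net) all(is.na(net$responders))

#' @rdname trial_network
#' @param ... ignored
#' @export
print.trial_network <- function(x, ...) {
  k <- length(treatments(x))
  cat(sprintf("Trial network: %d trials, %d arms, %d treatments, %d participants\n",
              n_trials(x), n_arms(x), k, n_participants(x)))
  if (is_skeleton(x)) {
    cat("Responders: unset (skeleton)\n")
  } else {
    cat(sprintf("Pooled response rate: %.3f\n",
                sum(x$responders) / sum(x$sampleSize)))
  }
  cat("Treatments:", paste(treatments(x), collapse = ", "), "\n")
  invisible(x)
}

# comparison graph of a network as an igraph object
comparison_graph <- function(net) {
  edges <- do.call(rbind, lapply(split(net$treatment, net$study), function(tr) {
    if (length(tr) < 2L) return(NULL)
    t(utils::combn(tr, 2L))
  }))
  igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = attr(net, "treatments"))
  )
}

#' Validate a trial network
#'
#' Reports every violation of the network invariants rather than stopping at
#' the first: trials with fewer than two arms, duplicated treatments within a
#' trial, responder counts exceeding sample sizes, non-positive sample sizes,
#' and a disconnected comparison graph.  An empty report means the network is
#' valid.
#'
#' @param net a `trial_network`, or a plain data frame in the same layout.
#' @return data frame with columns `check`, `study`, `message`; zero rows iff
#'   the network is valid.
#' @export
validate_network <- function(net) {
  viol <- list()
  add <- function(check, study, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      check = check, study = study, message = message,
      stringsAsFactors = FALSE)
  }
  by_study <- split(seq_len(nrow(net)), net$study)
  for (sid in names(by_study)) {
    idx <- by_study[[sid]]
    if (length(idx) < 2L) {
      add("arm_count", sid,
          sprintf("study %s has %d arm(s); at least 2 required", sid, length(idx)))
    }
    dup <- net$treatment[idx][duplicated(net$treatment[idx])]
    if (length(dup) > 0L) {
      add("duplicate_treatment", sid,
          sprintf("study %s randomizes treatment %s in more than one arm",
                  sid, paste(unique(dup), collapse = ", ")))
    }
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!is.na(net$sampleSize[i]) && net$sampleSize[i] < 1L) {
        add("sample_size", sid,
            sprintf("study %s arm %d (treatment %s) has non-positive sample size",
                    sid, j, net$treatment[i]))
      }
      if (!is.na(net$responders[i]) &&
          (net$responders[i] < 0L || net$responders[i] > net$sampleSize[i])) {
        add("responders_range", sid,
            sprintf("study %s arm %d (treatment %s): responders %d outside [0, %d]",
                    sid, j, net$treatment[i], net$responders[i], net$sampleSize[i]))
      }
    }
  }
  trts <- if (!is.null(attr(net, "treatments"))) attr(net, "treatments") else
    sort(unique(net$treatment))
  unused <- setdiff(trts, unique(net$treatment))
  if (length(unused) > 0L) {
    add("unused_treatment", NA_character_,
        sprintf("treatment(s) %s appear in no trial", paste(unused, collapse = ", ")))
  }
  g <- tryCatch(comparison_graph(structure(net, treatments = trts)),
                error = function(e) NULL)
  if (!is.null(g) && !igraph::is_connected(g)) {
    add("connectivity", NA_character_,
        "comparison graph is disconnected: some treatment pairs have no direct or indirect comparison path")
  }
  if (length(viol) == 0L) {
    data.frame(check = character(), study = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}

#' Read and write arm-level trial networks as CSV
#'
#' The on-disk format is a comma-separated UTF-8 file with a header row and
#' columns `study,treatment,responders,sampleSize`, one row per arm — the
#' layout in common use for arm-level network meta-analysis datasets.  An
#' empty `responders` field marks a skeleton arm.  `write_network()` writes
#' rows ordered by study id then arm order, so that writing a freshly read
#' network reproduces the canonical file byte for byte.
#'
#' @param path file path.
#' @param net a valid `trial_network`.
#' @return `read_network()` returns a validated `trial_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("study", "treatment", "responders", "sampleSize")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("network CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$responders[raw$responders == ""] <- NA_character_
  trial_network(raw)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "trial_network"))
  ord <- order(net$study)  # stable: preserves arm order within a study
  out <- as.data.frame(net)[ord, c("study", "treatment", "responders", "sampleSize")]
  out$responders <- ifelse(is.na(out$responders), "", as.character(out$responders))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
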