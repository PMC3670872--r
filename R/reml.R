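#' Per-study log odds ratio from a 2x2 table
#'
#' Converts one study's 2x2 table (responders/size in each of two arms) to a
#' log odds ratio and its large-sample variance.  When any cell of the table
#' is zero, `correction` (default 0.5) is added to all four cells of that
#' study before computation; tables that carry no information about the odds
#' ratio even after correction (both arms all-responders or both arms
#' zero-responders) are rejected as non-informative.
#'
#' @param r1,n1 responders and sample size in arm 1.
#' @param r2,n2 responders and sample size in arm 2.
#' @param correction non-negative continuity correction, applied only when a
#'   zero cell exists.
#' @return data frame with columns `y` (log-OR of arm 1 versus arm 2) and
#'   `v` (its variance); one row per study (arguments are vectorized).
#' @export
table_to_effect <- function(r1, n1, r2, n2, correction = 0.5) {
  if (correction < 0) stop("correction must be non-negative")
  if (any(r1 < 0 | r2 < 0 | r1 > n1 | r2 > n2)) {
    stop("responder counts must satisfy 0 <= r <= n in both arms")
  }
  noninf <- (r1 == 0 & r2 == 0) | (r1 == n1 & r2 == n2)
  if (any(noninf)) {
    warning(sprintf("%d non-informative double-zero stud(ies) excluded",
                    sum(noninf)))
    r1 <- r1[!noninf]; n1 <- n1[!noninf]
    r2 <- r2[!noninf]; n2 <- n2[!noninf]
  }
  a <- r1; b <- n1 - r1; c_ <- r2; d <- n2 - r2
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a <- a + correction * zero; b <- b + correction * zero
  c_ <- c_ + correction * zero; d <- d + correction * zero
  data.frame(y = log(a * d / (b * c_)),
             v = 1 / a + 1 / b + 1 / c_ + 1 / d)
}

#' Random-effects pooling by restricted maximum likelihood
#'
#' Pools per-study log odds ratios under the random-effects model
#' `y_i ~ N(theta, v_i + tau^2)`.  The between-study variance `tau^2` is
#' estimated by REML via Fisher scoring, started at the DerSimonian-Laird
#' moment estimate and floored at zero; iteration stops when successive
#' `tau^2` values differ by less than `1e-8`.  The pooled effect is the
#' inverse-variance weighted mean with weights `1/(v_i + tau^2)`, with Wald
#' standard error, z statistic, two-sided p value and a 95% confidence
#' interval reported on the odds-ratio scale.
#'
#' This is the classical direct-comparison companion to the network model:
#' e.g. pooling the trials that compare one drug head-to-head against any
#' other drug, each contributing one 2x2 table, comparator identity ignored.
#'
#' @param effects data frame with columns `y` (log-OR) and `v` (variance),
#'   e.g. from [table_to_effect()].
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tol convergence tolerance on successive `tau^2` values.
#' @return object of class `reml_meta`: pooled log-OR (`theta`), `se`,
#'   `or`, `ci` (OR scale), `z`, `p`, `tau2`, `k_studies`, and the
#'   per-study inputs.
#' @export
reml_pool <- function(effects, max_iter = 200L, tol = 1e-8) {
  y <- effects$y
  v <- effects$v
  if (length(y) < 1L) stop("need at least one study effect")
  if (any(v <= 0)) stop("all within-study variances must be positive")
  k <- length(y)

  if (k == 1L) {
    tau2 <- 0
    iterations <- 0L
  } else {
    # DerSimonian-Laird start
    w <- 1 / v
    theta_fe <- sum(w * y) / sum(w)
    Q <- sum(w * (y - theta_fe)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    iterations <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- 1 / (v + tau2)
      theta <- sum(w * y) / sum(w)
      sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
      # REML score and expected information in tau^2
      score <- 0.5 * (sum(w^2 * (y - theta)^2) - sw + sw2 / sw)
      info <- 0.5 * (sw2 - 2 * sw3 / sw + (sw2 / sw)^2)
      step <- score / info
      tau2_new <- max(0, tau2 + step)
      iterations <- it
      if (abs(tau2_new - tau2) < tol) {
        tau2 <- tau2_new
        converged <- TRUE
        break
      }
      tau2 <- tau2_new
    }
    if (!converged) {
      stop(sprintf("REML did not converge in %d iterations (last tau^2 = %.6g)",
                   max_iter, tau2))
    }
  }

  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- theta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- exp(theta + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(theta = theta, se = se, or = exp(theta), ci = ci,
                 z = z, p = p, tau2 = tau2, k_studies = k,
                 iterations = iterations, effects = data.frame(y = y, v = v)),
            class = "reml_meta")
}

# restricted log-likelihood of the random-effects model at a given tau^2
# (used by the grid-search oracle in the tests, exported for reuse)
#' Restricted log-likelihood at a fixed between-study variance
#'
#' @param tau2 between-study variance.
#' @param y,v per-study effects and variances.
#' @return the restricted log-likelihood (up to an additive constant).
#' @export
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - theta)^2))
}

#' @export
print.reml_meta <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (REML), %d studies\n", x$k_studies))
  cat(sprintf("OR = %.2f, 95%% CI [%.2f, %.2f], p = %.3g\n",
              x$or, x$ci[1L], x$ci[2L], x$p))
  cat(sprintf("log-OR = %.4f (SE %.4f), tau^2 = %.4g\n", x$theta, x$se, x$tau2))
  invisible(x)
}

#' @export
summary.reml_meta <- function(object, ...) {
  print(object)
  cat("\nPer-study effects:\n")
  print(object$effects, row.names = FALSE)
  invisible(object)
}

#' @export
coef.reml_meta <- function(object, ...) {
  c(logOR = object$theta)
}

#' @export
confint.reml_meta <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  pct <- 100 * (1 - level) / 2
  matrix(object$theta + c(-1, 1) * zq * object$se, nrow = 1,
         dimnames = list("logOR", sprintf("%.1f %%", c(pct, 100 - pct))))
}

#' Direct-comparison effects from an arm-level network
#'
#' Converts each two-arm trial of an arm-level network into a per-study
#' log-OR effect (first listed arm versus second), ready for [reml_pool()].
#'
#' @param net a `trial_network` with responders set; every trial must have
#'   exactly two arms.
#' @param correction passed to [table_to_effect()].
#' @return data frame of per-study `y` and `v` with a `study` column.
#' @export
effects_from_network <- function(net, correction = 0.5) {
  stopifnot(inherits(net, "trial_network"))
  if (any(is.na(net$responders))) stop("network has unset responders")
  by_study <- split(as.data.frame(net), net$study)
  if (any(vapply(by_study, nrow, 0L) != 2L)) {
    stop("direct meta-analysis needs exactly two arms per study")
  }
  out <- do.call(rbind, lapply(by_study, function(s) {
    eff <- table_to_effect(s$responders[1L], s$sampleSize[1L],
                           s$responders[2L], s$sampleSize[2L],
                           correction = correction)
    cbind(study = s$study[1L], eff)
  }))
  rownames(out) <- NULL
  out
}
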