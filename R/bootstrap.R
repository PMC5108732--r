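#' BCa confidence interval from bootstrap resamples
#'
#' Bias-corrected and accelerated percentile interval. The bias correction
#' `z0` is the normal quantile of the fraction of resample statistics below
#' the observed value; the acceleration `a` is the jackknife skewness
#' `sum((m - t_i)^3) / (6 * sum((m - t_i)^2)^(3/2))`. The adjusted
#' percentile levels are `Phi(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha)))`
#' for each tail, and the interval endpoints are the corresponding
#' (type-7) quantiles of the resample distribution. With `z0 = a = 0` this
#' reduces to the simple percentile interval.
#'
#' Degenerate cases are flagged, never silently repaired: an all-equal
#' resample distribution collapses the interval to a point; zero jackknife
#' variance sets `a = 0`; an observed value outside its own interval is
#' reported via the `flags` field.
#'
#' @param resamples Numeric vector of bootstrap statistics.
#' @param observed Observed statistic.
#' @param jackknife Numeric vector of leave-one-out statistics.
#' @param alpha Nominal two-sided miss level (default 0.05 for a 95% CI).
#' @return List with `observed`, `lower`, `upper`, `z0`, `a`, `flags`
#'   (character vector, empty when clean).
#' @export
bca_interval <- function(resamples, observed, jackknife, alpha = 0.05) {
  stopifnot(length(resamples) >= 1, alpha > 0, alpha < 1)
  flags <- character(0)
  B <- length(resamples)
  if (max(resamples) - min(resamples) == 0) {
    return(list(observed = observed, lower = resamples[1], upper = resamples[1],
                z0 = 0, a = 0, flags = "degenerate"))
  }
  frac <- mean(resamples < observed)
  if (frac == 0 || frac == 1) {
    # observed beyond every resample; clamp the bias correction to the
    # resolution of the bootstrap and flag it
    frac <- if (frac == 0) 1 / (B + 1) else B / (B + 1)
    flags <- c(flags, "extreme_bias_correction")
  }
  z0 <- stats::qnorm(frac)
  jm <- mean(jackknife)
  d <- jm - jackknife
  s2 <- sum(d^2)
  a <- if (s2 > 0) sum(d^3) / (6 * s2^1.5) else {
    flags <- c(flags, "zero_jackknife_variance")
    0
  }
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  q <- stats::quantile(resamples, c(a1, a2), names = FALSE, type = 7)
  if (observed < q[1] || observed > q[2]) flags <- c(flags, "observed_outside")
  list(observed = observed, lower = q[1], upper = q[2], z0 = z0, a = a,
       flags = flags)
}

#' Bootstrap confidence intervals for group AHP weights
#'
#' Nonparametric bootstrap over respondents: whole respondents (their full
#' set of block weight vectors) are resampled with replacement, preserving
#' the within-person correlation of judgments across blocks, and the group
#' statistic — by default the AIP geometric-mean global weight of every
#' elicited criterion — is recomputed on each resample. Per-criterion BCa
#' intervals are then formed with [bca_interval()].
#'
#' @param fit An [ahp()] fit (its included respondents are resampled), or a
#'   named list of per-block respondent-by-member local weight matrices.
#' @param B Number of bootstrap resamples (>= 100).
#' @param alpha Nominal two-sided miss level.
#' @param seed Integer seed; intervals are reproducible given the seed.
#' @param central Central tendency used to aggregate priorities on each
#'   resample.
#' @return Object of class `ahp_boot`: data frame `intervals` with columns
#'   `node`, `observed`, `lower`, `upper`, `z0`, `a`, `flags`, plus fields
#'   `B`, `alpha`, `seed`, `n_respondents`.
#' @seealso [rank_stability()]
#' @export
ahp_boot <- function(fit, B = 1000, alpha = 0.05, seed = 1L,
                     central = "geometric") {
  if (inherits(fit, "ahp")) {
    hierarchy <- fit$hierarchy
    incl <- fit$inclusion$included
    local_mats <- lapply(fit$respondent_local,
                         function(W) W[incl, , drop = FALSE])
  } else {
    stop("fit must be an 'ahp' object")
  }
  if (B < 100) stop("B must be at least 100")
  n <- nrow(local_mats[[1]])
  if (n < 2) stop("bootstrap needs at least 2 respondents")
  elicited <- elicited_nodes(hierarchy)

  statistic <- function(idx) {
    local <- lapply(local_mats, function(W) {
      aggregate_priorities(W[idx, , drop = FALSE], central)
    })
    global_weights(hierarchy, local)[elicited]
  }

  observed <- statistic(seq_len(n))
  set.seed(seed)
  boot_stats <- matrix(NA_real_, B, length(elicited),
                       dimnames = list(NULL, elicited))
  for (b in seq_len(B)) {
    boot_stats[b, ] <- statistic(sample.int(n, n, replace = TRUE))
  }
  jack <- t(vapply(seq_len(n), function(i) statistic(setdiff(seq_len(n), i)),
                   numeric(length(elicited))))

  rows <- lapply(elicited, function(node) {
    ci <- bca_interval(boot_stats[, node], observed[[node]], jack[, node],
                       alpha = alpha)
    data.frame(node = node, observed = ci$observed, lower = ci$lower,
               upper = ci$upper, z0 = ci$z0, a = ci$a,
               flags = paste(ci$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  structure(list(intervals = do.call(rbind, rows), B = B, alpha = alpha,
                 seed = seed, n_respondents = n, central = central,
                 resamples = boot_stats),
            class = "ahp_boot")
}

#' @export
print.ahp_boot <- function(x, digits = 4, ...) {
  cat(sprintf("BCa bootstrap CIs for global weights (B = %d, %g%% CI, n = %d, seed = %d)\n",
              x$B, 100 * (1 - x$alpha), x$n_respondents, x$seed))
  tab <- x$intervals
  for (col in c("observed", "lower", "upper", "z0", "a")) {
    tab[[col]] <- round(tab[[col]], digits)
  }
  print(tab[order(-tab$observed), ], row.names = FALSE)
  invisible(x)
}

#' @export
confint.ahp_boot <- function(object, parm, level, ...) {
  ci <- object$intervals
  if (!missing(parm)) ci <- ci[ci$node %in% parm, , drop = FALSE]
  out <- as.matrix(ci[, c("lower", "upper")])
  rownames(out) <- ci$node
  colnames(out) <- paste0(100 * c(object$alpha / 2, 1 - object$alpha / 2), " %")
  out
}

#' Plot bootstrap confidence intervals
#'
#' Point estimates with CI whiskers, ordered by weight — overlapping
#' whiskers indicate ranks vulnerable to reversal.
#'
#' @param x An `ahp_boot` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ahp_boot <- function(x, ...) {
  ci <- x$intervals[order(x$intervals$observed), ]
  p <- nrow(ci)
  graphics::plot(ci$observed, seq_len(p), xlim = range(ci$lower, ci$upper),
                 yaxt = "n", ylab = "", xlab = "global weight", pch = 19, ...)
  graphics::axis(2, at = seq_len(p), labels = ci$node, las = 2)
  graphics::segments(ci$lower, seq_len(p), ci$upper, seq_len(p))
  invisible(x)
}

#' Rank stability from interval overlap
#'
#' Where confidence intervals of similarly weighted criteria overlap, the
#' risk of rank reversal is elevated; an interval overlapping no other marks
#' a robust ranking position. Reports the pairwise overlap matrix, the
#' maximal groups of mutually overlapping intervals (the cliques of the
#' interval graph, found by a sweep over interval endpoints), and the
#' robust (isolated) criteria.
#'
#' @param x An `ahp_boot` object, or a data frame with columns `node`,
#'   `lower`, `upper`.
#' @return List with `overlap` (logical matrix), `groups` (list of
#'   character vectors, each a maximal mutually-overlapping set of size >=
#'   2), `robust` (character vector).
#' @export
rank_stability <- function(x) {
  ci <- if (inherits(x, "ahp_boot")) x$intervals else x
  stopifnot(all(c("node", "lower", "upper") %in% names(ci)))
  p <- nrow(ci)
  ov <- matrix(FALSE, p, p, dimnames = list(ci$node, ci$node))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ov[i, j] <- ci$lower[i] <= ci$upper[j] & ci$lower[j] <= ci$upper[i]
    }
  }
  diag(ov) <- TRUE
  # interval-graph maximal cliques: the active sets at each left endpoint,
  # pruned to those maximal under inclusion
  cliques <- list()
  for (i in seq_len(p)) {
    active <- ci$node[ci$lower <= ci$lower[i] + 0 & ci$upper >= ci$lower[i]]
    cliques[[i]] <- sort(active)
  }
  cliques <- unique(cliques)
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  groups <- Filter(function(g) length(g) >= 2, cliques[keep])
  robust <- ci$node[rowSums(ov) == 1]
  list(overlap = ov, groups = groups, robust = robust)
}
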