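central_fun <- function(central = c("geometric", "arithmetic", "median")) {
  central <- match.arg(central)
  switch(central,
         geometric = function(x) exp(mean(log(x))),
         arithmetic = mean,
         median = stats::median)
}

#' Aggregate individual judgment matrices (AIJ)
#'
#' Combines one comparison matrix per respondent into a single group matrix
#' before weights are computed — the "group decides as a new individual"
#' model. The geometric mean is the canonical choice: applied element-wise
#' it preserves reciprocity exactly (the Aczel–Saaty result). Arithmetic
#' mean and median do not; for those the elicited upper triangle is
#' aggregated and the lower triangle mirrored by reciprocal, and a warning
#' records the axiom violation.
#'
#' @param matrices List of same-size reciprocal matrices (same block, same
#'   member order).
#' @param central `"geometric"` (default), `"arithmetic"`, or `"median"`.
#' @return The aggregated reciprocal matrix.
#' @export
aggregate_judgments <- function(matrices,
                                central = c("geometric", "arithmetic", "median")) {
  central <- match.arg(central)
  if (length(matrices) == 0) stop("no matrices to aggregate")
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1 ||
      length(unique(lapply(matrices, rownames))) != 1) {
    stop("matrices to aggregate must share block and member order")
  }
  for (A in matrices) check_reciprocal(A)
  n <- dims[1]
  f <- central_fun(central)
  if (central == "geometric") {
    out <- exp(Reduce(`+`, lapply(matrices, log)) / length(matrices))
  } else {
    warning("element-wise ", central,
            " aggregation of judgments violates the reciprocity axiom; ",
            "upper-triangle entries are aggregated and mirrored by reciprocal")
    out <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- f(vapply(matrices, function(A) A[i, j], numeric(1)))
        out[i, j] <- v
        out[j, i] <- 1 / v
      }
    }
  }
  dimnames(out) <- dimnames(matrices[[1]])
  out
}

#' Aggregate individual priority vectors (AIP)
#'
#' Combines per-respondent weight vectors element-wise by a central
#' tendency — each individual decides alone and the decisions are pooled.
#' Geometric-mean and median aggregates no longer sum to one, so the result
#' is renormalized; the raw (pre-normalization) aggregate is kept as an
#' attribute because its magnitude is informative when comparing
#' aggregation schemes.
#'
#' @param vectors List (or matrix with respondents in rows) of weight
#'   vectors over the same block members.
#' @param central `"geometric"` (default), `"arithmetic"`, or `"median"`.
#' @return Named weight vector summing to 1, with attribute `"raw"` holding
#'   the unnormalized aggregate.
#' @export
aggregate_priorities <- function(vectors,
                                 central = c("geometric", "arithmetic", "median")) {
  central <- match.arg(central)
  W <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (is.null(W) || nrow(W) == 0) stop("no priority vectors to aggregate")
  if (any(W <= 0)) stop("priority vectors must be strictly positive")
  f <- central_fun(central)
  raw <- apply(W, 2, f)
  out <- raw / sum(raw)
  attr(out, "raw") <- raw
  out
}

#' Competition ranking of weighted items
#'
#' Orders items by descending weight and assigns competition ranks: tied
#' items (weights within `tie_tol`, chained) share the best applicable rank
#' and the next rank skips accordingly, so an item's rank is one plus the
#' number of strictly better items.
#'
#' @param weights Named nonnegative numeric vector.
#' @param tie_tol Absolute tolerance under which adjacent weights tie.
#' @return Data frame `item`, `weight`, `rank`, in the input order, of
#'   class `rank_table`.
#' @export
rank_table <- function(weights, tie_tol = 1e-9) {
  stopifnot(is.numeric(weights), all(weights >= 0))
  if (is.null(names(weights))) names(weights) <- paste0("item", seq_along(weights))
  ord <- order(weights, decreasing = TRUE)
  w_sorted <- weights[ord]
  group <- integer(length(weights))
  g <- 1L
  group[1] <- 1L
  for (i in seq_along(w_sorted)[-1]) {
    if (w_sorted[i - 1] - w_sorted[i] > tie_tol) g <- i  # rank = position of group head
    group[i] <- g
  }
  rank_sorted <- group
  ranks <- integer(length(weights))
  ranks[ord] <- rank_sorted
  structure(data.frame(item = names(weights), weight = unname(weights),
                       rank = ranks, stringsAsFactors = FALSE),
            class = c("rank_table", "data.frame"))
}

ranks_of <- function(tab) stats::setNames(tab$rank, tab$item)

#' Rank span of an item across ranking tables
#'
#' The extreme ranking positions an item takes over a collection of
#' rankings (e.g. six aggregation scenarios); a wide span flags an unstable
#' valuation.
#'
#' @param tables List of `rank_table`s (or of named rank vectors), or a
#'   data frame whose first column is `item` and remaining columns are rank
#'   vectors.
#' @param item Item id.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
rank_span <- function(tables, item) {
  ranks <- if (is.data.frame(tables) && !inherits(tables, "rank_table")) {
    if (!item %in% tables$item) stop("item '", item, "' not present")
    as.numeric(tables[tables$item == item, setdiff(names(tables), "item")])
  } else {
    vapply(tables, function(t) {
      r <- if (inherits(t, "rank_table") || is.data.frame(t)) ranks_of(t) else t
      if (!item %in% names(r)) stop("item '", item, "' not present in every table")
      as.numeric(r[[item]])
    }, numeric(1))
  }
  c(min = min(ranks), max = max(ranks))
}

#' Detect rank reversals between two rankings
#'
#' Items whose ranking position differs between two tables — e.g. between
#' CR-threshold choices or aggregation schemes — sorted by the magnitude of
#' the shift.
#'
#' @param a,b `rank_table`s (or named rank vectors) over the same items.
#' @return Data frame `item`, `rank_a`, `rank_b`, `delta` (rank_b -
#'   rank_a), ordered by decreasing `|delta|`; zero rows when the rankings
#'   agree.
#' @export
rank_reversals <- function(a, b) {
  ra <- if (is.data.frame(a)) ranks_of(a) else a
  rb <- if (is.data.frame(b)) ranks_of(b) else b
  if (!setequal(names(ra), names(rb))) stop("rankings cover different item sets")
  rb <- rb[names(ra)]
  d <- rb - ra
  moved <- d != 0
  out <- data.frame(item = names(ra)[moved], rank_a = unname(ra[moved]),
                    rank_b = unname(rb[moved]), delta = unname(d[moved]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta)), , drop = FALSE]
}
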