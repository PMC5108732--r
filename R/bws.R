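#' Best-worst scaling (Case 1) count analysis
#'
#' Fits the count-analysis scores for an object-case BWS task: in each
#' choice set the respondent marks one best and one worst item (two
#' decisions per set). Per criterion, the best count B, worst count W and
#' appearance count r are tallied; the standardized score is (B - W) / r;
#' and scores are unit-rescaled to \[0, 1\] within each scored group so the
#' best item of a group is 1 and the worst 0. Scoring is per comparison
#' block by default (each block carries its own 0–1 scale); `scope =
#' "pooled"` scores all criteria on one scale for designs that mix items
#' across blocks.
#'
#' @param choices Data frame `respondent_id`, `set_id`, `best_id`,
#'   `worst_id`.
#' @param design Data frame `set_id`, `block_id`, `item_id` (one row per
#'   item shown in a set).
#' @param scope `"block"` (default) or `"pooled"`.
#' @param tie_tol Weight tolerance for ranking ties.
#' @return An object of class `bws`: list with `scores` (data frame
#'   `item`, `block`, `B`, `W`, `r`, `bw`, `standardized`, `rescaled`,
#'   `rank` — rank within scope by standardized score), `by_respondent`
#'   (per-respondent count table), `n_respondents`, `scope`.
#' @examples
#' design <- data.frame(set_id = c(1, 1, 1), block_id = "b",
#'                      item_id = c("A", "B", "C"))
#' choices <- data.frame(respondent_id = "r1", set_id = 1,
#'                       best_id = "A", worst_id = "C")
#' bws(choices, design)
#' @export
bws <- function(choices, design, scope = c("block", "pooled"), tie_tol = 1e-9) {
  scope <- match.arg(scope)
  tal <- bws_tally(choices, design)
  counts <- tal$counts
  counts$standardized <- bws_standardize(counts)
  group <- if (scope == "block") counts$block else rep("all", nrow(counts))
  counts$rescaled <- NA_real_
  counts$rank <- NA_integer_
  for (g in unique(group)) {
    idx <- group == g
    counts$rescaled[idx] <- tryCatch(
      unit_rescale(counts$standardized[idx]),
      error = function(e) {
        warning("degenerate BWS scores in group '", g,
                "' (all equal); rescaled values set to 0.5")
        rep(0.5, sum(idx))
      })
    # standardized scores live in [-1, 1]; shift into the nonnegative range
    # rank_table expects (rank-preserving)
    s <- counts$standardized[idx]
    rt <- rank_table(stats::setNames(s - min(s), counts$item[idx]),
                     tie_tol = tie_tol)
    counts$rank[idx] <- rt$rank
  }
  structure(list(scores = counts, by_respondent = tal$by_respondent,
                 n_respondents = length(unique(as.character(choices$respondent_id))),
                 scope = scope),
            class = "bws")
}

#' Tally best/worst counts
#'
#' Accumulates, per criterion, the number of times it was picked best (B),
#' picked worst (W), and shown (r), pooled over respondents and also per
#' respondent. Each completed set contributes one +1 and one -1, so each
#' respondent's best-minus-worst scores sum to zero.
#'
#' @inheritParams bws
#' @return List with `counts` (pooled data frame `item`, `block`, `B`, `W`,
#'   `r`, `bw`) and `by_respondent` (the same per respondent).
#' @export
bws_tally <- function(choices, design) {
  required_d <- c("set_id", "block_id", "item_id")
  required_c <- c("respondent_id", "set_id", "best_id", "worst_id")
  if (length(setdiff(required_d, names(design)))) {
    stop("design needs columns ", paste(required_d, collapse = ", "))
  }
  if (length(setdiff(required_c, names(choices)))) {
    stop("choices need columns ", paste(required_c, collapse = ", "))
  }
  design$set_id <- as.character(design$set_id)
  design$item_id <- as.character(design$item_id)
  design$block_id <- as.character(design$block_id)
  choices$set_id <- as.character(choices$set_id)
  choices$respondent_id <- as.character(choices$respondent_id)
  choices$best_id <- as.character(choices$best_id)
  choices$worst_id <- as.character(choices$worst_id)

  sets <- split(design$item_id, design$set_id)
  if (any(vapply(sets, anyDuplicated, integer(1)) > 0)) {
    stop("a design set shows the same item twice")
  }
  block_of_set <- vapply(split(design$block_id, design$set_id),
                         function(b) unique(b)[1], character(1))
  items <- unique(design$item_id)
  block_of_item <- design$block_id[match(items, design$item_id)]

  if (anyDuplicated(choices[c("respondent_id", "set_id")])) {
    stop("a respondent answered the same set more than once")
  }

  zero <- function() data.frame(item = items, block = block_of_item,
                                B = 0, W = 0, r = 0, bw = 0,
                                stringsAsFactors = FALSE)
  pooled <- zero()
  rownames(pooled) <- items
  by_resp <- list()
  for (k in seq_len(nrow(choices))) {
    sid <- choices$set_id[k]
    if (!sid %in% names(sets)) stop("choice references unknown set '", sid, "'")
    shown <- sets[[sid]]
    best <- choices$best_id[k]; worst <- choices$worst_id[k]
    if (best == worst) {
      stop("best and worst coincide ('", best, "') for respondent '",
           choices$respondent_id[k], "', set '", sid, "'")
    }
    if (!best %in% shown || !worst %in% shown) {
      stop("pick outside the shown set for respondent '",
           choices$respondent_id[k], "', set '", sid, "'")
    }
    resp <- choices$respondent_id[k]
    if (is.null(by_resp[[resp]])) {
      by_resp[[resp]] <- zero()
      rownames(by_resp[[resp]]) <- items
    }
    pooled[shown, "r"] <- pooled[shown, "r"] + 1
    pooled[best, "B"] <- pooled[best, "B"] + 1
    pooled[worst, "W"] <- pooled[worst, "W"] + 1
    by_resp[[resp]][shown, "r"] <- by_resp[[resp]][shown, "r"] + 1
    by_resp[[resp]][best, "B"] <- by_resp[[resp]][best, "B"] + 1
    by_resp[[resp]][worst, "W"] <- by_resp[[resp]][worst, "W"] + 1
  }
  pooled$bw <- pooled$B - pooled$W
  by_resp <- lapply(by_resp, function(d) { d$bw <- d$B - d$W; d })
  list(counts = pooled, by_respondent = by_resp)
}

#' Standardized best-minus-worst scores
#'
#' `(B - W) / r` per criterion: the net preference per appearance. Dividing
#' by the per-criterion appearance count makes the score robust to
#' unbalanced designs; in a balanced design the divisor is a constant and
#' cancels in rescaling.
#'
#' @param counts A count data frame with columns `B`, `W`, `r` (from
#'   [bws_tally()]).
#' @return Numeric vector of standardized scores.
#' @export
bws_standardize <- function(counts) {
  if (any(counts$r == 0)) {
    stop("criterion never shown: ",
         paste(counts$item[counts$r == 0], collapse = ", "))
  }
  (counts$B - counts$W) / counts$r
}

#' Rescale scores to the unit interval
#'
#' `x -> (x - min) / (max - min)`, so the best-scoring item of a group maps
#' to 1 and the worst to 0. All-equal input has no defined rescaling and is
#' an error; callers may substitute a flat 0.5 with a warning.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector in \[0, 1\].
#' @export
unit_rescale <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot unit-rescale: all scores are equal")
  (x - rng[1]) / diff(rng)
}

#' @export
print.bws <- function(x, digits = 3, ...) {
  cat("BWS Case-1 count analysis: ", x$n_respondents, " respondent(s), scope = ",
      x$scope, "\n", sep = "")
  tab <- x$scores
  tab$standardized <- round(tab$standardized, digits)
  tab$rescaled <- round(tab$rescaled, digits)
  print(tab[order(tab$block, tab$rank), ], row.names = FALSE)
  invisible(x)
}

#' @export
coef.bws <- function(object, type = c("rescaled", "standardized"), ...) {
  type <- match.arg(type)
  stats::setNames(object$scores[[type]], object$scores$item)
}

#' @export
summary.bws <- function(object, ...) {
  zs <- vapply(object$by_respondent, function(d) sum(d$bw), numeric(1))
  structure(list(fit = object, respondent_zero_sum = zs), class = "summary.bws")
}

#' @export
print.summary.bws <- function(x, ...) {
  print(x$fit)
  cat("\nPer-respondent sum of best-minus-worst scores (0 when complete):\n")
  print(x$respondent_zero_sum)
  invisible(x)
}

#' Plot BWS scores
#'
#' Barplot of rescaled best-minus-worst scores, grouped by block.
#'
#' @param x A `bws` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.bws <- function(x, ...) {
  tab <- x$scores[order(x$scores$block, -x$scores$standardized), ]
  graphics::barplot(tab$rescaled, names.arg = tab$item, las = 2,
                    ylab = "rescaled B-W score",
                    col = as.integer(factor(tab$block)) + 1, ...)
  invisible(x)
}
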