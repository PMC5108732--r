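tau_pair_counts <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  tx <- dx[up] == 0
  ty <- dy[up] == 0
  list(n = n,
       n0 = n * (n - 1) / 2,
       concordant = sum(s > 0),
       discordant = sum(s < 0),
       ties_x = sum(tx & !ty),
       ties_y = sum(ty & !tx),
       ties_both = sum(tx & ty),
       # tie corrections from group sizes: sum t(t-1)/2 per tied group
       n1 = sum(vapply(unname(table(x)), function(t) t * (t - 1) / 2, numeric(1))),
       n2 = sum(vapply(unname(table(y)), function(t) t * (t - 1) / 2, numeric(1))))
}

# tie-corrected variance of T = C - D under the null (normal approximation,
# the standard Kendall formula used for tied data)
tau_normal_p <- function(x, y, Tstat) {
  n <- length(x)
  tg <- unname(table(x)); ug <- unname(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tg * (tg - 1) * (2 * tg + 5))
  vu <- sum(ug * (ug - 1) * (2 * ug + 5))
  v1 <- sum(tg * (tg - 1)) * sum(ug * (ug - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tg * (tg - 1) * (tg - 2)) * sum(ug * (ug - 1) * (ug - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  v <- (v0 - vt - vu) / 18 + v1 + v2
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(abs(Tstat) / sqrt(v), lower.tail = FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Tie-adjusted Kendall rank correlation (tau-b)
#'
#' Concordance between two rankings with an explicit adjustment for ties:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where C and D are the
#' concordant and discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2`
#' are the tied-pair corrections for each ranking. Unlike tau-a, tau-b can
#' reach +/-1 only in the absence of ties.
#'
#' @param x,y Numeric vectors of equal length >= 2 (ranks or scores; only
#'   order and ties matter).
#' @param p_method `"normal"` (default): two-sided p from the tie-corrected
#'   normal approximation to C - D; `"exact"`: permutation enumeration over
#'   all orderings of `y` (n <= 8); `"none"`.
#' @return Object of class `concordance`: `tau_b`, `p_value`, `n`,
#'   `n_pairs`, `concordant`, `discordant`, `ties_x`, `ties_y`.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
kendall_tau_b <- function(x, y, p_method = c("normal", "exact", "none")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  pc <- tau_pair_counts(x, y)
  den <- sqrt((pc$n0 - pc$n1) * (pc$n0 - pc$n2))
  if (den == 0) {
    stop("tau-b undefined: at least one vector is entirely tied")
  }
  tau <- (pc$concordant - pc$discordant) / den
  p <- switch(p_method,
    none = NA_real_,
    normal = tau_normal_p(x, y, pc$concordant - pc$discordant),
    exact = {
      n <- length(y)
      if (n > 8) stop("exact p-value supported for n <= 8 only")
      perms <- all_permutations(n)
      taus <- apply(perms, 1, function(idx) {
        p2 <- tau_pair_counts(x, y[idx])
        d2 <- sqrt((p2$n0 - p2$n1) * (p2$n0 - p2$n2))
        (p2$concordant - p2$discordant) / d2
      })
      mean(abs(taus) >= abs(tau) - 1e-12)
    })
  structure(list(tau_b = tau, p_value = p, n = pc$n, n_pairs = pc$n0,
                 concordant = pc$concordant, discordant = pc$discordant,
                 ties_x = pc$ties_x, ties_y = pc$ties_y,
                 p_method = p_method),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f (n = %d; C = %d, D = %d, ties x/y = %d/%d)\n",
              x$tau_b, x$n, x$concordant, x$discordant, x$ties_x, x$ties_y))
  if (!is.na(x$p_value)) {
    cat(sprintf("two-sided p = %.4g (%s)\n", x$p_value, x$p_method))
  }
  invisible(x)
}

#' Pooled within-respondent Kendall tau-b
#'
#' Tau-b computed over the pooled set of within-respondent item pairs: each
#' respondent contributes the pairs among their own matched rankings, pairs
#' never cross respondents, and the concordant/discordant/tie counts are
#' summed before the tau-b ratio is formed. This is the appropriate pooled
#' measure when each respondent ranks the same few items under two methods.
#'
#' @param x_list,y_list Lists of equal-length rank vectors, one element per
#'   respondent.
#' @param p_method `"normal"` or `"none"` (exact enumeration is not defined
#'   for the pooled statistic).
#' @return A `concordance` object; the p-value sums the per-respondent null
#'   variances (respondents are independent).
#' @export
pooled_tau <- function(x_list, y_list, p_method = c("normal", "none")) {
  p_method <- match.arg(p_method)
  if (length(x_list) == 0) stop("no respondents")
  if (length(x_list) != length(y_list)) stop("x_list and y_list lengths differ")
  tot <- list(n0 = 0, n1 = 0, n2 = 0, concordant = 0, discordant = 0,
              ties_x = 0, ties_y = 0)
  vsum <- 0
  for (i in seq_along(x_list)) {
    x <- x_list[[i]]; y <- y_list[[i]]
    if (length(x) != length(y)) stop("rank vectors of respondent ", i, " differ in length")
    pc <- tau_pair_counts(x, y)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + pc[[f]]
    if (p_method == "normal") {
      n <- length(x)
      tg <- unname(table(x)); ug <- unname(table(y))
      v0 <- n * (n - 1) * (2 * n + 5)
      vt <- sum(tg * (tg - 1) * (2 * tg + 5))
      vu <- sum(ug * (ug - 1) * (2 * ug + 5))
      v1 <- sum(tg * (tg - 1)) * sum(ug * (ug - 1)) / (2 * n * (n - 1))
      v2 <- if (n > 2) {
        sum(tg * (tg - 1) * (tg - 2)) * sum(ug * (ug - 1) * (ug - 2)) /
          (9 * n * (n - 1) * (n - 2))
      } else 0
      vsum <- vsum + (v0 - vt - vu) / 18 + v1 + v2
    }
  }
  den <- sqrt((tot$n0 - tot$n1) * (tot$n0 - tot$n2))
  if (den == 0) stop("pooled tau-b undefined: all pairs tied")
  tau <- (tot$concordant - tot$discordant) / den
  p <- if (p_method == "normal" && vsum > 0) {
    2 * stats::pnorm(abs(tot$concordant - tot$discordant) / sqrt(vsum),
                     lower.tail = FALSE)
  } else NA_real_
  structure(list(tau_b = tau, p_value = p,
                 n = sum(vapply(x_list, length, numeric(1))),
                 n_pairs = tot$n0,
                 concordant = tot$concordant, discordant = tot$discordant,
                 ties_x = tot$ties_x, ties_y = tot$ties_y,
                 p_method = p_method),
            class = "concordance")
}

#' Read ranking-card data
#'
#' Card rankings are ordinal: each respondent sorts the criteria cards,
#' ties permitted. Long CSV with columns `respondent_id`, `criterion_id`,
#' `rank`.
#'
#' @param path CSV path.
#' @param hierarchy Optional [criteria_hierarchy()] for id validation.
#' @return Data frame `respondent_id`, `criterion_id`, `rank`.
#' @export
read_cards <- function(path, hierarchy = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("respondent_id", "criterion_id", "rank")
  if (length(setdiff(required, names(d)))) {
    stop("card CSV needs columns ", paste(required, collapse = ", "))
  }
  if (!is.numeric(d$rank) || any(d$rank < 1)) stop("card ranks must be positive integers")
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(d$criterion_id), hierarchy$nodes$id)
    if (length(unknown)) stop("card data references unknown criterion id(s): ",
                              paste(unknown, collapse = ", "))
  }
  d
}

#' Aggregate card rankings across respondents
#'
#' Takes the median rank per criterion over respondents and converts the
#' medians back to a competition ranking; ties in the medians are kept as
#' tied positions (duplicated ranking positions are a normal feature of
#' card data).
#'
#' @param cards Data frame `respondent_id`, `criterion_id`, `rank`.
#' @return A [rank_table()] over the criteria (item, weight = negative
#'   median rank used for ordering, rank).
#' @export
aggregate_cards <- function(cards) {
  med <- tapply(cards$rank, cards$criterion_id, stats::median)
  # smaller median rank = better; flip to a nonnegative "the larger the
  # better" score for rank_table
  rank_table(max(med) + 1 - med)
}

#' Cross-method comparison table
#'
#' Lines up, per criterion and per comparison block, the BWS rescaled value
#' and rank, the AHP local weight and rank, and the aggregated card rank —
#' the standard side-by-side convergent-validity display. Methods not
#' supplied appear as `NA` columns.
#'
#' @param ahp_fit An [ahp()] fit, or `NULL`.
#' @param bws_fit A [bws()] fit, or `NULL`.
#' @param cards Card data frame (see [read_cards()]), or `NULL`.
#' @param hierarchy A [criteria_hierarchy()]; taken from `ahp_fit` if
#'   missing.
#' @param tie_tol Ranking tie tolerance.
#' @return Data frame `item`, `block`, `bws_value`, `ahp_local_weight`,
#'   `bws_rank`, `ahp_rank`, `card_rank`.
#' @export
method_comparison <- function(ahp_fit = NULL, bws_fit = NULL, cards = NULL,
                              hierarchy = NULL, tie_tol = 1e-9) {
  if (is.null(hierarchy) && !is.null(ahp_fit)) hierarchy <- ahp_fit$hierarchy
  if (is.null(hierarchy)) stop("a criteria hierarchy is required")
  rows <- list()
  card_ranks_all <- if (!is.null(cards)) {
    # card task ranks all elicited criteria together; within-block positions
    # are obtained by re-ranking the block subset of the aggregated ranking
    agg <- aggregate_cards(cards)
    stats::setNames(agg$weight, agg$item)  # -median rank, larger = better
  } else NULL
  for (bid in names(hierarchy$blocks)) {
    members <- hierarchy$blocks[[bid]]$members
    ahp_w <- ahp_rank <- bws_v <- bws_rank <- card_rank <-
      stats::setNames(rep(NA_real_, length(members)), members)
    if (!is.null(ahp_fit)) {
      w <- ahp_fit$local[[bid]]
      ahp_w[names(w)] <- w
      rt <- rank_table(w, tie_tol)
      ahp_rank[rt$item] <- rt$rank
    }
    if (!is.null(bws_fit)) {
      sc <- bws_fit$scores[bws_fit$scores$item %in% members, ]
      if (nrow(sc) && !setequal(sc$item, members)) {
        stop("BWS scores cover only part of block '", bid, "'")
      }
      if (nrow(sc)) {
        bws_v[sc$item] <- sc$rescaled
        shifted <- sc$standardized - min(sc$standardized)
        rt <- rank_table(stats::setNames(shifted, sc$item), tie_tol)
        bws_rank[rt$item] <- rt$rank
      }
    }
    if (!is.null(card_ranks_all)) {
      have <- intersect(members, names(card_ranks_all))
      if (length(have) >= 2) {
        rt <- rank_table(card_ranks_all[have], tie_tol = 1e-9)
        card_rank[rt$item] <- rt$rank
      }
    }
    rows[[bid]] <- data.frame(
      item = members, block = bid,
      bws_value = unname(bws_v[members]),
      ahp_local_weight = unname(ahp_w[members]),
      bws_rank = unname(bws_rank[members]),
      ahp_rank = unname(ahp_rank[members]),
      card_rank = unname(card_rank[members]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-block rank concordance between two methods
#'
#' Kendall tau-b between two methods' per-respondent rankings, one result
#' per comparison block, pooling within-respondent pairs (see
#' [pooled_tau()]); with `level = "group"`, the tau-b between the two
#' group-level rankings instead.
#'
#' @param x_by_block,y_by_block Named lists (by block id) of lists of
#'   per-respondent rank vectors (`level = "pooled"`), or of single group
#'   rank vectors (`level = "group"`).
#' @param level `"pooled"` (default) or `"group"`.
#' @return Data frame `block`, `tau_b`, `p_value`, `n_pairs`.
#' @export
rank_concordance <- function(x_by_block, y_by_block,
                             level = c("pooled", "group")) {
  level <- match.arg(level)
  blocks <- names(x_by_block)
  if (!setequal(blocks, names(y_by_block))) stop("block sets differ")
  rows <- lapply(blocks, function(b) {
    res <- if (level == "pooled") {
      pooled_tau(x_by_block[[b]], y_by_block[[b]])
    } else {
      kendall_tau_b(x_by_block[[b]], y_by_block[[b]])
    }
    data.frame(block = b, tau_b = res$tau_b, p_value = res$p_value,
               n_pairs = res$n_pairs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
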