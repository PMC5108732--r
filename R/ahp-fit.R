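#' Fit group AHP priorities from pairwise judgments
#'
#' The central estimator of the package. Per-respondent reciprocal judgment
#' matrices are built for every comparison block of the hierarchy, priority
#' weights are extracted by the eigenvector method, and a group result is
#' formed either by aggregating individual judgments first (AIJ — the group
#' answers as a new individual) or by aggregating individual priorities
#' (AIP — each respondent's weights are computed, consistency-screened, and
#' pooled). Local block weights are propagated to global weights down the
#' hierarchy and the elicited criteria are ranked by competition ranking.
#'
#' Respondents missing one or more queried blocks are set aside as
#' incomplete and reported, not silently dropped or imputed.
#'
#' @param judgments Data frame with columns `respondent_id`, `block_id`,
#'   `row_id`, `col_id`, `value`: one row per elicited upper-triangle pair,
#'   `value` = how many times `row_id` dominates `col_id` (Saaty scale).
#' @param hierarchy A [criteria_hierarchy()].
#' @param mode `"AIP"` (default) or `"AIJ"`.
#' @param central Central tendency for aggregation: `"geometric"`
#'   (default; the only one preserving the AHP axioms), `"arithmetic"`, or
#'   `"median"`.
#' @param cr_threshold Consistency-ratio cutoff for screening (0.1 strict,
#'   0.2 lenient).
#' @param screen Apply CR screening? Defaults to `TRUE` for AIP (the usual
#'   practice) and `FALSE` for AIJ (aggregation tames individual
#'   inconsistency and the group CR is checked instead).
#' @param screen_blocks `"level2"` (screen the root block only, default) or
#'   `"all"` (maximum CR across blocks).
#' @param strict Reject off-grid judgment values (see [pairwise_matrix()]).
#' @param tie_tol Absolute weight tolerance for ranking ties.
#' @return An object of class `ahp`. Key components: `local` (named list of
#'   group local weight vectors per block), `global` (named vector over root
#'   and elicited nodes), `ranking` (a [rank_table()] over the elicited
#'   criteria, by global weight), `respondent_local` / `respondent_global`
#'   (per-respondent weight matrices for all complete respondents),
#'   `consistency` (per-respondent per-block CR table), `group_consistency`
#'   (per-block reports for the aggregated matrix; a diagnostic under AIP),
#'   `inclusion` (included / excluded / incomplete respondent ids),
#'   `raw_aggregate` (pre-normalization AIP aggregates).
#' @seealso [aggregate_judgments()], [aggregate_priorities()],
#'   [ahp_boot()], [summary.ahp()]
#' @examples
#' h <- info_hierarchy()
#' sim <- simulate_study(synthetic_config(hierarchy = h, n_respondents = 8,
#'                                        seed = 42))
#' fit <- ahp(sim$judgments, h)
#' fit
#' coef(fit)
#' @export
ahp <- function(judgments, hierarchy,
                mode = c("AIP", "AIJ"),
                central = c("geometric", "arithmetic", "median"),
                cr_threshold = 0.1,
                screen = (mode == "AIP"),
                screen_blocks = c("level2", "all"),
                strict = TRUE,
                tie_tol = 1e-9) {
  mode <- match.arg(mode)
  central <- match.arg(central)
  screen_blocks <- match.arg(screen_blocks)
  screen <- isTRUE(screen)
  stopifnot(inherits(hierarchy, "criteria_hierarchy"),
            is.numeric(cr_threshold), cr_threshold > 0, cr_threshold <= 1)
  judgments <- validate_judgments(judgments, hierarchy)

  block_ids <- names(hierarchy$blocks)
  respondents <- unique(as.character(judgments$respondent_id))

  matrices <- list()
  incomplete <- character(0)
  for (resp in respondents) {
    jr <- judgments[judgments$respondent_id == resp, , drop = FALSE]
    mats <- list()
    ok <- TRUE
    for (b in block_ids) {
      jb <- jr[jr$block_id == b, , drop = FALSE]
      need <- choose(hierarchy$blocks[[b]]$size, 2)
      if (nrow(jb) != need) { ok <- FALSE; break }
      mats[[b]] <- pairwise_matrix(jb, hierarchy$blocks[[b]]$members,
                                   strict = strict)
    }
    if (ok) matrices[[resp]] <- mats else incomplete <- c(incomplete, resp)
  }
  if (length(matrices) == 0) stop("no complete respondents")

  scr <- screen_respondents(matrices, hierarchy, threshold = cr_threshold,
                            blocks = screen_blocks)
  included <- if (screen) scr$included else names(matrices)
  excluded <- if (screen) scr$excluded else character(0)
  if (length(included) == 0) {
    stop("all respondents screened out at CR <= ", cr_threshold)
  }

  # per-respondent weights (all complete respondents, for summaries/bootstrap)
  resp_local <- lapply(stats::setNames(block_ids, block_ids), function(b) {
    t(vapply(matrices,
             function(m) principal_eigenvector(m[[b]])$weights,
             numeric(hierarchy$blocks[[b]]$size)))
  })
  elicited <- elicited_nodes(hierarchy)
  resp_global <- t(vapply(names(matrices), function(resp) {
    local_r <- lapply(resp_local, function(W) W[resp, ])
    global_weights(hierarchy, local_r)[elicited]
  }, numeric(length(elicited))))

  raw_aggregate <- NULL
  if (mode == "AIJ") {
    group_mats <- lapply(stats::setNames(block_ids, block_ids), function(b) {
      aggregate_judgments(lapply(matrices[included], `[[`, b), central)
    })
    local <- lapply(group_mats, function(A) principal_eigenvector(A)$weights)
    group_consistency <- lapply(group_mats, consistency)
  } else {
    local <- lapply(stats::setNames(block_ids, block_ids), function(b) {
      w <- aggregate_priorities(resp_local[[b]][included, , drop = FALSE], central)
      stats::setNames(as.vector(w), colnames(resp_local[[b]])) -> out
      attr(out, "raw") <- attr(w, "raw")
      out
    })
    raw_aggregate <- lapply(local, attr, "raw")
    local <- lapply(local, function(w) { attributes(w)$raw <- NULL; w })
    # diagnostic only: CR of the element-wise aggregated matrix of the
    # *included* respondents; AIP itself defines no group matrix
    group_consistency <- lapply(stats::setNames(block_ids, block_ids), function(b) {
      A <- suppressWarnings(
        aggregate_judgments(lapply(matrices[included], `[[`, b), central))
      consistency(A)
    })
  }

  global <- global_weights(hierarchy, local)
  ranking <- rank_table(global[elicited], tie_tol = tie_tol)
  ranking$label <- hierarchy$nodes$label[match(ranking$item, hierarchy$nodes$id)]

  structure(list(
    mode = mode, central = central,
    cr_threshold = cr_threshold, screen = screen, screen_blocks = screen_blocks,
    hierarchy = hierarchy,
    local = local, global = global, ranking = ranking,
    raw_aggregate = raw_aggregate,
    respondent_local = resp_local, respondent_global = resp_global,
    consistency = scr$reports,
    group_consistency = group_consistency,
    inclusion = list(included = included, excluded = excluded,
                     incomplete = incomplete)
  ), class = "ahp")
}

validate_judgments <- function(judgments, hierarchy) {
  required <- c("respondent_id", "block_id", "row_id", "col_id", "value")
  missing_cols <- setdiff(required, names(judgments))
  if (length(missing_cols)) {
    stop("judgment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  judgments$respondent_id <- as.character(judgments$respondent_id)
  judgments$block_id <- as.character(judgments$block_id)
  judgments$row_id <- as.character(judgments$row_id)
  judgments$col_id <- as.character(judgments$col_id)
  unknown_block <- setdiff(unique(judgments$block_id), names(hierarchy$blocks))
  if (length(unknown_block)) {
    stop("judgments reference unknown block(s): ",
         paste(unknown_block, collapse = ", "))
  }
  ids <- hierarchy$nodes$id
  unknown <- setdiff(unique(c(judgments$row_id, judgments$col_id)), ids)
  if (length(unknown)) {
    stop("judgments reference unknown criterion id(s): ",
         paste(unknown, collapse = ", "))
  }
  judgments
}

#' @export
print.ahp <- function(x, digits = 4, ...) {
  cat("Group AHP fit (", x$mode, ", ", x$central, " mean",
      if (x$screen) paste0(", CR <= ", format(x$cr_threshold)) else "",
      ")\n", sep = "")
  inc <- x$inclusion
  cat("Respondents: ", length(inc$included), " included",
      if (length(inc$excluded)) paste0(", ", length(inc$excluded), " excluded by CR"),
      if (length(inc$incomplete)) paste0(", ", length(inc$incomplete), " incomplete"),
      "\n", sep = "")
  tab <- x$ranking[order(x$ranking$rank), c("item", "label", "weight", "rank")]
  tab$weight <- round(tab$weight, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract group weights from an AHP fit
#'
#' @param object An `ahp` fit.
#' @param type `"global"` (default) for global weights of the elicited
#'   criteria, or `"local"` for the list of per-block local weights.
#' @param ... Unused.
#' @return Named numeric vector, or list of vectors for `type = "local"`.
#' @export
coef.ahp <- function(object, type = c("global", "local"), ...) {
  type <- match.arg(type)
  if (type == "local") object$local
  else object$global[elicited_nodes(object$hierarchy)]
}

#' Summarize an AHP fit
#'
#' Reports the group ranking, the distribution of per-respondent weights
#' (median, quartiles, SD), consistency-ratio summaries, and inclusion
#' counts.
#'
#' @param object An `ahp` fit.
#' @param ... Unused.
#' @return An object of class `summary.ahp`.
#' @export
summary.ahp <- function(object, ...) {
  incl <- object$inclusion$included
  Wg <- object$respondent_global[incl, , drop = FALSE]
  spread <- summarize_weights(Wg)
  cr2 <- object$consistency[
    object$consistency$block == root_id(object$hierarchy) &
      object$consistency$respondent %in% incl, "cr"]
  structure(list(fit = object, weight_summary = spread,
                 cr_level2 = summary(cr2)),
            class = "summary.ahp")
}

#' @export
print.summary.ahp <- function(x, ...) {
  print(x$fit)
  cat("\nPer-respondent global weights (included respondents):\n")
  print(x$weight_summary, row.names = FALSE, digits = 4)
  cat("\nLevel-two CR of included respondents:\n")
  print(x$cr_level2)
  invisible(x)
}

#' Plot group AHP weights
#'
#' Boxplots of per-respondent global weights for the included respondents,
#' with the group aggregate overplotted — the standard way to display the
#' spread of priorities in a cohort.
#'
#' @param x An `ahp` fit.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ahp <- function(x, ...) {
  incl <- x$inclusion$included
  W <- x$respondent_global[incl, , drop = FALSE]
  ord <- order(colMeans(W), decreasing = TRUE)
  graphics::boxplot(W[, ord, drop = FALSE], las = 2,
                    ylab = "global weight", ...)
  graphics::points(seq_len(ncol(W)), x$global[colnames(W)][ord],
                   pch = 19, col = "red3")
  invisible(x)
}

root_id <- function(h) h$nodes$id[is.na(h$nodes$parent)]
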