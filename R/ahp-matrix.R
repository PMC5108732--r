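#' The Saaty judgment scale
#'
#' The discrete ratio grid used in AHP elicitation: the integers 1..9 and
#' their reciprocals. `a_ij = k` means criterion i dominates j with
#' intensity k; the reciprocal entry is implied.
#'
#' @return Sorted numeric vector of the 17 grid values.
#' @export
saaty_scale <- function() {
  sort(c(1 / (9:2), 1:9))
}

#' Snap a positive ratio to the nearest Saaty grid value
#'
#' Nearest is measured in log space, so the grid's reciprocal symmetry is
#' respected: `snap_saaty(x)` and `snap_saaty(1/x)` are reciprocals.
#'
#' @param x Positive numeric vector.
#' @return Numeric vector of grid values.
#' @export
snap_saaty <- function(x) {
  stopifnot(all(x > 0))
  grid <- saaty_scale()
  lg <- log(grid)
  grid[vapply(log(x), function(v) which.min(abs(lg - v)), integer(1))]
}

is_on_saaty_grid <- function(x, tol = 1e-9) {
  vapply(x, function(v) any(abs(saaty_scale() - v) < tol), logical(1))
}

#' Build a reciprocal pairwise comparison matrix from elicited judgments
#'
#' Only the upper half of an AHP matrix is queried; the reciprocal request
#' fixes the lower half and the unit diagonal. `judgments` carries one row
#' per elicited unordered pair: `value` is how many times `row_id` dominates
#' `col_id` (either orientation of the pair is accepted).
#'
#' @param judgments Data frame with columns `row_id`, `col_id`, `value`.
#' @param members Character vector of the block's criteria, in block order;
#'   defines the row/column order of the matrix.
#' @param strict If `TRUE` (default), values must sit on the Saaty grid;
#'   lenient mode accepts any positive value (aggregated matrices leave the
#'   grid).
#' @return A numeric `n x n` reciprocal matrix with dimnames `members`.
#' @export
pairwise_matrix <- function(judgments, members, strict = TRUE) {
  stopifnot(is.data.frame(judgments), length(members) >= 2)
  n <- length(members)
  A <- matrix(NA_real_, n, n, dimnames = list(members, members))
  diag(A) <- 1
  for (k in seq_len(nrow(judgments))) {
    r <- as.character(judgments$row_id[k])
    c <- as.character(judgments$col_id[k])
    v <- judgments$value[k]
    if (!r %in% members || !c %in% members) {
      stop("judgment references criterion outside the block: '", r, "' vs '", c, "'")
    }
    if (r == c) stop("self-comparison for criterion '", r, "'")
    if (!is.finite(v) || v <= 0) {
      stop("judgment value for ", r, " vs ", c, " must be a positive number, got ", v)
    }
    if (strict && !is_on_saaty_grid(v)) {
      stop("judgment value ", format(v), " (", r, " vs ", c,
           ") is off the Saaty grid; use strict = FALSE to accept it")
    }
    if (!is.na(A[r, c])) stop("duplicate judgment for pair ", r, " / ", c)
    A[r, c] <- v
    A[c, r] <- 1 / v
  }
  if (anyNA(A)) {
    idx <- which(is.na(A) & upper.tri(A), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i) paste0(members[i[1]], "/", members[i[2]]))
    stop("missing judgment(s) for pair(s): ", paste(pairs, collapse = ", "))
  }
  A
}

#' Validate reciprocity of a comparison matrix
#' @param A Square positive matrix.
#' @param tol Tolerance on `a_ij * a_ji - 1`.
#' @return `A`, invisibly; errors if not reciprocal.
#' @export
check_reciprocal <- function(A, tol = 1e-12) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A <= 0)) stop("comparison matrix must be strictly positive")
  if (max(abs(diag(A) - 1)) > tol) stop("comparison matrix diagonal must be 1")
  if (max(abs(A * t(A) - 1)) > tol) stop("matrix is not reciprocal (a_ij * a_ji != 1)")
  invisible(A)
}

#' Principal eigenvector of a positive reciprocal matrix
#'
#' The eigenvector method of AHP: priority weights are the Perron
#' eigenvector, computed by power iteration with L1 normalization. The
#' principal eigenvalue is estimated from the L1 Rayleigh ratio at
#' convergence and equals `n` exactly when the matrix is consistent.
#'
#' @param A Positive reciprocal matrix.
#' @param tol Convergence tolerance on successive normalized iterates.
#' @param max_iter Iteration cap; non-convergence is an error, never a
#'   silent truncation.
#' @return List with `weights` (named, summing to 1), `lambda_max`, and
#'   `iterations`.
#' @export
principal_eigenvector <- function(A, tol = 1e-12, max_iter = 10000L) {
  check_reciprocal(A)
  n <- nrow(A)
  v <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(max_iter)) {
    Av <- as.vector(A %*% v)
    lambda <- sum(Av)          # since sum(v) == 1
    v_new <- Av / lambda
    if (max(abs(v_new - v)) < tol) {
      names(v_new) <- rownames(A)
      return(list(weights = v_new, lambda_max = lambda, iterations = it))
    }
    v <- v_new
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' Random index table for the consistency ratio
#'
#' Expected consistency index of random reciprocal matrices, used to
#' normalize the consistency index into the consistency ratio. Values for
#' n = 1..9 after Saaty; pass a custom table to use other calibrations.
#'
#' @return Named numeric vector indexed by matrix size.
#' @export
saaty_random_index <- function() {
  c(`1` = 0, `2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12,
    `6` = 1.24, `7` = 1.32, `8` = 1.41, `9` = 1.45)
}

#' Consistency of a pairwise comparison matrix
#'
#' Computes the principal eigenvalue `lambda_max`, the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, the random index `RI(n)`, and the
#' consistency ratio `CR = CI / RI`. Judgments are conventionally screened
#' at CR <= 0.1 (strict) or CR <= 0.2 (lenient). For n <= 2 a reciprocal
#' matrix is always consistent and CR is defined as 0.
#'
#' @param A Positive reciprocal matrix.
#' @param ri Random index table, indexed by size (default
#'   [saaty_random_index()]).
#' @return Object of class `consistency_report`: list with `n`,
#'   `lambda_max`, `ci`, `ri`, `cr`.
#' @export
consistency <- function(A, ri = saaty_random_index()) {
  check_reciprocal(A)
  n <- nrow(A)
  if (n <= 1) stop("consistency is undefined for a 1 x 1 matrix")
  eig <- principal_eigenvector(A)
  if (n == 2) {
    rep_ <- list(n = n, lambda_max = eig$lambda_max, ci = 0, ri = 0, cr = 0)
    return(structure(rep_, class = "consistency_report"))
  }
  if (!as.character(n) %in% names(ri)) {
    stop("no random index for matrix size ", n)
  }
  ci <- (eig$lambda_max - n) / (n - 1)
  rin <- ri[[as.character(n)]]
  structure(list(n = n, lambda_max = eig$lambda_max, ci = ci,
                 ri = rin, cr = ci / rin),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("n = %d, lambda_max = %.6f, CI = %.6f, RI = %.2f, CR = %.4f\n",
              x$n, x$lambda_max, x$ci, x$ri, x$cr))
  invisible(x)
}

#' Screen respondents by consistency ratio
#'
#' Partitions respondents into included and excluded by comparing the CR of
#' a selected comparison block against a threshold. By default only the
#' level-two block (the children of the root) is screened, which is the
#' usual practice when one top block carries the main decision; `blocks =
#' "all"` screens on the maximum CR across every block for sensitivity
#' checks.
#'
#' @param matrices Named list (by respondent) of named lists (by block id)
#'   of comparison matrices.
#' @param hierarchy A [criteria_hierarchy()].
#' @param threshold CR cutoff; 0.1 by convention, 0.2 as the lenient
#'   alternative.
#' @param blocks `"level2"` (default) or `"all"`.
#' @return List with `included`, `excluded` (character vectors of respondent
#'   ids) and `reports`, a data frame of per-respondent per-block CR values.
#' @export
screen_respondents <- function(matrices, hierarchy, threshold = 0.1,
                               blocks = c("level2", "all")) {
  blocks <- match.arg(blocks)
  stopifnot(inherits(hierarchy, "criteria_hierarchy"))
  root <- hierarchy$nodes$id[is.na(hierarchy$nodes$parent)]
  sel <- if (blocks == "level2") root else names(hierarchy$blocks)
  rows <- list()
  decision <- logical(length(matrices))
  names(decision) <- names(matrices)
  for (resp in names(matrices)) {
    mats <- matrices[[resp]]
    missing_sel <- setdiff(sel, names(mats))
    if (length(missing_sel)) {
      stop("respondent '", resp, "' is missing screening block(s): ",
           paste(missing_sel, collapse = ", "))
    }
    crs <- numeric(0)
    for (b in names(mats)) {
      rep_ <- consistency(mats[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        respondent = resp, block = b, lambda_max = rep_$lambda_max,
        ci = rep_$ci, cr = rep_$cr, stringsAsFactors = FALSE)
      if (b %in% sel) crs <- c(crs, rep_$cr)
    }
    decision[resp] <- max(crs) <= threshold
  }
  list(included = names(decision)[decision],
       excluded = names(decision)[!decision],
       reports = do.call(rbind, rows))
}
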