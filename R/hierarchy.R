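#' Criteria hierarchies for multi-criteria priority measurement
#'
#' A `criteria_hierarchy` is the decision tree underlying an AHP study: a
#' single root (the study goal) whose descendants are the criteria and
#' sub-criteria. Children of a *queried* node form a comparison block — the
#' set of items a respondent judges pairwise (and, in BWS or card tasks, the
#' set scored together). Nodes below the last queried level may be present
#' for documentation without being elicited.
#'
#' @param nodes A data frame with columns `id` (unique token), `label`
#'   (display text), `parent` (id of the parent, `NA` for the root), and
#'   `queried` (logical: do this node's children form an elicited block?).
#'   Row order fixes the member order of every block, and thereby the
#'   row/column order of all judgment matrices and weight vectors.
#' @return An object of class `criteria_hierarchy`: a list with `nodes`
#'   (the validated node table plus a `level` column, root = level 1) and
#'   `blocks` (named list of comparison blocks, each with `parent`,
#'   `members`, `size`).
#' @examples
#' h <- criteria_hierarchy(data.frame(
#'   id = c("goal", "a", "b"),
#'   label = c("Goal", "A", "B"),
#'   parent = c(NA, "goal", "goal"),
#'   queried = c(TRUE, FALSE, FALSE)
#' ))
#' count_pairwise_comparisons(h)
#' @seealso [read_hierarchy()], [global_weights()], [info_hierarchy()]
#' @export
criteria_hierarchy <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  required <- c("id", "label", "parent", "queried")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop("hierarchy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- nodes[required]
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$parent <- as.character(nodes$parent)
  nodes$queried <- as.logical(nodes$queried)

  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1L) {
    stop("hierarchy must have exactly one root (one node with no parent), found ",
         sum(is_root))
  }
  orphan <- !is_root & !(nodes$parent %in% nodes$id)
  if (any(orphan)) {
    stop("parent id(s) not found: ",
         paste(unique(nodes$parent[orphan]), collapse = ", "))
  }

  # levels by walking up the parent chain; a chain longer than the node count
  # means a cycle
  n <- nrow(nodes)
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  level <- integer(n)
  for (i in seq_len(n)) {
    lvl <- 1L
    p <- parent_of[[nodes$id[i]]]
    while (!is.na(p)) {
      lvl <- lvl + 1L
      if (lvl > n) stop("cycle detected in parent links at node '", nodes$id[i], "'")
      p <- parent_of[[p]]
    }
    level[i] <- lvl
  }
  nodes$level <- level

  blocks <- list()
  for (pid in nodes$id[nodes$queried]) {
    members <- nodes$id[!is.na(nodes$parent) & nodes$parent == pid]
    if (length(members) < 2L) {
      stop("queried node '", pid, "' has ", length(members),
           " child(ren); a comparison block needs at least 2")
    }
    blocks[[pid]] <- list(parent = pid, members = members,
                          size = length(members))
  }

  structure(list(nodes = nodes, blocks = blocks), class = "criteria_hierarchy")
}

#' Read a criteria hierarchy from a JSON document
#'
#' The document is an array of objects `{id, label, parent, queried}`;
#' `parent` is `null` for the root. Array order fixes block member order.
#'
#' @param path Path to a JSON file.
#' @return A [criteria_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.data.frame(doc)) stop("hierarchy JSON must be an array of node objects")
  if (!"queried" %in% names(doc)) doc$queried <- FALSE
  doc$queried[is.na(doc$queried)] <- FALSE
  if (!"parent" %in% names(doc)) stop("hierarchy JSON nodes need a 'parent' field")
  criteria_hierarchy(doc)
}

#' The rare-disease information-needs study hierarchy
#'
#' The four-level hierarchy shipped with the package: an information-portal
#' goal, four level-two information categories (medical issues, research,
#' current events, social advisory and support services), nine level-three
#' sub-criteria in blocks of three under medical issues, research and social
#' support (current events has no elicited subcategories), and level-four
#' subcategories that are represented but not elicited. Its queried blocks
#' have sizes 4, 3, 3, 3, i.e. 15 pairwise comparisons.
#'
#' @return A [criteria_hierarchy()].
#' @export
info_hierarchy <- function() {
  read_hierarchy(system.file("extdata", "info_hierarchy.json",
                             package = "prefrank", mustWork = TRUE))
}

#' @export
print.criteria_hierarchy <- function(x, ...) {
  nb <- length(x$blocks)
  cat("Criteria hierarchy: ", nrow(x$nodes), " nodes, ",
      max(x$nodes$level), " levels, ", nb, " comparison block(s) (",
      count_pairwise_comparisons(x), " pairwise comparisons)\n", sep = "")
  for (b in x$blocks) {
    cat("  [", b$parent, "] ", paste(b$members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of elicited pairwise comparisons
#'
#' Sum of n(n-1)/2 over the queried comparison blocks — the count of
#' judgments each complete respondent contributes.
#'
#' @param h A [criteria_hierarchy()].
#' @return Integer.
#' @export
count_pairwise_comparisons <- function(h) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  sizes <- vapply(h$blocks, `[[`, integer(1), "size")
  as.integer(sum(sizes * (sizes - 1) / 2))
}

#' Elicited (ranked) criteria
#'
#' The nodes whose weights the study elicits: members of any queried block.
#' These are the items that enter combined rankings across levels; a node
#' whose own children are not queried (e.g. a category without elicited
#' subcategories) appears through its own weight.
#'
#' @param h A [criteria_hierarchy()].
#' @return Character vector of node ids, in hierarchy order.
#' @export
elicited_nodes <- function(h) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  members <- unlist(lapply(h$blocks, `[[`, "members"), use.names = FALSE)
  h$nodes$id[h$nodes$id %in% members]
}

#' Propagate local block weights to global weights
#'
#' The root has global weight 1; a block member's global weight is its local
#' weight within the block times the parent's global weight, so the members
#' of every block conserve their parent's global mass.
#'
#' @param h A [criteria_hierarchy()].
#' @param local Named list: one named numeric weight vector per queried block
#'   (names = block parent id; vector names = member ids), each summing to 1.
#' @return Named numeric vector of global weights for the root and every
#'   block member.
#' @export
global_weights <- function(h, local) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  missing_blocks <- setdiff(names(h$blocks), names(local))
  if (length(missing_blocks)) {
    stop("no local weights for queried block(s): ",
         paste(missing_blocks, collapse = ", "))
  }
  root <- h$nodes$id[is.na(h$nodes$parent)]
  global <- stats::setNames(1, root)
  # parents precede children in level order
  ord <- names(h$blocks)[order(vapply(
    h$blocks, function(b) h$nodes$level[h$nodes$id == b$parent], numeric(1)))]
  for (pid in ord) {
    b <- h$blocks[[pid]]
    w <- local[[pid]]
    if (is.null(names(w))) names(w) <- b$members
    if (!setequal(names(w), b$members)) {
      stop("local weights for block '", pid, "' do not match its members")
    }
    if (!pid %in% names(global)) {
      stop("block parent '", pid, "' has no global weight; ",
           "is its own block missing?")
    }
    global[b$members] <- w[b$members] * global[[pid]]
  }
  global
}
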