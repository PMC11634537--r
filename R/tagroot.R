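## Duplication/speciation tagging and duplication-loss parsimony rooting.
##
## A node is a duplication iff the species sets of its two child subtrees
## intersect; rooting of an unrooted tree picks, over all edges, the rooting
## whose tagging minimizes the weighted duplication-loss score.

#' Tag internal nodes of a rooted gene tree
#'
#' Marks each internal node as a duplication (\code{"D"}) if some species can
#' be reached from both of its children, and as a speciation (\code{"S"})
#' otherwise.  Purely topological; idempotent.
#'
#' @param tree a rooted binary \code{gene_tree} with resolved species labels.
#' @return the tree with every internal node tagged.
#' @export
tag_rooted <- function(tree) {
  stopifnot(is_gene_tree(tree))
  if (!tree$rooted) stop("tag_rooted() requires a rooted tree", call. = FALSE)
  if (!tree_is_binary(tree))
    stop("tag_rooted() requires a binary tree; see resolve_polytomies()",
         call. = FALSE)
  if (anyNA(tree_species(tree)))
    stop("species labels not resolved; see resolve_species()", call. = FALSE)
  tree$root <- tag_node(tree$root)$node
  tree
}

## returns list(node = tagged node, species = unique species under it)
tag_node <- function(node) {
  if (node$leaf) return(list(node = node, species = node$species))
  res <- lapply(node$children, tag_node)
  node$children <- lapply(res, `[[`, "node")
  sets <- lapply(res, `[[`, "species")
  dup <- FALSE
  for (i in seq_along(sets)[-1])
    for (j in seq_len(i - 1))
      if (length(intersect(sets[[i]], sets[[j]])) > 0) dup <- TRUE
  node$tag <- if (dup) "D" else "S"
  list(node = node, species = unique(unlist(sets, use.names = FALSE)))
}

#' Weighted duplication-loss parsimony score of a tagged tree
#'
#' Returns \code{w_dup * D + w_loss * L}, where \code{D} is the number of
#' duplication nodes and \code{L} sums, over duplication nodes with child
#' species sets \code{A} and \code{B}, the implied losses
#' \code{|A \ B| + |B \ A|} (a species present under one duplicate but absent
#' under the other implies one loss).  Speciation nodes contribute nothing.
#'
#' @param tree a tagged rooted \code{gene_tree}.
#' @param w_dup,w_loss non-negative penalties per duplication / per implied
#'   loss; not both zero.  Default 1 and 1 (equal penalties).
#' @return a non-negative number.
#' @export
dl_score <- function(tree, w_dup = 1, w_loss = 1) {
  check_dl_weights(w_dup, w_loss)
  stopifnot(is_gene_tree(tree))
  if (anyNA(node_tags(tree_root(tree))))
    stop("tree is not tagged; see tag_rooted()", call. = FALSE)
  dl_score_node(tree_root(tree), w_dup, w_loss)$score
}

check_dl_weights <- function(w_dup, w_loss) {
  stopifnot(is.numeric(w_dup), is.numeric(w_loss), w_dup >= 0, w_loss >= 0)
  if (w_dup == 0 && w_loss == 0)
    stop("duplication and loss weights must not both be zero", call. = FALSE)
  invisible(TRUE)
}

dl_score_node <- function(node, w_dup, w_loss) {
  if (node$leaf) return(list(score = 0, species = node$species))
  res <- lapply(node$children, dl_score_node, w_dup = w_dup, w_loss = w_loss)
  score <- sum(vapply(res, `[[`, numeric(1), "score"))
  sets <- lapply(res, `[[`, "species")
  if (identical(node$tag, "D")) {
    a <- sets[[1]]; b <- sets[[2]]
    losses <- length(setdiff(a, b)) + length(setdiff(b, a))
    score <- score + w_dup + w_loss * losses
  }
  list(score = score, species = unique(unlist(sets, use.names = FALSE)))
}

#' Root and tag an unrooted gene tree by duplication-loss parsimony
#'
#' Considers every edge of the unrooted tree as a candidate root position,
#' tags the resulting rooted tree, and keeps the rooting with the minimal
#' \code{\link{dl_score}}.  Ties are broken deterministically by the first
#' minimizing edge in a postorder edge enumeration started at the leaf with
#' the lexicographically smallest gene label.
#'
#' @param tree a \code{gene_tree} (its stored orientation is ignored) with
#'   at least 2 leaves and resolved species labels.
#' @inheritParams dl_score
#' @return a tagged rooted \code{gene_tree}, with attributes
#'   \code{"dl_score"} (the minimal score) and \code{"n_candidates"}.
#' @export
root_and_tag <- function(tree, w_dup = 1, w_loss = 1) {
  check_dl_weights(w_dup, w_loss)
  stopifnot(is_gene_tree(tree))
  if (anyNA(tree_species(tree)))
    stop("species labels not resolved; see resolve_species()", call. = FALSE)
  if (n_leaves(tree) == 1L) {
    tree$rooted <- TRUE
    attr(tree, "dl_score") <- 0
    attr(tree, "n_candidates") <- 0L
    return(tree)
  }
  if (n_leaves(tree) == 2L) {
    out <- tag_rooted(new_gene_tree(tree_root(tree), rooted = TRUE))
    attr(out, "dl_score") <- dl_score(out, w_dup, w_loss)
    attr(out, "n_candidates") <- 1L
    return(out)
  }
  g <- tree_graph(tree)
  edges <- graph_edges_postorder(g)
  best <- NULL
  best_score <- Inf
  for (k in seq_len(nrow(edges))) {
    cand <- tag_rooted(graph_root_on_edge(g, edges[k, 1], edges[k, 2]))
    sc <- dl_score(cand, w_dup, w_loss)
    if (sc < best_score) {
      best_score <- sc
      best <- cand
    }
  }
  attr(best, "dl_score") <- best_score
  attr(best, "n_candidates") <- nrow(edges)
  best
}
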