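## Internal recursive tree model.
##
## A tree node is a plain list:
##   leaf node:     list(leaf = TRUE,  gene = <chr>, species = <chr|NA>, length = <num|NA>)
##   internal node: list(leaf = FALSE, children = <list of nodes>,
##                       tag = <"S"|"D"|NA>, length = <num|NA>)
## A gene_tree wraps a root node plus a rooted flag.  Unrooted trees are stored
## with an arbitrary basal arrangement; algorithms that care (rooting search,
## quartet induction) treat them accordingly.

new_leaf_node <- function(gene, species = NA_character_, length = NA_real_) {
  list(leaf = TRUE, gene = gene, species = species, length = length)
}

new_internal_node <- function(children, tag = NA_character_, length = NA_real_) {
  list(leaf = FALSE, children = children, tag = tag, length = length)
}

new_gene_tree <- function(root, rooted = TRUE) {
  structure(list(root = root, rooted = rooted), class = "gene_tree")
}

is_gene_tree <- function(x) inherits(x, "gene_tree")

#' Number of leaves of a gene tree
#'
#' @param tree a \code{gene_tree}.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) {
  node_n_leaves(tree_root(tree))
}

tree_root <- function(tree) {
  if (is_gene_tree(tree)) tree$root else tree
}

node_n_leaves <- function(node) {
  if (node$leaf) return(1L)
  sum(vapply(node$children, node_n_leaves, integer(1)))
}

#' Gene labels of a tree's leaves
#'
#' @param tree a \code{gene_tree}.
#' @return character vector of gene labels in traversal order.
#' @export
tree_genes <- function(tree) {
  node_leaf_field(tree_root(tree), "gene")
}

#' Species labels of a tree's leaves
#'
#' @param tree a \code{gene_tree} whose species labels have been resolved.
#' @return character vector of species labels in traversal order (with
#'   repetitions for multi-copy trees).
#' @export
tree_species <- function(tree) {
  node_leaf_field(tree_root(tree), "species")
}

node_leaf_field <- function(node, field) {
  if (node$leaf) return(node[[field]])
  unlist(lapply(node$children, node_leaf_field, field = field), use.names = FALSE)
}

node_is_binary <- function(node) {
  if (node$leaf) return(TRUE)
  length(node$children) == 2L && all(vapply(node$children, node_is_binary, logical(1)))
}

tree_is_binary <- function(tree) node_is_binary(tree_root(tree))

## Apply f to every internal node bottom-up, rebuilding the tree.
node_postorder_map <- function(node, f) {
  if (node$leaf) return(node)
  node$children <- lapply(node$children, node_postorder_map, f = f)
  f(node)
}

## Collect all nodes in postorder (children before parents) as a flat list.
node_postorder <- function(node) {
  if (node$leaf) return(list(node))
  c(unlist(lapply(node$children, node_postorder), recursive = FALSE), list(node))
}

#' Resolve polytomies to a binary tree
#'
#' Multifurcations are resolved deterministically by left-to-right caterpillar
#' expansion: children are combined pairwise in their stored order, so
#' \code{(a,b,c,d)} becomes \code{(((a,b),c),d)}.  Introduced branches have no
#' length.  Binary trees are returned unchanged.
#'
#' @param tree a \code{gene_tree}.
#' @return a binary \code{gene_tree}.
#' @export
resolve_polytomies <- function(tree) {
  stopifnot(is_gene_tree(tree))
  tree$root <- node_resolve_polytomies(tree$root)
  tree
}

node_resolve_polytomies <- function(node) {
  if (node$leaf) return(node)
  ch <- lapply(node$children, node_resolve_polytomies)
  while (length(ch) > 2L) {
    merged <- new_internal_node(ch[1:2])
    ch <- c(list(merged), ch[-(1:2)])
  }
  node$children <- ch
  node
}

#' @export
print.gene_tree <- function(x, ...) {
  tags <- node_tags(x$root)
  cat(sprintf("gene_tree: %d leaves, %s%s\n", n_leaves(x),
              if (x$rooted) "rooted" else "unrooted",
              if (any(!is.na(tags))) sprintf(", tagged (%d duplication)",
                                             sum(tags == "D", na.rm = TRUE))
              else ""))
  nw <- write_newick(x)
  if (nchar(nw) > 70) nw <- paste0(substr(nw, 1, 67), "...")
  cat(" ", nw, "\n")
  invisible(x)
}

## tags of all internal nodes, preorder
node_tags <- function(node) {
  if (node$leaf) return(character(0))
  c(node$tag, unlist(lapply(node$children, node_tags), use.names = FALSE))
}

n_duplication_nodes <- function(tree) {
  sum(node_tags(tree_root(tree)) == "D", na.rm = TRUE)
}

## ---- adjacency (graph) view, used for re-rooting ------------------------

## Returns list(nbr = list<int vec>, leaf = list<NULL|list(gene, species)>,
##              n = node count).  For a stored-rooted binary tree the root of
## degree 2 is suppressed so the graph is the unrooted topology.
tree_graph <- function(tree) {
  root <- tree_root(tree)
  env <- new.env(parent = emptyenv())
  env$nbr <- list()
  env$leaf <- list()
  env$n <- 0L
  add_node <- function() {
    env$n <- env$n + 1L
    env$nbr[[env$n]] <- integer(0)
    env$leaf[env$n] <- list(NULL)
    env$n
  }
  add_edge <- function(a, b) {
    env$nbr[[a]] <- c(env$nbr[[a]], b)
    env$nbr[[b]] <- c(env$nbr[[b]], a)
  }
  walk <- function(node) {
    id <- add_node()
    if (node$leaf) {
      env$leaf[[id]] <- list(gene = node$gene, species = node$species)
    } else {
      for (ch in node$children) add_edge(id, walk(ch))
    }
    id
  }
  rid <- walk(root)
  ## suppress a degree-2 root (stored-rooted representation of unrooted tree)
  if (length(env$nbr[[rid]]) == 2L) {
    ab <- env$nbr[[rid]]
    env$nbr[[ab[1]]] <- c(setdiff(env$nbr[[ab[1]]], rid), ab[2])
    env$nbr[[ab[2]]] <- c(setdiff(env$nbr[[ab[2]]], rid), ab[1])
    env$nbr[[rid]] <- integer(0)
  }
  list(nbr = env$nbr, leaf = env$leaf, n = env$n)
}

## Deterministic edge enumeration: depth-first postorder from the leaf with
## the lexicographically smallest gene label; neighbours visited in id order.
graph_edges_postorder <- function(g) {
  leaves <- which(!vapply(g$leaf, is.null, logical(1)))
  genes <- vapply(leaves, function(i) g$leaf[[i]]$gene, character(1))
  start <- leaves[order(genes)][1]
  edges <- matrix(integer(0), ncol = 2)
  visit <- function(u, parent) {
    for (v in sort(g$nbr[[u]])) {
      if (v != parent) {
        visit(v, u)
        edges <<- rbind(edges, c(u, v))
      }
    }
  }
  visit(start, 0L)
  edges
}

## Subtree hanging from u, looking away from `parent`, as a recursive node.
graph_subtree <- function(g, u, parent) {
  if (!is.null(g$leaf[[u]])) {
    return(new_leaf_node(g$leaf[[u]]$gene, g$leaf[[u]]$species))
  }
  ch <- lapply(sort(setdiff(g$nbr[[u]], parent)), graph_subtree, g = g, parent = u)
  new_internal_node(ch)
}

## Root the unrooted graph on edge (u, v): new root with the two half-trees.
graph_root_on_edge <- function(g, u, v) {
  new_gene_tree(new_internal_node(list(graph_subtree(g, u, v),
                                       graph_subtree(g, v, u))),
                rooted = TRUE)
}
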