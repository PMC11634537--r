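## DISCO / DISCO-R decomposition of a tagged multi-copy gene tree into
## single-copy trees.
##
## Postorder over the tagged tree; at each duplication node one child subtree
## is pruned (strategy: larger / smaller / random; ties prune the right
## child) and emitted untrimmed.  DISCO-R additionally regrafts, at the
## duplication point, a copy of the pruned subtree trimmed to the species
## absent from the remaining backbone, then contracts degree-2 nodes.  The
## residual backbone is emitted last.

#' Decompose a tagged gene tree into single-copy trees
#'
#' @param tree a tagged rooted binary \code{gene_tree} (see
#'   \code{\link{tag_rooted}} / \code{\link{root_and_tag}}).
#' @param mode \code{"disco"} or \code{"disco-r"} (prune-and-regraft).
#' @param prune_strategy which child subtree to prune at a duplication node:
#'   \code{"larger"} (default; ties prune the right child), \code{"smaller"}
#'   (ties also prune the right child), or \code{"random"}.
#' @param seed integer seed, required iff \code{prune_strategy = "random"}.
#' @return an object of class \code{decomposition}: a list with
#'   \describe{
#'     \item{outputs}{list of single-copy \code{gene_tree}s; the backbone is
#'       the last element.}
#'     \item{provenance}{character vector: \code{"pruned@dup<k>:<L|R>"} for
#'       the subtree emitted at the k-th duplication node in postorder (with
#'       the pruned side), or \code{"backbone"}.}
#'     \item{n_duplications}{duplication-node count of the input.}
#'   }
#'   The number of outputs always equals \code{n_duplications + 1}.
#' @export
decompose <- function(tree, mode = c("disco", "disco-r"),
                      prune_strategy = c("larger", "smaller", "random"),
                      seed = NULL) {
  mode <- match.arg(mode)
  prune_strategy <- match.arg(prune_strategy)
  stopifnot(is_gene_tree(tree))
  if (anyNA(node_tags(tree_root(tree))))
    stop("decompose() requires a tagged tree; see tag_rooted()", call. = FALSE)
  if (!tree_is_binary(tree))
    stop("decompose() requires a binary tree", call. = FALSE)
  if (prune_strategy == "random") {
    if (is.null(seed)) stop("prune_strategy = \"random\" requires a seed",
                            call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  st <- new.env(parent = emptyenv())
  sp_all <- tree_species(tree)
  st$counts <- table_counts(sp_all)
  st$outputs <- list()
  st$prov <- character(0)
  st$dup_i <- 0L

  backbone_root <- decompose_walk(tree_root(tree), mode, prune_strategy, st)
  outputs <- c(st$outputs, list(new_gene_tree(backbone_root, rooted = TRUE)))
  prov <- c(st$prov, "backbone")
  structure(list(outputs = outputs, provenance = prov,
                 mode = mode, prune_strategy = prune_strategy,
                 n_duplications = st$dup_i),
            class = "decomposition")
}

table_counts <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

decompose_walk <- function(node, mode, strategy, st) {
  if (node$leaf) return(node)
  node$children <- lapply(node$children, decompose_walk,
                          mode = mode, strategy = strategy, st = st)
  if (!identical(node$tag, "D")) return(node)

  st$dup_i <- st$dup_i + 1L
  sizes <- vapply(node$children, node_n_leaves, integer(1))
  prune_i <- switch(strategy,
    larger  = if (sizes[1] > sizes[2]) 1L else 2L,
    smaller = if (sizes[1] < sizes[2]) 1L else 2L,
    random  = sample.int(2L, 1L))
  gv <- node$children[[prune_i]]
  keep <- node$children[[3L - prune_i]]

  ## emit the untrimmed pruned subtree
  st$outputs <- c(st$outputs, list(new_gene_tree(strip_length(gv), rooted = TRUE)))
  st$prov <- c(st$prov, sprintf("pruned@dup%d:%s", st$dup_i, c("L", "R")[prune_i]))

  ## the whole-tree species multiset loses g_v's leaves
  st$counts <- decrement_counts(st$counts, tree_species(gv))

  if (mode == "disco-r") {
    backbone_species <- names(st$counts)[st$counts > 0L]
    trimmed <- node_drop_species(gv, backbone_species)
    if (!is.null(trimmed)) {
      st$counts <- increment_counts(st$counts, node_leaf_field(trimmed, "species"))
      return(new_internal_node(list(keep, strip_length(trimmed)), tag = "S"))
    }
  }
  keep
}

strip_length <- function(node) { node$length <- NA_real_; node }

decrement_counts <- function(counts, species) {
  d <- table_counts(species)
  counts[names(d)] <- counts[names(d)] - d
  counts
}

increment_counts <- function(counts, species) {
  d <- table_counts(species)
  new <- setdiff(names(d), names(counts))
  if (length(new)) counts[new] <- 0L
  counts[names(d)] <- counts[names(d)] + d
  counts
}

## delete every leaf whose species is in `drop`; contract degree-2 nodes.
## Returns NULL when nothing remains.
node_drop_species <- function(node, drop) {
  if (node$leaf) {
    if (node$species %in% drop) return(NULL)
    return(node)
  }
  ch <- Filter(Negate(is.null),
               lapply(node$children, node_drop_species, drop = drop))
  if (length(ch) == 0L) return(NULL)
  if (length(ch) == 1L) return(ch[[1]])
  node$children <- ch
  node
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition (%s, prune %s): %d duplication node(s), %d output tree(s)\n",
              x$mode, x$prune_strategy, x$n_duplications, length(x$outputs)))
  sizes <- vapply(x$outputs, n_leaves, integer(1))
  cat("  leaves per output:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
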