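## Robinson-Foulds comparison of estimated vs true species trees.

#' Robinson-Foulds distance between two species trees
#'
#' Counts the symmetric difference of the two trees' nontrivial bipartition
#' sets (via phangorn) and normalizes by \code{2(n-3)}, its maximum for two
#' binary trees on n shared leaves.  The two trees must have identical leaf
#' sets; mismatches are an error rather than a silent restriction.
#'
#' @param t1,t2 single-labeled binary \code{gene_tree}s (or newick strings)
#'   on the same n >= 4 leaves.
#' @return a \code{tree_comparison}: list with \code{rf_raw},
#'   \code{rf_normalized} and \code{shared_leaf_count}.
#' @export
rf_distance <- function(t1, t2) {
  t1 <- as_species_phylo(t1)
  t2 <- as_species_phylo(t2)
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in tree 1: {",
         paste(only1, collapse = ", "), "}; only in tree 2: {",
         paste(only2, collapse = ", "), "}", call. = FALSE)
  }
  n <- length(l1)
  if (n < 4L) stop("rf_distance() requires n >= 4 leaves", call. = FALSE)
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  if (!ape::is.binary(u1) || !ape::is.binary(u2))
    stop("rf_distance() requires binary trees", call. = FALSE)
  raw <- as.integer(phangorn::RF.dist(u1, u2))
  structure(list(rf_raw = raw, rf_normalized = raw / (2 * (n - 3)),
                 shared_leaf_count = n),
            class = "tree_comparison")
}

as_species_phylo <- function(t) {
  if (inherits(t, "phylo")) return(t)
  if (is.character(t)) t <- parse_newick(t)
  stopifnot(is_gene_tree(t))
  labels <- if (!anyNA(tree_species(t))) "species" else "gene"
  gene_tree_to_phylo(t, labels = labels)
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("tree_comparison: RF %d / %d shared leaves (normalized %.4f)\n",
              x$rf_raw, x$shared_leaf_count, x$rf_normalized))
  invisible(x)
}

#' Summarize normalized RF distances over replicates
#'
#' @param comparisons a non-empty list of \code{tree_comparison} objects (or
#'   a numeric vector of normalized RF values).
#' @return list with \code{mean}, \code{se} (standard error of the mean; 0
#'   for a single replicate) and \code{n}.
#' @export
summarize_replicates <- function(comparisons) {
  vals <- if (is.numeric(comparisons)) comparisons
          else vapply(comparisons, function(x) x$rf_normalized, numeric(1))
  if (!length(vals)) stop("empty collection of comparisons", call. = FALSE)
  se <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else 0
  list(mean = mean(vals), se = se, n = length(vals))
}
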