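## Quartet machinery: induced quartets of single-copy trees, gene-tree
## frequency (GTF) weight tables, speciation-driven quartet (SQ)
## classification of tagged multi-copy trees, and the weighted-quartet file
## dialect.
##
## A quartet topology on species {a,b,c,d} is one of ab|cd, ac|bd, ad|bc and
## is stored as the canonical key "a,b|c,d": labels sorted within each pair,
## pairs ordered by their smallest member.

canonical_quartet <- function(p1, p2) {
  p1 <- sort(p1); p2 <- sort(p2)
  if (p2[1] < p1[1]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  paste0(p1[1], ",", p1[2], "|", p2[1], ",", p2[2])
}

parse_quartet_key <- function(key) {
  halves <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("malformed quartet key: ", key, call. = FALSE)
  list(p1 = strsplit(halves[1], ",", fixed = TRUE)[[1]],
       p2 = strsplit(halves[2], ",", fixed = TRUE)[[1]])
}

#' Construct a quartet weight table
#'
#' @param weights a named numeric vector; names are quartet keys of the form
#'   \code{"a,b|c,d"} (canonicalized on input), values non-negative weights.
#' @return a \code{quartet_table}: a named numeric vector in canonical sorted
#'   key order.
#' @export
quartet_table <- function(weights = numeric(0)) {
  stopifnot(is.numeric(weights), all(weights >= 0))
  if (length(weights)) {
    stopifnot(!is.null(names(weights)))
    keys <- vapply(names(weights), function(k) {
      p <- parse_quartet_key(k)
      if (length(unique(c(p$p1, p$p2))) != 4L)
        stop("quartet key must name four distinct species: ", k, call. = FALSE)
      canonical_quartet(p$p1, p$p2)
    }, character(1))
    weights <- tapply(weights, keys, sum)
    weights <- stats::setNames(as.numeric(weights), names(weights))
    weights <- weights[order(names(weights))]
  }
  structure(weights, class = "quartet_table")
}

#' @export
print.quartet_table <- function(x, ...) {
  cat(sprintf("quartet_table: %d topologies, total weight %g, %d species\n",
              length(x), sum(x), length(table_species(x))))
  if (length(x)) {
    show <- utils::head(unclass(x), 6)
    for (i in seq_along(show)) cat(sprintf("  %s  %g\n", names(show)[i], show[i]))
    if (length(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

table_species <- function(table) {
  if (!length(table)) return(character(0))
  sort(unique(unlist(lapply(names(table), function(k) {
    p <- parse_quartet_key(k)
    c(p$p1, p$p2)
  }), use.names = FALSE)))
}

## ---- topological leaf distances -----------------------------------------
##
## Unrooted path lengths (unit edges) between species of a single-copy tree.
## A stored degree-2 root is suppressed so distances are those of the
## unrooted topology.

species_distance_matrix <- function(tree) {
  root <- tree_root(tree)
  sp <- tree_species(if (is_gene_tree(tree)) tree else new_gene_tree(root))
  if (anyNA(sp)) stop("species labels not resolved", call. = FALSE)
  if (anyDuplicated(sp)) stop("tree is not single-labeled", call. = FALSE)
  n <- length(sp)
  D <- matrix(0L, n, n, dimnames = list(sp, sp))
  walk <- function(node, at_root) {
    if (node$leaf) return(list(idx = match(node$species, sp), d = 0L))
    parts <- lapply(node$children, walk, at_root = FALSE)
    suppress <- at_root && length(parts) == 2L
    for (i in seq_along(parts)[-1]) {
      for (j in seq_len(i - 1)) {
        extra <- if (suppress) 1L else 2L
        cross <- outer(parts[[i]]$d, parts[[j]]$d, `+`) + extra
        D[parts[[i]]$idx, parts[[j]]$idx] <<- cross
        D[parts[[j]]$idx, parts[[i]]$idx] <<- t(cross)
      }
    }
    list(idx = unlist(lapply(parts, `[[`, "idx"), use.names = FALSE),
         d = unlist(lapply(parts, function(p) p$d + 1L), use.names = FALSE))
  }
  walk(root, at_root = TRUE)
  D
}

## induced pairing indices for sorted 4-sets given a distance matrix.
## combs: 4 x m matrix of sorted indices i<j<k<l.  Returns 1 (ij|kl),
## 2 (ik|jl) or 3 (il|jk) per column (four-point condition: the split pair
## sum is strictly the smallest for a binary tree).
induced_pairings <- function(D, combs) {
  i <- combs[1, ]; j <- combs[2, ]; k <- combs[3, ]; l <- combs[4, ]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  ifelse(s1 <= s2 & s1 <= s3, 1L, ifelse(s2 <= s3, 2L, 3L))
}

pairing_key <- function(sp4, pairing) {
  ## sp4 sorted ascending
  switch(pairing,
         canonical_quartet(sp4[c(1, 2)], sp4[c(3, 4)]),
         canonical_quartet(sp4[c(1, 3)], sp4[c(2, 4)]),
         canonical_quartet(sp4[c(1, 4)], sp4[c(2, 3)]))
}

## all induced quartet keys of one single-copy tree (character vector)
tree_quartet_keys <- function(tree) {
  sp <- sort(tree_species(tree))
  n <- length(sp)
  if (n < 4L) return(character(0))
  D <- species_distance_matrix(tree)
  D <- D[sp, sp, drop = FALSE]
  combs <- utils::combn(n, 4L)
  pr <- induced_pairings(D, combs)
  vapply(seq_len(ncol(combs)), function(q)
    pairing_key(sp[combs[, q]], pr[q]), character(1))
}

#' Induced quartet topology of four species in a single-copy tree
#'
#' @param tree a single-labeled \code{gene_tree} (rooted or unrooted).
#' @param species four distinct species labels, all present in the tree.
#' @return the canonical quartet key, e.g. \code{"a,b|c,d"}.
#' @export
induced_quartet <- function(tree, species) {
  species <- sort(unique(species))
  stopifnot(length(species) == 4L)
  sp <- tree_species(tree)
  missing <- setdiff(species, sp)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  D <- species_distance_matrix(tree)[species, species]
  pr <- induced_pairings(D, matrix(1:4, ncol = 1))
  pairing_key(species, pr)
}

#' Gene-tree frequency (GTF) quartet table
#'
#' The weight of a topology is the number of input trees that both contain
#' its four species and induce it; every 4-subset of every tree is
#' enumerated.  Trees with fewer than four leaves induce no quartets and are
#' skipped.
#'
#' @param trees a list of single-labeled \code{gene_tree}s (e.g. the outputs
#'   of \code{\link{decompose}}), or a \code{decomposition}.
#' @return a \code{quartet_table} with integer weights.
#' @export
gtf_table <- function(trees) {
  trees <- as_tree_list(trees)
  for (t in trees)
    if (!check_single_labeled(t))
      stop("gtf_table() requires single-labeled trees", call. = FALSE)
  keys <- unlist(lapply(trees, tree_quartet_keys), use.names = FALSE)
  if (!length(keys)) return(quartet_table())
  tb <- table(keys)
  quartet_table(stats::setNames(as.numeric(tb), names(tb)))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "decomposition")) return(trees$outputs)
  if (is_gene_tree(trees)) return(list(trees))
  stopifnot(is.list(trees))
  trees
}

#' Quartet topologies covered by a collection of single-copy trees
#'
#' @inheritParams gtf_table
#' @return sorted character vector of canonical quartet keys (the union over
#'   trees of all induced topologies).
#' @export
covered_quartets <- function(trees) {
  trees <- as_tree_list(trees)
  keys <- unlist(lapply(trees, tree_quartet_keys), use.names = FALSE)
  sort(unique(as.character(keys)))
}

#' Speciation-driven quartets of a tagged multi-copy gene tree
#'
#' A quartet of four genes from four distinct species is speciation-driven
#' (SQ) when every cross-pair least common ancestor -- LCA(x, y) for x in one
#' pair and y in the other of the induced pairing -- is tagged speciation.
#' Quartets are reported at species level (copy indices dropped).
#'
#' @param tree a tagged rooted \code{gene_tree}.
#' @return sorted character vector of canonical quartet keys.
#' @export
sq_set <- function(tree) {
  stopifnot(is_gene_tree(tree))
  root <- tree_root(tree)
  if (anyNA(node_tags(root)))
    stop("sq_set() requires a tagged tree; see tag_rooted()", call. = FALSE)

  ## flatten: per-leaf ancestor paths (node ids root->leaf), tags per node
  st <- new.env(parent = emptyenv())
  st$tag <- character(0)
  st$leaf_path <- list()
  st$leaf_sp <- character(0)
  walk <- function(node, path) {
    id <- length(st$tag) + 1L
    st$tag[id] <- if (node$leaf) NA_character_ else node$tag
    path <- c(path, id)
    if (node$leaf) {
      st$leaf_path[[length(st$leaf_path) + 1L]] <- path
      st$leaf_sp[length(st$leaf_sp) + 1L] <- node$species
    } else {
      for (ch in node$children) walk(ch, path)
    }
  }
  walk(root, integer(0))

  nl <- length(st$leaf_sp)
  if (nl < 4L) return(character(0))
  ## pairwise LCA id and depth
  lca <- matrix(0L, nl, nl)
  lca_depth <- matrix(0L, nl, nl)
  for (i in seq_len(nl - 1)) {
    pi <- st$leaf_path[[i]]
    for (j in (i + 1):nl) {
      pj <- st$leaf_path[[j]]
      m <- min(length(pi), length(pj))
      common <- which(pi[seq_len(m)] == pj[seq_len(m)])
      d <- max(common)
      lca[i, j] <- lca[j, i] <- pi[d]
      lca_depth[i, j] <- lca_depth[j, i] <- d
    }
  }

  combs <- utils::combn(nl, 4L)
  out <- character(0)
  pair_idx <- utils::combn(4L, 2L)            # six pairs within a 4-set
  for (q in seq_len(ncol(combs))) {
    g <- combs[, q]
    sp <- st$leaf_sp[g]
    if (anyDuplicated(sp)) next
    ## induced pairing: the pair with the deepest LCA is a cherry
    depths <- lca_depth[cbind(g[pair_idx[1, ]], g[pair_idx[2, ]])]
    cherry <- pair_idx[, which.max(depths)]
    p1 <- g[cherry]
    p2 <- setdiff(g, p1)
    ## all cross-pair LCAs must be speciation nodes
    cross <- lca[cbind(rep(p1, each = 2L), rep(p2, 2L))]
    if (all(st$tag[unique(cross)] == "S"))
      out <- c(out, canonical_quartet(sp[match(p1, g)], sp[match(p2, g)]))
  }
  sort(unique(out))
}

## ---- weighted-quartet file dialect --------------------------------------

#' Write a quartet table to a weighted-quartet file
#'
#' One record per line, \code{"((A,B),(C,D)); W"}, in canonical ordering and
#' sorted line order -- the input dialect of weighted quartet amalgamation
#' tools.
#'
#' @param table a \code{quartet_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_quartets <- function(table, path) {
  stopifnot(inherits(table, "quartet_table"))
  keys <- sort(names(table))
  lines <- vapply(keys, function(k) {
    p <- parse_quartet_key(k)
    sprintf("((%s,%s),(%s,%s)); %g", p$p1[1], p$p1[2], p$p2[1], p$p2[2],
            unname(table[k]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted-quartet file
#'
#' @param path file path in the \code{\link{write_quartets}} dialect.
#' @return a \code{quartet_table}.
#' @export
read_quartets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(quartet_table())
  pat <- "^\\(\\(([^,()]+),([^,()]+)\\),\\(([^,()]+),([^,()]+)\\)\\);\\s*([0-9eE.+-]+)$"
  bad <- !grepl(pat, lines)
  if (any(bad))
    stop("malformed weighted-quartet line: ", lines[which(bad)[1]], call. = FALSE)
  m <- regmatches(lines, regexec(pat, lines))
  keys <- vapply(m, function(x) canonical_quartet(x[2:3], x[4:5]), character(1))
  w <- vapply(m, function(x) as.numeric(x[6]), numeric(1))
  quartet_table(stats::setNames(w, keys))
}
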