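## Weighted Maximum Quartet Consistency (WMQC): given a quartet weight table
## on a taxon set, find the unrooted binary tree maximizing the total weight
## of consistent quartets.  `exact_wmqc()` enumerates all (2n-5)!! topologies
## (the correctness anchor, n <= 9); `heuristic_wmqc()` is a
## Fiduccia-Mattheyses-style recursive bipartitioning of the same objective.

.wmqc_cache <- new.env(parent = emptyenv())

## Enumerate all unrooted binary topologies on n taxa by stepwise addition.
## Taxon 1 hangs off the root of a nested-pair structure over taxa 2..n.
## Returns list(combs = 4 x m sorted index 4-sets,
##              ind   = n_top x m induced-pairing matrix (values 1..3),
##              trees = character vector of nested serializations).
enumerate_topologies <- function(n) {
  key <- as.character(n)
  if (!is.null(.wmqc_cache[[key]])) return(.wmqc_cache[[key]])
  stopifnot(n >= 4L, n <= 9L)
  combs <- utils::combn(n, 4L)

  insert_all <- function(t, x) {
    res <- list(list(t, x))
    if (is.list(t)) {
      for (v in insert_all(t[[1]], x)) res[[length(res) + 1L]] <- list(v, t[[2]])
      for (v in insert_all(t[[2]], x)) res[[length(res) + 1L]] <- list(t[[1]], v)
    }
    res
  }
  trees <- list(2L)
  if (n >= 4L) for (x in 3:(n - 1)) {
    trees <- unlist(lapply(trees, insert_all, x = n_to_int(x)), recursive = FALSE)
  }
  ## stream the final insertion, computing pairing rows on the fly
  n_top <- prod(seq(2L * n - 5L, 1L, by = -2L))
  m <- ncol(combs)
  ind <- matrix(0L, n_top, m)
  strs <- character(n_top)
  row <- 0L
  for (t in trees) {
    for (full in insert_all(t, n_to_int(n))) {
      row <- row + 1L
      D <- nested_distances(full, n)
      ind[row, ] <- induced_pairings(D, combs)
      strs[row] <- nested_to_str(full)
    }
  }
  stopifnot(row == n_top)
  res <- list(combs = combs, ind = ind, trees = strs)
  .wmqc_cache[[key]] <- res
  res
}

n_to_int <- function(x) as.integer(x)

nested_to_str <- function(t) {
  if (!is.list(t)) return(as.character(t))
  paste0("(", nested_to_str(t[[1]]), ",", nested_to_str(t[[2]]), ")")
}

## unrooted unit-edge leaf distances: the root of the nested structure is a
## real degree-3 node (its two children plus leaf 1).
nested_distances <- function(t, n) {
  D <- matrix(0L, n, n)
  walk <- function(t) {
    if (!is.list(t)) return(list(idx = t, d = 0L))
    a <- walk(t[[1]]); b <- walk(t[[2]])
    cross <- outer(a$d, b$d, `+`) + 2L
    D[a$idx, b$idx] <<- cross
    D[b$idx, a$idx] <<- t(cross)
    list(idx = c(a$idx, b$idx), d = c(a$d + 1L, b$d + 1L))
  }
  top <- walk(t)
  D[1, top$idx] <- top$d + 1L
  D[top$idx, 1] <- top$d + 1L
  D
}

## weight matrix (m x 3) of a table over sorted taxa; entries with species
## outside `taxa` are ignored.
table_weight_matrix <- function(table, taxa, combs) {
  m <- ncol(combs)
  W <- matrix(0, m, 3L)
  if (!length(table)) return(W)
  rowkey <- apply(combs, 2, paste, collapse = ".")
  rowix <- stats::setNames(seq_len(m), rowkey)
  for (k in seq_along(table)) {
    p <- parse_quartet_key(names(table)[k])
    idx <- match(c(p$p1, p$p2), taxa)
    if (anyNA(idx)) next
    s <- sort(idx)
    ## pairing index relative to sorted order: which element pairs with s[1]
    first <- s[1]
    mate <- if (first == idx[1]) idx[2] else if (first == idx[2]) idx[1]
            else if (first == idx[3]) idx[4] else idx[3]
    pairing <- match(mate, s) - 1L          # 1 -> ij|kl, 2 -> ik|jl, 3 -> il|jk
    W[rowix[[paste(s, collapse = ".")]], pairing] <-
      W[rowix[[paste(s, collapse = ".")]], pairing] + unname(table[k])
  }
  W
}

wmqc_result <- function(tree, satisfied, total) {
  structure(list(tree = tree,
                 satisfied_weight = satisfied,
                 normalized_score = if (total > 0) satisfied / total else 0),
            class = "wmqc_result")
}

#' @export
print.wmqc_result <- function(x, ...) {
  cat(sprintf("wmqc_result: satisfied weight %g (normalized score %.4f)\n",
              x$satisfied_weight, x$normalized_score))
  cat(" ", write_newick(x$tree, labels = "species"), "\n")
  invisible(x)
}

## nested serialization -> gene_tree with taxa labels
nested_str_to_tree <- function(str, taxa) {
  gt <- parse_newick(paste0(sub("\\)$", ",1)", str), ";"))
  relabel <- function(node) {
    if (node$leaf) {
      lab <- taxa[as.integer(node$gene)]
      node$gene <- lab; node$species <- lab
      return(node)
    }
    node$children <- lapply(node$children, relabel)
    node
  }
  new_gene_tree(relabel(gt$root), rooted = FALSE)
}

#' Exact weighted maximum quartet consistency
#'
#' Scores every unrooted binary topology on the taxon set against the quartet
#' table and returns one attaining the maximum satisfied weight (ties broken
#' by the first topology in a deterministic stepwise-addition enumeration
#' order).  Intended as the correctness anchor for small taxon sets; the
#' number of topologies is (2n-5)!!, so n is capped at 9.
#'
#' @param table a \code{quartet_table}; entries naming species outside
#'   \code{taxa} are ignored (and excluded from the score denominator).
#' @param taxa character vector of 4 to 9 distinct taxon labels.
#' @return a \code{wmqc_result}: list with \code{tree} (unrooted
#'   \code{gene_tree}), \code{satisfied_weight} and \code{normalized_score}.
#' @export
exact_wmqc <- function(table, taxa) {
  taxa <- sort(unique(taxa))
  n <- length(taxa)
  if (n < 4L || n > 9L)
    stop("exact_wmqc() requires 4 <= |taxa| <= 9 (got ", n, ")", call. = FALSE)
  stopifnot(inherits(table, "quartet_table"))
  enum <- enumerate_topologies(n)
  W <- table_weight_matrix(table, taxa, enum$combs)
  scores <- score_topologies(enum$ind, W)
  best <- which.max(scores)
  tree <- nested_str_to_tree(enum$trees[best], taxa)
  wmqc_result(tree, scores[best], sum(W))
}

score_topologies <- function(ind, W, chunk = 20000L) {
  m <- ncol(ind)
  Wv <- as.vector(W)                         # column-major: W[q, p] = Wv[(p-1)m + q]
  n_top <- nrow(ind)
  scores <- numeric(n_top)
  for (start in seq(1L, n_top, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_top)
    block <- ind[rows, , drop = FALSE]
    li <- (block - 1L) * m + matrix(seq_len(m), nrow(block), m, byrow = TRUE)
    scores[rows] <- rowSums(matrix(Wv[li], nrow(block), m))
  }
  scores
}

#' Quartet consistency score of a given species tree
#'
#' Computes the total table weight consistent with the tree and the
#' normalized quartet score (satisfied weight over the total weight of table
#' entries whose four species are all present in the tree; entries with
#' absent species are ignored and excluded from the denominator).
#'
#' @param tree a single-labeled \code{gene_tree} on (a superset of) the
#'   table's species.
#' @param table a \code{quartet_table}.
#' @return a \code{wmqc_result}.
#' @export
quartet_score <- function(tree, table) {
  stopifnot(inherits(table, "quartet_table"))
  if (anyNA(tree_species(tree))) {
    if (is_gene_tree(tree)) tree$root <- species_from_genes(tree$root)
    else tree <- species_from_genes(tree)
  }
  sp <- tree_species(tree)
  satisfied <- 0; total <- 0
  if (length(table)) {
    D <- species_distance_matrix(tree)
    for (k in seq_along(table)) {
      p <- parse_quartet_key(names(table)[k])
      four <- c(p$p1, p$p2)
      if (!all(four %in% sp)) next
      w <- unname(table[k])
      total <- total + w
      if (D[p$p1[1], p$p1[2]] + D[p$p2[1], p$p2[2]] <
          min(D[p$p1[1], p$p2[1]] + D[p$p1[2], p$p2[2]],
              D[p$p1[1], p$p2[2]] + D[p$p1[2], p$p2[1]]))
        satisfied <- satisfied + w
    }
  }
  wmqc_result(tree, satisfied, total)
}

## ---- Fiduccia-Mattheyses heuristic --------------------------------------

#' Heuristic weighted maximum quartet consistency
#'
#' Divide-and-conquer in the Quartet-FM style: the taxon set is recursively
#' bipartitioned, starting from a seed-driven random balanced split and
#' improved by single-taxon moves with quartet-weight gain under the
#' Fiduccia-Mattheyses discipline (each taxon locked after moving, the best
#' prefix of each move pass kept).  Quartets spanning both sides with a 3-1
#' split are deferred into the subproblem via a dummy taxon representing the
#' opposite side.  Several seeded restarts are taken and the tree with the
#' best quartet score is returned.  Deterministic given the seed.
#'
#' @inheritParams exact_wmqc
#' @param taxa character vector of at least 4 distinct taxon labels.
#' @param seed integer seed driving all random choices.
#' @param n_starts number of random restarts (default 5).
#' @return a \code{wmqc_result}.
#' @export
heuristic_wmqc <- function(table, taxa, seed = 1L, n_starts = 5L) {
  taxa <- sort(unique(taxa))
  stopifnot(length(taxa) >= 4L, inherits(table, "quartet_table"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  entries <- lapply(names(table), function(k) {
    p <- parse_quartet_key(k)
    list(p1 = p$p1, p2 = p$p2, lab = c(p$p1, p$p2), w = unname(table[[k]]))
  })
  entries <- Filter(function(e) all(e$lab %in% taxa), entries)

  dummy_counter <- new.env(parent = emptyenv()); dummy_counter$i <- 0L
  best <- NULL
  for (s in seq_len(n_starts)) {
    root <- fm_recurse(taxa, entries, dummy_counter)
    cand <- quartet_score(new_gene_tree(root, rooted = FALSE), table)
    if (is.null(best) || cand$satisfied_weight > best$satisfied_weight)
      best <- cand
  }
  best
}

fm_new_dummy <- function(counter) {
  counter$i <- counter$i + 1L
  sprintf(".side%d", counter$i)
}

taxon_leaf <- function(lab) new_leaf_node(lab, species = lab)

## returns an (arbitrarily rooted) recursive node over `taxa`
fm_recurse <- function(taxa, entries, counter) {
  m <- length(taxa)
  if (m == 1L) return(taxon_leaf(taxa))
  if (m == 2L) return(new_internal_node(lapply(taxa, taxon_leaf)))
  if (m == 3L) return(new_internal_node(list(
    taxon_leaf(taxa[1]),
    new_internal_node(lapply(taxa[-1], taxon_leaf)))))
  if (m == 4L) {
    s <- sort(taxa)
    w3 <- vapply(1:3, function(p) {
      key <- pairing_key(s, p)
      sum(vapply(entries, function(e)
        if (canonical_quartet(e$p1, e$p2) == key) e$w else 0, numeric(1)))
    }, numeric(1))
    p <- which.max(w3)
    pairs <- switch(p, list(s[c(1, 2)], s[c(3, 4)]),
                       list(s[c(1, 3)], s[c(2, 4)]),
                       list(s[c(1, 4)], s[c(2, 3)]))
    return(new_internal_node(list(
      new_internal_node(lapply(pairs[[1]], taxon_leaf)),
      new_internal_node(lapply(pairs[[2]], taxon_leaf)))))
  }

  split <- fm_partition(taxa, entries)
  A <- split$A; B <- split$B
  dB <- fm_new_dummy(counter)
  dA <- fm_new_dummy(counter)
  tA <- fm_recurse(c(A, dB), fm_project(entries, A, dB), counter)
  tB <- fm_recurse(c(B, dA), fm_project(entries, B, dA), counter)
  new_internal_node(list(root_at_leaf(tA, dB), root_at_leaf(tB, dA)))
}

## keep 4-in-side quartets; map 3-in-side quartets' outside taxon to `dummy`
fm_project <- function(entries, side, dummy) {
  out <- list()
  for (e in entries) {
    inside <- e$lab %in% side
    k <- sum(inside)
    if (k == 4L) {
      out[[length(out) + 1L]] <- e
    } else if (k == 3L) {
      repl <- function(p) { p[!(p %in% side)] <- dummy; p }
      p1 <- repl(e$p1); p2 <- repl(e$p2)
      out[[length(out) + 1L]] <- list(p1 = p1, p2 = p2, lab = c(p1, p2), w = e$w)
    }
  }
  out
}

## FM bipartition with both sides kept >= 2
fm_partition <- function(taxa, entries, max_passes = 10L) {
  taxa <- sort(taxa)
  m <- length(taxa)
  rel <- Filter(function(e) all(e$lab %in% taxa), entries)
  side <- stats::setNames(integer(m), taxa)
  perm <- sample.int(m)
  side[perm[seq_len(m %/% 2L)]] <- 1L
  side[perm[(m %/% 2L + 1L):m]] <- 2L

  part_score <- function(side) {
    s <- 0
    for (e in rel) {
      a <- side[e$p1]; b <- side[e$p2]
      if (a[1] == a[2] && b[1] == b[2]) {
        if (a[1] != b[1]) s <- s + e$w
      } else if (a[1] != a[2] && b[1] != b[2]) {
        s <- s - e$w                          # 2-2 split with the wrong pairing
      }
    }
    s
  }

  cur <- part_score(side)
  for (pass in seq_len(max_passes)) {
    locked <- stats::setNames(logical(m), taxa)
    trail <- character(0)
    cum <- numeric(0)
    side0 <- side
    start_score <- cur
    repeat {
      movable <- names(side)[!locked & side %in%
                               which(tabulate(side, 2L) > 2L)]
      if (!length(movable)) break
      gains <- vapply(movable, function(t) {
        s2 <- side; s2[t] <- 3L - s2[t]
        part_score(s2) - cur
      }, numeric(1))
      t <- movable[which.max(gains)]
      side[t] <- 3L - side[t]
      cur <- cur + gains[t]
      locked[t] <- TRUE
      trail <- c(trail, t)
      cum <- c(cum, cur)
    }
    if (!length(cum) || max(cum) <= start_score) {
      side <- side0; cur <- start_score
      break
    }
    kstar <- which.max(cum)
    if (kstar < length(trail))
      for (t in trail[(kstar + 1L):length(trail)]) side[t] <- 3L - side[t]
    cur <- cum[kstar]
  }
  list(A = names(side)[side == 1L], B = names(side)[side == 2L])
}

## reroot an arbitrarily rooted node structure at leaf `label`'s attachment
## point and drop that leaf
root_at_leaf <- function(node, label) {
  g <- tree_graph(node)
  leaf_ids <- which(!vapply(g$leaf, is.null, logical(1)))
  id <- leaf_ids[vapply(leaf_ids, function(i) g$leaf[[i]]$gene == label, logical(1))]
  stopifnot(length(id) == 1L)
  u <- g$nbr[[id]]
  stopifnot(length(u) == 1L)
  graph_subtree(g, u, id)
}
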