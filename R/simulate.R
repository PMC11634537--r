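## DLCoal simulation of multi-copy gene trees: a top-down duplication/loss
## process along the species tree produces a locus tree; a bottom-up bounded
## multispecies coalescent (b-MSC) along the locus tree produces the gene
## tree.  Times are in generations; one coalescent unit equals `pop_size`
## generations (haploid population).

#' DLCoal simulation parameters
#'
#' @param species_tree a rooted binary \code{gene_tree} (or newick string)
#'   with positive branch lengths in generations; leaf labels are species
#'   names.
#' @param dup_rate duplication rate, events per gene per generation.
#' @param loss_rate loss rate, events per gene per generation.
#' @param pop_size haploid population size (constant across branches).
#' @param n_genes number of gene families to draw.
#' @param seed integer seed.
#' @return a \code{dlcoal_params} object.
#' @export
dlcoal_params <- function(species_tree, dup_rate, loss_rate, pop_size,
                          n_genes = 1L, seed = 1L) {
  if (is.character(species_tree)) species_tree <- parse_newick(species_tree)
  stopifnot(is_gene_tree(species_tree))
  species_tree$root <- species_from_genes(species_tree$root)
  if (!species_tree$rooted || !tree_is_binary(species_tree))
    stop("species tree must be rooted and binary", call. = FALSE)
  lens <- node_all_lengths(species_tree$root)
  if (anyNA(lens) || any(lens <= 0))
    stop("species tree must have positive branch lengths on all non-root edges",
         call. = FALSE)
  stopifnot(dup_rate >= 0, loss_rate >= 0, pop_size > 0, n_genes >= 1)
  structure(list(species_tree = species_tree, dup_rate = dup_rate,
                 loss_rate = loss_rate, pop_size = pop_size,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "dlcoal_params")
}

## species labels of a species tree are its leaf labels verbatim
species_from_genes <- function(node) {
  if (node$leaf) { node$species <- node$gene; return(node) }
  node$children <- lapply(node$children, species_from_genes)
  node
}

## branch lengths of all non-root nodes
node_all_lengths <- function(node) {
  if (node$leaf) return(node$length)
  unlist(c(lapply(node$children, node_all_lengths)), use.names = FALSE)
}

#' Simulate a locus tree under the duplication/loss process
#'
#' Runs independent Poisson duplication (rate \code{dup_rate}) and loss
#' (rate \code{loss_rate}) processes top-down along every lineage of the
#' species tree.  A duplication spawns a daughter locus that continues down
#' the species tree from the duplication point; a loss terminates the
#' lineage.  Lost lineages are pruned (contracting degree-2 nodes and adding
#' branch lengths); a family in which every copy is lost is reported as
#' extinct.
#'
#' @param params a \code{dlcoal_params} object.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return a \code{locus_tree}: list with \code{root} (annotated node
#'   structure; internal nodes carry \code{type} \code{"spec"}/\code{"dup"},
#'   duplication children are ordered mother-then-daughter), \code{extinct}
#'   (logical) and \code{n_duplications} (surviving duplication nodes).
#' @export
simulate_locus_tree <- function(params, seed = NULL) {
  stopifnot(inherits(params, "dlcoal_params"))
  if (!is.null(seed)) set.seed(seed)
  rate <- params$dup_rate + params$loss_rate
  p_dup <- if (rate > 0) params$dup_rate / rate else 0

  evolve <- function(sp_node, offset) {
    blen <- sp_node$length
    t <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (offset + t < blen) {
      if (stats::runif(1) < p_dup) {
        mother <- evolve(sp_node, offset + t)
        daughter <- evolve(sp_node, offset + t)
        locus_node("dup", list(mother, daughter), len = t)
      } else {
        locus_node("loss", NULL, len = t)
      }
    } else {
      dt <- blen - offset
      if (sp_node$leaf) {
        locus_node("copy", NULL, len = dt, species = sp_node$species)
      } else {
        locus_node("spec", lapply(sp_node$children, evolve, offset = 0), len = dt)
      }
    }
  }
  sp_root <- params$species_tree$root
  root <- locus_node("spec", lapply(sp_root$children, evolve, offset = 0), len = 0)
  pruned <- prune_losses(root)
  extinct <- is.null(pruned) || pruned$type %in% c("loss")
  n_dup <- if (extinct) 0L else count_locus_dups(pruned)
  structure(list(root = if (extinct) NULL else pruned, extinct = extinct,
                 n_duplications = n_dup),
            class = "locus_tree")
}

locus_node <- function(type, children, len, species = NA_character_) {
  list(type = type, children = children, length = len, species = species)
}

## remove loss tips; contract degree-2 nodes, summing branch lengths
prune_losses <- function(node) {
  if (node$type == "loss") return(NULL)
  if (node$type == "copy") return(node)
  ch <- Filter(Negate(is.null), lapply(node$children, prune_losses))
  if (length(ch) == 0L) return(NULL)
  if (length(ch) == 1L) {
    ch[[1]]$length <- ch[[1]]$length + node$length
    return(ch[[1]])
  }
  node$children <- ch
  node
}

count_locus_dups <- function(node) {
  if (node$type == "copy") return(0L)
  (node$type == "dup") + sum(vapply(node$children, count_locus_dups, integer(1)))
}

#' Simulate a gene tree along a locus tree (bounded coalescent)
#'
#' Runs the multispecies coalescent with haploid population size \code{N}
#' bottom-up within each locus-tree branch.  At a duplication node the
#' daughter locus is constrained to a single ancestral lineage at the
#' duplication time; the bound is enforced by rejection (the daughter
#' subtree's coalescent history is redrawn until the constraint holds).
#'
#' @param locus a non-extinct \code{locus_tree}.
#' @param N haploid population size.
#' @param seed optional integer seed.
#' @param max_tries rejection cap for the daughter-lineage bound; exhaustion
#'   raises a classed error (\code{"discoq_bound_exhausted"}).  The cap can
#'   be hit when a duplication falls just above the next locus-tree node, so
#'   the daughter branch is too short for its entering lineages to coalesce.
#' @return a rooted \code{gene_tree}; leaves are labelled
#'   \code{"<species>_<copy index>"} with species labels resolved.
#' @export
simulate_gene_tree <- function(locus, N, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(locus, "locus_tree"))
  if (locus$extinct) stop("locus tree is extinct; no gene tree exists", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  copy_counter <- new.env(parent = emptyenv())

  ## A lineage is list(tree = gene node, t = absolute time of its apex).
  ## Absolute time increases root -> tips; the locus root is at time 0.
  lineages_at <- function(node, t_node) {
    if (node$type == "copy") {
      sp <- node$species
      i <- (if (is.null(copy_counter[[sp]])) 0L else copy_counter[[sp]]) + 1L
      copy_counter[[sp]] <- i
      leaf <- new_leaf_node(paste0(sp, "_", i), species = sp)
      return(list(list(tree = leaf, t = t_node)))
    }
    if (node$type == "spec") {
      out <- list()
      for (ch in node$children) {
        lins <- lineages_at(ch, t_node + ch$length)
        out <- c(out, coalesce_branch(lins, t_node + ch$length, t_node, N))
      }
      return(out)
    }
    ## duplication: children are (mother, daughter)
    mch <- node$children[[1]]; dch <- node$children[[2]]
    mother <- coalesce_branch(lineages_at(mch, t_node + mch$length),
                              t_node + mch$length, t_node, N)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        cond <- simpleError(
          "bounded-coalescent rejection cap exceeded at a duplication node")
        class(cond) <- c("discoq_bound_exhausted", class(cond))
        stop(cond)
      }
      save <- as.list(copy_counter)
      daughter <- coalesce_branch(lineages_at(dch, t_node + dch$length),
                                  t_node + dch$length, t_node, N)
      if (length(daughter) == 1L) break
      ## redraw: reset copy indices consumed by the rejected draw
      rm(list = ls(copy_counter), envir = copy_counter)
      for (nm in names(save)) copy_counter[[nm]] <- save[[nm]]
    }
    c(mother, daughter)
  }

  coalesce_branch <- function(lins, t_from, t_to, N) {
    t_cur <- t_from
    while (length(lins) > 1L) {
      k <- length(lins)
      tau <- stats::rexp(1, k * (k - 1) / 2 / N)
      if (t_cur - tau < t_to) break
      t_cur <- t_cur - tau
      pair <- sample.int(k, 2L)
      merged <- merge_lineages(lins[[pair[1]]], lins[[pair[2]]], t_cur)
      lins <- c(lins[-pair], list(merged))
    }
    lins
  }

  merge_lineages <- function(a, b, t_merge) {
    a$tree$length <- a$t - t_merge
    b$tree$length <- b$t - t_merge
    list(tree = new_internal_node(list(a$tree, b$tree)), t = t_merge)
  }

  root_lins <- lineages_at(locus$root, 0)
  ## above the locus root: free coalescence until one lineage remains
  t_cur <- 0
  while (length(root_lins) > 1L) {
    k <- length(root_lins)
    t_cur <- t_cur - stats::rexp(1, k * (k - 1) / 2 / N)
    pair <- sample.int(k, 2L)
    merged <- merge_lineages(root_lins[[pair[1]]], root_lins[[pair[2]]], t_cur)
    root_lins <- c(root_lins[-pair], list(merged))
  }
  new_gene_tree(root_lins[[1]]$tree, rooted = TRUE)
}

#' Generate a DLCoal dataset of multi-copy gene trees
#'
#' Draws \code{n_genes} independent locus/gene-tree pairs.  Families in which
#' every copy is lost are redrawn (conditioning on survival), as are the rare
#' families whose daughter-lineage bound exhausts the rejection cap (see
#' \code{\link{simulate_gene_tree}}); both redraw counts are reported.  All
#' randomness flows from \code{params$seed}; a fixed seed reproduces the
#' dataset exactly.
#'
#' @param params a \code{dlcoal_params} object.
#' @return a \code{dlcoal_dataset}: list with \code{species_tree},
#'   \code{gene_trees} (list of rooted multi-copy \code{gene_tree}s with
#'   resolved species labels), \code{locus_trees}, \code{mapping} (explicit
#'   \code{species_mapping} over all gene labels) and \code{n_redraws}.
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "dlcoal_params"))
  set.seed(params$seed)
  gene_trees <- vector("list", params$n_genes)
  locus_trees <- vector("list", params$n_genes)
  n_redraws <- 0L
  n_bound_redraws <- 0L
  for (i in seq_len(params$n_genes)) {
    repeat {
      locus <- simulate_locus_tree(params)
      if (locus$extinct) {
        n_redraws <- n_redraws + 1L
        next
      }
      gt <- tryCatch(simulate_gene_tree(locus, params$pop_size),
                     discoq_bound_exhausted = function(e) NULL)
      if (!is.null(gt)) break
      n_bound_redraws <- n_bound_redraws + 1L
    }
    locus_trees[[i]] <- locus
    gene_trees[[i]] <- gt
  }
  genes <- unlist(lapply(gene_trees, tree_genes), use.names = FALSE)
  species <- unlist(lapply(gene_trees, tree_species), use.names = FALSE)
  map <- species_mapping(stats::setNames(species, genes)[!duplicated(genes)])
  structure(list(species_tree = params$species_tree, gene_trees = gene_trees,
                 locus_trees = locus_trees, mapping = map,
                 n_redraws = n_redraws, n_bound_redraws = n_bound_redraws,
                 params = params),
            class = "dlcoal_dataset")
}

#' @export
print.dlcoal_dataset <- function(x, ...) {
  sizes <- vapply(x$gene_trees, n_leaves, integer(1))
  cat(sprintf(
    "dlcoal_dataset: %d gene trees over %d species (dup %g, loss %g, N %g)\n",
    length(x$gene_trees), n_leaves(x$species_tree),
    x$params$dup_rate, x$params$loss_rate, x$params$pop_size))
  cat(sprintf("  leaves per tree: min %d / median %g / max %d; %d redraw(s)\n",
              min(sizes), stats::median(sizes), max(sizes), x$n_redraws))
  invisible(x)
}
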