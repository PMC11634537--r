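## End-to-end paralog-aware species-tree inference:
## root-and-tag -> decompose -> GTF quartet table -> WMQC.

#' Run the full decomposition-and-amalgamation pipeline
#'
#' Roots and tags each multi-copy gene tree by duplication-loss parsimony,
#' decomposes it into single-copy trees (DISCO or DISCO-R), pools the
#' gene-tree-frequency quartet weights of all outputs, and amalgamates them
#' into a species tree by exact or heuristic weighted maximum quartet
#' consistency.  Errors are labelled with the stage in which they occur.
#'
#' @param gene_trees a list of \code{gene_tree}s, a character vector of
#'   newick strings, or the path of a one-tree-per-line newick file.
#' @param mapping a \code{species_mapping} (default: species is the leaf
#'   label prefix before \code{"_"}).
#' @param mode decomposition mode, \code{"disco-r"} (default) or
#'   \code{"disco"}.
#' @param prune_strategy see \code{\link{decompose}}.
#' @param w_dup,w_loss rooting/tagging penalties, see \code{\link{dl_score}}.
#' @param method \code{"heuristic"} (default) or \code{"exact"} WMQC solver.
#' @param seed integer seed (random pruning and the heuristic solver).
#' @return a \code{pipeline_result}: list with \code{species_tree} (unrooted
#'   \code{gene_tree}), \code{result} (the \code{wmqc_result}),
#'   \code{quartets} (the pooled \code{quartet_table}) and \code{report}
#'   (per-stage counts and timings in seconds).
#' @export
run_pipeline <- function(gene_trees, mapping = delimiter_mapping("_"),
                         mode = c("disco-r", "disco"),
                         prune_strategy = c("larger", "smaller", "random"),
                         w_dup = 1, w_loss = 1,
                         method = c("heuristic", "exact"), seed = 1L) {
  mode <- match.arg(mode)
  prune_strategy <- match.arg(prune_strategy)
  method <- match.arg(method)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  trees <- tick("io", {
    tl <- if (is.character(gene_trees)) read_gene_trees(gene_trees)
          else as_tree_list(gene_trees)
    if (!length(tl)) stop("no input gene trees")
    lapply(tl, function(t) resolve_polytomies(resolve_species(t, mapping)))
  })

  tagged <- tick("tagroot",
    lapply(trees, root_and_tag, w_dup = w_dup, w_loss = w_loss))
  n_dup <- sum(vapply(tagged, n_duplication_nodes, integer(1)))

  outputs <- tick("decompose", {
    dec <- lapply(seq_along(tagged), function(i)
      decompose(tagged[[i]], mode = mode, prune_strategy = prune_strategy,
                seed = if (prune_strategy == "random") seed + i else NULL))
    unlist(lapply(dec, `[[`, "outputs"), recursive = FALSE)
  })

  table <- tick("quartets", gtf_table(outputs))

  taxa <- sort(unique(unlist(lapply(trees, tree_species), use.names = FALSE)))
  result <- tick("amalgamate", {
    if (length(taxa) < 4L)
      stop("need at least 4 species to amalgamate (got ", length(taxa), ")")
    if (method == "exact") exact_wmqc(table, taxa)
    else heuristic_wmqc(table, taxa, seed = seed)
  })

  structure(list(
    species_tree = result$tree,
    result = result,
    quartets = table,
    report = list(
      n_gene_trees = length(trees),
      n_species = length(taxa),
      n_duplication_nodes = n_dup,
      n_output_trees = length(outputs),
      n_quartet_topologies = length(table),
      total_quartet_weight = sum(table),
      mode = mode, prune_strategy = prune_strategy, method = method,
      seed = seed, timings = unlist(timings))),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline_result (%s, %s WMQC): %d gene trees -> %d species\n",
              r$mode, r$method, r$n_gene_trees, r$n_species))
  cat(sprintf("  duplication nodes: %d; single-copy trees: %d; quartet topologies: %d (weight %g)\n",
              r$n_duplication_nodes, r$n_output_trees,
              r$n_quartet_topologies, r$total_quartet_weight))
  cat(sprintf("  normalized quartet score: %.4f\n", x$result$normalized_score))
  cat("  species tree:", write_newick(x$species_tree, labels = "species"), "\n")
  invisible(x)
}
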