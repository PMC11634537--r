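## Newick I/O and gene -> species mapping resolution.
##
## Parsing and serialization lean on ape; a light pre-scan gives the
## character-position diagnostics ape does not provide.

#' Parse a newick string into a gene tree
#'
#' Leaf labels are preserved verbatim; branch lengths are retained when
#' present.  Internal-node labels \code{"D"} / \code{"S"} are interpreted as
#' duplication/speciation tags (the serialization used by
#' \code{\link{write_newick}} for tagged trees); other internal labels are
#' dropped.  Rootedness is inferred from the basal degree: a basal bifurcation
#' is read as rooted, a basal multifurcation as unrooted.
#'
#' @param text a newick string terminated by \code{";"}.
#' @return a \code{gene_tree}.
#' @examples
#' parse_newick("((a,b),(c,d));")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  scan_newick_syntax(text)
  body <- sub(";\\s*$", "", text)
  if (!grepl("(", body, fixed = TRUE)) {
    ## single-leaf tree "a;" (ape cannot represent it)
    lab <- trimws(body)
    if (!nzchar(lab)) stop("newick parse error: empty tree", call. = FALSE)
    return(new_gene_tree(new_leaf_node(lab), rooted = TRUE))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("newick parse error: ape could not parse the string",
                         call. = FALSE)
  phylo_to_gene_tree(phy)
}

## position-reporting syntax pre-scan
scan_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf(
      "newick parse error: %d unclosed '(' at end of string (character %d)",
      depth, length(chars)), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("newick parse error: missing terminal ';' (character %d)",
                 nchar(text) + 1L), call. = FALSE)
  invisible(TRUE)
}

phylo_to_gene_tree <- function(phy) {
  n_tip <- length(phy$tip.label)
  has_len <- !is.null(phy$edge.length)
  nodelab <- phy$node.label
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  build <- function(id, elen) {
    if (id <= n_tip) return(new_leaf_node(phy$tip.label[id], length = elen))
    rows <- children[[as.character(id)]]
    ch <- lapply(rows, function(r)
      build(phy$edge[r, 2], if (has_len) phy$edge.length[r] else NA_real_))
    lab <- if (!is.null(nodelab)) nodelab[id - n_tip] else NA_character_
    tag <- if (!is.na(lab) && lab %in% c("D", "S")) lab else NA_character_
    new_internal_node(ch, tag = tag, length = elen)
  }
  root_id <- n_tip + 1L
  root <- build(root_id, NA_real_)
  new_gene_tree(root, rooted = length(root$children) == 2L ||
                  n_tip <= 2L)
}

#' Serialize a gene tree to newick
#'
#' @param tree a \code{gene_tree}.
#' @param labels \code{"gene"} (default) or \code{"species"}: which leaf label
#'   to write.
#' @param tags write internal duplication/speciation tags as internal-node
#'   labels \code{"D"}/\code{"S"}.  Defaults to \code{TRUE} when any node is
#'   tagged.
#' @param lengths write branch lengths when present.
#' @return a newick string ending in \code{";"}.
#' @export
write_newick <- function(tree, labels = c("gene", "species"),
                         tags = NULL, lengths = TRUE) {
  labels <- match.arg(labels)
  root <- tree_root(tree)
  if (is.null(tags)) tags <- any(!is.na(node_tags(root)))
  paste0(node_to_newick(root, labels, tags, lengths, is_root = TRUE), ";")
}

node_to_newick <- function(node, labels, tags, lengths, is_root = FALSE) {
  len <- if (lengths && !is.na(node$length) && !is_root)
    sprintf(":%g", node$length) else ""
  if (node$leaf) {
    lab <- if (labels == "species" && !is.na(node$species)) node$species else node$gene
    return(paste0(lab, len))
  }
  inner <- paste(vapply(node$children, node_to_newick, character(1),
                        labels = labels, tags = tags, lengths = lengths),
                 collapse = ",")
  tag <- if (tags && !is.na(node$tag)) node$tag else ""
  paste0("(", inner, ")", tag, len)
}

#' Read gene trees from a newick file (one tree per line)
#'
#' @param path file path, or a character vector of newick strings.
#' @return list of \code{gene_tree} objects.
#' @export
read_gene_trees <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick)
}

#' Write gene trees to a newick file, one per line
#'
#' @param trees list of \code{gene_tree} objects.
#' @param path output file path.
#' @inheritParams write_newick
#' @return \code{path}, invisibly.
#' @export
write_gene_trees <- function(trees, path, labels = c("gene", "species"),
                             tags = NULL, lengths = TRUE) {
  labels <- match.arg(labels)
  writeLines(vapply(trees, write_newick, character(1),
                    labels = labels, tags = tags, lengths = lengths), path)
  invisible(path)
}

## ---- species mappings ---------------------------------------------------

#' Explicit gene-to-species mapping
#'
#' @param map a named character vector: names are gene labels, values species
#'   labels.
#' @return a \code{species_mapping} object.
#' @export
species_mapping <- function(map) {
  stopifnot(is.character(map), !is.null(names(map)), all(nzchar(names(map))))
  structure(list(type = "table", map = map), class = "species_mapping")
}

#' Delimiter-based gene-to-species mapping
#'
#' The species label is the gene-label prefix before the first occurrence of
#' \code{delim} (the whole label if the delimiter is absent), e.g. gene
#' \code{"c_2"} maps to species \code{"c"} under the default \code{"_"}.
#'
#' @param delim delimiter string (fixed, not a regex).  Default \code{"_"}.
#' @return a \code{species_mapping} object.
#' @export
delimiter_mapping <- function(delim = "_") {
  stopifnot(is.character(delim), length(delim) == 1L, nzchar(delim))
  structure(list(type = "delimiter", delim = delim), class = "species_mapping")
}

#' Identity gene-to-species mapping
#'
#' Each leaf label is its own species name -- the convention for single-copy
#' trees whose leaves are already labelled by species (e.g. decomposition
#' outputs written with \code{labels = "species"}).
#'
#' @return a \code{species_mapping} object.
#' @export
identity_mapping <- function() {
  structure(list(type = "identity"), class = "species_mapping")
}

#' Read a two-column mapping file
#'
#' Each line holds two whitespace-separated fields: gene label, species label.
#'
#' @param path file path.
#' @return a \code{species_mapping} object.
#' @export
read_species_mapping <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("gene", "species"),
                           colClasses = "character")
  species_mapping(stats::setNames(tab$species, tab$gene))
}

map_gene_to_species <- function(mapping, genes) {
  if (mapping$type == "identity") {
    genes
  } else if (mapping$type == "delimiter") {
    vapply(strsplit(genes, mapping$delim, fixed = TRUE),
           `[`, character(1), 1L)
  } else {
    unname(mapping$map[genes])
  }
}

#' Resolve species labels on a gene tree
#'
#' Sets every leaf's species label from the mapping; the tree is otherwise
#' unchanged.  Idempotent.
#'
#' @param tree a \code{gene_tree}.
#' @param mapping a \code{species_mapping}.
#' @return the tree with species labels set.
#' @export
resolve_species <- function(tree, mapping) {
  stopifnot(is_gene_tree(tree), inherits(mapping, "species_mapping"))
  genes <- tree_genes(tree)
  sp <- map_gene_to_species(mapping, genes)
  if (anyNA(sp))
    stop("species mapping does not cover gene label(s): ",
         paste(genes[is.na(sp)], collapse = ", "), call. = FALSE)
  tree$root <- node_set_species(tree$root, mapping)
  tree
}

node_set_species <- function(node, mapping) {
  if (node$leaf) {
    node$species <- map_gene_to_species(mapping, node$gene)
    return(node)
  }
  node$children <- lapply(node$children, node_set_species, mapping = mapping)
  node
}

#' Is a tree single-labeled?
#'
#' @param tree a \code{gene_tree} with resolved species labels.
#' @return \code{TRUE} iff no species labels two leaves.
#' @export
check_single_labeled <- function(tree) {
  sp <- tree_species(tree)
  if (anyNA(sp)) stop("species labels not resolved", call. = FALSE)
  !anyDuplicated(sp) > 0
}

## convert to ape phylo (via newick text; robust and simple)
gene_tree_to_phylo <- function(tree, labels = "gene") {
  nw <- write_newick(tree, labels = labels, tags = FALSE, lengths = TRUE)
  if (n_leaves(tree) < 2L)
    stop("cannot convert a single-leaf tree to phylo", call. = FALSE)
  ape::read.tree(text = nw)
}
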