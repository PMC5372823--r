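#' Taxonomy tree
#'
#' A rooted taxonomy: every node has a parent, a rank label and a name.
#' The root is the unique node whose parent is itself (NCBI convention) or
#' absent. Ranks must include "phylum" somewhere in the tree for the
#' phylum-conflict logic to be meaningful.
#'
#' @param id,parent,rank,name parallel character vectors describing nodes.
#' @return Object of class `taxonomy` with a `nodes` data.frame and a
#'   precomputed id index.
#' @export
taxonomy <- function(id, parent, rank, name = id) {
  id <- as.character(id); parent <- as.character(parent)
  rank <- as.character(rank); name <- as.character(name)
  if (anyDuplicated(id)) stop("duplicate taxonomy node ids")
  parent[is.na(parent) | parent == "" | parent == "-"] <- NA_character_
  root <- id[is.na(parent) | parent == id]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root, found ", length(root))
  parent[id == root] <- root  # normalize: root points to itself
  unknown <- setdiff(parent, id)
  if (length(unknown) > 0)
    stop("parents not present as nodes: ", paste(unknown, collapse = ", "))
  tx <- structure(
    list(nodes = data.frame(id = id, parent = parent, rank = rank,
                            name = name, stringsAsFactors = FALSE),
         root = root,
         index = setNames(seq_along(id), id)),
    class = "taxonomy")
  # every node must reach the root (catches cycles off the root)
  depth <- tax_depth(tx, id)
  if (any(is.na(depth))) stop("taxonomy contains nodes that do not reach the root")
  tx$depth <- setNames(depth, id)
  tx
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("taxonomy: %d nodes, root '%s', ranks: %s\n",
              nrow(x$nodes), x$root,
              paste(unique(x$nodes$rank), collapse = ", ")))
  invisible(x)
}

tax_has <- function(tx, ids) ids %in% x_names(tx)
x_names <- function(tx) tx$nodes$id

tax_parent <- function(tx, ids) tx$nodes$parent[tx$index[ids]]
tax_rank   <- function(tx, ids) tx$nodes$rank[tx$index[ids]]

# path from node to root, inclusive, node first
tax_path_to_root <- function(tx, id, max_steps = nrow(tx$nodes) + 1L) {
  path <- character(0)
  cur <- id
  for (i in seq_len(max_steps)) {
    path <- c(path, cur)
    if (cur == tx$root) return(path)
    cur <- tax_parent(tx, cur)
  }
  stop("no path to root from node ", id)
}

tax_depth <- function(tx, ids) {
  n <- nrow(tx$nodes)
  vapply(ids, function(id) {
    d <- 0L; cur <- id
    repeat {
      if (is.na(tx$index[cur])) return(NA_integer_)
      if (cur == tx$root) return(d)
      cur <- tx$nodes$parent[tx$index[cur]]
      d <- d + 1L
      if (d > n) return(NA_integer_)
    }
  }, integer(1))
}

# the ancestor-or-self of each id having the given rank, else NA
tax_ancestor_at_rank <- function(tx, ids, rank = "phylum") {
  vapply(ids, function(id) {
    for (node in tax_path_to_root(tx, id))
      if (tax_rank(tx, node) == rank) return(node)
    NA_character_
  }, character(1))
}

tax_is_ancestor <- function(tx, anc, id) anc %in% tax_path_to_root(tx, id)

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' taxon, by walking each node's path to the root and taking the last
#' node shared by all paths.
#'
#' @param taxon_ids non-empty character vector of node ids.
#' @param tx a [taxonomy()] tree.
#' @return A single node id.
#' @export
lca <- function(taxon_ids, tx) {
  taxon_ids <- unique(as.character(taxon_ids))
  if (length(taxon_ids) == 0L) stop("lca of an empty taxon set is undefined")
  missing <- taxon_ids[is.na(tx$index[taxon_ids])]
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxon_ids) == 1L) return(taxon_ids)
  # root-ward paths reversed so they align root-first; common prefix = LCA
  paths <- lapply(taxon_ids, function(id) rev(tax_path_to_root(tx, id)))
  k <- min(lengths(paths))
  lca_node <- tx$root
  for (i in seq_len(k)) {
    step <- vapply(paths, `[[`, character(1), i)
    if (all(step == step[[1]])) lca_node <- step[[1]] else break
  }
  lca_node
}

#' Read a taxonomy from NCBI-style dump files or a 4-column TSV
#'
#' Two layouts are understood: (a) NCBI `nodes.dmp` (+ optional
#' `names.dmp`, scientific names) with `\t|\t` field separators; (b) a
#' plain 4-column TSV `id<TAB>parent<TAB>rank<TAB>name` with or without a
#' header line.
#'
#' @param nodes path to `nodes.dmp` or the 4-column TSV.
#' @param names optional path to `names.dmp`.
#' @return A [taxonomy()].
#' @export
read_taxonomy <- function(nodes, names = NULL) {
  first <- readLines(nodes, n = 1L)
  if (grepl("\t\\|", first)) {
    raw <- readLines(nodes)
    parts <- strsplit(raw, "\t\\|\t?")
    id <- vapply(parts, `[[`, character(1), 1)
    parent <- vapply(parts, `[[`, character(1), 2)
    rank <- vapply(parts, `[[`, character(1), 3)
    nm <- id
    if (!is.null(names)) {
      nraw <- strsplit(readLines(names), "\t\\|\t?")
      keep <- vapply(nraw, function(p)
        length(p) >= 4 && grepl("scientific name", p[[4]]), logical(1))
      nid <- vapply(nraw[keep], `[[`, character(1), 1)
      nnm <- vapply(nraw[keep], `[[`, character(1), 2)
      m <- match(id, nid)
      nm <- ifelse(is.na(m), id, nnm[m])
    }
    return(taxonomy(id, parent, rank, nm))
  }
  df <- read.table(nodes, sep = "\t", header = FALSE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   col.names = c("id", "parent", "rank", "name"),
                   colClasses = "character", fill = TRUE)
  if (nrow(df) > 0 && tolower(df$id[1]) %in% c("id", "taxid", "node"))
    df <- df[-1, , drop = FALSE]
  if (all(df$name == "" | is.na(df$name))) df$name <- df$id
  taxonomy(df$id, df$parent, df$rank, df$name)
}

#' Write a taxonomy as the 4-column TSV dialect
#'
#' @param tx a [taxonomy()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tx, path) {
  write.table(tx$nodes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
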