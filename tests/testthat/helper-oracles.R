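# Independent brute-force oracles. These deliberately re-derive each
# result from the rule's plain statement, not by calling package
# internals, so agreement is meaningful.

# LCA by literal root-path intersection: collect every node's full path
# to the root, intersect the paths, return the intersection member
# farthest from the root.
oracle_lca <- function(taxon_ids, tx) {
  nodes <- tx$nodes
  path_of <- function(id) {
    p <- id
    while (nodes$parent[nodes$id == id] != id) {
      id <- nodes$parent[nodes$id == id]
      p <- c(p, id)
    }
    p
  }
  paths <- lapply(unique(taxon_ids), path_of)
  common <- Reduce(intersect, paths)
  depths <- sapply(common, function(n) length(path_of(n)))
  common[which.max(depths)]
}

# median filter by exhaustive per-scaffold check
oracle_median_filter <- function(members, depth, factor = 3) {
  med <- apply(depth[members, , drop = FALSE], 2, median)
  usable <- med > 0
  removed <- character(0)
  for (s in members) {
    for (ds in colnames(depth)[usable]) {
      if (depth[s, ds] > factor * med[[ds]]) {
        removed <- c(removed, s)
        break
      }
    }
  }
  removed
}

# z-score purification transcribed naively: full z-vectors (scale(),
# sample sd) recomputed after every single removal; cutoff shrinks from
# start to end when no member exceeds it.
oracle_zscore_purify <- function(members, depth, start_cutoff = 4,
                                 end_cutoff = 2, step = 1,
                                 min_members = 4) {
  members <- sort(members)
  removed <- character(0)
  cutoff <- start_cutoff
  repeat {
    za <- as.vector(scale(depth[members, 1]))
    zb <- as.vector(scale(depth[members, 2]))
    za[is.nan(za)] <- 0; zb[is.nan(zb)] <- 0
    d <- abs(za - zb)
    names(d) <- members
    if (any(d > cutoff)) {
      if (length(members) - 1 < min_members) break
      worst <- min(names(d)[d == max(d[d > cutoff])])
      removed <- c(removed, worst)
      members <- setdiff(members, worst)
    } else if (cutoff > end_cutoff) {
      cutoff <- max(cutoff - step, end_cutoff)
    } else break
  }
  list(kept = members, removed = removed)
}

# unique core genome by row-wise scan
oracle_core_genome <- function(groups, counts) {
  out <- character(0)
  for (i in seq_along(groups))
    if (all(counts[i, ] == 1)) out <- c(out, groups[i])
  out
}

# random rooted taxonomy: node i attaches to a random earlier node;
# ranks cycle through a fixed ladder so phylum nodes exist
random_taxonomy <- function(n = 200) {
  id <- paste0("n", seq_len(n))
  parent <- c("n1", vapply(2:n, function(i)
    paste0("n", sample.int(i - 1L, 1L)), ""))
  ranks <- c("no rank", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species")
  rank <- c("no rank", sample(ranks[-1], n - 1L, replace = TRUE))
  taxonomy(id, parent, rank)
}
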