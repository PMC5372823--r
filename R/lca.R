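#' Assign a scaffold its LCA taxon from homology hits
#'
#' MEGAN-style assignment: hits are first restricted to
#' `evalue <= evalue_max`; within each hit source (e.g. protein-level and
#' nucleotide-level searches) only hits with
#' `bitscore >= (1 - top_percent/100) * best bitscore` are retained; the
#' retained hits are pooled across sources and their taxa reduced to the
#' lowest common ancestor. A scaffold with no qualifying hit is
#' `"unassigned"`.
#'
#' The `conflict` flag encodes the conservative removal rule: it is set
#' only when the LCA lies *at or below* rank phylum and that phylum
#' differs from `target_phylum` — a scaffold whose LCA sits above phylum
#' is ambiguous, not unambiguously foreign, and is never flagged.
#'
#' @param hits a `hit_table` (see [read_hits()]).
#' @param scaffold_id scaffold to assign.
#' @param tx a [taxonomy()].
#' @param target_phylum optional node id of the bin's expected phylum
#'   (any node; its phylum-rank ancestor is used).
#' @param evalue_max e-value cutoff, default `1e-20`.
#' @param top_percent retain hits within this percentage of the best
#'   bitscore, per source; default 10.
#' @return list with `scaffold_id`, `lca_node` (node id or
#'   `"unassigned"`), `n_hits_used`, `conflict`.
#' @export
assign_scaffold_lca <- function(hits, scaffold_id, tx, target_phylum = NULL,
                                evalue_max = 1e-20, top_percent = 10) {
  h <- hits[hits$scaffold_id == scaffold_id & hits$evalue <= evalue_max, ,
            drop = FALSE]
  if (nrow(h) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(h)), h$source), function(i) {
      best <- max(h$bitscore[i])
      i[h$bitscore[i] >= (1 - top_percent / 100) * best]
    }))
    h <- h[sort(keep), , drop = FALSE]
  }
  if (nrow(h) == 0)
    return(list(scaffold_id = scaffold_id, lca_node = "unassigned",
                n_hits_used = 0L, conflict = FALSE))
  node <- lca(h$taxon_id, tx)
  conflict <- FALSE
  if (!is.null(target_phylum)) {
    lca_phylum <- tax_ancestor_at_rank(tx, node, "phylum")
    target_ph <- tax_ancestor_at_rank(tx, target_phylum, "phylum")
    if (is.na(target_ph))
      stop("target taxon ", target_phylum, " has no phylum-rank ancestor")
    conflict <- !is.na(lca_phylum) && lca_phylum != target_ph
  }
  list(scaffold_id = scaffold_id, lca_node = node,
       n_hits_used = nrow(h), conflict = conflict)
}

#' LCA-assign every member of a bin
#'
#' @inheritParams assign_scaffold_lca
#' @param b a [bin()]; its `target_taxon` defines the expected phylum.
#' @return data.frame with one row per member: `scaffold_id`, `lca_node`,
#'   `n_hits_used`, `conflict`.
#' @export
assign_bin_lca <- function(b, hits, tx, evalue_max = 1e-20,
                           top_percent = 10) {
  rows <- lapply(b$members, function(s)
    assign_scaffold_lca(hits, s, tx, target_phylum = b$target_taxon,
                        evalue_max = evalue_max, top_percent = top_percent))
  data.frame(scaffold_id = vapply(rows, `[[`, "", "scaffold_id"),
             lca_node = vapply(rows, `[[`, "", "lca_node"),
             n_hits_used = vapply(rows, `[[`, 0L, "n_hits_used"),
             conflict = vapply(rows, `[[`, FALSE, "conflict"),
             stringsAsFactors = FALSE)
}

#' Remove scaffolds unambiguously assigned to a foreign phylum
#'
#' Drops exactly the members whose LCA assignment carries
#' `conflict == TRUE`; unassigned and ambiguous scaffolds are retained.
#' Members without an assignment row count as unassigned.
#'
#' @param b a [bin()] with a `target_taxon`.
#' @param assignments data.frame from [assign_bin_lca()].
#' @return list with `kept` (a [bin()], possibly with zero members — then
#'   `kept` is `NULL` and the trace carries a flag), `removed` (character
#'   vector) and `trace` (a [refinement_trace()]).
#' @export
filter_bin_by_taxonomy <- function(b, assignments) {
  if (is.null(b$target_taxon))
    stop("bin ", b$bin_id, " has no target taxon; conflict is undefined")
  m <- match(b$members, assignments$scaffold_id)
  conflict <- ifelse(is.na(m), FALSE, assignments$conflict[m])
  removed <- b$members[conflict]
  kept_members <- b$members[!conflict]
  trace <- if (length(removed) > 0)
    refinement_trace(stage = "lca_filter", bin = b$bin_id,
                     scaffold = removed, action = "remove",
                     reason = paste0("lca=",
                                     assignments$lca_node[m[conflict]]),
                     cutoff = NA, value_a = NA, value_b = NA)
  else empty_trace()
  if (length(kept_members) == 0) {
    trace <- bind_traces(trace, refinement_trace(
      stage = "lca_filter", bin = b$bin_id, scaffold = "*",
      action = "flag", reason = "all members conflict; bin emptied",
      cutoff = NA, value_a = NA, value_b = NA))
    return(list(kept = NULL, removed = removed, trace = trace))
  }
  list(kept = bin(b$bin_id, kept_members, b$target_taxon),
       removed = removed, trace = trace)
}
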