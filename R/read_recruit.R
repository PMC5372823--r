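#' Recruit reads for targeted reassembly of a bin
#'
#' Applies the strict acceptance rules for assembling a read subset from
#' end-to-end alignments:
#' \itemize{
#'   \item a read pair is accepted only when *both* mates map full length
#'     (no clipping) to scaffolds of the *same* bin;
#'   \item merged read pairs and orphaned (unpaired) reads are accepted
#'     when they map full length to a bin scaffold;
#'   \item clipped or local alignments are always rejected.
#' }
#' A `mate1` record whose `mate2` record is absent (or vice versa) is
#' downgraded to an orphan, counted in `n_halfpairs`, and a warning is
#' raised. Pairs whose mates map to two different bins fail the same-bin
#' rule for both bins: cross-bin pairs are evidence of ambiguity.
#'
#' @param alignments data.frame of alignment records as produced by
#'   [read_alignments()]: `read_id`, `mate_flag`, `scaffold_id`,
#'   `full_length`, `mapped`.
#' @param b a [bin()] (or character vector of member scaffold ids).
#' @return list with `accepted` (data.frame: `read_id`, `category` in
#'   pair/merged/orphan) and `counts` (named: n_pair, n_merged, n_orphan,
#'   n_rejected, n_halfpairs). Category counts sum to the accepted total.
#' @export
recruit_reads <- function(alignments, b) {
  members <- if (inherits(b, "bin")) b$members else as.character(b)
  a <- alignments[order(alignments$read_id, alignments$mate_flag), ,
                  drop = FALSE]  # determinism under record reordering
  ok <- a$mapped & a$full_length & (a$scaffold_id %in% members)

  paired <- a$mate_flag %in% c("mate1", "mate2")
  n_half <- 0L
  acc_pair <- character(0)
  if (any(paired)) {
    by_read <- split(seq_len(nrow(a))[paired], a$read_id[paired])
    flags_of <- function(i) a$mate_flag[i]
    complete <- vapply(by_read, function(i)
      all(c("mate1", "mate2") %in% flags_of(i)), logical(1))
    n_half <- sum(!complete)
    if (n_half > 0)
      warning(n_half, " read(s) with a missing mate treated as orphans")
    acc_pair <- names(by_read)[complete &
      vapply(by_read, function(i) all(ok[i]), logical(1))]
    # half-pairs: the surviving single mate follows the orphan rule
    half_idx <- unlist(by_read[!complete], use.names = FALSE)
  } else half_idx <- integer(0)

  single <- which(a$mate_flag == "single" | seq_len(nrow(a)) %in% half_idx)
  merged <- which(a$mate_flag == "merged")
  acc_orphan <- unique(a$read_id[single][ok[single]])
  acc_merged <- unique(a$read_id[merged][ok[merged]])

  accepted <- data.frame(
    read_id = c(sort(acc_pair), sort(acc_merged), sort(acc_orphan)),
    category = c(rep("pair", length(acc_pair)),
                 rep("merged", length(acc_merged)),
                 rep("orphan", length(acc_orphan))),
    stringsAsFactors = FALSE)
  n_total_reads <- length(unique(a$read_id))
  counts <- c(n_pair = length(acc_pair), n_merged = length(acc_merged),
              n_orphan = length(acc_orphan), n_halfpairs = n_half,
              n_rejected = n_total_reads - nrow(accepted))
  list(accepted = accepted, counts = counts)
}

#' Export per-bin read manifests (and optional read subsets)
#'
#' Writes one read-id list per category for a bin's accepted reads. For
#' pairs, both mate ids (`<id>/1`, `<id>/2`) are listed. When a source of
#' raw reads is supplied (a named character vector mapping read id to
#' sequence, or a FASTA/FASTQ-like two-column table), a per-bin read file
#' is written whose record count equals the manifest length. The purified
#' bin FASTA path, when given, is recorded in the manifest so an external
#' assembler can take it as its trusted/untrusted reference.
#'
#' @param accepted the `accepted` data.frame from [recruit_reads()].
#' @param out_dir output directory.
#' @param bin_id label used in file names.
#' @param reads optional named character vector of read sequences.
#' @param bin_fasta optional path of the purified bin FASTA to record.
#' @return (invisibly) a list describing the written files.
#' @export
export_read_manifest <- function(accepted, out_dir, bin_id,
                                 reads = NULL, bin_fasta = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair_ids <- accepted$read_id[accepted$category == "pair"]
  pair_list <- if (length(pair_ids) == 0) character(0) else
    as.vector(rbind(paste0(pair_ids, "/1"), paste0(pair_ids, "/2")))
  single_ids <- accepted$read_id[accepted$category != "pair"]
  manifest <- list(bin = bin_id,
                   n_pair = length(pair_ids),
                   n_single = length(single_ids),
                   reference = bin_fasta)
  p1 <- file.path(out_dir, paste0(bin_id, ".pairs.ids"))
  p2 <- file.path(out_dir, paste0(bin_id, ".single.ids"))
  writeLines(pair_list, p1)
  writeLines(single_ids, p2)
  manifest$pairs_ids <- p1
  manifest$single_ids <- p2
  if (!is.null(reads)) {
    wanted <- c(pair_list, single_ids)
    missing <- setdiff(wanted, names(reads))
    if (length(missing) > 0)
      stop(length(missing), " accepted read(s) absent from the read source")
    fa <- file.path(out_dir, paste0(bin_id, ".reads.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(reads[wanted]), fa)
    manifest$reads_fasta <- fa
  }
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(bin_id, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
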