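#' @importFrom stats median sd setNames rnorm rlnorm runif rbinom
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaffold set
#'
#' A set of assembled scaffolds: per-scaffold id, length and GC content,
#' with optional sequences held as a [Biostrings::DNAStringSet].
#'
#' GC is the fraction of G+C over non-N positions. A scaffold consisting
#' only of N has undefined GC and is reported as `NA`, never 0.
#'
#' @param id character vector of unique scaffold ids.
#' @param length integer vector of scaffold lengths (bp, > 0).
#' @param sequence optional `DNAStringSet` (or named character vector)
#'   parallel to `id`; when given, lengths are taken from the sequences.
#' @return An object of class `scaffold_set` with elements `info`
#'   (data.frame: id, length, gc) and `seq` (`DNAStringSet` or `NULL`).
#' @export
scaffold_set <- function(id, length = NULL, sequence = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate scaffold ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- NULL
  gc <- rep(NA_real_, base::length(id))
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    if (base::length(sequence) != base::length(id))
      stop("sequence and id lengths differ")
    names(sequence) <- id
    seq <- sequence
    length <- Biostrings::width(sequence)
    gc <- gc_content(sequence)
  }
  if (is.null(length)) stop("either length or sequence is required")
  length <- as.integer(length)
  if (any(length <= 0L)) stop("scaffold lengths must be > 0")
  structure(
    list(info = data.frame(id = id, length = length, gc = gc,
                           stringsAsFactors = FALSE),
         seq = seq),
    class = "scaffold_set")
}

#' GC content over non-N positions
#'
#' @param x a `DNAStringSet` or character vector of sequences.
#' @return numeric vector of G+C fractions; `NA` when a sequence has no
#'   unambiguous base (e.g. all-N).
#' @export
gc_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  freq <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  out <- (freq[, "G"] + freq[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d scaffolds, %s bp total, sequences: %s\n",
              nrow(x$info), format(sum(as.numeric(x$info$length)),
                                   big.mark = ","),
              if (is.null(x$seq)) "absent" else "present"))
  invisible(x)
}

scaffold_ids <- function(scaffolds) scaffolds$info$id

scaffold_lengths <- function(scaffolds, ids = NULL) {
  v <- setNames(scaffolds$info$length, scaffolds$info$id)
  if (is.null(ids)) v else v[ids]
}

#' Genome bin
#'
#' A named set of scaffold ids putatively originating from one genome,
#' optionally carrying the taxonomy node of its expected phylum
#' (`target_taxon`), against which LCA conflicts are defined.
#'
#' @param bin_id bin name.
#' @param members character vector of scaffold ids (non-empty, unique).
#' @param target_taxon optional taxonomy node id of the expected phylum.
#' @return Object of class `bin`.
#' @export
bin <- function(bin_id, members, target_taxon = NULL) {
  members <- as.character(members)
  if (length(members) == 0L) stop("bin ", bin_id, " has no members")
  if (anyDuplicated(members))
    stop("bin ", bin_id, " lists duplicated members")
  structure(list(bin_id = as.character(bin_id), members = members,
                 target_taxon = target_taxon),
            class = "bin")
}

#' @export
print.bin <- function(x, ...) {
  cat(sprintf("bin '%s': %d scaffolds%s\n", x$bin_id, length(x$members),
              if (is.null(x$target_taxon)) ""
              else paste0(", target taxon ", x$target_taxon)))
  invisible(x)
}

#' Collect bins into a bin set
#'
#' @param ... `bin` objects, or a single list of them.
#' @return Named list of bins with class `bin_set`. A scaffold may belong
#'   to at most one bin.
#' @export
bin_set <- function(...) {
  bins <- list(...)
  if (length(bins) == 1L && !inherits(bins[[1]], "bin")) bins <- bins[[1]]
  stopifnot(all(vapply(bins, inherits, logical(1), "bin")))
  names(bins) <- vapply(bins, `[[`, character(1), "bin_id")
  if (anyDuplicated(names(bins))) stop("duplicate bin ids")
  all_members <- unlist(lapply(bins, `[[`, "members"))
  if (anyDuplicated(all_members))
    stop("scaffolds assigned to more than one bin: ",
         paste(head(unique(all_members[duplicated(all_members)]), 5),
               collapse = ", "))
  structure(bins, class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins (%s)\n", length(x),
              paste(sprintf("%s:%d", names(x),
                            vapply(x, function(b) length(b$members),
                                   integer(1))), collapse = ", ")))
  invisible(x)
}

#' Coverage matrix
#'
#' Mean per-base read depth of each scaffold in each sequencing dataset.
#' Stored as a numeric matrix with scaffolds as rows and datasets as
#' columns; depths are finite and non-negative.
#'
#' @param depth numeric matrix (or data.frame) of mean depths; rownames are
#'   scaffold ids, colnames dataset labels.
#' @return Numeric matrix of class `coverage_matrix`.
#' @export
coverage_matrix <- function(depth) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "double"
  if (is.null(rownames(depth)) || is.null(colnames(depth)))
    stop("coverage matrix needs scaffold rownames and dataset colnames")
  if (any(!is.finite(depth))) stop("coverage depths must be finite")
  if (any(depth < 0)) stop("coverage depths must be non-negative")
  class(depth) <- c("coverage_matrix", class(depth))
  depth
}

# Depth lookup; scaffolds absent from the matrix count as depth 0.
cov_depth <- function(coverage, ids, dataset) {
  stopifnot(dataset %in% colnames(coverage))
  out <- rep(0, length(ids))
  hit <- ids %in% rownames(coverage)
  out[hit] <- unclass(coverage)[ids[hit], dataset]
  setNames(out, ids)
}

#' Refinement trace
#'
#' An ordered record of every removal/split decision the pipeline makes:
#' one row per action with the stage, bin, scaffold, action, reason, the
#' cutoff in force and the offending values.
#'
#' @param stage,bin,scaffold,action,reason character vectors (recycled).
#' @param cutoff,value_a,value_b numeric vectors (recycled; `NA` allowed).
#' @return data.frame of class `refinement_trace`.
#' @export
refinement_trace <- function(stage = character(), bin = character(),
                             scaffold = character(), action = character(),
                             reason = character(), cutoff = numeric(),
                             value_a = numeric(), value_b = numeric()) {
  df <- data.frame(stage = as.character(stage), bin = as.character(bin),
                   scaffold = as.character(scaffold),
                   action = as.character(action),
                   reason = as.character(reason),
                   cutoff = as.numeric(cutoff),
                   value_a = as.numeric(value_a),
                   value_b = as.numeric(value_b),
                   stringsAsFactors = FALSE)
  class(df) <- c("refinement_trace", "data.frame")
  df
}

empty_trace <- function() refinement_trace()

bind_traces <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_trace())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("refinement_trace", "data.frame")
  rownames(out) <- NULL
  out
}
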