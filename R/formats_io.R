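#' Read bins from FASTA files and an optional contig-to-bin table
#'
#' Each FASTA holds assembled scaffolds. Without a table, every file
#' becomes one bin named after the file stem. With a two-column table
#' (`scaffold id<TAB>bin id`), bins are built from the table and scaffolds
#' not listed remain unbinned. Scaffold ids must be unique across all
#' input files; a table entry referencing a scaffold absent from the FASTA
#' input is a hard error.
#'
#' @param fasta_paths character vector of FASTA files.
#' @param contig2bin optional path to the scaffold-to-bin table (no
#'   header), or a data.frame with columns scaffold/bin.
#' @param targets optional named character vector mapping bin id to the
#'   taxonomy node of its expected phylum.
#' @return list with `scaffolds` (a [scaffold_set()]) and `bins`
#'   (a [bin_set()]).
#' @export
read_bins <- function(fasta_paths, contig2bin = NULL, targets = NULL) {
  seqs <- list()
  origin <- character(0)
  for (fp in fasta_paths) {
    s <- Biostrings::readDNAStringSet(fp)
    names(s) <- sub("\\s.*$", "", names(s))  # id = first token of header
    dup <- intersect(names(s), names(origin))
    if (length(dup) > 0)
      stop("duplicate scaffold id '", dup[[1]], "' in ", fp, " and ",
           origin[[dup[[1]]]])
    origin <- c(origin, setNames(rep(fp, length(s)), names(s)))
    seqs[[fp]] <- s
  }
  all_seq <- do.call(c, unname(seqs))
  scaffolds <- scaffold_set(names(all_seq), sequence = all_seq)

  if (is.null(contig2bin)) {
    bins <- lapply(fasta_paths, function(fp) {
      stem <- tools::file_path_sans_ext(basename(fp))
      bin(stem, names(seqs[[fp]]), target_taxon = targets[[stem]])
    })
    return(list(scaffolds = scaffolds, bins = bin_set(bins)))
  }

  tab <- if (is.data.frame(contig2bin)) contig2bin else
    read.table(contig2bin, sep = "\t", header = FALSE,
               stringsAsFactors = FALSE, colClasses = "character")
  names(tab)[1:2] <- c("scaffold", "bin")
  orphan <- setdiff(tab$scaffold, names(all_seq))
  if (length(orphan) > 0)
    stop("contig2bin references scaffolds absent from FASTA input: ",
         paste(orphan, collapse = ", "))
  bins <- lapply(split(tab$scaffold, tab$bin), function(m) m)
  empty <- names(bins)[lengths(bins) == 0]
  if (length(empty) > 0) {
    warning("dropping empty bins: ", paste(empty, collapse = ", "))
    bins <- bins[lengths(bins) > 0]
  }
  bins <- lapply(names(bins), function(b)
    bin(b, bins[[b]], target_taxon = targets[[b]]))
  list(scaffolds = scaffolds, bins = bin_set(bins))
}

#' Read per-scaffold mean coverage
#'
#' Three input routes, all normalized to a [coverage_matrix()]:
#' \describe{
#'   \item{`depth_tsv`}{the common contig-depth summary table: a header
#'     line, then one row per scaffold with name, length, an optional
#'     total-average column (name matching "total"), one mean-depth column
#'     per dataset, and optional per-dataset variance columns (suffix
#'     `-var`/`.var`/`_var`, ignored).}
#'   \item{`per_base`}{1-based `(scaffold, position, depth)` rows, one
#'     file (or data.frame) per dataset, given as a named list; mean depth
#'     is the summed depth over the scaffold length, so positions with no
#'     row count as 0.}
#'   \item{`sam`}{a named list of SAM/BAM files, one per dataset; mean
#'     depth is total aligned reference bases (CIGAR M/=/X of primary
#'     alignments) divided by scaffold length.}
#' }
#'
#' @param depth_tsv,per_base,sam exactly one route must be supplied.
#' @param scaffolds optional [scaffold_set()]; required for the per-base
#'   route, and used by the SAM route to skip (with a warning) records on
#'   unknown scaffolds.
#' @return A [coverage_matrix()]. An attribute `skipped` counts SAM
#'   records dropped for unknown scaffolds.
#' @export
read_coverage <- function(depth_tsv = NULL, per_base = NULL, sam = NULL,
                          scaffolds = NULL) {
  supplied <- sum(!vapply(list(depth_tsv, per_base, sam), is.null, logical(1)))
  if (supplied != 1L)
    stop("supply exactly one of depth_tsv, per_base, sam")
  if (!is.null(depth_tsv)) return(read_coverage_tsv(depth_tsv))
  if (!is.null(per_base)) return(read_coverage_per_base(per_base, scaffolds))
  read_coverage_sam(sam, scaffolds)
}

read_coverage_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("depth TSV needs name, length and depth columns")
  ids <- as.character(df[[1]])
  keep <- names(df)[-(1:2)]
  keep <- keep[!grepl("([-._]var)$", keep, ignore.case = TRUE)]
  keep <- keep[!grepl("total", keep, ignore.case = TRUE)]
  if (length(keep) == 0) stop("no dataset columns found in depth TSV")
  m <- as.matrix(df[, keep, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0)) stop("negative depth in ", path)
  coverage_matrix(m)
}

read_coverage_per_base <- function(per_base, scaffolds) {
  if (is.null(scaffolds))
    stop("the per-base depth route needs scaffolds for the lengths")
  if (!is.list(per_base) || is.data.frame(per_base))
    per_base <- list(depth = per_base)
  lens <- scaffold_lengths(scaffolds)
  cols <- lapply(per_base, function(x) {
    df <- if (is.data.frame(x)) x else
      read.table(x, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("scaffold", "pos", "depth")
    if (any(df$depth < 0)) stop("negative per-base depth")
    tot <- tapply(df$depth, df$scaffold, sum)
    out <- setNames(rep(0, length(lens)), names(lens))
    out[names(tot)] <- tot
    out / lens
  })
  coverage_matrix(do.call(cbind, cols))
}

read_coverage_sam <- function(sam, scaffolds = NULL) {
  stopifnot(is.list(sam) || is.character(sam))
  sam <- as.list(sam)
  if (is.null(names(sam)) || any(names(sam) == ""))
    names(sam) <- paste0("dataset", seq_along(sam))
  skipped <- 0L
  cols <- lapply(sam, function(path) {
    rec <- read_sam_records(path)
    hdr <- Rsamtools::scanBamHeader(
      if (tolower(tools::file_ext(path)) == "bam") path
      else Rsamtools::asBam(path, tempfile(), overwrite = TRUE))[[1]]$targets
    lens <- if (is.null(scaffolds)) hdr else scaffold_lengths(scaffolds)
    unknown <- !(rec$rname %in% names(lens))
    if (any(unknown)) {
      warning(sum(unknown), " alignments on unknown scaffolds skipped")
      skipped <<- skipped + sum(unknown)
      rec <- rec[!unknown, , drop = FALSE]
    }
    tot <- tapply(rec$aligned_bases, rec$rname, sum)
    out <- setNames(rep(0, length(lens)), names(lens))
    out[names(tot)] <- tot
    out / lens
  })
  cov <- coverage_matrix(do.call(cbind, cols))
  attr(cov, "skipped") <- skipped
  cov
}

#' Write a coverage matrix as a contig-depth summary TSV
#'
#' Emits the dialect [read_coverage()] accepts: contigName, contigLen,
#' totalAvgDepth, then one column per dataset.
#'
#' @param coverage a [coverage_matrix()].
#' @param scaffolds a [scaffold_set()] providing lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(coverage, scaffolds, path) {
  m <- unclass(coverage)
  df <- data.frame(contigName = rownames(m),
                   contigLen = scaffold_lengths(scaffolds, rownames(m)),
                   totalAvgDepth = rowSums(m), check.names = FALSE)
  df <- cbind(df, as.data.frame(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST-style tabular homology hits
#'
#' Accepts outfmt-6-like tabular files with at least 12 columns plus a
#' taxon-id column. Hits whose taxon is absent from the taxonomy are
#' dropped and counted; the e-value cutoff is *not* applied here but at
#' LCA assignment time.
#'
#' @param paths tabular files; may be a named vector, names become the
#'   hit `source` label (e.g. blastx/blastn), else the file stem is used.
#' @param tx a [taxonomy()].
#' @param taxid_col 1-based index of the taxon-id column (default 13,
#'   directly after the 12 standard columns).
#' @param strict error on malformed lines instead of skipping them.
#' @return data.frame of class `hit_table` with columns `scaffold_id`,
#'   `taxon_id`, `evalue`, `bitscore`, `source`; attribute `dropped`
#'   counts hits with unresolvable taxa.
#' @export
read_hits <- function(paths, tx, taxid_col = 13L, strict = FALSE) {
  if (is.null(names(paths)))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  dropped <- 0L
  parts <- lapply(names(paths), function(src) {
    lines <- readLines(paths[[src]])
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0)
      return(data.frame(scaffold_id = character(), taxon_id = character(),
                        evalue = numeric(), bitscore = numeric(),
                        source = character(), stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= taxid_col
    evalue <- suppressWarnings(
      as.numeric(vapply(fields, function(f) f[min(11L, length(f))], "")))
    bitscore <- suppressWarnings(
      as.numeric(vapply(fields, function(f) f[min(12L, length(f))], "")))
    ok <- ok & !is.na(evalue) & !is.na(bitscore)
    if (any(!ok)) {
      if (strict) stop("malformed hit line in ", paths[[src]], ": ",
                       lines[!ok][[1]])
      message(sum(!ok), " malformed lines skipped in ", paths[[src]])
    }
    data.frame(
      scaffold_id = vapply(fields[ok], `[[`, "", 1L),
      taxon_id = vapply(fields[ok], `[[`, "", taxid_col),
      evalue = evalue[ok], bitscore = bitscore[ok],
      source = src, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, parts)
  unresolved <- is.na(tx$index[hits$taxon_id])
  dropped <- sum(unresolved)
  hits <- hits[!unresolved, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  attr(hits, "dropped") <- dropped
  hits
}

#' Write refined bins as FASTA plus a JSON manifest
#'
#' @param bins a [bin_set()] (or list of [bin()]s).
#' @param scaffolds a [scaffold_set()] carrying sequences for all members.
#' @param out_dir output directory, created if needed.
#' @param overwrite allow clobbering existing files.
#' @return (invisibly) the manifest: a named list of written FASTA paths.
#' @export
write_refined_bins <- function(bins, scaffolds, out_dir, overwrite = FALSE) {
  if (is.null(scaffolds$seq))
    stop("scaffold set carries no sequences; FASTA output impossible")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (b in bins) {
    missing <- setdiff(b$members, names(scaffolds$seq))
    if (length(missing) > 0)
      stop("no sequence for scaffolds: ", paste(missing, collapse = ", "))
    path <- file.path(out_dir, paste0(b$bin_id, ".fasta"))
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    Biostrings::writeXStringSet(scaffolds$seq[b$members], path, width = 70L)
    manifest[[b$bin_id]] <- path
  }
  # the JSON manifest records file names relative to out_dir so that two
  # identical runs in different directories stay diffable
  jsonlite::write_json(lapply(manifest, basename),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write / read a refinement trace as TSV
#'
#' @param trace a [refinement_trace()].
#' @param path file path.
#' @return `path` (write) or the trace (read).
#' @export
write_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c(rep("character", 5), rep("numeric", 3)))
  class(df) <- c("refinement_trace", "data.frame")
  df
}

#' Write a contig-to-bin table
#'
#' @param bins a [bin_set()].
#' @param path output TSV (scaffold id, bin id; no header).
#' @return `path`, invisibly.
#' @export
write_contig2bin <- function(bins, path) {
  df <- do.call(rbind, lapply(bins, function(b)
    data.frame(scaffold = b$members, bin = b$bin_id,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
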