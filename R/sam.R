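# SAM/BAM ingestion. SAM text is converted to BAM with Rsamtools and read
# through GenomicAlignments; both coverage summarization and read
# recruitment consume the same record table.

# Read mapped records from a SAM or BAM file into a flat table.
# Secondary and supplementary alignments are dropped: mean depth and
# recruitment should reflect primary placements only.
read_sam_records <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext != "bam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(aln)
  flag <- mc$flag
  cig <- GenomicAlignments::cigar(aln)
  aligned <- vapply(
    GenomicAlignments::explodeCigarOpLengths(cig, ops = c("M", "=", "X")),
    sum, numeric(1))
  data.frame(
    qname = mc$qname,
    rname = as.character(GenomicAlignments::seqnames(aln)),
    pos = GenomicAlignments::start(aln),
    paired = bitwAnd(flag, 0x1) > 0,
    mate1 = bitwAnd(flag, 0x40) > 0,
    mate2 = bitwAnd(flag, 0x80) > 0,
    clipped = grepl("[SH]", cig),
    aligned_bases = aligned,
    stringsAsFactors = FALSE)
}

#' Read alignment records for recruitment
#'
#' Parses a SAM/BAM file into the per-read alignment table used by
#' [recruit_reads()]. Only primary mapped records are kept. An alignment
#' is *full length* when its CIGAR contains no soft or hard clipping:
#' mismatches and indels are allowed, clipping is not, matching the
#' semantics of end-to-end alignment mode.
#'
#' Unpaired records are classified as `merged` when their read id matches
#' `merged_pattern`, otherwise as `single` (orphan).
#'
#' @param path SAM or BAM file.
#' @param merged_pattern optional regular expression identifying merged
#'   read pairs among unpaired records.
#' @return data.frame with columns `read_id`, `mate_flag`
#'   (`single`/`mate1`/`mate2`/`merged`), `scaffold_id`, `full_length`,
#'   `mapped`.
#' @export
read_alignments <- function(path, merged_pattern = NULL) {
  rec <- read_sam_records(path)
  mate_flag <- ifelse(rec$paired & rec$mate1, "mate1",
               ifelse(rec$paired & rec$mate2, "mate2", "single"))
  if (!is.null(merged_pattern))
    mate_flag[mate_flag == "single" &
                grepl(merged_pattern, rec$qname)] <- "merged"
  data.frame(read_id = rec$qname, mate_flag = mate_flag,
             scaffold_id = rec$rname, full_length = !rec$clipped,
             mapped = TRUE, stringsAsFactors = FALSE)
}
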