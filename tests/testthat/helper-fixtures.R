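# shared fixture builders; everything constructed in code

make_cov <- function(...) {
  cols <- list(...)
  coverage_matrix(do.call(cbind, cols))
}

# small hand-built taxonomy: two phyla, each with genus/species leaves
tiny_tax <- function() {
  taxonomy(
    id     = c("root", "bact", "phyA", "phyB", "genA1", "genA2", "genB1",
               "spA1a", "spA1b", "spA2a", "spB1a", "spB1b"),
    parent = c("root", "root", "bact", "bact", "phyA", "phyA", "phyB",
               "genA1", "genA1", "genA2", "genB1", "genB1"),
    rank   = c("no rank", "superkingdom", "phylum", "phylum", "genus",
               "genus", "genus", "species", "species", "species",
               "species", "species"))
}

make_hits <- function(scaffold_id, taxon_id, evalue = 1e-30,
                      bitscore = 500, source = "blastx") {
  h <- data.frame(scaffold_id = scaffold_id, taxon_id = taxon_id,
                  evalue = evalue, bitscore = bitscore, source = source,
                  stringsAsFactors = FALSE)
  class(h) <- c("hit_table", "data.frame")
  h
}

sam_header <- function(lengths) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), lengths))
}

sam_line <- function(qname, flag, rname, pos, cigar) {
  paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}

write_sam <- function(lines, lengths, path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(lengths), lines), path)
  path
}

# the 20-record alignment fixture exercising every recruitment rule;
# s1/s2 belong to binA, s3 to binB
recruit_fixture_sam <- function() {
  lens <- c(s1 = 1000L, s2 = 1000L, s3 = 1000L)
  lines <- c(
    sam_line("pair_ok", 99, "s1", 10, "50M"),          # 1 both full length
    sam_line("pair_ok", 147, "s2", 200, "50M"),        # 2 same bin
    sam_line("pair_indel", 99, "s1", 300, "20M2D30M"), # 3 indels allowed
    sam_line("pair_indel", 147, "s1", 400, "25M1I24M"),# 4
    sam_line("pair_cross", 97, "s1", 10, "50M"),       # 5 mates on two bins
    sam_line("pair_cross", 145, "s3", 10, "50M"),      # 6 -> rejected
    sam_line("pair_clip", 99, "s1", 50, "45M5S"),      # 7 one mate clipped
    sam_line("pair_clip", 147, "s1", 150, "50M"),      # 8 -> rejected
    sam_line("pair_bothclip", 99, "s1", 60, "5S45M"),  # 9 both clipped
    sam_line("pair_bothclip", 147, "s1", 160, "45M5H"),# 10 -> rejected
    sam_line("pair_half", 73, "s1", 70, "50M"),        # 11 mate unmapped ->
    sam_line("pair_half", 133, "s1", 70, "*"),         # 12 orphan rule
    sam_line("pair_outside", 99, "s3", 10, "50M"),     # 13 both mates on
    sam_line("pair_outside", 147, "s3", 90, "50M"),    # 14 the other bin
    sam_line("merged_ok", 0, "s2", 20, "80M"),         # 15 merged accepted
    sam_line("merged_clip", 0, "s1", 30, "75M5S"),     # 16 clipped merged
    sam_line("orphan_ok", 0, "s1", 40, "50M"),         # 17 orphan accepted
    sam_line("orphan_other", 0, "s3", 40, "50M"),      # 18 other bin
    sam_line("orphan_hard", 0, "s1", 45, "45M5H"),     # 19 hard clip
    sam_line("orphan_sec", 256, "s1", 55, "50M")       # 20 secondary only
  )
  write_sam(lines, lens)
}
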