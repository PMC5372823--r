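#' Relative abundance of a bin against the bacterial population
#'
#' Depth-weighted mass fraction: per dataset, the summed
#' `depth x length` over the bin's scaffolds divided by the same sum over
#' a caller-supplied denominator set (typically all scaffolds flagged
#' bacterial). The basis of the denominator is always reported alongside
#' the numbers. Abundances of disjoint bins are additive, so a grouped
#' estimate is the sum of its members' estimates.
#'
#' @param b a [bin()] or a list of disjoint bins (grouped estimate).
#' @param coverage a [coverage_matrix()].
#' @param scaffolds a [scaffold_set()] providing lengths.
#' @param denominator character vector of scaffold ids forming the
#'   reference population.
#' @param basis free-text description of the denominator, carried in the
#'   result.
#' @return list with `bin_id`, `abundance` (named per-dataset fractions
#'   in \[0,1\]) and `basis`.
#' @export
relative_abundance <- function(b, coverage, scaffolds, denominator,
                               basis = "depth x length over bacterial scaffolds") {
  members <- if (inherits(b, "bin")) b$members
             else unlist(lapply(b, `[[`, "members"))
  if (anyDuplicated(members)) stop("grouped bins must be disjoint")
  lab <- if (inherits(b, "bin")) b$bin_id
         else paste(vapply(b, `[[`, "", "bin_id"), collapse = "+")
  lens <- scaffold_lengths(scaffolds)
  mass <- function(ids, ds) sum(cov_depth(coverage, ids, ds) * lens[ids])
  ab <- vapply(colnames(coverage), function(ds) {
    den <- mass(denominator, ds)
    if (den == 0) stop("zero denominator mass in dataset ", ds)
    mass(members, ds) / den
  }, numeric(1))
  list(bin_id = lab, abundance = ab, basis = basis)
}

# the 20 standard amino-acid isotypes, three-letter codes as tRNA
# scanners emit them; Sec/Pyl and suppressors are not counted
STANDARD_ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                       "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                       "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

#' tRNA-based completeness of a bin
#'
#' The fraction of the 20 standard amino-acid tRNA isotypes found among
#' the bin's tRNA annotations, as a percentage. Selenocysteine,
#' pyrrolysine and undetermined isotypes are ignored. When all 20 are
#' present the printed label is `">99"` (a complete isotype set cannot
#' distinguish 100% from near-complete genomes); the numeric value is
#' still 100.
#'
#' @param annotations data.frame with columns `scaffold` and `isotype`
#'   (three-letter amino-acid codes, case-insensitive), or a path to such
#'   a TSV (with or without header).
#' @return list with `percent` (numeric), `label` (character, `">99"`
#'   when complete), `n_isotypes` and `missing` isotypes.
#' @export
trna_completeness <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_trna_table(annotations)
  iso <- character(0)
  if (nrow(annotations) > 0) {
    raw <- tolower(annotations$isotype)
    std <- tolower(STANDARD_ISOTYPES)
    iso <- unique(raw[raw %in% std])
  }
  n <- length(iso)
  pct <- 100 * n / 20
  list(percent = pct,
       label = if (n == 20L) ">99" else formatC(pct, format = "g"),
       n_isotypes = n,
       missing = STANDARD_ISOTYPES[!(tolower(STANDARD_ISOTYPES) %in% iso)])
}

#' Read a tRNA annotation table
#'
#' Two-column TSV `(scaffold, isotype)`; a header line is detected and
#' skipped when the second field is not an amino-acid code.
#'
#' @param path TSV file.
#' @return data.frame with columns `scaffold`, `isotype`.
#' @export
read_trna_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  names(df)[1:2] <- c("scaffold", "isotype")
  if (nrow(df) > 0 &&
      !(tolower(df$isotype[1]) %in% tolower(STANDARD_ISOTYPES)) &&
      tolower(df$isotype[1]) %in% c("isotype", "aa", "amino_acid"))
    df <- df[-1, , drop = FALSE]
  df
}

#' Select the unique core genome from an ortholog table
#'
#' The unique core genome is the set of ortholog groups present in
#' exactly one copy in *every* compared genome — the groups usable for a
#' concatenated multi-locus sequence analysis.
#'
#' @param table data.frame: column `group` (or rownames) plus one integer
#'   copy-count column per genome; or a path to such a TSV with header.
#' @return character vector of group ids, in table order.
#' @export
unique_core_genome <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- read.table(table, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(table) == 0) return(character(0))
  if ("group" %in% names(table)) {
    groups <- as.character(table$group)
    counts <- table[, setdiff(names(table), "group"), drop = FALSE]
  } else if (!is.numeric(table[[1]])) {
    groups <- as.character(table[[1]])
    counts <- table[, -1, drop = FALSE]
  } else {
    groups <- rownames(table)
    counts <- table
  }
  m <- as.matrix(counts)
  if (any(m != round(m)) || any(m < 0))
    stop("copy counts must be non-negative integers")
  groups[rowSums(m == 1) == ncol(m)]
}

#' Link 16S rRNA scaffolds to bins by coverage profile
#'
#' Ribosomal scaffolds rarely end up inside strict bins; this links them
#' back post hoc. Every profile (the 16S scaffold's per-dataset depths
#' and each bin's per-dataset mean member depth) is log-scaled as
#' `log2(depth + pseudo)`; the best bin minimizes the Euclidean distance
#' between profiles. A link is flagged ambiguous when the runner-up is
#' too close: `second < ambiguity_factor x best`, or an exact tie. This
#' is coverage-only evidence — phylogenetic placement must corroborate a
#' link before it is treated as a connection between bin and 16S gene.
#'
#' @param seq_profiles matrix (or [coverage_matrix()] rows) of 16S
#'   scaffold depths: rownames sequence ids, one column per dataset.
#' @param bins a [bin_set()] or list of [bin()]s.
#' @param coverage a [coverage_matrix()] covering the bin members, with
#'   the same dataset columns as `seq_profiles`.
#' @param ambiguity_factor runner-up distance ratio below which a link is
#'   ambiguous; default 2.
#' @param pseudo pseudo-depth for log scaling; default 0.1.
#' @return data.frame: `seq_id`, `best_bin`, `distance`,
#'   `second_bin`, `second_distance`, `ambiguous`, `evidence`
#'   (always `"coverage-only"`).
#' @export
link_16s_to_bins <- function(seq_profiles, bins, coverage,
                             ambiguity_factor = 2, pseudo = 0.1) {
  if (length(bins) == 0) stop("no bins to link against")
  datasets <- colnames(seq_profiles)
  stopifnot(all(datasets %in% colnames(coverage)))
  bin_prof <- t(vapply(bins, function(b)
    vapply(datasets, function(ds) mean(cov_depth(coverage, b$members, ds)),
           numeric(1)), numeric(length(datasets))))
  rownames(bin_prof) <- vapply(bins, `[[`, "", "bin_id")
  lp <- function(x) log2(x + pseudo)
  out <- lapply(rownames(seq_profiles), function(sid) {
    d <- sqrt(rowSums((lp(bin_prof) -
      matrix(lp(seq_profiles[sid, datasets]), nrow = nrow(bin_prof),
             ncol = length(datasets), byrow = TRUE))^2))
    ord <- order(d, names(d))
    best <- ord[1]
    second <- if (length(d) > 1) ord[2] else NA_integer_
    amb <- if (is.na(second)) FALSE
           else d[second] < ambiguity_factor * d[best] ||
                d[second] == d[best]
    data.frame(seq_id = sid, best_bin = names(d)[best],
               distance = unname(d[best]),
               second_bin = if (is.na(second)) NA_character_
                            else names(d)[second],
               second_distance = if (is.na(second)) NA_real_
                                 else unname(d[second]),
               ambiguous = amb, evidence = "coverage-only",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
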