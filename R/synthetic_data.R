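#' Specification for a synthetic two-sample community
#'
#' Describes a fully labeled synthetic metagenome emulating the
#' two-dataset design (two sequencing datasets of the same community,
#' e.g. two extractions of one host) that differential-coverage
#' refinement relies on.
#'
#' The coverage model: genome `g` has a base abundance
#' `m_g ~ Lognormal(abund_meanlog, abund_sdlog)`; each dataset scales it
#' by an independent lognormal factor (`genome_ratio_sdlog`), giving the
#' genome-level differential profile that drives coverage binning.
#' Per-scaffold depth combines a *shared* lognormal factor
#' (`noise_shared_sdlog`, coverage variation along the genome that
#' reproduces across datasets: GC bias, repeats, copy number) with a
#' smaller dataset-specific factor (`noise_dataset_sdlog`, sampling
#' noise). The shared factor dominating the dataset-specific one is what
#' makes within-genome z-score profiles track each other across datasets.
#'
#' Planted contaminants share the host bin's overall coverage scale —
#' that is exactly why an initial binner would have co-binned them — but
#' split differentially between the datasets by `contaminant_fold`
#' (depth multiplied by `sqrt(fold)` in one dataset and divided by it in
#' the other, direction random per contaminant).
#'
#' @param n_genomes number of genomes (one true bin each); default 5.
#' @param scaffolds_per_genome scaffolds per genome; default 50.
#' @param length_meanlog,length_sdlog lognormal scaffold length (bp);
#'   defaults log(8000) and 0.5.
#' @param abund_meanlog,abund_sdlog lognormal genome base abundance
#'   (mean depth units); defaults log(20) and 0.7.
#' @param genome_ratio_sdlog lognormal sd of the per-dataset scaling of a
#'   genome's abundance; default 0.5.
#' @param noise_shared_sdlog per-scaffold shared (cross-dataset)
#'   lognormal depth noise; default 0.3.
#' @param noise_dataset_sdlog per-scaffold dataset-specific lognormal
#'   depth noise; default 0.05.
#' @param contamination_rate fraction of a bin's scaffold count added as
#'   foreign contaminant scaffolds; default 0.1.
#' @param contaminant_fold differential abundance of contaminants between
#'   the two datasets; default 8.
#' @param n_phyla phyla in the toy taxonomy; default 3.
#' @param strain_pair when `TRUE`, genome 2 is a strain of genome 1:
#'   its sequences derive from genome 1 at `strain_identity`.
#' @param strain_identity sequence identity of the strain pair; 0.97.
#' @param with_sequences generate nucleotide sequences (needed for FASTA
#'   output; depth-only studies can skip them); default `TRUE`.
#' @param datasets the two dataset labels; default `c("A", "B")`.
#' @param seed integer seed; identical seeds give identical communities.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_genomes = 5, scaffolds_per_genome = 50,
                     length_meanlog = log(8000), length_sdlog = 0.5,
                     abund_meanlog = log(20), abund_sdlog = 0.7,
                     genome_ratio_sdlog = 0.5,
                     noise_shared_sdlog = 0.3,
                     noise_dataset_sdlog = 0.05,
                     contamination_rate = 0.1, contaminant_fold = 8,
                     n_phyla = 3, strain_pair = FALSE,
                     strain_identity = 0.97, with_sequences = TRUE,
                     datasets = c("A", "B"), seed = 1L) {
  stopifnot(n_genomes >= 1, scaffolds_per_genome >= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            contaminant_fold > 0, n_phyla >= 1, length(datasets) == 2,
            strain_identity > 0, strain_identity <= 1)
  if (contamination_rate > 0 && n_genomes < 2)
    stop("contaminants need at least two genomes")
  structure(as.list(environment()), class = "sim_spec")
}

# toy taxonomy: root -> Bacteria -> phylum_i -> genus_i -> species per
# genome (+ one decoy species per phylum for cross-phylum noise hits)
toy_taxonomy <- function(n_phyla, genome_phylum) {
  id <- c("root", "bacteria"); parent <- c("root", "root")
  rank <- c("no rank", "superkingdom"); name <- c("root", "Bacteria")
  for (p in seq_len(n_phyla)) {
    ph <- paste0("phylum", p); ge <- paste0("genus", p)
    id <- c(id, ph, ge, paste0("decoy_sp", p))
    parent <- c(parent, "bacteria", ph, ge)
    rank <- c(rank, "phylum", "genus", "species")
    name <- c(name, paste0("Phylum ", p), paste0("Genus ", p),
              paste0("Decoy species ", p))
  }
  for (g in seq_along(genome_phylum)) {
    id <- c(id, paste0("sp_g", g))
    parent <- c(parent, paste0("genus", genome_phylum[g]))
    rank <- c(rank, "species")
    name <- c(name, paste0("Species g", g))
  }
  taxonomy(id, parent, rank, name)
}

random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut > 0) {
    pos <- sample(length(chars), n_mut)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a labeled synthetic community
#'
#' Draws genomes, scaffolds, two-dataset coverage, true bins and
#' contaminated bins (true bins plus planted foreign scaffolds) from a
#' [sim_spec()]. Every emitted scaffold appears exactly once in the truth
#' table with its source genome, phylum, the bin it was placed in, and a
#' contaminant flag. Identical seeds give identical output.
#'
#' @param spec a [sim_spec()].
#' @return list with `scaffolds` ([scaffold_set()]), `true_bins`,
#'   `contaminated_bins` (both [bin_set()]), `coverage`
#'   ([coverage_matrix()]), `taxonomy` ([taxonomy()]), `truth`
#'   (data.frame) and `abundance` (genome x dataset matrix of the drawn
#'   mean depths).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  G <- spec$n_genomes; S <- spec$scaffolds_per_genome
  ds <- spec$datasets
  genome_phylum <- ((seq_len(G) - 1L) %% spec$n_phyla) + 1L
  tx <- toy_taxonomy(spec$n_phyla, genome_phylum)
  genome_gc <- runif(G, 0.35, 0.65)
  m <- rlnorm(G, spec$abund_meanlog, spec$abund_sdlog)
  abund <- vapply(ds, function(d)
    m * rlnorm(G, 0, spec$genome_ratio_sdlog), numeric(G))
  rownames(abund) <- paste0("g", seq_len(G))

  ids <- character(0); lens <- integer(0); seqs <- character(0)
  truth <- list()
  depth <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, ds))
  scaffold_depths <- function(base_a, base_b, n) {
    shared <- rlnorm(n, 0, spec$noise_shared_sdlog)
    cbind(base_a * shared * rlnorm(n, 0, spec$noise_dataset_sdlog),
          base_b * shared * rlnorm(n, 0, spec$noise_dataset_sdlog))
  }
  for (g in seq_len(G)) {
    sid <- sprintf("g%d_s%03d", g, seq_len(S))
    sl <- pmax(500L, as.integer(round(
      rlnorm(S, spec$length_meanlog, spec$length_sdlog))))
    if (spec$with_sequences) {
      if (spec$strain_pair && g == 2L) {
        # strain of genome 1: same scaffold lengths, mutated sequences
        src <- seqs[seq_len(min(S, length(seqs)))]
        sq <- vapply(seq_len(S), function(i)
          if (i <= length(src)) mutate_seq(src[i], spec$strain_identity)
          else random_seq(sl[i], genome_gc[1]), "")
        sl <- nchar(sq)
      } else {
        sq <- vapply(sl, random_seq, "", gc = genome_gc[g])
      }
      seqs <- c(seqs, setNames(sq, sid))
    }
    d <- scaffold_depths(abund[g, 1], abund[g, 2], S)
    rownames(d) <- sid
    depth <- rbind(depth, d)
    ids <- c(ids, sid); lens <- c(lens, sl)
    truth[[g]] <- data.frame(
      scaffold_id = sid, genome = paste0("g", g),
      phylum = paste0("phylum", genome_phylum[g]),
      bin = paste0("bin", g), contaminant = FALSE,
      stringsAsFactors = FALSE)
  }

  # planted contaminants: host-scale coverage, differential A/B split
  n_cont <- round(spec$contamination_rate * S)
  cont_truth <- list()
  cont_members <- setNames(vector("list", G), paste0("bin", seq_len(G)))
  if (n_cont > 0) {
    half <- sqrt(spec$contaminant_fold)
    for (g in seq_len(G)) {
      donors <- sample(setdiff(seq_len(G), g), n_cont, replace = TRUE)
      dir <- sample(c(1, -1), n_cont, replace = TRUE)
      sid <- sprintf("bin%d_cont%02d", g, seq_len(n_cont))
      sl <- pmax(500L, as.integer(round(
        rlnorm(n_cont, spec$length_meanlog, spec$length_sdlog))))
      if (spec$with_sequences) {
        sq <- vapply(seq_len(n_cont), function(i)
          random_seq(sl[i], genome_gc[donors[i]]), "")
        seqs <- c(seqs, setNames(sq, sid))
      }
      base <- m[g] * rlnorm(n_cont, 0, spec$noise_shared_sdlog)
      d <- cbind(base * half^dir * rlnorm(n_cont, 0, spec$noise_dataset_sdlog),
                 base * half^(-dir) * rlnorm(n_cont, 0, spec$noise_dataset_sdlog))
      rownames(d) <- sid
      colnames(d) <- ds
      depth <- rbind(depth, d)
      ids <- c(ids, sid); lens <- c(lens, sl)
      cont_members[[g]] <- sid
      cont_truth[[g]] <- data.frame(
        scaffold_id = sid, genome = paste0("g", donors),
        phylum = paste0("phylum", genome_phylum[donors]),
        bin = paste0("bin", g), contaminant = TRUE,
        stringsAsFactors = FALSE)
    }
  }

  scaffolds <- if (spec$with_sequences)
    scaffold_set(ids, sequence = Biostrings::DNAStringSet(seqs[ids]))
  else scaffold_set(ids, length = lens)

  true_bins <- bin_set(lapply(seq_len(G), function(g)
    bin(paste0("bin", g), truth[[g]]$scaffold_id,
        target_taxon = paste0("phylum", genome_phylum[g]))))
  cont_bins <- bin_set(lapply(seq_len(G), function(g)
    bin(paste0("bin", g),
        c(truth[[g]]$scaffold_id, cont_members[[g]]),
        target_taxon = paste0("phylum", genome_phylum[g]))))

  truth_df <- do.call(rbind, c(truth, cont_truth))
  rownames(truth_df) <- NULL
  list(scaffolds = scaffolds, true_bins = true_bins,
       contaminated_bins = cont_bins,
       coverage = coverage_matrix(depth[ids, , drop = FALSE]),
       taxonomy = tx, truth = truth_df, abundance = abund)
}

#' Simulate BLAST-style hits consistent with a community's truth
#'
#' Each scaffold receives `n_hits` hits. A hit points to the scaffold's
#' true species with probability `1 - cross_phylum_noise`, otherwise to a
#' decoy species in a random other phylum. Bitscores are drawn within a
#' 10% band so every hit survives MEGAN-style top-percent filtering; a
#' fraction `weak_evalue_frac` of hits get e-values above the 1e-20
#' cutoff (1e-10..1e-5) so the cutoff is exercised, the rest fall well
#' below it (1e-50..1e-25).
#'
#' @param truth the `truth` table from [simulate_community()].
#' @param tx the community's [taxonomy()].
#' @param n_hits hits per scaffold; default 3.
#' @param cross_phylum_noise probability a hit lands in a foreign phylum;
#'   default 0.
#' @param weak_evalue_frac fraction of hits with e-values above the
#'   cutoff; default 0.1.
#' @param seed integer seed.
#' @return a `hit_table` data.frame (`scaffold_id`, `taxon_id`, `evalue`,
#'   `bitscore`, `source`).
#' @export
simulate_hits <- function(truth, tx, n_hits = 3, cross_phylum_noise = 0,
                          weak_evalue_frac = 0.1, seed = 1L) {
  set.seed(seed)
  phyla <- grep("^phylum", tx$nodes$id, value = TRUE)
  if (length(phyla) < 3) stop("toy taxonomy needs at least 3 phyla")
  n <- nrow(truth) * n_hits
  scaffold_id <- rep(truth$scaffold_id, each = n_hits)
  own_species <- rep(paste0("sp_", truth$genome), each = n_hits)
  own_phylum <- rep(truth$phylum, each = n_hits)
  cross <- runif(n) < cross_phylum_noise
  taxon <- own_species
  if (any(cross)) {
    foreign <- vapply(own_phylum[cross], function(ph)
      sample(setdiff(phyla, ph), 1), "")
    taxon[cross] <- paste0("decoy_sp", sub("phylum", "", foreign))
  }
  weak <- runif(n) < weak_evalue_frac
  evalue <- ifelse(weak, 10^runif(n, -10, -5), 10^runif(n, -50, -25))
  bitscore <- runif(n, 460, 500)  # all within the 10% top band
  hits <- data.frame(scaffold_id = scaffold_id, taxon_id = taxon,
                     evalue = evalue, bitscore = bitscore,
                     source = "sim_blast", stringsAsFactors = FALSE)
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Write a simulated community in the formats the readers accept
#'
#' Emits scaffolds FASTA (when sequences were generated), contig-to-bin
#' tables for the true and the contaminated binning, a contig-depth
#' summary TSV, the toy taxonomy TSV and the truth table.
#'
#' @param sim result of [simulate_community()].
#' @param out_dir output directory.
#' @param hits optional `hit_table` to write as a 13-column BLAST-like
#'   TSV (taxon id in column 13).
#' @return (invisibly) named list of written paths.
#' @export
write_community <- function(sim, out_dir, hits = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(sim$scaffolds$seq)) {
    out$fasta <- file.path(out_dir, "scaffolds.fasta")
    Biostrings::writeXStringSet(sim$scaffolds$seq, out$fasta, width = 70L)
  }
  out$contig2bin_true <- file.path(out_dir, "contig2bin.true.tsv")
  write_contig2bin(sim$true_bins, out$contig2bin_true)
  out$contig2bin <- file.path(out_dir, "contig2bin.tsv")
  write_contig2bin(sim$contaminated_bins, out$contig2bin)
  out$depth <- file.path(out_dir, "depth.tsv")
  write_depth_tsv(sim$coverage, sim$scaffolds, out$depth)
  out$taxonomy <- file.path(out_dir, "taxonomy.tsv")
  write_taxonomy(sim$taxonomy, out$taxonomy)
  out$truth <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, out$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(hits)) {
    out$hits <- file.path(out_dir, "hits.tsv")
    blank <- rep("*", nrow(hits))
    blast <- data.frame(hits$scaffold_id, blank, 100, 100, 0, 0, 1, 100,
                        1, 100, hits$evalue, hits$bitscore, hits$taxon_id)
    write.table(blast, out$hits, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(out)
}
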