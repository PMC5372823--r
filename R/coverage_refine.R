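# The three differential-coverage purification steps. Conventions shared
# by all three: a step never mutates its input bin; kept and removed
# members always partition the input; every decision lands in the trace.

# sample sd (n-1); z-scores of a depth vector over the current members.
# Zero variance (or a single member) yields all-zero z, flagged upstream.
zscores <- function(depth) {
  if (length(depth) < 2) return(setNames(rep(0, length(depth)), names(depth)))
  s <- sd(depth)
  if (!is.finite(s) || s == 0) return(setNames(rep(0, length(depth)),
                                               names(depth)))
  (depth - mean(depth)) / s
}

#' Remove coverage outliers above a multiple of the bin median
#'
#' A scaffold is removed when its mean depth exceeds
#' `factor x median(bin depths)` in *any* dataset (OR semantics;
#' `all_datasets = TRUE` switches to AND). Medians are computed once on
#' the input membership — a single filtering pass — unless
#' `iterative = TRUE`, which repeats the pass on the kept set until it
#' converges.
#'
#' Datasets whose median depth is 0 are skipped with a warning: with a
#' zero median the rule would strip every scaffold with positive depth.
#'
#' @param b a [bin()].
#' @param coverage a [coverage_matrix()].
#' @param factor removal threshold as a multiple of the median; default 3.
#' @param datasets dataset labels to test (default: all columns).
#' @param all_datasets require the threshold to be exceeded in every
#'   dataset instead of any.
#' @param iterative recompute medians after each pass until stable.
#' @return list with `kept` ([bin()]), `removed` (character), `medians`
#'   (per-dataset medians of the input membership) and `trace`.
#' @export
median_outlier_filter <- function(b, coverage, factor = 3,
                                  datasets = colnames(coverage),
                                  all_datasets = FALSE, iterative = FALSE) {
  members <- b$members
  removed_all <- character(0)
  trace <- empty_trace()
  first_medians <- NULL
  repeat {
    depth <- vapply(datasets, function(ds) cov_depth(coverage, members, ds),
                    numeric(length(members)))
    depth <- matrix(depth, nrow = length(members),
                    dimnames = list(members, datasets))
    med <- apply(depth, 2, median)
    if (is.null(first_medians)) first_medians <- med
    usable <- med > 0
    if (any(!usable))
      warning("dataset(s) with zero median depth skipped in bin ",
              b$bin_id, ": ", paste(datasets[!usable], collapse = ", "))
    if (!any(usable)) break
    over <- depth[, usable, drop = FALSE] >
      matrix(factor * med[usable], nrow = length(members),
             ncol = sum(usable), byrow = TRUE)
    hit <- if (all_datasets) apply(over, 1, all) else apply(over, 1, any)
    removed <- members[hit]
    if (length(removed) > 0) {
      ds_a <- datasets[usable][1]
      ds_b <- if (sum(usable) > 1) datasets[usable][2] else ds_a
      trace <- bind_traces(trace, refinement_trace(
        stage = "median_filter", bin = b$bin_id, scaffold = removed,
        action = "remove", reason = sprintf("depth > %gx median", factor),
        cutoff = factor, value_a = depth[removed, ds_a],
        value_b = depth[removed, ds_b]))
    }
    removed_all <- c(removed_all, removed)
    members <- members[!hit]
    if (!iterative || length(removed) == 0 || length(members) == 0) break
  }
  list(kept = if (length(members) > 0) bin(b$bin_id, members, b$target_taxon)
       else NULL,
       removed = removed_all, medians = first_medians, trace = trace)
}

#' Split a bin whose members show inverse relative coverage profiles
#'
#' A mixed bin can contain two genuine genomes that are abundant in
#' opposite datasets (high in A, low in B, or vice versa). Per member the
#' log2 coverage ratio `r = log2((depth_A + pseudo)/(depth_B + pseudo))`
#' is computed; the members are sorted by `r` and the largest gap between
#' consecutive values located. The bin is split at that gap only when
#' all three conditions hold: the gap is at least `min_gap_log2`, both
#' sides keep at least `min_side` members, and the mean ratios of the two
#' sides have opposite signs (the "high in one, low in the other"
#' criterion). Otherwise the bin is returned unchanged.
#'
#' @param b a [bin()].
#' @param coverage a [coverage_matrix()].
#' @param dataset_a,dataset_b the two datasets to compare.
#' @param min_gap_log2 minimum log2-ratio gap to split at; default 2.
#' @param min_side minimum members on each side; default 5.
#' @param pseudo pseudo-depth guarding against zero coverage; default 0.1.
#' @return list with `parent`, `sub_bins` (list of [bin()]s),
#'   `split_statistic` (the gap), `was_split`, `trace`.
#' @export
split_inverse_profiles <- function(b, coverage, dataset_a, dataset_b,
                                   min_gap_log2 = 2, min_side = 5,
                                   pseudo = 0.1) {
  no_split <- function(reason, stat = NA_real_) {
    list(parent = b$bin_id, sub_bins = list(b), split_statistic = stat,
         was_split = FALSE,
         trace = refinement_trace(stage = "split", bin = b$bin_id,
                                  scaffold = "*", action = "keep",
                                  reason = reason, cutoff = min_gap_log2,
                                  value_a = stat, value_b = NA))
  }
  if (length(b$members) < 2 * min_side)
    return(no_split(sprintf("bin smaller than 2 x min_side (%d)", min_side)))
  da <- cov_depth(coverage, b$members, dataset_a)
  db <- cov_depth(coverage, b$members, dataset_b)
  r <- log2((da + pseudo) / (db + pseudo))
  ord <- order(r, names(r))  # ties broken by id for determinism
  rs <- r[ord]
  gaps <- diff(rs)
  g <- which.max(gaps)
  gap <- gaps[g]
  low <- names(rs)[seq_len(g)]
  high <- names(rs)[(g + 1):length(rs)]
  if (gap < min_gap_log2)
    return(no_split(sprintf("largest gap %.2f < %g", gap, min_gap_log2), gap))
  if (length(low) < min_side || length(high) < min_side)
    return(no_split("split side below min_side", gap))
  if (!(mean(r[low]) < 0 && mean(r[high]) > 0))
    return(no_split("sides not inverse (same-sign mean ratios)", gap))
  subs <- list(bin(paste0(b$bin_id, ".1"), low, b$target_taxon),
               bin(paste0(b$bin_id, ".2"), high, b$target_taxon))
  trace <- refinement_trace(
    stage = "split", bin = b$bin_id,
    scaffold = c(low, high), action = "assign",
    reason = c(rep(paste0("sub-bin ", b$bin_id, ".1"), length(low)),
               rep(paste0("sub-bin ", b$bin_id, ".2"), length(high))),
    cutoff = min_gap_log2, value_a = r[c(low, high)], value_b = gap)
  list(parent = b$bin_id, sub_bins = subs, split_statistic = gap,
       was_split = TRUE, trace = trace)
}

#' Iterative z-score decontamination with a shrinking cutoff
#'
#' Final purification of a bin by differential coverage. Per dataset the
#' depths of the *current* members are converted to z-scores (deviation
#' from the bin mean in units of the sample standard deviation, n-1). A
#' scaffold whose z-scores in the two datasets differ by more than the
#' cutoff is a putative contaminant: the single worst offender (largest
#' `|z_A - z_B|`; ties broken by smallest id) is removed and the z-scores
#' recomputed on the remaining members. When no member exceeds the
#' cutoff, the cutoff is lowered by `step`, down to `end_cutoff`
#' inclusive. On termination every remaining member satisfies
#' `|z_A - z_B| <= end_cutoff` under z-scores computed on the final
#' membership.
#'
#' `batch = TRUE` removes all members above the cutoff per recomputation
#' instead of one at a time; the default follows the one-at-a-time
#' recomputation rule.
#'
#' If a removal would drop the membership below `min_members`, the run
#' stops early and is flagged in the trace: standard deviations over very
#' few scaffolds are meaningless.
#'
#' @param b a [bin()].
#' @param coverage a [coverage_matrix()].
#' @param dataset_a,dataset_b the differencing pair of datasets.
#' @param start_cutoff,end_cutoff,step the shrinking cutoff schedule;
#'   defaults 4, 2, 1.
#' @param min_members stop before shrinking below this size; default 4.
#' @param batch remove every offender per round instead of one at a time.
#' @return list with `kept` ([bin()]), `removed` (ordered character
#'   vector), `z` (final per-member `z_a`, `z_b` data.frame), `flags`
#'   (character) and `trace`.
#' @export
zscore_purify <- function(b, coverage, dataset_a, dataset_b,
                          start_cutoff = 4, end_cutoff = 2, step = 1,
                          min_members = 4, batch = FALSE) {
  stopifnot(start_cutoff >= end_cutoff, end_cutoff > 0, step > 0)
  members <- sort(b$members)  # order-invariance: canonical order
  if (length(members) < min_members)
    stop("bin ", b$bin_id, " has fewer than min_members = ", min_members,
         " members")
  removed <- character(0)
  trace <- empty_trace()
  flags <- character(0)
  cutoff <- start_cutoff
  zab <- function(m) {
    za <- zscores(cov_depth(coverage, m, dataset_a))
    zb <- zscores(cov_depth(coverage, m, dataset_b))
    list(a = za, b = zb, d = abs(za - zb))
  }
  repeat {
    z <- zab(members)
    over <- which(z$d > cutoff)
    if (length(over) == 0) {
      if (cutoff <= end_cutoff) break
      cutoff <- max(cutoff - step, end_cutoff)
      next
    }
    victims <- if (batch) members[over] else {
      worst <- max(z$d[over])
      # ties: lexicographically smallest id
      min(members[over][z$d[over] == worst])
    }
    if (length(members) - length(victims) < min_members) {
      flags <- c(flags, "min_members")
      trace <- bind_traces(trace, refinement_trace(
        stage = "zscore_purify", bin = b$bin_id, scaffold = "*",
        action = "flag",
        reason = sprintf("stopped: removal would leave < %d members",
                         min_members),
        cutoff = cutoff, value_a = NA, value_b = NA))
      break
    }
    trace <- bind_traces(trace, refinement_trace(
      stage = "zscore_purify", bin = b$bin_id, scaffold = victims,
      action = "remove", reason = "|z_A - z_B| > cutoff", cutoff = cutoff,
      value_a = z$a[victims], value_b = z$b[victims]))
    removed <- c(removed, victims)
    members <- setdiff(members, victims)
  }
  z <- zab(members)
  sda <- sd(cov_depth(coverage, members, dataset_a))
  sdb <- sd(cov_depth(coverage, members, dataset_b))
  if (!is.finite(sda) || sda == 0 || !is.finite(sdb) || sdb == 0)
    flags <- c(flags, "zero_variance")
  list(kept = bin(b$bin_id, members, b$target_taxon), removed = removed,
       z = data.frame(scaffold_id = members, z_a = unname(z$a),
                      z_b = unname(z$b), stringsAsFactors = FALSE),
       flags = unique(flags), trace = trace)
}
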