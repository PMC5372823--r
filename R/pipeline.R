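#' Default refinement parameters
#'
#' All tunables of the refinement pipeline with their defaults: e-value
#' cutoff and top-percent band for LCA assignment, the median-outlier
#' factor, the inverse-profile split thresholds, the z-score cutoff
#' schedule and the linking ambiguity factor.
#'
#' @return named list of parameters.
#' @export
refine_params <- function() {
  list(evalue_max = 1e-20, top_percent = 10, median_factor = 3,
       min_gap_log2 = 2, min_side = 5, split_pseudo = 0.1,
       start_cutoff = 4, end_cutoff = 2, step = 1, min_members = 4,
       batch = FALSE, ambiguity_factor = 2)
}

#' Refine one bin through the full stage order
#'
#' Runs the refinement stages in pipeline order: LCA taxonomic filter
#' (when hits and a taxonomy are supplied), median-outlier removal,
#' inverse-profile splitting, then iterative z-score purification of each
#' resulting sub-bin. Sub-bins created by the split are processed
#' independently downstream.
#'
#' @param b a [bin()].
#' @param coverage a [coverage_matrix()].
#' @param dataset_a,dataset_b the differencing pair of datasets.
#' @param hits optional `hit_table`; enables the LCA stage.
#' @param tx optional [taxonomy()]; required with `hits`.
#' @param params parameter list, see [refine_params()].
#' @return list with `bins` (list of refined [bin()]s; empty if the bin
#'   was emptied or fell below `min_members`), `removed` (character),
#'   `trace` ([refinement_trace()]) and `report` (per-stage data.frame:
#'   stage, bin, members_in, removed, members_out).
#' @export
refine_bin <- function(b, coverage, dataset_a, dataset_b, hits = NULL,
                       tx = NULL, params = refine_params()) {
  p <- utils::modifyList(refine_params(), params)
  trace <- empty_trace()
  removed <- character(0)
  report <- list()
  note <- function(stage, bid, n_in, n_rm)
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, bin = bid, members_in = n_in, removed = n_rm,
      members_out = n_in - n_rm, stringsAsFactors = FALSE)

  cur <- b
  if (!is.null(hits)) {
    if (is.null(tx)) stop("hits supplied without a taxonomy")
    asg <- assign_bin_lca(cur, hits, tx, evalue_max = p$evalue_max,
                          top_percent = p$top_percent)
    fl <- filter_bin_by_taxonomy(cur, asg)
    note("lca_filter", cur$bin_id, length(cur$members), length(fl$removed))
    trace <- bind_traces(trace, fl$trace)
    removed <- c(removed, fl$removed)
    if (is.null(fl$kept))
      return(list(bins = list(), removed = removed, trace = trace,
                  report = do.call(rbind, report)))
    cur <- fl$kept
  }

  mf <- median_outlier_filter(cur, coverage, factor = p$median_factor,
                              datasets = c(dataset_a, dataset_b))
  note("median_filter", cur$bin_id, length(cur$members), length(mf$removed))
  trace <- bind_traces(trace, mf$trace)
  removed <- c(removed, mf$removed)
  if (is.null(mf$kept))
    return(list(bins = list(), removed = removed, trace = trace,
                report = do.call(rbind, report)))
  cur <- mf$kept

  sp <- split_inverse_profiles(cur, coverage, dataset_a, dataset_b,
                               min_gap_log2 = p$min_gap_log2,
                               min_side = p$min_side,
                               pseudo = p$split_pseudo)
  note("split", cur$bin_id, length(cur$members), 0L)
  trace <- bind_traces(trace, sp$trace)

  final <- list()
  for (sb in sp$sub_bins) {
    if (length(sb$members) < p$min_members) {
      trace <- bind_traces(trace, refinement_trace(
        stage = "zscore_purify", bin = sb$bin_id, scaffold = "*",
        action = "flag", reason = "too few members to purify",
        cutoff = NA, value_a = NA, value_b = NA))
      final[[length(final) + 1L]] <- sb
      next
    }
    zp <- zscore_purify(sb, coverage, dataset_a, dataset_b,
                        start_cutoff = p$start_cutoff,
                        end_cutoff = p$end_cutoff, step = p$step,
                        min_members = p$min_members, batch = p$batch)
    note("zscore_purify", sb$bin_id, length(sb$members),
         length(zp$removed))
    trace <- bind_traces(trace, zp$trace)
    removed <- c(removed, zp$removed)
    final[[length(final) + 1L]] <- zp$kept
  }
  list(bins = final, removed = removed, trace = trace,
       report = do.call(rbind, report))
}

#' Run the full refinement over a set of bins
#'
#' In-memory driver used both directly and by the file-level
#' [run_refinement()].
#'
#' @param bins a [bin_set()].
#' @inheritParams refine_bin
#' @return list with `bins` (list of refined bins across all inputs),
#'   `removed`, `trace`, `report`.
#' @export
refine_bins <- function(bins, coverage, dataset_a, dataset_b, hits = NULL,
                        tx = NULL, params = refine_params()) {
  res <- lapply(bins[order(names(bins))], refine_bin, coverage = coverage,
                dataset_a = dataset_a, dataset_b = dataset_b, hits = hits,
                tx = tx, params = params)
  list(bins = do.call(c, lapply(res, `[[`, "bins")) %||% list(),
       removed = unlist(lapply(res, `[[`, "removed"), use.names = FALSE),
       trace = do.call(bind_traces, lapply(res, `[[`, "trace")),
       report = do.call(rbind, lapply(res, `[[`, "report")))
}

#' Read / write a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept
#' as strings except numbers, which round-trip losslessly.
#'
#' @param path config file.
#' @return named list (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][[1]])
  vals <- lapply(kv, function(p) {
    v <- p[[2]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && !grepl("[^0-9eE+.-]", v)) num else v
  })
  setNames(vals, vapply(kv, `[[`, "", 1))
}

#' @rdname read_run_config
#' @param config named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  fmt <- vapply(config, function(v)
    if (is.numeric(v)) format(v, digits = 15) else as.character(v), "")
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' Run the refinement pipeline from a configuration
#'
#' File-level entry point: reads bins (FASTA + contig-to-bin table),
#' coverage (depth TSV), optionally hits and a taxonomy, refines every
#' bin in stage order, and writes refined bin FASTAs, the removal trace
#' and a machine-readable JSON run report to the output directory. The
#' report body carries no timestamps or hostnames (a sidecar does), so
#' reports from identical runs are diffable.
#'
#' Recognized config keys: `fasta`, `contig2bin`, `depth_tsv`,
#' `hits`, `taxonomy`, `targets` (TSV bin<TAB>taxon), `dataset_a`,
#' `dataset_b`, `out_dir`, `overwrite`, `seed`, plus any name from
#' [refine_params()].
#'
#' @param config named list or path to a key=value config file.
#' @return (invisibly) the run report list.
#' @export
run_refinement <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  req <- c("fasta", "depth_tsv", "dataset_a", "dataset_b", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0) stop("config missing: ", paste(miss, collapse = ", "))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  targets <- NULL
  if (!is.null(config$targets)) {
    tt <- read.table(config$targets, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character")
    targets <- setNames(tt[[2]], tt[[1]])
  }
  inp <- read_bins(strsplit(config$fasta, ",")[[1]],
                   contig2bin = config$contig2bin, targets = targets)
  coverage <- read_coverage(depth_tsv = config$depth_tsv)
  tx <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
  hits <- if (!is.null(config$hits) && !is.null(tx))
    read_hits(setNames(strsplit(config$hits, ",")[[1]], NULL), tx)

  params <- config[intersect(names(config), names(refine_params()))]
  res <- refine_bins(inp$bins, coverage, config$dataset_a,
                     config$dataset_b, hits = hits, tx = tx,
                     params = params)

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  overwrite <- isTRUE(config$overwrite) ||
    identical(config$overwrite, "true") || identical(config$overwrite, 1)
  if (length(res$bins) > 0 && !is.null(inp$scaffolds$seq))
    write_refined_bins(res$bins, inp$scaffolds,
                       file.path(out_dir, "bins"), overwrite = overwrite)
  write_trace(res$trace, file.path(out_dir, "trace.tsv"))
  report <- list(
    parameters = utils::modifyList(refine_params(), params),
    datasets = c(config$dataset_a, config$dataset_b),
    stages = res$report,
    n_bins_in = length(inp$bins), n_bins_out = length(res$bins),
    n_removed = length(res$removed),
    removed = sort(res$removed))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(paste0("run_completed\t", format(Sys.time(), usetz = TRUE)),
             file.path(out_dir, "report.sidecar.txt"))
  invisible(report)
}
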