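#' Pool an experiment's DEGs across conditions
#'
#' Union of the genes significant (empirical FDR below `fdr`) in any
#' condition of one experiment (time points, stages, brain regions).
#'
#' @param tables list of DEG tables sharing one gene universe.
#' @param fdr significance threshold (default 0.01).
#' @return character vector of pooled DEG ids, with attribute `universe`.
#' @export
pool_experiment_degs <- function(tables, fdr = 0.01) {
  if (!length(tables)) stop("need at least one table")
  ids <- lapply(tables, function(t) sort(t$gene_id))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    stop("inconsistent gene universes across tables")
  }
  pool <- sort(unique(unlist(lapply(tables, function(t)
    t$gene_id[t$fdr_empirical < fdr]))))
  attr(pool, "universe") <- ids[[1]]
  pool
}

#' Overlap of two experiments' pooled DEG sets
#'
#' @param pool_a,pool_b pooled DEG sets.
#' @param universe shared measured gene universe.
#' @return list with `overlap` (shared gene ids), `n_overlap`, and the
#'   upper-tail hypergeometric `p`.
#' @export
cross_experiment_overlap <- function(pool_a, pool_b, universe) {
  shared <- intersect(pool_a, pool_b)
  p <- hyper_overlap_p(length(shared), length(pool_a), length(pool_b),
                       length(universe))
  list(overlap = shared, n_overlap = length(shared), p = p)
}

#' Genes unique to one of two experiments
#'
#' The two-state analogue of [unique_genes()]: a gene is unique to
#' experiment A when its best (minimum) empirical FDR across A's conditions
#' is below `focal_fdr` while its best FDR across B's conditions stays at or
#' above the relaxed threshold, and vice versa.
#'
#' @param tables_a,tables_b lists of DEG tables for the two experiments
#'   (shared gene universe).
#' @param focal_fdr focal significance cutoff (default 0.01).
#' @param relaxed exclusion threshold on the other experiment (default 0.2).
#' @return list with `unique_a` and `unique_b`.
#' @export
experiment_unique_genes <- function(tables_a, tables_b,
                                    focal_fdr = 0.01, relaxed = 0.2) {
  if (relaxed <= focal_fdr) stop("relaxed must exceed focal_fdr")
  min_fdr <- function(tables) {
    universe <- sort(tables[[1]]$gene_id)
    m <- vapply(tables, function(t) t$fdr_empirical[match(universe, t$gene_id)],
                numeric(length(universe)))
    stats::setNames(apply(m, 1, min), universe)
  }
  fa <- min_fdr(tables_a)
  fb <- min_fdr(tables_b)
  if (!identical(names(fa), names(fb))) {
    stop("inconsistent gene universes across experiments")
  }
  list(unique_a = names(fa)[fa < focal_fdr & fb >= relaxed],
       unique_b = names(fb)[fb < focal_fdr & fa >= relaxed])
}

## ---- tabular I/O -----------------------------------------------------------

#' Read / write the package's TSV dialects
#'
#' Counts are genes x samples with a header row of sample ids and gene ids in
#' the first column; the design sheet has columns sample_id, stage, arm,
#' region, circadian_batch; DEG tables carry gene_id, log2_fold_change,
#' p_raw, fdr_empirical, mean_cpm; orthogroup maps carry orthogroup_id,
#' species, gene_id; gene sets are one id per line.
#'
#' @param path file path.
#' @param counts,design,deg,map,genes objects to write.
#' @name stagedyn_io
NULL

#' @rdname stagedyn_io
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname stagedyn_io
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname stagedyn_io
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname stagedyn_io
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname stagedyn_io
#' @export
read_deg_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname stagedyn_io
#' @export
write_deg_table_tsv <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname stagedyn_io
#' @export
read_orthogroup_map_tsv <- function(path) {
  orthogroup_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname stagedyn_io
#' @export
write_orthogroup_map_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname stagedyn_io
#' @export
read_gene_set <- function(path) readLines(path)

#' @rdname stagedyn_io
#' @export
write_gene_set <- function(genes, path) writeLines(genes, path)

#' Run the full stage-dynamics analysis for one region
#'
#' Convenience orchestration: per-stage differential expression with
#' permutation FDR, stage-unique genes, pairwise overlap, added shared genes
#' and their concordance.
#'
#' @param counts gene x sample counts for the region.
#' @param design design sheet.
#' @param region region label.
#' @param stages ordered stage labels.
#' @param deg_fdr,overlap_prescreen_fdr,focal_fdr,relaxed_schedule thresholds
#'   (see the individual functions).
#' @param n_perm permutations per contrast.
#' @param seed master seed.
#' @return list with `deg`, `series`, `unique`, `overlap`, `added_shared`,
#'   `concordance`.
#' @export
run_stage_pipeline <- function(counts, design, region, stages = NULL,
                               deg_fdr = 0.01, overlap_prescreen_fdr = 0.05,
                               focal_fdr = 0.01,
                               relaxed_schedule = c(0.05, 0.10, 0.20),
                               n_perm = 500, seed = 1) {
  deg <- run_de(counts, design, region, stages = stages, n_perm = n_perm,
                seed = seed)
  series <- stage_series(deg, region = region)
  ov <- pairwise_overlap(series, deg_fdr = deg_fdr)
  asr <- added_shared(series, deg_fdr = deg_fdr,
                      overlap_prescreen_fdr = overlap_prescreen_fdr,
                      overlap = ov)
  conc <- tryCatch(concordance_test(asr), error = function(e) NULL)
  list(deg = deg, series = series,
       unique = unique_genes(series, focal_fdr = focal_fdr,
                             relaxed_schedule = relaxed_schedule),
       overlap = ov, added_shared = asr, concordance = conc)
}

#' Write a machine-readable JSON summary
#'
#' @param x a named list of scalar summaries.
#' @param path output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
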