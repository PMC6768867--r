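#' Derive a reproducible substream seed from a master seed
#'
#' @param seed master integer seed.
#' @param i substream index.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6 * 1009 + as.numeric(i) * 9973) %%
               2147483647L)
}

#' Simulation configuration
#'
#' Collects and validates all parameters of the synthetic multi-stage
#' experiment: the NB count model, the planted stage-unique / carryover /
#' additive differential-expression structure, the planted TF-target linear
#' structure, and the cross-species orthogroup map. Defaults emulate the
#' study design this package targets: five ordered stages of paternal care
#' (nest, eggs, early/mid/late hatching), each with a circadian-matched
#' control group of the same size, n = 5 males per group, and two brain
#' regions analyzed independently. The first three stages share the 9 a.m.
#' control batch; mid and late hatching have 1 p.m. and 5 p.m. controls.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (default 5).
#' @param stages ordered stage labels.
#' @param regions region labels.
#' @param stage_batches integer batch index per stage; stages sharing an
#'   index share a control group. NULL assigns batches `c(1,1,1,2,3)` for a
#'   five-stage series and one batch per stage otherwise.
#' @param baseline_mean_log,baseline_sd_log log-normal parameters of the
#'   per-gene baseline NB means (natural-log scale).
#' @param dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param effect_lfc planted absolute log2 fold change.
#' @param n_unique_per_stage planted stage-unique genes per stage.
#' @param n_carryover planted carryover genes (DE from an onset stage through
#'   a contiguous later, non-final stage).
#' @param n_additive_per_stage planted additive genes per onset stage (DE
#'   from onset through the final stage); onsets run over all non-final
#'   stages.
#' @param min_planted_mean minimum baseline mean count for a gene to be
#'   eligible for effect planting.
#' @param tf_count,targets_per_tf,edge_noise_sd TF-target planting: number of
#'   TFs, targets per TF, and the noise s.d. added on the standardized
#'   expression scale.
#' @param orthogroup_count number of orthogroups in the synthetic map.
#' @param genes_per_orthogroup_range inclusive range of per-species member
#'   counts per orthogroup.
#' @param shared_signal_orthogroups orthogroups planted with a shared
#'   cross-species signal.
#' @param species_set_sizes sizes of the two species' reported gene sets.
#' @param species_universe_sizes per-species measured-transcriptome sizes;
#'   genes beyond the map-covered ones belong to no orthogroup, as in a
#'   real orthology map covering only part of the transcriptome.
#' @param seed master seed; all generators derive substreams from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 5,
                       stages = c("nest", "eggs", "early_hatch",
                                  "mid_hatch", "late_hatch"),
                       regions = c("diencephalon", "telencephalon"),
                       stage_batches = NULL,
                       baseline_mean_log = log(50), baseline_sd_log = 1.2,
                       dispersion = 0.1, effect_lfc = 2,
                       n_unique_per_stage = 20, n_carryover = 20,
                       n_additive_per_stage = 15, min_planted_mean = 20,
                       tf_count = 10, targets_per_tf = 20,
                       edge_noise_sd = 0.2,
                       orthogroup_count = 3790,
                       genes_per_orthogroup_range = c(1, 3),
                       shared_signal_orthogroups = 14,
                       species_set_sizes = c(356, 838),
                       species_universe_sizes = c(18000, 18000),
                       seed = 1) {
  if (length(stages) < 2) stop("need at least two ordered stages")
  if (is.null(stage_batches)) {
    stage_batches <- if (length(stages) == 5) c(1L, 1L, 1L, 2L, 3L) else
      seq_along(stages)
  }
  if (length(stage_batches) != length(stages)) {
    stop("stage_batches must have one entry per stage")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_per_group < 1 || n_genes < 1) stop("counts must be at least 1")
  if (orthogroup_count < shared_signal_orthogroups) {
    stop("orthogroup_count must be at least shared_signal_orthogroups")
  }
  S <- length(stages)
  n_planted <- n_unique_per_stage * S + n_carryover +
    n_additive_per_stage * (S - 1)
  reserve <- tf_count * (1 + targets_per_tf)
  if (n_planted + reserve > n_genes) {
    stop("planted gene counts exceed n_genes")
  }
  cfg <- list(
    n_genes = n_genes, n_per_group = n_per_group, stages = stages,
    regions = regions, stage_batches = as.integer(stage_batches),
    baseline_mean_log = baseline_mean_log, baseline_sd_log = baseline_sd_log,
    dispersion = dispersion, effect_lfc = effect_lfc,
    n_unique_per_stage = n_unique_per_stage, n_carryover = n_carryover,
    n_additive_per_stage = n_additive_per_stage,
    min_planted_mean = min_planted_mean,
    tf_count = tf_count, targets_per_tf = targets_per_tf,
    edge_noise_sd = edge_noise_sd,
    orthogroup_count = orthogroup_count,
    genes_per_orthogroup_range = genes_per_orthogroup_range,
    shared_signal_orthogroups = shared_signal_orthogroups,
    species_set_sizes = species_set_sizes,
    species_universe_sizes = species_universe_sizes,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

## batch label shown in the design sheet
.batch_label <- function(i) paste0("batch", i)

## assign planted labels: returns data.frame(gene_id, class, onset, end, sign)
.plant_truth <- function(config, base_mean) {
  G <- config$n_genes
  S <- length(config$stages)
  reserve <- config$tf_count * (1 + config$targets_per_tf)
  eligible <- which(base_mean >= config$min_planted_mean &
                      seq_len(G) <= G - reserve)
  n_add_onsets <- S - 1
  n_need <- config$n_unique_per_stage * S + config$n_carryover +
    config$n_additive_per_stage * n_add_onsets
  if (length(eligible) < n_need) {
    stop("not enough eligible genes above min_planted_mean to plant effects")
  }
  picked <- sample(eligible, n_need)
  lab <- data.frame(gene = picked,
                    class = rep("null", n_need),
                    onset = rep(NA_integer_, n_need),
                    end = rep(NA_integer_, n_need),
                    sign = sample(c(-1, 1), n_need, replace = TRUE))
  k <- 0
  for (s in seq_len(S)) {
    idx <- k + seq_len(config$n_unique_per_stage)
    lab$class[idx] <- "unique"
    lab$onset[idx] <- s
    lab$end[idx] <- s
    if (length(idx)) k <- max(idx)
  }
  if (config$n_carryover > 0) {
    if (S < 3) stop("carryover genes need at least three stages")
    idx <- k + seq_len(config$n_carryover)
    onset <- sample.int(S - 2, config$n_carryover, replace = TRUE)
    span <- vapply(onset, function(o) {
      cand <- seq.int(o + 1, S - 1)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    lab$class[idx] <- "carryover"
    lab$onset[idx] <- onset
    lab$end[idx] <- span
    k <- max(idx)
  }
  for (s in seq_len(n_add_onsets)) {
    idx <- k + seq_len(config$n_additive_per_stage)
    lab$class[idx] <- "additive"
    lab$onset[idx] <- s
    lab$end[idx] <- S
    if (length(idx)) k <- max(idx)
  }
  lab
}

#' Simulate multi-stage NB counts with planted truth
#'
#' Generates, for each brain region, a gene x sample count matrix under the
#' staged design: for every experimental stage a group of `n_per_group`
#' samples plus a circadian-matched control group of the same size (stages
#' sharing a batch share one control group). Counts are negative binomial
#' with variance mu + phi mu^2 and log-normally distributed baseline means.
#' Planted genes have their NB mean multiplied by `2^(sign * effect_lfc)` in
#' the experimental groups of their active stages only; the planted labels
#' (unique / carryover / additive, onset and end stage, sign) are returned as
#' ground truth. Identical labels and baseline means are shared across
#' regions; counts are drawn independently per region from derived
#' substreams.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (named list of matrices, one per region),
#'   `design` (sample sheet with columns sample_id, stage, arm, region,
#'   circadian_batch) and `truth` (planted labels and per-stage active sets).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- length(config$stages)
  n <- config$n_per_group
  G <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  batches <- config$stage_batches
  ub <- sort(unique(batches))

  design <- list()
  for (r_i in seq_along(config$regions)) {
    r <- config$regions[r_i]
    for (s_i in seq_len(S)) {
      design[[length(design) + 1]] <- data.frame(
        sample_id = sprintf("%s_%s_rep%d", r, config$stages[s_i], seq_len(n)),
        stage = config$stages[s_i], arm = "experimental", region = r,
        circadian_batch = .batch_label(batches[s_i]),
        stringsAsFactors = FALSE)
    }
    for (b in ub) {
      design[[length(design) + 1]] <- data.frame(
        sample_id = sprintf("%s_ctrl_%s_rep%d", r, .batch_label(b),
                            seq_len(n)),
        stage = "control", arm = "control", region = r,
        circadian_batch = .batch_label(b), stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, design)

  set.seed(derive_seed(config$seed, 0))
  base_mean0 <- exp(rnorm(G, config$baseline_mean_log, config$baseline_sd_log))
  truth_lab <- .plant_truth(config, base_mean0)

  active <- matrix(FALSE, G, S)   # gene active in stage contrast
  sgn <- numeric(G)
  for (i in seq_len(nrow(truth_lab))) {
    g <- truth_lab$gene[i]
    active[g, truth_lab$onset[i]:truth_lab$end[i]] <- TRUE
    sgn[g] <- truth_lab$sign[i]
  }

  counts <- vector("list", length(config$regions))
  names(counts) <- config$regions
  for (r_i in seq_along(config$regions)) {
    r <- config$regions[r_i]
    set.seed(derive_seed(config$seed, r_i))
    d <- design[design$region == r, , drop = FALSE]
    mat <- matrix(0L, G, nrow(d), dimnames = list(gene_ids, d$sample_id))
    for (j in seq_len(nrow(d))) {
      mu <- base_mean0
      if (d$arm[j] == "experimental") {
        s_i <- match(d$stage[j], config$stages)
        on <- active[, s_i]
        mu[on] <- mu[on] * 2^(sgn[on] * config$effect_lfc)
      }
      mat[, j] <- as.integer(rnbinom(G, mu = mu, size = 1 / config$dispersion))
    }
    counts[[r]] <- mat
  }

  labels <- truth_lab
  labels$gene_id <- gene_ids[labels$gene]
  labels$onset_stage <- config$stages[labels$onset]
  labels$end_stage <- config$stages[labels$end]
  truth <- list(
    labels = labels[, c("gene_id", "class", "onset_stage", "end_stage",
                        "onset", "end", "sign")],
    active = `dimnames<-`(active, list(gene_ids, config$stages)),
    sign = stats::setNames(sgn, gene_ids)
  )
  list(counts = counts, design = design, truth = truth)
}

#' Plant TF-target linear structure into a count matrix
#'
#' Designates TF and target genes (the tail block of the gene list, disjoint
#' from the DE-planted block), and rewrites each target's standardized
#' log-cpm profile as `sign * z_TF` plus Gaussian noise of s.d.
#' `edge_noise_sd`, renormalized to unit variance. Counts for the targets are
#' regenerated from the rewritten log-cpm profiles; the exact standardized
#' panel is returned alongside so that downstream network inference can be
#' run either from counts or from the noiseless panel.
#'
#' @param config a [sim_config()] object (uses `tf_count`, `targets_per_tf`,
#'   `edge_noise_sd`, and a seed substream).
#' @param counts gene x sample count matrix (any number of samples >= 8).
#' @param lib_sizes library sizes for the cpm transform.
#' @return list with `counts` (modified matrix), `panel` (an
#'   [expression_panel()] whose target profiles are exact), and `edges`
#'   (data.frame tf, target, sign).
#' @export
simulate_tf_structure <- function(config, counts,
                                  lib_sizes = colSums(counts)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tf_count < 1) stop("tf_count must be at least 1")
  G <- nrow(counts)
  need <- config$tf_count * (1 + config$targets_per_tf)
  if (need > G) stop("targets_per_tf x tf_count exceeds available genes")
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(G))

  block <- (G - need + 1):G
  tf_idx <- block[seq_len(config$tf_count)]
  tgt_idx <- setdiff(block, tf_idx)

  logcpm <- log2((counts + 0.5) / (lib_sizes + 1) * 1e6)
  mu_g <- rowMeans(logcpm)
  sd_g <- apply(logcpm, 1, sd)
  sd_g[sd_g < 1e-12] <- 1
  z <- (logcpm - mu_g) / sd_g

  set.seed(derive_seed(config$seed, 97))
  edges <- data.frame(
    tf = rep(gene_ids[tf_idx], each = config$targets_per_tf),
    target = gene_ids[tgt_idx],
    sign = sample(c(-1, 1), length(tgt_idx), replace = TRUE),
    stringsAsFactors = FALSE)

  nsamp <- ncol(counts)
  scale <- sqrt(1 + config$edge_noise_sd^2)
  for (i in seq_len(nrow(edges))) {
    zt <- (edges$sign[i] * z[edges$tf[i], ] +
             rnorm(nsamp, 0, config$edge_noise_sd)) / scale
    zt <- (zt - mean(zt)) / sd(zt)
    z[edges$target[i], ] <- zt
  }

  new_logcpm <- z[tgt_idx, , drop = FALSE] * sd_g[tgt_idx] + mu_g[tgt_idx]
  new_counts <- round(2^new_logcpm * rep(lib_sizes + 1, each = length(tgt_idx)) /
                        1e6 - 0.5)
  counts[tgt_idx, ] <- pmax(new_counts, 0)

  panel <- structure(list(z = z, tf_ids = gene_ids[tf_idx],
                          gene_ids = gene_ids, samples = colnames(counts)),
                     class = "expression_panel")
  list(counts = counts, panel = panel, edges = edges)
}

#' Simulate a many-to-many orthogroup map with planted shared signal
#'
#' Builds a two-species orthogroup map (each gene in exactly one orthogroup;
#' per-species member counts drawn from `genes_per_orthogroup_range`) and two
#' species' gene sets of sizes `species_set_sizes`, emulating the added-shared
#' gene lists that the cross-species overlap test consumes. Each species'
#' universe is of size `species_universe_sizes`, of which only the map
#' members belong to orthogroups — as in a real orthology map that covers
#' only part of the measured transcriptome — so a gene set of a few hundred
#' genes hits only a few dozen orthogroups. In each of the
#' `shared_signal_orthogroups` planted signal orthogroups, both species' sets
#' include at least one member gene; the remaining set members are drawn
#' independently from each species' full universe.
#'
#' @param config a [sim_config()] object.
#' @return list with `map` (data.frame orthogroup_id, species, gene_id),
#'   `sets` (named list of the two species' gene sets), `universes` and
#'   `truth` (ids of the planted signal orthogroups).
#' @export
simulate_orthogroup_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 211))
  K <- config$orthogroup_count
  rng <- config$genes_per_orthogroup_range
  og_ids <- sprintf("OG%05d", seq_len(K))
  species <- c("speciesA", "speciesB")

  map <- list()
  for (sp in species) {
    sizes <- if (rng[2] > rng[1]) {
      # skewed toward single-member orthogroups, as in real orthology maps
      rng[1] + rbinom(K, rng[2] - rng[1], 0.135)
    } else rep(rng[1], K)
    gene_ids <- sprintf("%s_g%05d", sp, seq_len(sum(sizes)))
    map[[sp]] <- data.frame(orthogroup_id = rep(og_ids, sizes),
                            species = sp, gene_id = gene_ids,
                            stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map)
  rownames(map) <- NULL

  signal <- sample(og_ids, config$shared_signal_orthogroups)
  sets <- list()
  universes <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    mapped <- map$gene_id[map$species == sp]
    n_extra_univ <- max(0, config$species_universe_sizes[i] - length(mapped))
    universes[[sp]] <- c(mapped,
                         sprintf("%s_u%05d", sp, seq_len(n_extra_univ)))
    seeded <- vapply(signal, function(og) {
      members <- map$gene_id[map$species == sp & map$orthogroup_id == og]
      members[sample.int(length(members), 1)]
    }, "")
    n_extra <- max(0, config$species_set_sizes[i] - length(seeded))
    extra <- sample(setdiff(universes[[sp]], seeded), n_extra)
    sets[[sp]] <- unname(c(seeded, extra))
  }
  list(map = map, sets = sets, universes = universes,
       truth = list(signal_orthogroups = sort(signal)))
}
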