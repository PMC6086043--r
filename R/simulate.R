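#' Specify a synthetic spike-in benchmark
#'
#' Describes a synthetic miRNA-target compendium plus a "spiked" gene
#' set emulating a miRNA perturbation experiment: the gene set contains
#' a sample of the spiked miRNA's true targets (the repressed genes a
#' knock-in — or derepressed genes a knock-out — would surface) mixed
#' with background genes.  Several miRNAs may be spiked at once to
#' emulate double-perturbation designs.
#'
#' The defaults define the package's reference benchmark conditions: a
#' 2000-gene universe, 50 miRNAs with 40 targets each, 20% target
#' sharing between miRNAs, three databases each reporting a true
#' interaction with probability 0.9, and a gene set of 30 spiked
#' targets plus 20 background genes.
#'
#' @param n_genes_universe Number of genes in the simulated universe.
#' @param n_mirnas Number of simulated miRNAs.
#' @param targets_per_mirna Target-set size, a single value or an
#'   inclusive `c(lo, hi)` range sampled per miRNA.
#' @param overlap_factor Probability that a target slot is filled with
#'   a gene already targeted by a previously generated miRNA (0 =
#'   pairwise disjoint target sets).
#' @param n_databases Number of database files to emit.
#' @param db_agreement Probability that each database independently
#'   reports a true interaction (models inter-database discordance).
#' @param spike_mirna Index (or indices) of the spiked miRNA(s).
#' @param n_spiked_targets Targets of each spiked miRNA sampled into
#'   the gene set (recycled over `spike_mirna`; 0 = negative control).
#' @param n_background_genes Background genes (non-targets of the
#'   spiked miRNAs) added to the gene set.
#' @param rng_seed Integer seed; all randomness derives from it.
#' @return An object of class `mirem_sim_spec`.
#' @export
sim_spec <- function(n_genes_universe = 2000L, n_mirnas = 50L,
                     targets_per_mirna = 40L, overlap_factor = 0.2,
                     n_databases = 3L, db_agreement = 0.9,
                     spike_mirna = 1L, n_spiked_targets = 30L,
                     n_background_genes = 20L, rng_seed = 1L) {
  fail <- function(msg) mirem_stop(msg, "mirem_validation_error")
  n_genes_universe <- as.integer(n_genes_universe)
  n_mirnas <- as.integer(n_mirnas)
  n_databases <- as.integer(n_databases)
  targets_per_mirna <- as.integer(targets_per_mirna)
  if (length(targets_per_mirna) == 1L) {
    targets_per_mirna <- rep(targets_per_mirna, 2L)
  }
  if (any(c(n_genes_universe, n_mirnas, n_databases) < 1L)) {
    fail("universe, miRNA and database counts must be positive")
  }
  if (length(targets_per_mirna) != 2L || any(targets_per_mirna < 1L) ||
      targets_per_mirna[1L] > targets_per_mirna[2L]) {
    fail("targets_per_mirna must be a positive value or ascending c(lo, hi) range")
  }
  if (targets_per_mirna[2L] > n_genes_universe) {
    fail("targets_per_mirna exceeds the universe size")
  }
  for (prob in c(overlap_factor, db_agreement)) {
    if (!is.numeric(prob) || prob < 0 || prob > 1) {
      fail("overlap_factor and db_agreement must lie in [0, 1]")
    }
  }
  spike_mirna <- as.integer(spike_mirna)
  if (length(spike_mirna) < 1L || any(spike_mirna < 1L) ||
      any(spike_mirna > n_mirnas) || anyDuplicated(spike_mirna)) {
    fail("spike_mirna must be distinct indices in [1, n_mirnas]")
  }
  n_spiked_targets <- rep_len(as.integer(n_spiked_targets), length(spike_mirna))
  if (any(n_spiked_targets < 0L) || any(n_spiked_targets > targets_per_mirna[1L])) {
    fail("n_spiked_targets must lie in [0, min targets_per_mirna]")
  }
  n_background_genes <- as.integer(n_background_genes)
  if (n_background_genes < 0L) fail("n_background_genes must be non-negative")
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) fail("rng_seed must be an integer")
  structure(list(n_genes_universe = n_genes_universe, n_mirnas = n_mirnas,
                 targets_per_mirna = targets_per_mirna,
                 overlap_factor = overlap_factor, n_databases = n_databases,
                 db_agreement = db_agreement, spike_mirna = spike_mirna,
                 n_spiked_targets = n_spiked_targets,
                 n_background_genes = n_background_genes, rng_seed = rng_seed),
            class = "mirem_sim_spec")
}

# Deterministic per-stage RNG streams: stage `stream` reseeds from the
# spec seed plus a fixed offset, so adding files never shifts the
# stream of an earlier one.
.sim_seed <- function(spec, stream) {
  as.integer((as.numeric(spec$rng_seed) + stream) %% (.Machine$integer.max - 1))
}

#' Generate a synthetic interaction compendium on disk
#'
#' Draws random 22-nt mature sequences (uniform RNA; seed collisions
#' are possible and deliberately exercise duplicate detection), builds
#' target sets with the requested sharing structure, and emits each
#' true `(miRNA, gene)` pair into each of `n_databases` TSV files
#' independently with probability `db_agreement` (all rows flagged
#' conserved).  Also writes an identity `mapping.tsv` (gene symbols map
#' to themselves) and a `truth.tsv` listing every true pair with its
#' spike status.  Output is byte-identical for identical specs.
#'
#' @param spec A `mirem_sim_spec`.
#' @param out_dir Directory to write into (created if needed).
#' @return An object of class `mirem_sim_truth`: `spiked_mirna_ids`,
#'   `target_sets` (the true targets per miRNA), `universe`,
#'   `mirna_ids`, `sequences`, and the emitted `db_paths` /
#'   `mapping_path` / `truth_path`.
#' @export
simulate_compendium <- function(spec, out_dir) {
  if (!inherits(spec, "mirem_sim_spec")) {
    mirem_stop("spec must be created by sim_spec()", "mirem_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("G%05d", seq_len(spec$n_genes_universe))
  mids <- sprintf("sim-miR-%03d-5p", seq_len(spec$n_mirnas))

  set.seed(.sim_seed(spec, 1L))
  seqs <- vapply(mids, function(unused) {
    paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = "")
  }, character(1L))

  set.seed(.sim_seed(spec, 2L))
  lo <- spec$targets_per_mirna[1L]; hi <- spec$targets_per_mirna[2L]
  pool <- character(0)
  target_sets <- vector("list", spec$n_mirnas)
  for (k in seq_len(spec$n_mirnas)) {
    n_t <- if (lo == hi) lo else sample(lo:hi, 1L)
    n_old <- min(stats::rbinom(1L, n_t, spec$overlap_factor), length(pool))
    old <- pool[sample.int(length(pool), n_old)]
    fresh_pool <- setdiff(genes, pool)
    if (n_t - n_old > length(fresh_pool)) {
      mirem_stop("universe too small for the requested target sets",
                 "mirem_validation_error")
    }
    fresh <- fresh_pool[sample.int(length(fresh_pool), n_t - n_old)]
    target_sets[[k]] <- sort(c(old, fresh))
    pool <- union(pool, target_sets[[k]])
  }
  names(target_sets) <- mids

  pair_m <- rep(mids, lengths(target_sets))
  pair_g <- unlist(target_sets, use.names = FALSE)

  set.seed(.sim_seed(spec, 3L))
  db_paths <- character(spec$n_databases)
  names(db_paths) <- sprintf("db%d", seq_len(spec$n_databases))
  for (d in seq_len(spec$n_databases)) {
    keep <- stats::runif(length(pair_m)) < spec$db_agreement
    df <- data.frame(mirna_id = pair_m[keep],
                     mature_sequence = unname(seqs[pair_m[keep]]),
                     gene_id = pair_g[keep],
                     conserved = 1L, stringsAsFactors = FALSE)
    path <- file.path(out_dir, sprintf("%s.tsv", names(db_paths)[d]))
    write_tsv(df, path)
    db_paths[d] <- path
  }

  mapping_path <- file.path(out_dir, "mapping.tsv")
  write_tsv(data.frame(source_id = genes, namespace = "symbol",
                       canonical_id = genes, stringsAsFactors = FALSE),
            mapping_path)

  spiked_ids <- mids[spec$spike_mirna]
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(data.frame(mirna_id = pair_m, gene_id = pair_g,
                       spiked = as.integer(pair_m %in% spiked_ids),
                       stringsAsFactors = FALSE),
            truth_path)

  structure(list(spiked_mirna_ids = spiked_ids, target_sets = target_sets,
                 universe = genes, mirna_ids = mids, sequences = seqs,
                 db_paths = db_paths, mapping_path = mapping_path,
                 truth_path = truth_path),
            class = "mirem_sim_truth")
}

#' Sample the spiked gene set and write the gene-list file
#'
#' Takes `n_spiked_targets` true targets of each spiked miRNA plus
#' `n_background_genes` drawn uniformly from the genes targeted by none
#' of the spiked miRNAs, deduplicates, and writes one identifier per
#' line.  With `n_spiked_targets = 0` the set is pure background — a
#' negative control in which no miRNA should be strongly favored.
#'
#' @param spec The `mirem_sim_spec` used for the compendium.
#' @param truth The `mirem_sim_truth` returned by
#'   [simulate_compendium()].
#' @param path Output file (default `genes.txt` next to the databases).
#' @return Invisibly, a list with `path`, `genes`, `spiked` (the
#'   sampled true targets) and `background`.
#' @export
simulate_spiked_gene_set <- function(spec, truth,
                                     path = file.path(dirname(truth$mapping_path),
                                                      "genes.txt")) {
  if (!inherits(truth, "mirem_sim_truth")) {
    mirem_stop("truth must be created by simulate_compendium()",
               "mirem_validation_error")
  }
  set.seed(.sim_seed(spec, 4L))
  spiked <- character(0)
  for (j in seq_along(truth$spiked_mirna_ids)) {
    tg <- truth$target_sets[[truth$spiked_mirna_ids[j]]]
    n <- spec$n_spiked_targets[j]
    if (n > length(tg)) {
      mirem_stop("n_spiked_targets exceeds the spiked miRNA's target count",
                 "mirem_validation_error")
    }
    spiked <- c(spiked, tg[sample.int(length(tg), n)])
  }
  non_target_pool <- setdiff(truth$universe,
                             unlist(truth$target_sets[truth$spiked_mirna_ids],
                                    use.names = FALSE))
  if (spec$n_background_genes > length(non_target_pool)) {
    mirem_stop("n_background_genes exceeds the non-target gene pool",
               "mirem_validation_error")
  }
  background <- non_target_pool[sample.int(length(non_target_pool),
                                           spec$n_background_genes)]
  gene_set <- unique(c(spiked, background))
  writeLines(gene_set, path)
  invisible(list(path = path, genes = gene_set, spiked = unique(spiked),
                 background = background))
}
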