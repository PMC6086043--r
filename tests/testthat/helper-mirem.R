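# Shared fixture builders and independent oracles.  The oracles here are
# deliberately naive (direct enumeration, hand-written step-up loops,
# grid search) so they stay independent of the implementation they check.

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Default two-entry mapping used across the id_mapping tests.
tp53_mapping <- function() {
  load_mapping(write_lines_tmp(c(
    "NM_000546\trefseq\tTP53",
    "ENSG00000141510\tensembl\tTP53",
    "NM_005228\trefseq\tEGFR",
    "uc002gig\tucsc\tTP53")))
}

# Write a database TSV from a data frame with columns
# mirna_id, mature_sequence, gene_id, conserved.
write_db <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

db_row <- function(mirna, seq, genes, conserved = 1L) {
  data.frame(mirna_id = mirna, mature_sequence = seq, gene_id = genes,
             conserved = conserved, stringsAsFactors = FALSE)
}

# A deterministic mature sequence whose seed is the given 6-mer.
seq_for_seed <- function(seed6, tail = "ACGUACGUACGUACG") {
  paste0("A", seed6, tail)
}

# Small single-database view: each element of `targets` is the target
# gene vector of one miRNA.
toy_view <- function(targets, seeds = NULL, min_db_count = 1L,
                     conserved_only = FALSE) {
  if (is.null(seeds)) {
    pool <- c("AACCGG", "CCGGUU", "GGUUAA", "UUAACC", "ACGUAC", "CAGUCA",
              "GUCAGU", "UGACUG")
    seeds <- rep_len(pool, length(targets))
  }
  df <- do.call(rbind, lapply(seq_along(targets), function(k) {
    db_row(names(targets)[k], seq_for_seed(seeds[k]), targets[[k]])
  }))
  comp <- load_database(write_db(df), "dbA")
  build_view(comp, min_db_count = min_db_count, conserved_only = conserved_only)
}

toy_geneset <- function(genes) {
  structure(list(genes = toupper(genes), n_input = length(genes),
                 n_unmapped = 0L, n_duplicates = 0L, unmapped = character(0)),
            class = "mirem_geneset")
}

make_problem <- function(Y) {
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("g%03d", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("mir%02d", seq_len(ncol(Y)))
  structure(list(genes = rownames(Y), mirnas = colnames(Y), Y = Y,
                 excluded_genes = character(0)),
            class = "mirem_em_problem")
}

# Random EM problem with every row and column non-empty.
rand_problem <- function(N, K, density = 0.4) {
  Y <- matrix(rbinom(N * K, 1L, density), N, K)
  for (i in which(rowSums(Y) == 0L)) Y[i, sample.int(K, 1L)] <- 1L
  for (j in which(colSums(Y) == 0L)) Y[sample.int(N, 1L), j] <- 1L
  make_problem(Y)
}

obs_loglik <- function(p, Y) sum(log(as.vector(Y %*% p)))

# --- independent oracles -------------------------------------------------

# Upper-tail hypergeometric by direct summation over the support.
hyper_oracle <- function(N, m, k, q) {
  xs <- q:min(m, k)
  xs <- xs[xs >= max(0L, k - (N - m))]
  if (length(xs) == 0L) return(0)
  sum(exp(lchoose(m, xs) + lchoose(N - m, k - xs) - lchoose(N, k)))
}

# Textbook BH step-up, written as an explicit loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1L) {
    for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Grid over the K-simplex with the given step; rows sum to 1.
simplex_grid <- function(K, step = 0.001) {
  n <- round(1 / step)
  if (K == 2L) {
    a <- seq(0L, n) / n
    return(cbind(a, 1 - a))
  }
  if (K == 3L) {
    i <- rep.int(0:n, n + 1L - 0:n)
    j <- unlist(lapply(0:n, function(a) 0:(n - a)), use.names = FALSE)
    return(cbind(i, j, n - i - j) / n)
  }
  stop("simplex_grid supports K = 2 or 3")
}

# Best observed-data log-likelihood over the simplex grid.
grid_max_loglik <- function(Y, step = 0.001, chunk = 200000L) {
  G <- simplex_grid(ncol(Y), step)
  best <- -Inf
  for (start in seq(1L, nrow(G), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(G))
    ll <- colSums(log(Y %*% t(G[idx, , drop = FALSE])))
    best <- max(best, max(ll, na.rm = TRUE), na.rm = TRUE)
  }
  best
}

# A deterministic fixture where exactly one miRNA passes the filter:
# mirA's ten targets are the gene set; mirB shares one of them.
single_hit_fixture <- function() {
  genes <- sprintf("SH%02d", 1:40)
  df <- rbind(
    db_row("mirA", seq_for_seed("AACCGG"), genes[1:10]),
    db_row("mirB", seq_for_seed("CCGGUU"), c(genes[10], genes[11:20])),
    db_row("mirC", seq_for_seed("GGUUAA"), genes[21:30]),
    db_row("mirD", seq_for_seed("UUAACC"), genes[31:40]))
  db <- write_db(df)
  mapping <- write_lines_tmp(c("source_id\tnamespace\tcanonical_id",
                               paste(genes, "symbol", genes, sep = "\t")))
  gene_list <- write_lines_tmp(genes[1:10], ext = ".txt")
  list(config = mirem_config(genes = gene_list, mapping = mapping,
                             databases = c(dbA = db), min_db_count = 1L),
       genes = genes)
}

# Scaled-down spike-in benchmark used by the pipeline tests.
small_sim_spec <- function(seed, ...) {
  args <- list(n_genes_universe = 400L, n_mirnas = 20L, targets_per_mirna = 20L,
               overlap_factor = 0.2, n_databases = 3L, db_agreement = 0.9,
               spike_mirna = 1L, n_spiked_targets = 15L, n_background_genes = 10L,
               rng_seed = seed)
  do.call(sim_spec, utils::modifyList(args, list(...)))
}

run_sim_pipeline <- function(spec, dir = tempfile("sim"), ...) {
  truth <- simulate_compendium(spec, dir)
  gs <- simulate_spiked_gene_set(spec, truth)
  cfg <- mirem_config(genes = gs$path, mapping = truth$mapping_path,
                      databases = truth$db_paths, ...)
  report <- suppressWarnings(run_pipeline(cfg))
  list(truth = truth, report = report, dir = dir, config = cfg)
}
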