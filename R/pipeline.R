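#' Assemble and validate a pipeline run configuration
#'
#' Defaults mirror the settings used for benchmark-style runs:
#' significance threshold 0.01 on the BH-adjusted p-value, EM
#' convergence parameter 0.001, interactions required in at least 3
#' databases, and non-conserved interactions excluded.
#'
#' @param genes Path to the gene list (one identifier per line, `#`
#'   comments allowed).
#' @param mapping Path to the identifier mapping table
#'   ([load_mapping()]).
#' @param databases Named character vector `c(name = path, ...)` of
#'   interaction database files.
#' @param selected_dbs Databases to use (default: all in `databases`).
#' @param min_db_count Minimum distinct databases per interaction
#'   (default 3).
#' @param conserved_only Restrict to conserved interactions (default
#'   `TRUE`).
#' @param p_threshold Significance cutoff for the hypergeometric filter
#'   (default 0.01).
#' @param use_adjusted Filter on BH-adjusted p-values (default `TRUE`).
#' @param em_tol EM convergence parameter (default 0.001).
#' @param em_max_iter EM iteration cap (default 1000).
#' @param cluster_cutoff Seed-cluster tree cut height (default 0 =
#'   exact-seed duplicate groups).
#' @param output_dir Optional output directory for [write_outputs()].
#' @return An object of class `mirem_config`.
#' @export
mirem_config <- function(genes, mapping, databases,
                         selected_dbs = names(databases),
                         min_db_count = 3L, conserved_only = TRUE,
                         p_threshold = 0.01, use_adjusted = TRUE,
                         em_tol = 0.001, em_max_iter = 1000L,
                         cluster_cutoff = 0, output_dir = NULL) {
  fail <- function(msg) mirem_stop(msg, "mirem_config_error")
  if (!is.character(genes) || length(genes) != 1L) fail("genes must be a single file path")
  if (!is.character(mapping) || length(mapping) != 1L) fail("mapping must be a single file path")
  if (length(databases) == 0L || is.null(names(databases)) ||
      any(!nzchar(names(databases)))) {
    fail("databases must be a non-empty named character vector (name = path)")
  }
  if (length(selected_dbs) == 0L || !all(selected_dbs %in% names(databases))) {
    fail("selected_dbs must be a non-empty subset of names(databases)")
  }
  min_db_count <- as.integer(min_db_count)
  if (is.na(min_db_count) || min_db_count < 1L || min_db_count > length(selected_dbs)) {
    fail(sprintf("min_db_count must lie in [1, %d]", length(selected_dbs)))
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    fail("p_threshold must lie in (0, 1]")
  }
  if (!is.numeric(em_tol) || em_tol <= 0) fail("em_tol must be positive")
  em_max_iter <- as.integer(em_max_iter)
  if (is.na(em_max_iter) || em_max_iter < 1L) fail("em_max_iter must be a positive integer")
  if (!is.numeric(cluster_cutoff) || cluster_cutoff < 0) {
    fail("cluster_cutoff must be non-negative")
  }
  structure(list(genes = genes, mapping = mapping, databases = databases,
                 selected_dbs = selected_dbs, min_db_count = min_db_count,
                 conserved_only = isTRUE(conserved_only),
                 p_threshold = p_threshold, use_adjusted = isTRUE(use_adjusted),
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 cluster_cutoff = cluster_cutoff, output_dir = output_dir),
            class = "mirem_config")
}

#' Read a key=value run configuration file
#'
#' Lines of the form `key=value`; `#` comments and blank lines are
#' ignored.  Database files are declared as `db.NAME=PATH` lines.
#' Recognized scalar keys match the [mirem_config()] arguments.  Values
#' supplied in `override` (e.g. parsed CLI flags) win over the file.
#'
#' @param path Path to the configuration file.
#' @param override Named list of values taking precedence.
#' @return A `mirem_config`.
#' @export
read_run_config <- function(path, override = list()) {
  if (!file.exists(path)) {
    mirem_stop(sprintf("config file not found: %s", path), "mirem_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) {
    mirem_stop("config lines must have the form key=value", "mirem_config_error")
  }
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))

  dbsel <- startsWith(keys, "db.")
  databases <- vals[dbsel]
  names(databases) <- substring(keys[dbsel], 4L)

  args <- as.list(vals[!dbsel])
  names(args) <- keys[!dbsel]
  if (length(databases)) args$databases <- databases
  for (k in c("min_db_count", "em_max_iter")) {
    if (!is.null(args[[k]]) && is.character(args[[k]])) args[[k]] <- as.integer(args[[k]])
  }
  for (k in c("p_threshold", "em_tol", "cluster_cutoff")) {
    if (!is.null(args[[k]]) && is.character(args[[k]])) args[[k]] <- as.numeric(args[[k]])
  }
  for (k in c("conserved_only", "use_adjusted")) {
    if (!is.null(args[[k]]) && is.character(args[[k]])) {
      args[[k]] <- toupper(args[[k]]) %in% c("TRUE", "T", "1", "YES")
    }
  }
  if (!is.null(args$selected_dbs) && is.character(args$selected_dbs) &&
      length(args$selected_dbs) == 1L) {
    args$selected_dbs <- strsplit(args$selected_dbs, ",", fixed = TRUE)[[1L]]
  }
  for (k in names(override)) args[[k]] <- override[[k]]
  unknown <- setdiff(names(args), names(formals(mirem_config)))
  if (length(unknown)) {
    mirem_stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
               "mirem_config_error")
  }
  do.call(mirem_config, args)
}

# Binary heatmap matrix: rows = reported miRNAs in rank order, columns =
# the input genes they target, ordered by first-targeting miRNA then ID.
build_heatmap <- function(mirnas_ordered, genes_pool, interactions) {
  ints <- interactions[interactions$mirna_id %in% mirnas_ordered &
                         interactions$gene_id %in% genes_pool, , drop = FALSE]
  genes <- sort(unique(ints$gene_id))
  H <- matrix(0L, nrow = length(mirnas_ordered), ncol = length(genes),
              dimnames = list(mirnas_ordered, genes))
  if (nrow(ints)) {
    H[cbind(match(ints$mirna_id, mirnas_ordered), match(ints$gene_id, genes))] <- 1L
    first_m <- apply(H, 2L, function(col) which(col == 1L)[1L])
    H <- H[, order(first_m, colnames(H)), drop = FALSE]
  }
  H
}

#' Run the full miRNA prioritization pipeline
#'
#' Executes the workflow end to end: identifier normalization, view
#' construction, hypergeometric filtering with BH correction, the EM
#' re-scoring (skipped, by design, when exactly one miRNA survives the
#' filter — that lone miRNA is reported as is, flagged `HP_ONLY`), seed
#' clustering of the reported miRNAs, and assembly of all report
#' artifacts.  The pipeline proper uses no random numbers, so identical
#' inputs give identical reports.
#'
#' @param config A `mirem_config`.
#' @return An object of class `mirem_report` with elements `results`
#'   (ranked table), `enrichment` (all tested miRNAs), `candidates`,
#'   `em` (`NULL` when EM was skipped), `clusters`, `heatmap`,
#'   `scatter`, `metadata` (stage counts and config echo) and `status`
#'   (`"ok"`, `"single_hit"` or `"no_candidates"`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "mirem_config")) {
    mirem_stop("config must be created by mirem_config()", "mirem_config_error")
  }
  for (p in c(config$genes, config$mapping, unname(config$databases))) {
    if (!file.exists(p)) {
      mirem_stop(sprintf("input file not found: %s", p), "mirem_io_error")
    }
  }
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  mapping <- load_mapping(config$mapping)
  gene_set <- normalize_gene_list(readLines(config$genes, warn = FALSE), mapping)
  compendium <- withCallingHandlers(
    load_compendium(config$databases, mapping = mapping), warning = note)
  view <- build_view(compendium, config$selected_dbs, config$min_db_count,
                     config$conserved_only)
  candidates <- withCallingHandlers(
    select_candidates(view, gene_set, config$p_threshold, config$use_adjusted),
    warning = note)

  empty_results <- data.frame(mirna_id = character(0), em_score = numeric(0),
                              em_rank = integer(0), p_raw = numeric(0),
                              p_adj = numeric(0), n_overlap = integer(0),
                              n_targets = integer(0), seed = character(0),
                              cluster_id = integer(0), flag = character(0),
                              stringsAsFactors = FALSE)
  em <- NULL
  problem <- NULL
  clusters <- NULL
  heatmap <- NULL
  scatter <- NULL

  if (length(candidates$selected) == 0L) {
    status <- "no_candidates"
    results <- empty_results
  } else if (candidates$single_hit) {
    status <- "single_hit"
    results <- candidates$results[candidates$results$mirna_id == candidates$selected, ,
                                  drop = FALSE]
    results$em_score <- NA_real_
    results$em_rank <- 1L
    results$flag <- "HP_ONLY"
    results <- results[, c("mirna_id", "em_score", "em_rank", "p_raw", "p_adj",
                           "n_overlap", "n_targets", "flag")]
    rownames(results) <- NULL
  } else {
    status <- "ok"
    problem <- build_problem(candidates, view, gene_set)
    em <- withCallingHandlers(run_em(problem, config$em_tol, config$em_max_iter),
                              warning = note)
    results <- rank_mirnas(em, candidates)
    results$flag <- "EM"
  }

  if (nrow(results) > 0L) {
    recs <- view$mirnas[view$mirnas$mirna_id %in% results$mirna_id, , drop = FALSE]
    clusters <- cluster_seeds(recs, config$cluster_cutoff)
    results$seed <- recs$seed[match(results$mirna_id, recs$mirna_id)]
    results$cluster_id <-
      clusters$assignments$cluster_id[match(results$mirna_id,
                                            clusters$assignments$mirna_id)]
    results <- results[, c("mirna_id", "em_score", "em_rank", "p_raw", "p_adj",
                           "n_overlap", "n_targets", "seed", "cluster_id", "flag")]
    heatmap <- build_heatmap(results$mirna_id, candidates$genes_in_universe,
                             view$interactions)
    scatter <- data.frame(mirna_id = results$mirna_id,
                          minus_log10_p_adj = -log10(results$p_adj),
                          em_score = results$em_score,
                          stringsAsFactors = FALSE)
  }

  metadata <- list(
    status = status,
    n_input = gene_set$n_input,
    n_mapped = length(gene_set$genes),
    n_unmapped = gene_set$n_unmapped,
    n_duplicates = gene_set$n_duplicates,
    n_in_universe = length(candidates$genes_in_universe),
    n_universe = length(view$universe),
    n_candidate_mirnas = length(view$candidate_mirnas),
    n_tested_mirnas = nrow(candidates$results),
    n_selected_mirnas = length(candidates$selected),
    n_in_em = if (is.null(problem)) 0L else nrow(problem$Y),
    n_excluded_from_em = if (is.null(problem)) 0L else length(problem$excluded_genes),
    em_iterations = if (is.null(em)) NA_integer_ else em$n_iterations,
    em_converged = if (is.null(em)) NA else em$converged,
    warnings = warnings_seen,
    config = config)

  structure(list(results = results, enrichment = candidates$results,
                 candidates = candidates, em = em, problem = problem,
                 clusters = clusters, heatmap = heatmap, scatter = scatter,
                 metadata = metadata, status = status),
            class = "mirem_report")
}

#' @export
print.mirem_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("mirem report (status: %s)\n", x$status))
  cat(sprintf("  genes: %d input -> %d mapped -> %d in universe -> %d in EM\n",
              md$n_input, md$n_mapped, md$n_in_universe, md$n_in_em))
  cat(sprintf("  miRNAs: %d candidates -> %d tested -> %d selected\n",
              md$n_candidate_mirnas, md$n_tested_mirnas, md$n_selected_mirnas))
  if (nrow(x$results)) {
    cat("  top predictions:\n")
    top <- utils::head(x$results, 5L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %d. %s  em_score=%s  p_adj=%.3g  (%s)\n",
                  top$em_rank[i], top$mirna_id[i],
                  ifelse(is.na(top$em_score[i]), "NA",
                         sprintf("%.4f", top$em_score[i])),
                  top$p_adj[i], top$flag[i]))
    }
  }
  invisible(x)
}

# Fixed scientific formatting (6 significant digits) used in the TSVs.
fmt_p <- function(p) sprintf("%.5e", p)

#' Write all report artifacts to a directory
#'
#' Emits `results.tsv`, `enrichment.tsv`, `heatmap.tsv` (miRNAs as
#' rows, genes as 0/1 columns), `scatter.tsv`, `seeds.nwk` (Newick
#' dendrogram), `clusters.tsv` and `run_metadata.txt` (key=value).
#' Every TSV carries a single header row.  Output is deterministic:
#' reruns on identical inputs produce byte-identical files (the
#' metadata records counts and configuration, never timestamps).  When
#' the run selected no candidates, only `enrichment.tsv` and
#' `run_metadata.txt` are written.
#'
#' @param report A `mirem_report`.
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_outputs <- function(report, output_dir) {
  if (!inherits(report, "mirem_report")) {
    mirem_stop("report must be a mirem_report", "mirem_validation_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(output_dir, mode = 2L) != 0L) {
    mirem_stop(sprintf("output directory is not writable: %s", output_dir),
               "mirem_io_error")
  }
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  enr <- report$enrichment
  enr$p_raw <- fmt_p(enr$p_raw)
  enr$p_adj <- fmt_p(enr$p_adj)
  add(write_tsv(enr[, c("mirna_id", "n_targets", "n_overlap", "n_set",
                        "n_universe", "p_raw", "p_adj")],
                file.path(output_dir, "enrichment.tsv")))

  if (nrow(report$results) > 0L) {
    res <- report$results
    res$em_score <- ifelse(is.na(res$em_score), "", sprintf("%.6f", res$em_score))
    res$p_raw <- fmt_p(res$p_raw)
    res$p_adj <- fmt_p(res$p_adj)
    add(write_tsv(res, file.path(output_dir, "results.tsv")))

    H <- report$heatmap
    hdf <- data.frame(mirna_id = rownames(H), H, check.names = FALSE,
                      stringsAsFactors = FALSE)
    add(write_tsv(hdf, file.path(output_dir, "heatmap.tsv")))

    sc <- report$scatter
    sc$minus_log10_p_adj <- sprintf("%.6f", sc$minus_log10_p_adj)
    sc$em_score <- ifelse(is.na(sc$em_score), "", sprintf("%.6f", sc$em_score))
    add(write_tsv(sc, file.path(output_dir, "scatter.tsv")))

    nwk <- file.path(output_dir, "seeds.nwk")
    writeLines(report$clusters$newick, nwk)
    add(nwk)

    cl <- merge(report$clusters$assignments,
                report$clusters$clusters[, c("cluster_id", "representative_seed",
                                             "is_duplicate_group")],
                by = "cluster_id", sort = FALSE)
    cl <- cl[order(cl$cluster_id, cl$mirna_id),
             c("cluster_id", "mirna_id", "seed", "representative_seed",
               "is_duplicate_group")]
    add(write_tsv(cl, file.path(output_dir, "clusters.tsv")))
  }

  md <- report$metadata
  cfg <- md$config
  kv <- c(
    sprintf("status=%s", md$status),
    sprintf("n_input=%d", md$n_input),
    sprintf("n_mapped=%d", md$n_mapped),
    sprintf("n_unmapped=%d", md$n_unmapped),
    sprintf("n_duplicates=%d", md$n_duplicates),
    sprintf("n_in_universe=%d", md$n_in_universe),
    sprintf("n_universe=%d", md$n_universe),
    sprintf("n_candidate_mirnas=%d", md$n_candidate_mirnas),
    sprintf("n_tested_mirnas=%d", md$n_tested_mirnas),
    sprintf("n_selected_mirnas=%d", md$n_selected_mirnas),
    sprintf("n_in_em=%d", md$n_in_em),
    sprintf("n_excluded_from_em=%d", md$n_excluded_from_em),
    sprintf("em_iterations=%s", md$em_iterations),
    sprintf("em_converged=%s", md$em_converged),
    sprintf("config.genes=%s", cfg$genes),
    sprintf("config.mapping=%s", cfg$mapping),
    sprintf("config.db.%s=%s", names(cfg$databases), unname(cfg$databases)),
    sprintf("config.selected_dbs=%s", paste(cfg$selected_dbs, collapse = ",")),
    sprintf("config.min_db_count=%d", cfg$min_db_count),
    sprintf("config.conserved_only=%s", cfg$conserved_only),
    sprintf("config.p_threshold=%g", cfg$p_threshold),
    sprintf("config.use_adjusted=%s", cfg$use_adjusted),
    sprintf("config.em_tol=%g", cfg$em_tol),
    sprintf("config.em_max_iter=%d", cfg$em_max_iter),
    sprintf("config.cluster_cutoff=%g", cfg$cluster_cutoff))
  if (length(md$warnings)) {
    kv <- c(kv, sprintf("warning=%s", md$warnings))
  }
  meta_path <- file.path(output_dir, "run_metadata.txt")
  writeLines(kv, meta_path)
  add(meta_path)

  invisible(paths)
}
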