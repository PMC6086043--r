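test_that("simulation specs validate counts, probabilities and spikes", {
  expect_s3_class(sim_spec(), "mirem_sim_spec")
  expect_error(sim_spec(overlap_factor = 1.2), class = "mirem_validation_error")
  expect_error(sim_spec(n_mirnas = 0L), class = "mirem_validation_error")
  expect_error(sim_spec(spike_mirna = 99L), class = "mirem_validation_error")
  expect_error(sim_spec(n_spiked_targets = 50L, targets_per_mirna = 40L),
               class = "mirem_validation_error")
  expect_error(sim_spec(targets_per_mirna = c(30L, 10L)),
               class = "mirem_validation_error")
  expect_error(sim_spec(n_genes_universe = 30L, targets_per_mirna = 40L),
               class = "mirem_validation_error")
})

test_that("identical specs produce byte-identical fixture files", {
  spec <- small_sim_spec(20260903L)
  d1 <- tempfile("simA"); d2 <- tempfile("simB")
  t1 <- simulate_compendium(spec, d1)
  t2 <- simulate_compendium(spec, d2)
  simulate_spiked_gene_set(spec, t1)
  simulate_spiked_gene_set(spec, t2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # and a different seed changes the data
  t3 <- simulate_compendium(small_sim_spec(20260904L), tempfile("simC"))
  expect_false(identical(t1$target_sets, t3$target_sets))
})

test_that("overlap_factor = 0 yields pairwise disjoint target sets", {
  spec <- sim_spec(n_genes_universe = 500L, n_mirnas = 10L,
                   targets_per_mirna = 20L, overlap_factor = 0,
                   n_spiked_targets = 15L, rng_seed = 20260905L)
  truth <- simulate_compendium(spec, tempfile("disj"))
  all_targets <- unlist(truth$target_sets, use.names = FALSE)
  expect_equal(anyDuplicated(all_targets), 0L)
})

test_that("full database agreement makes union and intersection views equal", {
  spec <- sim_spec(n_genes_universe = 300L, n_mirnas = 8L,
                   targets_per_mirna = 15L, db_agreement = 1,
                   n_databases = 3L, n_spiked_targets = 10L,
                   rng_seed = 20260906L)
  truth <- simulate_compendium(spec, tempfile("agree"))
  comp <- load_compendium(truth$db_paths)
  v_union <- build_view(comp, min_db_count = 1L)
  v_inter <- build_view(comp, min_db_count = 3L)
  expect_identical(v_union$interactions, v_inter$interactions)
  # and the union equals the simulated truth exactly
  expect_equal(nrow(v_union$interactions), length(unlist(truth$target_sets)))
})

test_that("gene set composition honours the spike configuration", {
  spec <- small_sim_spec(20260907L)
  truth <- simulate_compendium(spec, tempfile("spike"))
  gs <- simulate_spiked_gene_set(spec, truth)
  spiked_targets <- truth$target_sets[[truth$spiked_mirna_ids]]
  expect_length(gs$spiked, 15L)
  expect_true(all(gs$spiked %in% spiked_targets))
  expect_length(gs$background, 10L)
  expect_false(any(gs$background %in% spiked_targets))
  expect_setequal(gs$genes, c(gs$spiked, gs$background))
  expect_identical(readLines(gs$path), gs$genes)

  # no background: gene set is a subset of the spiked miRNA's targets
  spec0 <- small_sim_spec(20260907L, n_background_genes = 0L)
  truth0 <- simulate_compendium(spec0, tempfile("spike0"))
  gs0 <- simulate_spiked_gene_set(spec0, truth0)
  expect_true(all(gs0$genes %in% truth0$target_sets[[truth0$spiked_mirna_ids]]))

  # double spike: provenance covers both miRNAs
  spec2 <- small_sim_spec(20260908L, spike_mirna = c(1L, 2L),
                          n_spiked_targets = 12L)
  truth2 <- simulate_compendium(spec2, tempfile("spike2"))
  gs2 <- simulate_spiked_gene_set(spec2, truth2)
  expect_length(truth2$spiked_mirna_ids, 2L)
  expect_true(any(gs2$spiked %in% truth2$target_sets[[truth2$spiked_mirna_ids[1L]]]))
  expect_true(any(gs2$spiked %in% truth2$target_sets[[truth2$spiked_mirna_ids[2L]]]))
})

test_that("a pure-noise gene set rarely yields a significant miRNA", {
  # negative control at reduced scale: no spiked targets, only background
  hits <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    spec <- sim_spec(n_genes_universe = 1000L, n_mirnas = 25L,
                     targets_per_mirna = 30L, overlap_factor = 0.2,
                     n_databases = 3L, db_agreement = 0.9,
                     spike_mirna = 1L, n_spiked_targets = 0L,
                     n_background_genes = 40L, rng_seed = 40000L + i)
    truth <- simulate_compendium(spec, tempfile("neg"))
    gs <- simulate_spiked_gene_set(spec, truth)
    mapping <- load_mapping(truth$mapping_path)
    gene_set <- normalize_gene_list(readLines(gs$path), mapping)
    comp <- load_compendium(truth$db_paths)
    view <- build_view(comp, min_db_count = 3L, conserved_only = TRUE)
    cand <- tryCatch(
      suppressWarnings(select_candidates(view, gene_set, threshold = 0.01)),
      mirem_empty_overlap_error = function(e) NULL)
    if (!is.null(cand) && min(cand$results$p_adj) <= 0.01) hits <- hits + 1L
  }
  # expect no significant miRNA in >= 90% of replicates
  expect_lte(hits, 3L)
})
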