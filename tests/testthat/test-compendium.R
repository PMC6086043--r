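test_that("database loading derives seeds, converts T to U, and dedups", {
  db <- write_db(db_row("hsa-miR-X", "UAGCUUAUCA", "TP53"))
  comp <- load_database(db, "dbA")
  expect_equal(comp$mirnas$seed, "AGCUUA")   # positions 2-7
  expect_equal(comp$mirnas$mature_sequence, "UAGCUUAUCA")

  # DNA-style input converts to RNA
  comp <- load_database(write_db(db_row("m1", "TAGCTTATCA", "G1")), "dbA")
  expect_equal(comp$mirnas$mature_sequence, "UAGCUUAUCA")

  # same row twice collapses to one interaction
  df <- rbind(db_row("m1", "UAGCUUAUCA", "G1"), db_row("m1", "UAGCUUAUCA", "G1"))
  comp <- load_database(write_db(df), "dbA")
  expect_equal(nrow(comp$interactions), 1L)

  # short sequence and bad characters are rejected with line numbers
  err <- expect_error(load_database(write_db(db_row("m1", "UAGCUU", "G1")), "dbA"),
                      class = "mirem_validation_error")
  expect_match(conditionMessage(err), "line 2")   # line 1 is the header
  expect_error(load_database(write_db(db_row("m1", "UAGCNNAUCA", "G1")), "dbA"),
               class = "mirem_parse_error")

  # conflicting mature sequences for one miRNA ID are fatal
  df <- rbind(db_row("m1", "UAGCUUAUCA", "G1"), db_row("m1", "GGGCUUAUCA", "G2"))
  expect_error(load_database(write_db(df), "dbA"),
               class = "mirem_validation_error")
})

test_that("gene IDs are canonicalized through the mapping when supplied", {
  mapping <- tp53_mapping()
  df <- rbind(db_row("m1", "UAGCUUAUCA", "NM_000546.3"),
              db_row("m1", "UAGCUUAUCA", "unknowngene"))
  expect_warning(comp <- load_database(write_db(df), "dbA", mapping = mapping),
                 "unmappable")
  expect_equal(comp$interactions$gene_id, "TP53")
})

test_that("view selection implements union and intersection-of-k voting", {
  seqA <- "UAGCUUAUCA"
  dbA <- write_db(rbind(db_row("m1", seqA, c("G1", "G2")),
                        db_row("m2", "UCCCUGAGAC", "G3")))
  dbB <- write_db(rbind(db_row("m1", seqA, c("G1", "G4")),
                        db_row("m2", "UCCCUGAGAC", "G3")))
  dbC <- write_db(db_row("m1", seqA, "G5"))
  comp <- load_compendium(c(A = dbA, B = dbB, C = dbC))

  # union: all distinct pairs, computed independently by brute force
  union_view <- build_view(comp, min_db_count = 1L)
  expected_pairs <- unique(comp$interactions[, c("mirna_id", "gene_id")])
  expect_equal(nrow(union_view$interactions), nrow(expected_pairs))

  # pair in {A,B} survives min_db_count = 2; pair only in A does not
  v2 <- build_view(comp, min_db_count = 2L)
  keys <- paste(v2$interactions$mirna_id, v2$interactions$gene_id)
  expect_true("m1 G1" %in% keys)
  expect_true("m2 G3" %in% keys)
  expect_false("m1 G2" %in% keys)
  expect_false("m1 G5" %in% keys)

  # universe is exactly the surviving genes
  expect_equal(v2$universe, sort(unique(v2$interactions$gene_id)))

  expect_error(build_view(comp, selected_dbs = c("A", "B"), min_db_count = 3L),
               class = "mirem_validation_error")
  expect_error(build_view(comp, selected_dbs = "nope"),
               class = "mirem_validation_error")
})

test_that("conserved-only filtering prunes only annotated databases", {
  # dbA annotates conservation; dbB reports all rows conserved
  dbA <- write_db(rbind(db_row("m1", "UAGCUUAUCA", "G1", conserved = 0L),
                        db_row("m1", "UAGCUUAUCA", "G2", conserved = 1L)))
  dbB <- write_db(db_row("m2", "UCCCUGAGAC", c("G1", "G3"), conserved = 1L))
  comp <- load_compendium(c(A = dbA, B = dbB))

  all_view <- build_view(comp)
  cons_view <- build_view(comp, conserved_only = TRUE)
  keys_all <- paste(all_view$interactions$mirna_id, all_view$interactions$gene_id)
  keys_cons <- paste(cons_view$interactions$mirna_id, cons_view$interactions$gene_id)
  expect_true(all(keys_cons %in% keys_all))          # subset relation
  expect_false("m1 G1" %in% keys_cons)               # non-conserved pruned
  expect_true(all(c("m1 G2", "m2 G1", "m2 G3") %in% keys_cons))
})

test_that("views are monotone in min_db_count and independent of load order", {
  set.seed(11)
  for (rep in 1:5) {
    genes <- sprintf("G%02d", 1:30)
    dbs <- lapply(1:3, function(d) {
      rows <- do.call(rbind, lapply(1:6, function(k) {
        db_row(sprintf("m%d", k), seq_for_seed("AACCGG"),
               sample(genes, sample(3:10, 1L)))
      }))
      write_db(rows)
    })
    comp <- load_compendium(c(A = dbs[[1]], B = dbs[[2]], C = dbs[[3]]))
    prev <- NULL
    for (k in 1:3) {
      v <- build_view(comp, min_db_count = k)
      keys <- paste(v$interactions$mirna_id, v$interactions$gene_id)
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
    # load order must not matter
    comp_rev <- load_compendium(c(C = dbs[[3]], A = dbs[[1]], B = dbs[[2]]))
    v1 <- build_view(comp, min_db_count = 2L)
    v2 <- build_view(comp_rev, min_db_count = 2L)
    expect_identical(v1$interactions, v2$interactions)
    expect_identical(v1$universe, v2$universe)
  }
})
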