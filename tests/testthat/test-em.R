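toy_Y <- function() {
  matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L), 4L, 2L,
         dimnames = list(paste0("g", 1:4), c("mirA", "mirB")))
}

test_that("the EM problem is built from candidates, view and gene set", {
  view <- toy_view(list(mirA = c("g1", "g2", "g3"), mirB = c("g3", "g4"),
                        mirC = c("x1", "x2")))
  gs <- toy_geneset(c("g1", "g2", "g3", "g4", "g5"))   # g5 not in universe
  cand <- select_candidates(view, gs, threshold = 1, use_adjusted = FALSE)
  pr <- build_problem(cand, view, gs)
  expect_setequal(pr$mirnas, c("mirA", "mirB"))
  expect_equal(dim(pr$Y), c(4L, 2L))
  expect_equal(unname(rowSums(pr$Y[, order(pr$mirnas)])), c(1, 1, 2, 1))
  expect_equal(pr$excluded_genes, character(0))

  # a gene targeted by no candidate moves to excluded_genes
  view2 <- toy_view(list(mirA = c("g1", "g2", "g3"), mirB = c("g3", "g4"),
                         mirC = c("g5", "x1", "x2", "x3", "x4", "x5")))
  gs2 <- toy_geneset(c("g1", "g2", "g3", "g4", "g5"))
  cand2 <- select_candidates(view2, gs2, threshold = 0.9, use_adjusted = FALSE)
  expect_setequal(cand2$selected, c("mirA", "mirB"))
  pr2 <- build_problem(cand2, view2, gs2)
  expect_equal(pr2$excluded_genes, "G5")
  expect_equal(nrow(pr2$Y), 4L)

  # fewer than two candidates signals the single-hit short-circuit
  cand$selected <- "mirA"
  expect_error(build_problem(cand, view, gs), class = "mirem_single_hit")
})

test_that("initialization is uniform and E/M steps follow the update equations", {
  pr <- make_problem(toy_Y())
  st <- em_initialize(pr)
  expect_equal(unname(st$p_hat), c(0.5, 0.5))
  expect_equal(st$iteration, 0L)
  expect_equal(unname(em_initialize(make_problem(matrix(1L, 3, 5)))$p_hat),
               rep(0.2, 5L))

  # E-step: gene with support {A,B} at p = (0.3, 0.1) splits 0.75 / 0.25
  st$p_hat <- c(mirA = 0.3, mirB = 0.1)
  st <- em_e_step(st, pr)
  expect_equal(unname(st$z_hat[3L, ]), c(0.75, 0.25))
  # single-support genes get membership 1 regardless of p
  expect_equal(unname(st$z_hat[1L, ]), c(1, 0))
  expect_equal(unname(st$z_hat[4L, ]), c(0, 1))
  # uniform p over shared support splits evenly
  st2 <- em_initialize(pr)
  st2 <- em_e_step(st2, pr)
  expect_equal(unname(st2$z_hat[3L, ]), c(0.5, 0.5))

  # M-step: column means of z_hat
  st3 <- em_initialize(pr)
  st3$z_hat <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5), c(0, 1))
  st3 <- em_m_step(st3, pr)
  expect_equal(unname(st3$p_hat), c(0.625, 0.375))
  expect_equal(st3$iteration, 1L)

  # degenerate all-in-one assignment
  st4 <- em_initialize(pr)
  st4$z_hat <- cbind(rep(1, 4), rep(0, 4))
  expect_equal(unname(em_m_step(st4, pr)$p_hat), c(1, 0))
})

test_that("EM converges to the hand-solved fixed point on the toy problem", {
  # shared-gene membership x solves x = (2 + x)/4  =>  p = (2/3, 1/3)
  res <- run_em(make_problem(toy_Y()), tol = 1e-9, max_iter = 10000L)
  expect_true(res$converged)
  expect_equal(unname(res$em_scores), c(2 / 3, 1 / 3), tolerance = 1e-6)
  expect_equal(unname(res$ranks), c(1L, 2L))
  expect_equal(sum(res$em_scores), 1, tolerance = 1e-9)
})

test_that("disjoint supports converge after one M-step; symmetry is preserved", {
  # counts (3, 1) over N = 4: the fully observed estimator
  Y <- matrix(0L, 4L, 2L); Y[1:3, 1L] <- 1L; Y[4L, 2L] <- 1L
  res <- run_em(make_problem(Y), tol = 1e-9)
  expect_equal(unname(res$em_scores), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(res$n_iterations, 2L)   # second iteration only certifies delta = 0

  # every gene targeted by both miRNAs: uniform start is the fixed point
  res <- run_em(make_problem(matrix(1L, 5L, 2L)), tol = 1e-9)
  expect_equal(unname(res$em_scores), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("log-likelihood ascends and estimates stay normalized", {
  set.seed(404)
  for (i in 1:25) {
    pr <- rand_problem(sample(5:40, 1L), sample(2:8, 1L))
    res <- run_em(pr, tol = 1e-8, max_iter = 2000L)
    expect_true(all(diff(res$trace$loglik) >= -1e-10))
    expect_equal(sum(res$em_scores), 1, tolerance = 1e-9)
    Z <- res$final_state$z_hat
    expect_equal(unname(rowSums(Z)), rep(1, nrow(Z)), tolerance = 1e-12)
    expect_true(all(Z[pr$Y == 0L] == 0))     # structural zeros preserved
    expect_true(all(Z >= 0 & Z <= 1))
  }
})

test_that("EM output is equivariant under row and column permutations", {
  set.seed(505)
  pr <- rand_problem(12L, 4L)
  res <- run_em(pr, tol = 1e-10, max_iter = 5000L)
  rperm <- sample(nrow(pr$Y))
  cperm <- sample(ncol(pr$Y))
  pr2 <- make_problem(pr$Y[rperm, cperm])
  res2 <- run_em(pr2, tol = 1e-10, max_iter = 5000L)
  expect_equal(res2$em_scores, res$em_scores[cperm], tolerance = 1e-8)
})

test_that("a miRNA with a strict subset of another's targets never outscores it", {
  # constructed instances: B's support is contained in A's
  set.seed(606)
  for (i in 1:10) {
    N <- sample(6:20, 1L)
    K <- 3L
    Y <- matrix(rbinom(N * K, 1L, 0.5), N, K)
    for (r in which(rowSums(Y) == 0L)) Y[r, sample.int(K, 1L)] <- 1L
    Y[, 1L] <- pmax(Y[, 1L], Y[, 2L])   # col 2 subset of col 1
    if (any(colSums(Y) == 0L)) next
    res <- run_em(make_problem(Y), tol = 1e-10, max_iter = 5000L)
    expect_lte(res$em_scores[2L], res$em_scores[1L] + 1e-9)
  }
})

test_that("ranked reports order by score, then adjusted p, then ID", {
  cand <- structure(list(results = data.frame(
    mirna_id = c("A", "B", "C"),
    n_targets = c(10L, 10L, 10L), n_overlap = c(5L, 5L, 4L),
    n_set = 8L, n_universe = 50L,
    p_raw = c(0.01, 0.001, 0.02), p_adj = c(0.01, 0.001, 0.02),
    stringsAsFactors = FALSE)), class = "mirem_candidates")
  res <- structure(list(em_scores = c(A = 0.5, B = 0.5, C = 0.0)),
                   class = "mirem_em_result")
  rk <- rank_mirnas(res, cand)
  expect_equal(rk$mirna_id, c("B", "A", "C"))   # tie broken by p_adj
  expect_equal(rk$em_rank, c(1L, 1L, 2L))       # dense ranks on the score
})

test_that("non-convergence warns and returns the last iterate", {
  expect_warning(res <- run_em(make_problem(toy_Y()), tol = 1e-12, max_iter = 3L),
                 "did not converge")
  expect_false(res$converged)
  expect_equal(res$n_iterations, 3L)
})
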