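#' Assemble the EM problem from the selected candidates
#'
#' Restricts the observed prediction matrix `Y` to the input genes that
#' fall in the view universe (rows) and the selected candidate miRNAs
#' (columns).  Genes targeted by no selected miRNA cannot be attributed
#' to any candidate — their E-step denominator would be undefined — so
#' they are moved to `excluded_genes` and do not count towards `N`;
#' this is what makes the estimated proportions sum exactly to one.
#'
#' @param candidates A `mirem_candidates` with at least two selected
#'   miRNAs (a single survivor short-circuits before EM).
#' @param view The `mirem_view` the candidates were computed from.
#' @param gene_set The normalized input `mirem_geneset`.
#' @return An object of class `mirem_em_problem`: `genes` (size `N`),
#'   `mirnas` (size `K`), binary incidence matrix `Y` (`N x K`, every
#'   row and column non-zero), `excluded_genes`.
#' @export
build_problem <- function(candidates, view, gene_set) {
  sel <- candidates$selected
  if (length(sel) < 2L) {
    mirem_stop("fewer than two selected miRNAs: single-hit short-circuit, EM not applicable",
               "mirem_single_hit")
  }
  genes_in <- candidates$genes_in_universe
  ints <- view$interactions
  ints <- ints[ints$mirna_id %in% sel & ints$gene_id %in% genes_in, , drop = FALSE]
  Y <- matrix(0L, nrow = length(genes_in), ncol = length(sel),
              dimnames = list(genes_in, sel))
  Y[cbind(match(ints$gene_id, genes_in), match(ints$mirna_id, sel))] <- 1L
  covered <- rowSums(Y) > 0L
  excluded <- genes_in[!covered]
  Y <- Y[covered, , drop = FALSE]
  if (nrow(Y) == 0L) {
    mirem_stop("no input genes are targeted by any selected miRNA",
               "mirem_validation_error")
  }
  empty_cols <- colSums(Y) == 0L
  if (any(empty_cols)) {
    # cannot happen when candidates carry n_overlap >= 1; guarded anyway
    warning(sprintf("dropping %d selected miRNAs with no targets among the input genes",
                    sum(empty_cols)), call. = FALSE)
    Y <- Y[, !empty_cols, drop = FALSE]
    if (ncol(Y) < 2L) {
      mirem_stop("fewer than two miRNAs remain after dropping empty columns",
                 "mirem_single_hit")
    }
  }
  structure(list(genes = rownames(Y), mirnas = colnames(Y), Y = Y,
                 excluded_genes = excluded),
            class = "mirem_em_problem")
}

# Observed-data log-likelihood sum_i log(sum_k y_ik * p_k).
em_loglik <- function(p, Y) {
  sum(log(as.vector(Y %*% p)))
}

#' Initialize the EM state
#'
#' Uniform start `p_k = 1/K`: deterministic and data-independent, so
#' the whole pipeline is free of random numbers.
#'
#' @param problem A `mirem_em_problem`.
#' @return A `mirem_em_state` with `p_hat` uniform, `iteration = 0`,
#'   `z_hat` unset, and the log-likelihood at the start point.
#' @export
em_initialize <- function(problem) {
  K <- ncol(problem$Y)
  p <- rep(1 / K, K)
  names(p) <- problem$mirnas
  structure(list(p_hat = p, z_hat = NULL, iteration = 0L,
                 loglik = em_loglik(p, problem$Y),
                 converged = FALSE, delta = NA_real_),
            class = "mirem_em_state")
}

#' E-step: posterior membership of each gene across its miRNAs
#'
#' Sets `z_ik = y_ik * p_k / sum_k y_ik * p_k`: each gene is split
#' among the miRNAs predicted to target it, in proportion to the
#' current estimates.  Structural zeros are preserved (`z_ik = 0`
#' wherever `y_ik = 0`).  If a row's denominator underflows to zero
#' (every supported `p_k` exactly 0), membership falls back to uniform
#' over the row's support so the row stays stochastic.
#'
#' @param state A `mirem_em_state`.
#' @param problem The `mirem_em_problem`.
#' @return The state with `z_hat` updated; each row sums to 1.
#' @export
em_e_step <- function(state, problem) {
  Y <- problem$Y
  W <- Y * rep(state$p_hat, each = nrow(Y))
  denom <- rowSums(W)
  zero <- denom == 0
  if (any(zero)) {
    W[zero, ] <- Y[zero, , drop = FALSE]
    denom[zero] <- rowSums(Y[zero, , drop = FALSE])
  }
  state$z_hat <- W / denom
  state
}

#' M-step: re-estimate the repression proportions
#'
#' `p_k = (sum_i z_ik) / N` — the soft count of genes attributed to
#' miRNA `k`, averaged over the `N` covered genes.  Also advances the
#' iteration counter and records `delta`, the max-norm change in
#' `p_hat`, and the observed-data log-likelihood at the new estimate.
#'
#' @inheritParams em_e_step
#' @return The updated state; `sum(p_hat) == 1` up to rounding.
#' @export
em_m_step <- function(state, problem) {
  p_new <- colSums(state$z_hat) / nrow(problem$Y)
  state$delta <- max(abs(p_new - state$p_hat))
  state$p_hat <- p_new
  state$iteration <- state$iteration + 1L
  state$loglik <- em_loglik(p_new, problem$Y)
  state
}

#' Run the EM algorithm to convergence
#'
#' Alternates [em_e_step()] and [em_m_step()] from the uniform start
#' until the max-norm change in `p_hat` falls below `tol` or `max_iter`
#' is reached.  Row-stochasticity of `z_hat` and the unit sum of
#' `p_hat` are asserted at every iteration.  The converged `p_hat` are
#' the EM scores used for prioritization: the estimated fraction of the
#' gene set attributable to each miRNA.
#'
#' @param problem A `mirem_em_problem` from [build_problem()].
#' @param tol Convergence tolerance on `max_k |p_k(m) - p_k(m-1)|`;
#'   default 0.001.
#' @param max_iter Iteration cap; hitting it yields `converged = FALSE`
#'   and a warning, never an error.
#' @return An object of class `mirem_em_result`: `em_scores` (named,
#'   summing to 1), `ranks` (dense, descending score), `n_iterations`,
#'   `converged`, a per-iteration `trace` of `(delta, loglik)`, and the
#'   `final_state` (including the soft assignment matrix `z_hat`).
#' @export
#' @examples
#' Y <- matrix(c(1, 1, 1, 0, 0, 0, 1, 1), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("mirA", "mirB")))
#' pr <- structure(list(genes = rownames(Y), mirnas = colnames(Y), Y = Y,
#'                      excluded_genes = character(0)),
#'                 class = "mirem_em_problem")
#' run_em(pr, tol = 1e-9)$em_scores   # converges to (2/3, 1/3)
run_em <- function(problem, tol = 0.001, max_iter = 1000L) {
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    mirem_stop("tol must be a single positive number", "mirem_validation_error")
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) {
    mirem_stop("max_iter must be a positive integer", "mirem_validation_error")
  }
  state <- em_initialize(problem)
  deltas <- numeric(0)
  logliks <- numeric(0)
  repeat {
    state <- em_m_step(em_e_step(state, problem), problem)
    stopifnot(abs(sum(state$p_hat) - 1) < 1e-9,
              max(abs(rowSums(state$z_hat) - 1)) < 1e-12)
    deltas[state$iteration] <- state$delta
    logliks[state$iteration] <- state$loglik
    if (state$delta < tol) {
      state$converged <- TRUE
      break
    }
    if (state$iteration >= max_iter) {
      warning(sprintf("EM did not converge within %d iterations (delta = %.3g)",
                      max_iter, state$delta), call. = FALSE)
      break
    }
  }
  scores <- state$p_hat
  ranks <- match(-scores, sort(unique(-scores)))   # dense rank, descending
  names(ranks) <- names(scores)
  structure(list(em_scores = scores,
                 ranks = ranks,
                 n_iterations = state$iteration,
                 converged = state$converged,
                 trace = data.frame(iteration = seq_along(deltas),
                                    delta = deltas, loglik = logliks),
                 final_state = state),
            class = "mirem_em_result")
}

#' @export
print.mirem_em_result <- function(x, ...) {
  cat(sprintf("mirem EM result: %d miRNAs, %d iterations, converged = %s\n",
              length(x$em_scores), x$n_iterations, x$converged))
  top <- sort(x$em_scores, decreasing = TRUE)
  show <- utils::head(top, 5L)
  cat(paste(sprintf("  %s: %.4f", names(show), show), collapse = "\n"), "\n")
  invisible(x)
}

#' Merge EM scores with enrichment statistics into a ranked report
#'
#' Rows are ordered by EM score descending, ties broken by adjusted
#' p-value ascending, then miRNA ID; `em_rank` is a dense rank on the
#' score alone (tied scores share a rank).
#'
#' @param result A `mirem_em_result`.
#' @param candidates The `mirem_candidates` the problem was built from;
#'   every scored miRNA must have an enrichment row.
#' @return A data frame with columns `mirna_id`, `em_score`, `em_rank`,
#'   `p_raw`, `p_adj`, `n_overlap`, `n_targets`.
#' @export
rank_mirnas <- function(result, candidates) {
  res <- candidates$results
  idx <- match(names(result$em_scores), res$mirna_id)
  if (anyNA(idx)) {
    mirem_stop("every EM-scored miRNA must have an enrichment result",
               "mirem_validation_error")
  }
  df <- res[idx, , drop = FALSE]
  df$em_score <- unname(result$em_scores)
  df <- df[order(-df$em_score, df$p_adj, df$mirna_id), , drop = FALSE]
  df$em_rank <- match(-df$em_score, sort(unique(-df$em_score)))
  rownames(df) <- NULL
  df[, c("mirna_id", "em_score", "em_rank", "p_raw", "p_adj",
         "n_overlap", "n_targets")]
}
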