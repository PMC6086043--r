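#' Upper-tail hypergeometric over-representation probability
#'
#' Probability of drawing at least `n_overlap` of a miRNA's
#' `n_targets` target genes in a sample of `n_set` genes taken without
#' replacement from a universe of `n_universe` genes, i.e. `P(X >=
#' n_overlap)` for `X ~ Hypergeometric(n_universe, n_targets, n_set)`.
#' Computed through the survival function of [stats::phyper()], which
#' works in log space and is numerically exact for the count ranges
#' arising here.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param n_universe Background universe size.
#' @param n_targets Number of the miRNA's targets inside the universe.
#' @param n_set Number of input genes inside the universe.
#' @param n_overlap Number of input genes targeted by the miRNA.
#' @return The upper-tail probability, in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5)   # 1/choose(10,5) = 1/252
hypergeom_pvalue <- function(n_universe, n_targets, n_set, n_overlap) {
  n <- max(length(n_universe), length(n_targets), length(n_set), length(n_overlap))
  n_universe <- rep_len(n_universe, n); n_targets <- rep_len(n_targets, n)
  n_set <- rep_len(n_set, n); n_overlap <- rep_len(n_overlap, n)
  for (arg in c("n_universe", "n_targets", "n_set", "n_overlap")) {
    v <- get(arg)
    if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
      mirem_stop(sprintf("%s must be a non-negative integer count", arg),
                 "mirem_validation_error")
    }
  }
  if (any(n_targets > n_universe)) {
    mirem_stop("n_targets exceeds n_universe", "mirem_validation_error")
  }
  if (any(n_set > n_universe)) {
    mirem_stop("n_set exceeds n_universe", "mirem_validation_error")
  }
  if (any(n_overlap > pmin(n_targets, n_set))) {
    mirem_stop("n_overlap exceeds min(n_targets, n_set)", "mirem_validation_error")
  }
  stats::phyper(n_overlap - 1, n_targets, n_universe - n_targets, n_set,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (sort ascending, multiply by
#' `m/i`, enforce monotonicity from the largest rank down, cap at 1),
#' returned in the input order.  Delegates to
#' [stats::p.adjust()]`(method = "BH")` after validating the input.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`; must be
#'   non-empty.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) {
    mirem_stop("p-value vector is empty", "mirem_validation_error")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    mirem_stop("p-values must lie in (0, 1]", "mirem_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric filtering of candidate miRNAs
#'
#' Tests every miRNA of the view that targets at least one input gene
#' for over-representation of its targets within the gene set, adjusts
#' across all tested miRNAs by Benjamini-Hochberg, and selects the
#' candidates whose (adjusted, by default) p-value falls strictly below
#' the threshold.  miRNAs with zero overlap can never be candidates and
#' are excluded from the test family.  Input genes absent from the view
#' universe are dropped from `n_set` (the hypergeometric draw must come
#' from the background population) and reported via `genes_in_universe`.
#'
#' @param view A `mirem_view` from [build_view()].
#' @param gene_set A `mirem_geneset` from [normalize_gene_list()].
#' @param threshold Significance cutoff on the (adjusted) p-value;
#'   strict inequality.  Default 0.01.
#' @param use_adjusted Filter on the BH-adjusted p-value (default) or,
#'   when `FALSE`, on the raw hypergeometric p-value.
#' @return An object of class `mirem_candidates`: `results` (one row
#'   per tested miRNA with `n_targets`, `n_overlap`, `n_set`,
#'   `n_universe`, `p_raw`, `p_adj`, sorted by `p_adj`), `selected`
#'   (the passing miRNA IDs), `threshold`, `use_adjusted`, `single_hit`
#'   (`TRUE` when exactly one miRNA passes, in which case the pipeline
#'   skips EM), and `genes_in_universe`.  Zero survivors yield an empty
#'   selection with a warning, not an error.
#' @export
select_candidates <- function(view, gene_set, threshold = 0.01,
                              use_adjusted = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    mirem_stop("threshold must be a single probability in (0, 1]",
               "mirem_validation_error")
  }
  genes_in <- gene_set$genes[gene_set$genes %in% view$universe]
  if (length(genes_in) == 0L) {
    mirem_stop("none of the input genes occur in the selected interaction universe",
               "mirem_empty_overlap_error")
  }
  n_universe <- length(view$universe)
  n_set <- length(genes_in)

  ints <- view$interactions
  fm <- factor(ints$mirna_id, levels = view$candidate_mirnas)
  n_targets <- tabulate(fm, nbins = nlevels(fm))
  n_overlap <- tabulate(fm[ints$gene_id %in% genes_in], nbins = nlevels(fm))

  tested <- n_overlap >= 1L
  ids <- view$candidate_mirnas[tested]
  p_raw <- hypergeom_pvalue(n_universe, n_targets[tested], n_set, n_overlap[tested])
  p_adj <- bh_adjust(p_raw)

  results <- data.frame(mirna_id = ids,
                        n_targets = n_targets[tested],
                        n_overlap = n_overlap[tested],
                        n_set = n_set,
                        n_universe = n_universe,
                        p_raw = p_raw,
                        p_adj = p_adj,
                        stringsAsFactors = FALSE)
  results <- results[order(results$p_adj, results$p_raw, results$mirna_id), ]
  rownames(results) <- NULL

  pass <- if (isTRUE(use_adjusted)) results$p_adj < threshold else results$p_raw < threshold
  selected <- results$mirna_id[pass]
  if (length(selected) == 0L) {
    warning("no miRNAs pass the significance threshold", call. = FALSE)
  }
  structure(list(results = results,
                 selected = selected,
                 threshold = threshold,
                 use_adjusted = isTRUE(use_adjusted),
                 single_hit = length(selected) == 1L,
                 genes_in_universe = genes_in),
            class = "mirem_candidates")
}

#' @export
print.mirem_candidates <- function(x, ...) {
  cat(sprintf("mirem candidates: %d miRNAs tested, %d selected at %s < %g%s\n",
              nrow(x$results), length(x$selected),
              if (x$use_adjusted) "p_adj" else "p_raw", x$threshold,
              if (x$single_hit) " (single hit: EM will be skipped)" else ""))
  invisible(x)
}
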