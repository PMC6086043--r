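check_seed <- function(seed, what = "seed") {
  if (!is.character(seed) || length(seed) != 1L || nchar(seed) != 6L) {
    mirem_stop(sprintf("%s must be a single 6-nt string", what),
               "mirem_validation_error")
  }
  if (grepl("[^ACGU]", seed)) {
    mirem_stop(sprintf("%s must use the RNA alphabet {A,C,G,U}", what),
               "mirem_validation_error")
  }
  invisible(seed)
}

#' Hamming distance between two miRNA seeds
#'
#' Seeds are fixed-length 6-mers (positions 2-7 of the mature
#' sequence), so the number of mismatching positions is a natural
#' distance: 0 for identical seeds, 6 for fully distinct ones.  It is a
#' metric on 6-mers.
#'
#' @param seed_a,seed_b 6-nt strings over `{A,C,G,U}`.
#' @return Integer in `[0, 6]`.
#' @export
seed_distance <- function(seed_a, seed_b) {
  check_seed(seed_a, "seed_a")
  check_seed(seed_b, "seed_b")
  sum(strsplit(seed_a, "")[[1L]] != strsplit(seed_b, "")[[1L]])
}

# Per-position majority consensus; positional ties resolved
# alphabetically so the representative is deterministic.
consensus_seed <- function(seeds) {
  M <- do.call(rbind, strsplit(seeds, ""))
  paste(apply(M, 2L, function(col) {
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1L]
  }), collapse = "")
}

#' Cluster predicted miRNAs by seed similarity
#'
#' Builds the pairwise Hamming distance matrix over the 6-nt seeds,
#' runs average-linkage (UPGMA) hierarchical clustering, and cuts the
#' tree at `linkage_cutoff`.  The default cutoff 0 groups exactly the
#' miRNAs with identical seeds — the duplicated predictions that tend
#' to be co-predicted because seed pairing drives targeting.  Input is
#' first sorted by miRNA ID so merge order, cluster numbering and the
#' dendrogram are deterministic.
#'
#' The dendrogram is serialized as Newick with ultrametric branch
#' lengths (merge height / 2 on each side of a merge).
#'
#' @param predictions Data frame with columns `mirna_id` and `seed`
#'   (e.g. the `mirnas` table of a `mirem_view`); at least one row,
#'   unique IDs.
#' @param linkage_cutoff Height at which the UPGMA tree is cut;
#'   default 0 (exact-seed duplicate groups).
#' @return An object of class `mirem_seed_clusters`: `assignments`
#'   (`mirna_id`, `seed`, `cluster_id`), `clusters` (`cluster_id`,
#'   `n_members`, `members` comma-joined, `representative_seed`,
#'   `is_duplicate_group` — `TRUE` only when at least two members share
#'   one identical seed string), the `distance` matrix, the `tree`
#'   (`phylo`, `NULL` for a single prediction) and its `newick` string.
#' @export
cluster_seeds <- function(predictions, linkage_cutoff = 0) {
  if (!is.data.frame(predictions) ||
      !all(c("mirna_id", "seed") %in% names(predictions)) ||
      nrow(predictions) < 1L) {
    mirem_stop("predictions must be a data frame with >= 1 row and columns mirna_id, seed",
               "mirem_validation_error")
  }
  if (anyDuplicated(predictions$mirna_id)) {
    mirem_stop("duplicate mirna_id in predictions", "mirem_validation_error")
  }
  if (!is.numeric(linkage_cutoff) || length(linkage_cutoff) != 1L ||
      !is.finite(linkage_cutoff) || linkage_cutoff < 0) {
    mirem_stop("linkage_cutoff must be a single non-negative number",
               "mirem_validation_error")
  }
  ord <- order(predictions$mirna_id)
  ids <- predictions$mirna_id[ord]
  seeds <- predictions$seed[ord]
  for (s in seeds) check_seed(s)
  n <- length(ids)

  if (n == 1L) {
    assignments <- data.frame(mirna_id = ids, seed = seeds, cluster_id = 1L,
                              stringsAsFactors = FALSE)
    clusters <- data.frame(cluster_id = 1L, n_members = 1L, members = ids,
                           representative_seed = seeds,
                           is_duplicate_group = FALSE, stringsAsFactors = FALSE)
    return(structure(list(assignments = assignments, clusters = clusters,
                          distance = matrix(0L, 1L, 1L, dimnames = list(ids, ids)),
                          tree = NULL, newick = paste0(ids, ";"),
                          linkage_cutoff = linkage_cutoff),
                     class = "mirem_seed_clusters"))
  }

  M <- do.call(rbind, strsplit(seeds, ""))
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  memb <- stats::cutree(hc, h = linkage_cutoff)
  memb <- match(memb, unique(memb))   # renumber by first appearance in ID order

  assignments <- data.frame(mirna_id = ids, seed = seeds, cluster_id = memb,
                            stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(seq_len(max(memb)), function(cid) {
    sel <- memb == cid
    cl_seeds <- seeds[sel]
    data.frame(cluster_id = cid,
               n_members = sum(sel),
               members = paste(ids[sel], collapse = ","),
               representative_seed = consensus_seed(cl_seeds),
               is_duplicate_group = sum(sel) >= 2L && anyDuplicated(cl_seeds) > 0L,
               stringsAsFactors = FALSE)
  }))

  phy <- ape::as.phylo(hc)   # edge lengths = merge heights / 2 (ultrametric)
  structure(list(assignments = assignments, clusters = clusters,
                 distance = D, tree = phy, newick = ape::write.tree(phy),
                 linkage_cutoff = linkage_cutoff),
            class = "mirem_seed_clusters")
}

#' @export
print.mirem_seed_clusters <- function(x, ...) {
  ndup <- sum(x$clusters$is_duplicate_group)
  cat(sprintf("mirem seed clusters: %d miRNAs in %d clusters at cutoff %g (%d duplicate group%s)\n",
              nrow(x$assignments), nrow(x$clusters), x$linkage_cutoff,
              ndup, if (ndup == 1L) "" else "s"))
  invisible(x)
}
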