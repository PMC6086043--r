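#' Load a gene identifier mapping table
#'
#' Reads a tab-delimited table with columns `source_id`, `namespace`
#' (`refseq`, `ensembl`, `ucsc` or `symbol`) and `canonical_id`, used to
#' unify the heterogeneous identifiers accepted in gene lists and
#' interaction tables onto one canonical gene key.  A local mapping file
#' plays the role that an Ensembl Biomart lookup would play in an
#' online deployment, keeping runs reproducible and offline.
#'
#' A header row is auto-detected: if the second field of the first row
#' is not a recognized namespace, the row is treated as a header and
#' skipped.  Rows that duplicate a `(source_id, namespace)` pair with
#' the same canonical target are collapsed; duplicates that disagree on
#' the canonical target raise a validation error naming the offending
#' source identifiers.
#'
#' @param path Path to the tab-delimited mapping file.
#' @return A data frame of class `mirem_mapping` with columns
#'   `source_id`, `source_namespace`, `canonical_id` (canonical IDs are
#'   upper-cased).  An empty file yields an empty table.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("NM_000546\trefseq\tTP53",
#'              "ENSG00000141510\tensembl\tTP53"), f)
#' load_mapping(f)
load_mapping <- function(path) {
  if (!file.exists(path)) {
    mirem_stop(sprintf("mapping file not found: %s", path), "mirem_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- structure(
    data.frame(source_id = character(0), source_namespace = character(0),
               canonical_id = character(0), stringsAsFactors = FALSE),
    class = c("mirem_mapping", "data.frame"))
  if (length(lines) == 0L) return(empty)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L)
  if (length(bad)) {
    mirem_stop(sprintf("mapping line %d: expected 3 tab-delimited fields, found %d",
                       lineno[bad[1L]], nf[bad[1L]]), "mirem_parse_error")
  }
  m <- matrix(trimws(unlist(fields)), ncol = 3L, byrow = TRUE)
  if (!tolower(m[1L, 2L]) %in% .mirem_namespaces) {   # header row
    m <- m[-1L, , drop = FALSE]
    lineno <- lineno[-1L]
  }
  if (nrow(m) == 0L) return(empty)

  ns <- tolower(m[, 2L])
  bad <- which(!ns %in% .mirem_namespaces)
  if (length(bad)) {
    mirem_stop(sprintf("mapping line %d: unknown namespace '%s'",
                       lineno[bad[1L]], m[bad[1L], 2L]), "mirem_parse_error")
  }
  src <- m[, 1L]
  canon <- toupper(m[, 3L])
  bad <- which(!nzchar(src) | !nzchar(canon))
  if (length(bad)) {
    mirem_stop(sprintf("mapping line %d: empty identifier field", lineno[bad[1L]]),
               "mirem_validation_error")
  }

  key <- paste(tolower(src), ns, sep = "\r")
  first <- match(key, key)
  conflict <- canon != canon[first]
  if (any(conflict)) {
    offenders <- unique(src[conflict | key %in% key[conflict]])
    mirem_stop(sprintf("conflicting canonical mappings for: %s",
                       paste(offenders, collapse = ", ")),
               "mirem_validation_error")
  }
  uniq <- !duplicated(key)
  structure(
    data.frame(source_id = src[uniq], source_namespace = ns[uniq],
               canonical_id = canon[uniq], stringsAsFactors = FALSE),
    class = c("mirem_mapping", "data.frame"))
}

# Strip trailing ".<digits>" version suffixes from RefSeq/Ensembl-style
# accessions (NM_/NR_/NP_/XM_/XR_/XP_/ENS*) before lookup.
strip_id_version <- function(ids) {
  versioned <- grepl("^([nx][mrp]_|ens)", tolower(ids)) & grepl("\\.[0-9]+$", ids)
  ids[versioned] <- sub("\\.[0-9]+$", "", ids[versioned])
  ids
}

# Map a character vector of raw identifiers to canonical IDs (NA where
# unmapped).  Namespaces are tried in priority order refseq > ensembl >
# ucsc > symbol, case-insensitively; identifiers that already equal a
# canonical ID map to themselves, which makes normalization idempotent.
canonicalize_ids <- function(ids, mapping) {
  lookup <- tolower(strip_id_version(ids))
  canon <- rep(NA_character_, length(ids))
  for (ns in .mirem_namespaces) {
    sub <- mapping$source_namespace == ns
    if (!any(sub)) next
    hit <- match(lookup, tolower(mapping$source_id[sub]))
    fill <- is.na(canon) & !is.na(hit)
    canon[fill] <- mapping$canonical_id[sub][hit[fill]]
  }
  ucanon <- unique(mapping$canonical_id)
  hit <- match(lookup, tolower(ucanon))
  fill <- is.na(canon) & !is.na(hit)
  canon[fill] <- ucanon[hit[fill]]
  canon
}

#' Normalize a raw gene list to canonical identifiers
#'
#' Strips blank and `#`-comment lines, removes version suffixes from
#' RefSeq/Ensembl-style accessions, matches every remaining identifier
#' case-insensitively against all namespaces of the mapping table
#' (priority `refseq > ensembl > ucsc > symbol`, then canonical IDs
#' themselves), and collapses duplicates while preserving first-seen
#' order.  Unmapped identifiers are counted and kept in the result for
#' reporting; they abort the run only when *no* identifier maps.
#'
#' @param raw_lines Character vector of raw input lines (one identifier
#'   per line).
#' @param mapping A `mirem_mapping` table from [load_mapping()].
#' @return An object of class `mirem_geneset`: a list with `genes`
#'   (canonical IDs, first-seen order, no duplicates), `n_input`,
#'   `n_unmapped`, `n_duplicates` and `unmapped` (the unrecognized raw
#'   identifiers).  Always `n_input == length(genes) + n_unmapped +
#'   n_duplicates`.
#' @export
normalize_gene_list <- function(raw_lines, mapping) {
  ids <- trimws(raw_lines)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0L) {
    mirem_stop("gene list is empty after removing blank and comment lines",
               "mirem_validation_error")
  }
  canon <- canonicalize_ids(ids, mapping)
  n_unmapped <- sum(is.na(canon))
  mapped <- canon[!is.na(canon)]
  genes <- unique(mapped)
  if (length(genes) == 0L) {
    mirem_stop("no genes recognized", "mirem_no_genes_error")
  }
  structure(list(genes = genes,
                 n_input = length(ids),
                 n_unmapped = n_unmapped,
                 n_duplicates = length(mapped) - length(genes),
                 unmapped = ids[is.na(canon)]),
            class = "mirem_geneset")
}

#' @export
print.mirem_geneset <- function(x, ...) {
  cat(sprintf("mirem gene set: %d canonical genes (%d input lines, %d unmapped, %d duplicates)\n",
              length(x$genes), x$n_input, x$n_unmapped, x$n_duplicates))
  invisible(x)
}
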