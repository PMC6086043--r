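#' Load one miRNA-target prediction database
#'
#' Reads a tab-delimited table with columns `mirna_id`,
#' `mature_sequence`, `gene_id`, `conserved` (0/1).  One file stands
#' for one prediction database (TargetScan-, miRanda-style, ...) under a
#' single generic schema.  A header row is auto-detected (fourth field
#' of the first row not `0`/`1`).  `T` bases are converted to `U`;
#' sequences must otherwise be RNA over `{A,C,G,U}` and at least 7 nt
#' long so that the seed (positions 2-7 of the mature sequence) is
#' defined.  Duplicate `(miRNA, gene)` rows collapse to one interaction
#' (conserved if any copy is); two different mature sequences for one
#' miRNA ID raise a validation error.
#'
#' Databases without a conservation annotation should simply carry 1 in
#' the `conserved` column; conserved-only filtering then prunes only the
#' databases that really annotate conservation.
#'
#' @param path Path to the TSV file.
#' @param db_name Name under which the database is registered.
#' @param mapping Optional `mirem_mapping`; when given, `gene_id`s are
#'   canonicalized through it and rows whose gene cannot be mapped are
#'   dropped with a warning.
#' @return An object of class `mirem_compendium` holding this single
#'   database; combine several with [load_compendium()].
#' @export
load_database <- function(path, db_name, mapping = NULL) {
  if (!file.exists(path)) {
    mirem_stop(sprintf("database file not found: %s", path), "mirem_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    mirem_stop(sprintf("database '%s' is empty: %s", db_name, path),
               "mirem_validation_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4L)
  if (length(bad)) {
    mirem_stop(sprintf("database '%s' line %d: expected 4 tab-delimited fields, found %d",
                       db_name, lineno[bad[1L]], nf[bad[1L]]), "mirem_parse_error")
  }
  m <- matrix(trimws(unlist(fields)), ncol = 4L, byrow = TRUE)
  if (!m[1L, 4L] %in% c("0", "1")) {    # header row
    m <- m[-1L, , drop = FALSE]
    lineno <- lineno[-1L]
  }
  if (nrow(m) == 0L) {
    mirem_stop(sprintf("database '%s' has a header but no data rows", db_name),
               "mirem_validation_error")
  }

  mirna <- m[, 1L]
  seqs <- chartr("T", "U", toupper(m[, 2L]))
  bad <- which(grepl("[^ACGU]", seqs))
  if (length(bad)) {
    mirem_stop(sprintf("database '%s' line %d: mature sequence contains characters outside {A,C,G,U,T}",
                       db_name, lineno[bad[1L]]), "mirem_parse_error")
  }
  bad <- which(nchar(seqs) < 7L)
  if (length(bad)) {
    mirem_stop(sprintf("database '%s' line %d: mature sequence shorter than 7 nt",
                       db_name, lineno[bad[1L]]), "mirem_validation_error")
  }
  bad <- which(!m[, 4L] %in% c("0", "1"))
  if (length(bad)) {
    mirem_stop(sprintf("database '%s' line %d: conserved flag must be 0 or 1",
                       db_name, lineno[bad[1L]]), "mirem_parse_error")
  }
  conserved <- as.integer(m[, 4L])

  gene <- toupper(m[, 3L])
  if (!is.null(mapping)) {
    canon <- canonicalize_ids(m[, 3L], mapping)
    drop <- is.na(canon)
    if (any(drop)) {
      warning(sprintf("database '%s': dropped %d rows with unmappable gene IDs",
                      db_name, sum(drop)), call. = FALSE)
      m <- m[!drop, , drop = FALSE]
      mirna <- mirna[!drop]; seqs <- seqs[!drop]; conserved <- conserved[!drop]
      canon <- canon[!drop]
    }
    if (length(canon) == 0L) {
      mirem_stop(sprintf("database '%s': no rows left after gene ID mapping", db_name),
                 "mirem_validation_error")
    }
    gene <- canon
  }

  # one mature sequence per miRNA ID
  useq <- !duplicated(mirna)
  seq_of <- seqs[useq]
  names(seq_of) <- mirna[useq]
  conflict <- seqs != seq_of[mirna]
  if (any(conflict)) {
    mirem_stop(sprintf("database '%s': conflicting mature sequences for %s",
                       db_name, paste(unique(mirna[conflict]), collapse = ", ")),
               "mirem_validation_error")
  }

  # collapse duplicate (miRNA, gene) rows; conserved if any copy is
  key <- paste(mirna, gene, sep = "\r")
  cons_pair <- tapply(conserved, key, max)
  uniq <- !duplicated(key)
  interactions <- data.frame(mirna_id = mirna[uniq],
                             gene_id = gene[uniq],
                             source_db = db_name,
                             conserved = as.integer(cons_pair[key[uniq]]),
                             stringsAsFactors = FALSE)
  interactions <- interactions[order(interactions$mirna_id, interactions$gene_id), ]
  rownames(interactions) <- NULL

  ids <- sort(unique(mirna))
  mseq <- unname(seq_of[ids])
  mirnas <- data.frame(mirna_id = ids,
                       mature_sequence = mseq,
                       seed = substr(mseq, 2L, 7L),
                       conserved = as.integer(tapply(conserved, mirna, max)[ids]),
                       stringsAsFactors = FALSE)
  rownames(mirnas) <- NULL

  structure(list(interactions = interactions, mirnas = mirnas, databases = db_name),
            class = "mirem_compendium")
}

#' Load and merge several prediction databases into one compendium
#'
#' @param db_paths Named character vector `c(name = path, ...)`; each
#'   file is read with [load_database()].
#' @param mapping Optional `mirem_mapping` passed through to the loaders.
#' @return A `mirem_compendium` covering all databases.  A miRNA ID
#'   carrying different mature sequences in different databases is a
#'   validation error.
#' @export
load_compendium <- function(db_paths, mapping = NULL) {
  if (length(db_paths) == 0L || is.null(names(db_paths)) ||
      any(!nzchar(names(db_paths)))) {
    mirem_stop("db_paths must be a non-empty named character vector (name = path)",
               "mirem_config_error")
  }
  if (anyDuplicated(names(db_paths))) {
    mirem_stop("duplicate database names in db_paths", "mirem_config_error")
  }
  parts <- lapply(names(db_paths), function(nm) {
    load_database(db_paths[[nm]], nm, mapping = mapping)
  })
  interactions <- do.call(rbind, lapply(parts, `[[`, "interactions"))
  mirnas <- do.call(rbind, lapply(parts, `[[`, "mirnas"))

  first <- match(mirnas$mirna_id, mirnas$mirna_id)
  conflict <- mirnas$mature_sequence != mirnas$mature_sequence[first]
  if (any(conflict)) {
    mirem_stop(sprintf("conflicting mature sequences across databases for %s",
                       paste(unique(mirnas$mirna_id[conflict]), collapse = ", ")),
               "mirem_validation_error")
  }
  cons <- tapply(mirnas$conserved, mirnas$mirna_id, max)
  mirnas <- mirnas[!duplicated(mirnas$mirna_id), ]
  mirnas$conserved <- as.integer(cons[mirnas$mirna_id])
  mirnas <- mirnas[order(mirnas$mirna_id), ]
  rownames(mirnas) <- NULL
  rownames(interactions) <- NULL

  structure(list(interactions = interactions, mirnas = mirnas,
                 databases = names(db_paths)),
            class = "mirem_compendium")
}

#' @export
print.mirem_compendium <- function(x, ...) {
  cat(sprintf("mirem compendium: %d databases (%s), %d miRNAs, %d interaction rows\n",
              length(x$databases), paste(x$databases, collapse = ", "),
              nrow(x$mirnas), nrow(x$interactions)))
  invisible(x)
}

#' Build the selected view of the compendium (observed matrix Y)
#'
#' A `(miRNA, gene)` pair survives when it appears in at least
#' `min_db_count` distinct selected databases (`min_db_count = 1` is the
#' plain union; `min_db_count = length(selected_dbs)` the full
#' intersection).  With `conserved_only = TRUE`, rows flagged
#' non-conserved are removed before counting, which prunes only the
#' databases that annotate conservation (others carry 1 throughout).
#' Votes are counted per database, not per row, so a database listing a
#' pair twice contributes one vote.
#'
#' @param compendium A `mirem_compendium`.
#' @param selected_dbs Databases to consult (default: all loaded).
#' @param min_db_count Minimum number of distinct databases a pair must
#'   appear in, between 1 and `length(selected_dbs)`.
#' @param conserved_only Restrict to conserved interactions first.
#' @return An object of class `mirem_view` with `interactions` (the
#'   surviving pairs), `universe` (all genes with a surviving
#'   interaction), `candidate_mirnas`, the corresponding `mirnas`
#'   records, and a `selection` record echoing the arguments.
#' @export
build_view <- function(compendium, selected_dbs = compendium$databases,
                       min_db_count = 1L, conserved_only = FALSE) {
  if (length(selected_dbs) == 0L || !all(selected_dbs %in% compendium$databases)) {
    mirem_stop("selected_dbs must be a non-empty subset of the loaded databases",
               "mirem_validation_error")
  }
  min_db_count <- as.integer(min_db_count)
  if (is.na(min_db_count) || min_db_count < 1L ||
      min_db_count > length(selected_dbs)) {
    mirem_stop(sprintf("min_db_count must lie in [1, %d]", length(selected_dbs)),
               "mirem_validation_error")
  }

  ints <- compendium$interactions
  ints <- ints[ints$source_db %in% selected_dbs, , drop = FALSE]
  if (isTRUE(conserved_only)) {
    ints <- ints[ints$conserved == 1L, , drop = FALSE]
  }
  pairs <- data.frame(mirna_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ints) > 0L) {
    key <- paste(ints$mirna_id, ints$gene_id, sep = "\r")
    dbkey <- paste(key, ints$source_db, sep = "\r")
    uniq <- !duplicated(dbkey)
    ukey <- key[uniq]
    f <- factor(ukey)
    votes <- tabulate(f, nbins = nlevels(f))
    surviving <- levels(f)[votes >= min_db_count]
    firsts <- uniq & !duplicated(key)
    sel <- key[firsts] %in% surviving
    pairs <- ints[firsts, c("mirna_id", "gene_id")][sel, , drop = FALSE]
    pairs <- pairs[order(pairs$mirna_id, pairs$gene_id), ]
    rownames(pairs) <- NULL
  }
  cand <- unique(pairs$mirna_id)
  mirnas <- compendium$mirnas[compendium$mirnas$mirna_id %in% cand, , drop = FALSE]
  rownames(mirnas) <- NULL
  structure(list(interactions = pairs,
                 universe = sort(unique(pairs$gene_id)),
                 candidate_mirnas = sort(cand),
                 mirnas = mirnas,
                 selection = list(databases = sort(selected_dbs),
                                  min_db_count = min_db_count,
                                  conserved_only = isTRUE(conserved_only))),
            class = "mirem_view")
}

#' @export
print.mirem_view <- function(x, ...) {
  cat(sprintf("mirem view: %d interactions, %d genes, %d miRNAs (dbs: %s; min_db_count=%d; conserved_only=%s)\n",
              nrow(x$interactions), length(x$universe), length(x$candidate_mirnas),
              paste(x$selection$databases, collapse = ","),
              x$selection$min_db_count, x$selection$conserved_only))
  invisible(x)
}
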