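# Presence / position stores and reference catalog.
#
# The index is the server-side data structure: every reference is split into
# non-overlapping k-mers and each k-mer is recorded in
#   * the presence store:  k-mer code        -> sorted reference ids
#   * the position store: (k-mer code, ref)  -> sorted 0-based in-phase positions
# together with a catalog row per reference (description, source, length,
# indexed k-mer count).  Stores are environment-backed hash maps keyed by the
# decimal form of the packed code; `save_index()` serializes them canonically
# to a plain-text bundle directory.

new_kv <- function() new.env(parent = emptyenv(), hash = TRUE)

#' Create an empty k-mer index
#'
#' @param k k-mer length used for the non-overlapping decomposition of the
#'   references.  Fixed at build time: queries against a bundle must use the
#'   same k, and [load_index()] restores it from the bundle header.
#' @return An object of class `tapir_index`.
#' @export
new_index <- function(k = 16L) {
  structure(
    list(k = as.integer(k),
         presence = new_kv(),    # key: code        -> character ref_ids (sorted)
         positions = new_kv(),   # key: code \r ref -> integer positions (sorted)
         sequences = new_kv(),   # ref_id -> sequence (kept for retrieval/mapping)
         catalog = new_kv()),    # ref_id -> list(record)
    class = "tapir_index")
}

pos_key <- function(code_key, ref_id) paste0(code_key, "\r", ref_id)

#' @export
print.tapir_index <- function(x, ...) {
  cat(sprintf("tapir_index: k = %d, %d references, %d distinct k-mers\n",
              x$k, length(ls(x$catalog)), length(ls(x$presence))))
  invisible(x)
}

# Normalize reference input to a named character vector of sequences.
# Accepts: path(s) to (gzipped) FASTA, a DNAStringSet, or a named character
# vector.  Record id = first whitespace-delimited token of the header.
read_references <- function(references) {
  if (is.character(references) && is.null(names(references))) {
    missing <- references[!file.exists(references)]
    if (length(missing))
      stop("FASTA file(s) not found: ", paste(missing, collapse = ", "))
    sets <- lapply(references, function(f) {
      set <- tryCatch(Biostrings::readDNAStringSet(f),
                      error = function(e) stop("unparseable FASTA '", f, "': ",
                                               conditionMessage(e), call. = FALSE))
      if (length(set) == 0L) stop("no parseable FASTA record in '", f, "'")
      set
    })
    set <- do.call(c, sets)
    seqs <- as.character(set)
    names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
    descs <- names(set)
  } else if (methods::is(references, "DNAStringSet")) {
    seqs <- as.character(references)
    descs <- names(references)
    names(seqs) <- vapply(strsplit(descs, "[ \t]+"), `[`, "", 1L)
  } else if (is.character(references)) {
    seqs <- references
    descs <- names(references)
  } else {
    stop("references must be FASTA path(s), a DNAStringSet, or a named character vector")
  }
  if (any(names(seqs) == "" | is.na(names(seqs))))
    stop("every reference must have an id (first header token)")
  attr(seqs, "descriptions") <- descs
  seqs
}

#' Build a k-mer index from reference sequences
#'
#' Splits each reference into non-overlapping k-mers ([nonoverlapping_kmers()])
#' and populates the presence store, the position store and the catalog.
#' Building is idempotent: two builds from the same input produce identical
#' stores.  References are indexed on the forward strand only; reverse
#' complements are handled at query time.
#'
#' @param references Path(s) to multi-record FASTA (plain or gzipped), a
#'   `Biostrings::DNAStringSet`, or a named character vector of sequences.
#' @param k k-mer length (default 16).
#' @param source Provenance label stored in the catalog.
#' @return A `tapir_index`.
#' @export
build_index <- function(references, k = 16L, source = "local") {
  index_add(new_index(k), references, source = source)
}

#' Add references to an existing index (incremental indexing)
#'
#' @param index A `tapir_index`.
#' @param references As in [build_index()].
#' @param source Provenance label.
#' @return The index, invisibly (stores are updated by reference).
#' @export
index_add <- function(index, references, source = "local") {
  stopifnot(inherits(index, "tapir_index"))
  seqs <- read_references(references)
  descs <- attr(seqs, "descriptions")
  if (is.null(descs)) descs <- names(seqs)
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference id: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  k <- index$k
  for (i in seq_along(seqs)) {
    ref_id <- names(seqs)[i]
    if (!is.null(index$catalog[[ref_id]]))
      stop("duplicate reference id: ", ref_id)
    seq <- toupper(seqs[[i]])
    km <- nonoverlapping_kmers(seq, k)
    keys <- kmer_key(km$code)
    for (key in unique(keys)) {
      refs <- index$presence[[key]]
      index$presence[[key]] <- if (is.null(refs)) ref_id else sort(c(refs, ref_id))
    }
    pos_by_key <- split(km$pos, keys)
    for (key in names(pos_by_key)) {
      index$positions[[pos_key(key, ref_id)]] <- sort(as.integer(pos_by_key[[key]]))
    }
    index$sequences[[ref_id]] <- seq
    index$catalog[[ref_id]] <- list(
      ref_id = ref_id,
      description = descs[i],
      source = source,
      length = nchar(seq),
      indexed_kmer_count = nchar(seq) %/% k)
  }
  invisible(index)
}

#' Look up the references containing a k-mer
#'
#' @param index A `tapir_index`.
#' @param code Numeric k-mer code.
#' @return Sorted character vector of reference ids; empty when the k-mer is
#'   absent (this is not an error).
#' @export
lookup_presence <- function(index, code) {
  refs <- index$presence[[kmer_key(code)]]
  if (is.null(refs)) character(0) else refs
}

#' Look up the in-phase positions of a k-mer in one reference
#'
#' @param index A `tapir_index`.
#' @param code Numeric k-mer code.
#' @param ref_id Reference id.
#' @return Strictly increasing integer vector of 0-based positions, all
#'   multiples of k; empty when the pair is absent.
#' @export
lookup_positions <- function(index, code, ref_id) {
  pos <- index$positions[[pos_key(kmer_key(code), ref_id)]]
  if (is.null(pos)) integer(0) else pos
}

#' Reference catalog as a data frame
#'
#' @param index A `tapir_index`.
#' @return Data frame with one row per reference: `ref_id`, `description`,
#'   `source`, `length`, `indexed_kmer_count`, ordered by `ref_id`.
#' @export
index_catalog <- function(index) {
  ids <- sort(ls(index$catalog))
  recs <- lapply(ids, function(id) index$catalog[[id]])
  data.frame(
    ref_id = ids,
    description = vapply(recs, `[[`, "", "description"),
    source = vapply(recs, `[[`, "", "source"),
    length = vapply(recs, `[[`, 0L, "length"),
    indexed_kmer_count = vapply(recs, `[[`, 0L, "indexed_kmer_count"),
    row.names = NULL)
}

#' Retrieve one reference record (with sequence) from an index
#'
#' @param index A `tapir_index`.
#' @param ref_id Reference id.
#' @return A list `(ref_id, description, source, length, sequence)`.
#' @export
index_reference <- function(index, ref_id) {
  rec <- index$catalog[[ref_id]]
  if (is.null(rec))
    stop(structure(class = c("tapir_not_found", "error", "condition"),
                   list(message = paste0("unknown reference id: ", ref_id),
                        call = NULL)))
  rec$sequence <- index$sequences[[ref_id]]
  rec
}

# ---- on-disk bundle -------------------------------------------------------

#' Serialize an index to an on-disk bundle directory
#'
#' Writes `presence.tsv`, `positions.tsv`, `catalog.tsv`, `refs.fasta` and
#' `meta.json` in a canonical order (keys sorted numerically), so two builds
#' from the same input serialize byte-identically apart from the timestamp in
#' `meta.json`.
#'
#' @param index A `tapir_index`.
#' @param dir Output directory (created if needed).
#' @param build_time Timestamp recorded in `meta.json`; pass a fixed string
#'   for fully reproducible bundles.
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir, build_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- index_catalog(index)

  keys <- ls(index$presence)
  keys <- keys[order(as.numeric(keys))]
  presence_lines <- vapply(keys, function(key)
    paste0(key, "\t", paste(index$presence[[key]], collapse = ",")), "")
  writeLines(presence_lines, file.path(dir, "presence.tsv"))

  pos_keys <- ls(index$positions)
  parts <- strsplit(pos_keys, "\r", fixed = TRUE)
  pk_code <- vapply(parts, `[`, "", 1L)
  pk_ref <- vapply(parts, `[`, "", 2L)
  ord <- order(as.numeric(pk_code), pk_ref)
  position_lines <- vapply(ord, function(i)
    paste0(pk_code[i], "\t", pk_ref[i], "\t",
           paste(index$positions[[pos_keys[i]]], collapse = ",")), "")
  writeLines(position_lines, file.path(dir, "positions.tsv"))

  utils::write.table(cat_df, file.path(dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  seqs <- Biostrings::DNAStringSet(vapply(cat_df$ref_id, function(id)
    index$sequences[[id]], ""))
  names(seqs) <- cat_df$ref_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "refs.fasta"), width = 60L)

  meta <- list(format = "tapir-bundle-v1", k = index$k,
               build_time = build_time,
               n_references = nrow(cat_df),
               total_bases = sum(cat_df$length))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load an index bundle written by [save_index()]
#'
#' @param dir Bundle directory.
#' @return A `tapir_index` with the k recorded in the bundle header.
#' @export
load_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (!identical(meta$format, "tapir-bundle-v1"))
    stop("not a tapir index bundle: ", dir)
  index <- new_index(meta$k)

  pres <- readLines(file.path(dir, "presence.tsv"))
  for (line in pres) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    index$presence[[f[1L]]] <- strsplit(f[2L], ",", fixed = TRUE)[[1L]]
  }
  pos <- readLines(file.path(dir, "positions.tsv"))
  for (line in pos) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    index$positions[[pos_key(f[1L], f[2L])]] <-
      as.integer(strsplit(f[3L], ",", fixed = TRUE)[[1L]])
  }
  cat_df <- utils::read.table(file.path(dir, "catalog.tsv"), sep = "\t",
                              header = TRUE, colClasses = "character")
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "refs.fasta"))
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, "", 1L)
  for (i in seq_len(nrow(cat_df))) {
    id <- cat_df$ref_id[i]
    index$catalog[[id]] <- list(
      ref_id = id, description = cat_df$description[i],
      source = cat_df$source[i], length = as.integer(cat_df$length[i]),
      indexed_kmer_count = as.integer(cat_df$indexed_kmer_count[i]))
    index$sequences[[id]] <- as.character(seqs[[id]])
  }
  index
}
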